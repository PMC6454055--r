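#' @include simulate.R
NULL

.writeRunMetadata <- function(outDir, stage, params) {
  yaml::write_yaml(c(list(stage = stage,
                          version = as.character(
                            packageVersion("poolSweeps"))),
                     params),
                   file.path(outDir, paste0(stage, "_metadata.yaml")))
}

#' Pipeline stage: simulate a dataset
#'
#' Generates a full synthetic dataset and writes it in both dialects
#' (VCF and sync), together with the truth BED and a config echo.
#'
#' @param config A [SweepSimConfig-class].
#' @param outDir output directory (created if needed).
#' @param seed overrides `config@seed` when given.
#' @return list with the simulated `snps`, `truth`, and output `paths`,
#'   invisibly.
#' @export
runSimulate <- function(config = sweepSimConfig(), outDir,
                        seed = config@seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateSweepData(config, seed)
  paths <- list(vcf = file.path(outDir, "simulated.vcf"),
                sync = file.path(outDir, "simulated.sync"),
                truth = file.path(outDir, "truth.bed"),
                config = file.path(outDir, "config_echo.yaml"))
  writePoolVcf(sim$snps, paths$vcf)
  writeSync(sim$snps, paths$sync)
  writeRegionsBed(sim$truth, paths$truth)
  cfg <- config
  cfg@seed <- as.integer(seed)
  writeConfigEcho(cfg, paths$config)
  .writeRunMetadata(outDir, "simulate", list(seed = as.integer(seed)))
  invisible(c(sim, list(paths = paths)))
}

#' Pipeline stage: filter a variant table
#'
#' Reads a callset (VCF or snp-table TSV), applies the SNP hard filter
#' and the site filters, writes the surviving records as a snp-table
#' and a per-clause removal report. Rerunning on its own output removes
#' nothing further.
#'
#' @param input path to a VCF or a [writeSnpTable()] TSV, or a
#'   [PoolSnpSet-class].
#' @param outDir output directory.
#' @param poolSizes named pool sizes (required for VCF input).
#' @param wildSamples wild sample names (VCF input).
#' @param thresholds A [FilterThresholds-class].
#' @return list with the filtered `snps`, the `report` data.frame of
#'   per-clause removal counts, and output `paths`, invisibly.
#' @export
runFilter <- function(input, outDir, poolSizes = NULL,
                      wildSamples = character(),
                      thresholds = filterThresholds()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  x <- if (is(input, "PoolSnpSet")) input
  else if (grepl("\\.vcf(\\.gz)?$", input, ignore.case = TRUE)) {
    if (is.null(poolSizes)) stop("poolSizes required for VCF input")
    readVcfPools(input, poolSizes, wildSamples)
  } else readSnpTable(input)

  nIn <- length(x)
  if (nIn) {
    hardFlags <- snpHardFilterFlags(x, thresholds)
    x1 <- x[!apply(hardFlags, 1L, any)]
    siteFlags <- if (length(x1)) siteFilterFlags(x1, thresholds)
    else matrix(FALSE, 0L, 3L,
                dimnames = list(NULL, c("maf", "missing", "coverage")))
    x2 <- if (length(x1)) x1[!apply(siteFlags, 1L, any)] else x1
    report <- data.frame(
      clause = c(colnames(hardFlags), colnames(siteFlags)),
      stage = c(rep("hard", ncol(hardFlags)),
                rep("site", ncol(siteFlags))),
      nViolating = c(colSums(hardFlags), colSums(siteFlags)))
  } else {
    x2 <- x
    report <- data.frame(clause = character(), stage = character(),
                         nViolating = integer())
  }
  paths <- list(table = file.path(outDir, "filtered_snps.tsv"),
                report = file.path(outDir, "filter_report.tsv"))
  writeSnpTable(x2, paths$table)
  write.table(report, paths$report, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .writeRunMetadata(outDir, "filter",
                    list(nInput = nIn, nSurviving = length(x2)))
  invisible(list(snps = x2, report = report, paths = paths))
}

#' Pipeline stage: windowed scan and region calling
#'
#' Runs [scanGenome()], applies the dual top-quantile selection, merges
#' significant windows into regions, and writes the per-window TSV, the
#' region BED/TSV and a threshold report.
#'
#' @param input a [PoolSnpSet-class] or path to a snp-table TSV.
#' @param chromLengths named chromosome lengths (bp).
#' @param outDir output directory.
#' @param quantile tail mass of the selection rule.
#' @param ... passed to [scanGenome()] (`focalPools`, `background`,
#'   `windowSize`, `step`, `minSnps`, `estimator`, ...).
#' @return list with the `scan`, `selected` windows, `regions`, and
#'   output `paths`, invisibly.
#' @export
runScan <- function(input, chromLengths, outDir, quantile = 0.01, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  x <- if (is(input, "PoolSnpSet")) input else readSnpTable(input)
  scan <- scanGenome(x, chromLengths, ...)
  selected <- selectWindows(scan, quantile)
  regions <- mergeWindows(selected)

  w <- scanWindows(scan)
  winDf <- data.frame(chrom = as.character(seqnames(w)),
                      start = start(w) - 1L, end = end(w),
                      nSnps = w$nSnps,
                      hp_focal = w$hpFocal,
                      hp_background = w$hpBackground,
                      fst = w$fst, z_hp = w$zHp, z_fst = w$zFst)
  paths <- list(windows = file.path(outDir, "windows.tsv"),
                regionsBed = file.path(outDir, "regions.bed"),
                regionsTsv = file.path(outDir, "regions.tsv"),
                thresholds = file.path(outDir, "threshold_report.txt"))
  write.table(winDf, paths$windows, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeRegionsBed(regions, paths$regionsBed)
  regDf <- data.frame(chrom = as.character(seqnames(regions)),
                      start = start(regions) - 1L, end = end(regions),
                      nWindows = regions$nWindows,
                      meanFst = regions$meanFst, minHp = regions$minHp)
  write.table(regDf, paths$regionsTsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  z <- zStats(scan)
  md <- metadata(selected)
  writeLines(c(
    sprintf("comparison: %s", scan@comparison),
    sprintf("estimator: %s", scan@estimator),
    sprintf("windows retained: %d (discarded: %d)",
            length(w), scan@nDiscarded),
    sprintf("Fst: mu=%.6f sigma=%.6f", z$fst[["mu"]], z$fst[["sigma"]]),
    sprintf("Hp:  mu=%.6f sigma=%.6f", z$hp[["mu"]], z$hp[["sigma"]]),
    sprintf("selection quantile: %g", md$quantile),
    sprintf("Fst cutoff: %.6f (Z >= %.4f)", md$fstThreshold,
            md$zFstThreshold),
    sprintf("Hp cutoff: %.6f (Z <= %.4f)", md$hpThreshold,
            md$zHpThreshold),
    sprintf("selected windows: %d", length(selected)),
    sprintf("regions: %d (total length %.3f Mb)", length(regions),
            sum(width(regions)) / 1e6)), paths$thresholds)
  .writeRunMetadata(outDir, "scan",
                    list(comparison = scan@comparison,
                         quantile = quantile,
                         nRetained = length(w),
                         nSelected = length(selected),
                         nRegions = length(regions)))
  invisible(list(scan = scan, selected = selected, regions = regions,
                 paths = paths))
}

#' Pipeline stage: annotate candidate regions
#'
#' Maps regions to candidate genes (overlap, else nearest), and
#' optionally writes per-group allele-frequency tables at candidate
#' sites and domain-membership calls for coding changes.
#'
#' @param regions region `GRanges`, or path to a BED file of regions.
#' @param genes gene `GRanges` with `gene_id`, or path readable by
#'   [readGeneModels()].
#' @param outDir output directory.
#' @param snps optional [PoolSnpSet-class] for frequency tables.
#' @param candidateSites optional `GRanges`/"chrom:pos" sites to
#'   tabulate.
#' @param codingChanges optional data.frame with columns `gene_id`,
#'   `cds` (coding sequence), `cdsPos`, `altBase`; each row is
#'   annotated with [annotateCodingChange()].
#' @param domains optional data.frame (`name`, `start_aa`, `end_aa`)
#'   for [domainMembership()] of each coding change.
#' @return list with `genes` (the region-gene table), optional
#'   `frequencies` and `coding`, and output `paths`, invisibly.
#' @export
runAnnotate <- function(regions, genes, outDir, snps = NULL,
                        candidateSites = NULL, codingChanges = NULL,
                        domains = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(regions)) {
    df <- tryCatch(read.table(regions, sep = "\t",
                              stringsAsFactors = FALSE),
                   error = function(e) NULL)
    regions <- if (is.null(df)) GRanges()
    else GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
  }
  if (is.character(genes)) genes <- readGeneModels(genes)
  geneTab <- annotateRegions(regions, genes)
  paths <- list(genes = file.path(outDir, "candidate_genes.tsv"))
  write.table(geneTab, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- list(genes = geneTab)

  if (!is.null(snps) && !is.null(candidateSites)) {
    freqTab <- alleleFrequencyTable(snps, candidateSites)
    paths$frequencies <- file.path(outDir, "allele_frequencies.tsv")
    write.table(freqTab, paths$frequencies, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$frequencies <- freqTab
  }
  if (!is.null(codingChanges) && nrow(codingChanges)) {
    cc <- do.call(rbind, lapply(seq_len(nrow(codingChanges)),
      function(i) {
        row <- annotateCodingChange(codingChanges$cds[i],
                                    codingChanges$cdsPos[i],
                                    codingChanges$altBase[i])
        row$gene_id <- codingChanges$gene_id[i]
        row$domains <- if (is.null(domains)) NA_character_
        else paste(domainMembership(row$codonIndex, domains),
                   collapse = ",")
        row
      }))
    paths$coding <- file.path(outDir, "coding_changes.tsv")
    write.table(cc, paths$coding, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$coding <- cc
  }
  .writeRunMetadata(outDir, "annotate",
                    list(nRegions = length(regions),
                         nGenes = length(genes)))
  invisible(c(out, list(paths = paths)))
}
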