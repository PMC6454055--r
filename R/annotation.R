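#' @include sweep-detection.R
NULL

#' Read gene models from BED or a minimal GFF-like TSV
#'
#' BED input (0-based half-open; detected by extension `.bed`) is read
#' with `rtracklayer` when available, otherwise by column position.
#' Anything else is treated as a header-bearing TSV with columns
#' `gene_id`, `chrom`, `start`, `end` (1-based inclusive) and optional
#' `strand`.
#'
#' @param path annotation file path.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
readGeneModels <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path, format = "BED")
      gr$gene_id <- if (!is.null(gr$name)) gr$name
      else sprintf("gene%03d", seq_along(gr))
      return(gr[, "gene_id"])
    }
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
    gr$gene_id <- if (ncol(df) >= 4L) df[[4L]]
    else sprintf("gene%03d", seq_along(gr))
    return(gr)
  }
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                strand = if ("strand" %in% colnames(df)) df$strand
                else "*")
  gr$gene_id <- df$gene_id
  gr
}

#' Map candidate regions to genes
#'
#' Genes overlapping a region by at least 1 bp are its candidates. A
#' region overlapping no gene is assigned the nearest gene on the same
#' chromosome by edge distance (unbounded), flagged `nearest_only`;
#' distance ties report every tied gene.
#'
#' @param regions region `GRanges`.
#' @param genes gene `GRanges` with a `gene_id` metadata column.
#' @return data.frame with columns `chrom`, `regionStart`, `regionEnd`
#'   (1-based inclusive), `gene_id`, `overlap` (bp; 0 for nearest-only
#'   hits), `distance` (bp; 0 when overlapping) and `nearestOnly`.
#' @export
annotateRegions <- function(regions, genes) {
  empty <- data.frame(chrom = character(), regionStart = integer(),
                      regionEnd = integer(), gene_id = character(),
                      overlap = integer(), distance = integer(),
                      nearestOnly = logical())
  if (!length(regions)) return(empty)
  regions <- sort(regions)
  rows <- vector("list", length(regions))
  hits <- findOverlaps(regions, genes, ignore.strand = TRUE)
  for (i in seq_along(regions)) {
    gi <- subjectHits(hits)[queryHits(hits) == i]
    r <- regions[i]
    if (length(gi)) {
      ov <- width(pintersect(rep(r, length(gi)), genes[gi]))
      rows[[i]] <- data.frame(
        chrom = as.character(seqnames(r)),
        regionStart = start(r), regionEnd = end(r),
        gene_id = genes$gene_id[gi], overlap = ov,
        distance = 0L, nearestOnly = FALSE)
    } else {
      same <- which(as.character(seqnames(genes)) ==
                      as.character(seqnames(r)))
      if (!length(same)) { rows[[i]] <- empty; next }
      # gap in bp; book-ended neighbors are at distance 0
      d <- pmax(start(genes[same]) - end(r) - 1L,
                start(r) - end(genes[same]) - 1L, 0L)
      near <- same[d == min(d)]
      rows[[i]] <- data.frame(
        chrom = as.character(seqnames(r)),
        regionStart = start(r), regionEnd = end(r),
        gene_id = genes$gene_id[near], overlap = 0L,
        distance = min(d), nearestOnly = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Codon index of a CDS position
#'
#' 1-based coding-sequence position to 1-based codon index:
#' `ceiling(cdsPos / 3)`. The position within the codon is
#' `((cdsPos - 1) %% 3) + 1`.
#'
#' @param cdsPos integer vector of 1-based CDS positions.
#' @return Integer codon indices, with the within-codon positions
#'   attached as attribute `posInCodon`.
#' @examples
#' cdsToCodon(2284)  # codon 762
#' @export
cdsToCodon <- function(cdsPos) {
  if (any(cdsPos < 1)) stop("CDS positions are 1-based (>= 1)")
  out <- as.integer(ceiling(cdsPos / 3))
  attr(out, "posInCodon") <- as.integer(((cdsPos - 1) %% 3) + 1)
  out
}

#' Annotate a coding substitution
#'
#' Translates the affected codon before and after a single-base
#' substitution with the standard genetic code and classifies the
#' consequence, emitting HGVS-style `c.` and `p.` labels
#' (`c.<ref><pos><alt>` / `p.<refAA><codon><altAA>`).
#'
#' @param cdsSequence coding sequence (character or `DNAString`),
#'   length divisible by 3, transcript-strand oriented.
#' @param cdsPos 1-based position of the substituted base.
#' @param altBase replacement base (must differ from the reference
#'   base at `cdsPos`).
#' @return data.frame row with `cdsPos`, `refBase`, `altBase`,
#'   `codonIndex`, `refCodon`, `altCodon`, `refAa`, `altAa`,
#'   `consequence` (`synonymous`/`missense`/`nonsense`), `cNotation`,
#'   `pNotation`.
#' @examples
#' annotateCodingChange("ATGCTGTAA", 4, "A")  # p.L2M missense
#' @export
annotateCodingChange <- function(cdsSequence, cdsPos, altBase) {
  cds <- toupper(as.character(cdsSequence))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  if (cdsPos < 1 || cdsPos > nchar(cds))
    stop("cdsPos outside the CDS")
  altBase <- toupper(altBase)
  refBase <- substr(cds, cdsPos, cdsPos)
  if (refBase == altBase)
    stop("alternate base equals the reference base at this position")
  codon <- cdsToCodon(cdsPos)
  posIn <- attr(codon, "posInCodon")
  cstart <- (codon - 1L) * 3L + 1L
  refCodon <- substr(cds, cstart, cstart + 2L)
  altCodon <- refCodon
  substr(altCodon, posIn, posIn) <- altBase
  aa <- function(cod)
    as.character(translate(DNAString(cod), no.init.codon = TRUE))
  refAa <- aa(refCodon)
  altAa <- aa(altCodon)
  consequence <- if (refAa == altAa) "synonymous"
  else if (altAa == "*") "nonsense"
  else "missense"
  data.frame(cdsPos = cdsPos, refBase = refBase, altBase = altBase,
             codonIndex = as.integer(codon), refCodon = refCodon,
             altCodon = altCodon, refAa = refAa, altAa = altAa,
             consequence = consequence,
             cNotation = paste0("c.", refBase, cdsPos, altBase),
             pNotation = paste0("p.", refAa, codon, altAa),
             stringsAsFactors = FALSE)
}

#' Protein-domain membership of a codon
#'
#' @param codonIndex 1-based codon (amino-acid) index.
#' @param domains data.frame with columns `name`, `start_aa`, `end_aa`
#'   (1-based inclusive).
#' @return Character vector of domain names containing the codon
#'   (empty when none).
#' @examples
#' gaf <- data.frame(name = "GAF", start_aa = 71, end_aa = 310)
#' domainMembership(cdsToCodon(708), gaf)
#' @export
domainMembership <- function(codonIndex, domains) {
  stopifnot(all(domains$start_aa >= 1),
            all(domains$start_aa <= domains$end_aa))
  domains$name[domains$start_aa <= codonIndex &
                 codonIndex <= domains$end_aa]
}

#' Per-group allele-frequency table at candidate SNPs
#'
#' For each requested site and each group (every pool plus the wild
#' panel), reports the alternate-allele frequency (reads for pools,
#' dosage / 2n for wild individuals), the observation count (read
#' depth or chromosomes), and whether the group is fixed (frequency
#' exactly 0 or 1). Sites absent from the callset yield missing-value
#' rows with a warning.
#'
#' @param x A [PoolSnpSet-class].
#' @param at `GRanges` of positions, or a character vector of
#'   `"chrom:pos"` labels.
#' @return data.frame with one row per site x group: `chrom`, `pos`,
#'   `ref`, `alt`, `group`, `altFreq`, `n`, `state`
#'   (`fixed`/`segregating`).
#' @export
alleleFrequencyTable <- function(x, at) {
  if (is.character(at)) {
    sp <- strsplit(at, ":", fixed = TRUE)
    at <- GRanges(vapply(sp, `[`, "", 1L),
                  IRanges(as.integer(vapply(sp, `[`, "", 2L)),
                          width = 1L))
  }
  s <- sites(x)
  key <- paste(as.character(seqnames(s)), start(s))
  want <- paste(as.character(seqnames(at)), start(at))
  idx <- match(want, key)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " site(s) absent from the callset")
  groups <- c(poolNames(x),
              if (ncol(wildGenotypes(x))) "wild")
  rows <- lapply(seq_along(want), function(i) {
    base <- data.frame(chrom = as.character(seqnames(at))[i],
                       pos = start(at)[i], stringsAsFactors = FALSE)
    if (is.na(idx[i])) {
      return(cbind(base, ref = NA_character_, alt = NA_character_,
                   group = groups, altFreq = NA_real_, n = NA_real_,
                   state = NA_character_))
    }
    j <- idx[i]
    freqs <- vapply(groups, function(gp) {
      if (gp == "wild") {
        g <- wildGenotypes(x)[j, ]
        n <- 2 * sum(!is.na(g))
        c(if (n > 0) sum(g, na.rm = TRUE) / n else NA_real_, n)
      } else {
        d <- refCounts(x)[j, gp] + altCounts(x)[j, gp]
        c(if (d > 0) altCounts(x)[j, gp] / d else NA_real_, d)
      }
    }, numeric(2))
    cbind(base, ref = s$ref[j], alt = s$alt[j], group = groups,
          altFreq = freqs[1L, ], n = freqs[2L, ],
          state = ifelse(is.na(freqs[1L, ]), NA_character_,
                         ifelse(freqs[1L, ] %in% c(0, 1),
                                "fixed", "segregating")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
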