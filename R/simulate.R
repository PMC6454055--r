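#' @include annotation.R
NULL

## Deterministic per-stage substream of one global seed.
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 97 * stage) %% 2147483647)
}

.defaultSweeps <- function() {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(start = c(22500001L, 60000001L, 37500001L),
                        end = c(22950000L, 60450000L, 37950000L)))
  gr$s <- c(1, 1, 1)
  gr
}

#' Configure the pool-seq sweep simulator
#'
#' Constructor for [SweepSimConfig-class]. The defaults describe the
#' package's reference scene: five breed pools of 80/89/50/58/61
#' diploid individuals sequenced at a mean 45x each, a 17-individual
#' wild diploid panel, SNPs at an expected density of one per 500 bp,
#' Beta(0.5, 0.5) ancestral frequencies, per-group Beta drift with
#' F = 0.23 (calibrated so the expected per-SNP Fst between two
#' independently drifted groups matches a genome-wide average of about
#' 0.23), and three planted 450-kb sweeps of intensity 1 whose
#' boundaries sit on the 75-kb window grid. The two 90-Mb chromosomes
#' give about 2,400 scan windows, so the 1% outlier capacity
#' (ceiling(0.01 x 2400) = 24 windows) exceeds the ~21 windows touched
#' by the planted sweeps - a detectability requirement of the dual
#' top-1% rule.
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param snpDensity expected SNPs per bp.
#' @param poolSizes named diploid pool sizes.
#' @param nWild wild diploid individuals.
#' @param meanDepth mean per-pool depth (Poisson).
#' @param ancestralShape symmetric Beta shape of ancestral frequencies.
#' @param driftF,wildDriftF Beta-drift variance coefficients.
#' @param sweeps `GRanges` of sweep intervals with intensity column
#'   `s`; `NULL` or empty for a neutral scene.
#' @param wildMissingRate per-genotype missing probability.
#' @param seed global seed fanned out to per-stage substreams.
#' @return A [SweepSimConfig-class].
#' @export
sweepSimConfig <- function(chromLengths = c(chr1 = 9e7, chr2 = 9e7),
                           snpDensity = 1 / 500,
                           poolSizes = c(Tibetan = 80L, Mongolian = 89L,
                                         Altay = 50L, Hu = 58L,
                                         Duolang = 61L),
                           nWild = 17L,
                           meanDepth = 45,
                           ancestralShape = 0.5,
                           driftF = 0.23, wildDriftF = 0.23,
                           sweeps = .defaultSweeps(),
                           wildMissingRate = 0.02,
                           seed = 1L) {
  if (is.null(sweeps)) {
    sweeps <- GRanges()
    sweeps$s <- numeric()
  }
  new("SweepSimConfig",
      chromLengths = chromLengths, snpDensity = snpDensity,
      poolSizes = setNames(as.integer(poolSizes), names(poolSizes)),
      nWild = as.integer(nWild), meanDepth = meanDepth,
      ancestralShape = ancestralShape,
      driftF = driftF, wildDriftF = wildDriftF,
      sweeps = sweeps, wildMissingRate = wildMissingRate,
      seed = as.integer(seed))
}

## Beta draw with mean f and variance F f(1-f); F = 0 degenerates to f.
.driftDraw <- function(f, F) {
  if (F == 0) return(f)
  k <- 1 / F - 1
  p <- rbeta(length(f), f * k, (1 - f) * k)
  pmin(pmax(p, 0), 1)
}

#' Simulate true allele frequencies with planted sweeps
#'
#' Draws SNP positions as a Poisson process at the configured density,
#' ancestral frequencies from the symmetric Beta law (truncated to the
#' open unit interval), and each group's frequency from a Beta
#' distribution with mean equal to the ancestral frequency f and
#' variance `F * f * (1 - f)`. Inside a sweep interval of intensity s,
#' every domestic pool's frequency is pulled toward the allele opposing
#' the wild major allele:
#' `f_pool <- (1 - s) * f_pool + s * (1 - [f_wild >= 0.5])`.
#'
#' @param config A [SweepSimConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return list with `sites` (`GRanges`), `ancestral`, `poolFreq`
#'   (matrix SNPs x pools), `wildFreq`, and `truth` (the sweep
#'   `GRanges`).
#' @export
simulateFrequencies <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(.stageSeed(seed, 1L))
  cl <- config@chromLengths
  pieces <- lapply(names(cl), function(chr) {
    len <- cl[[chr]]
    n <- rpois(1L, len * config@snpDensity)
    list(chrom = rep(chr, n), pos = sort(sample.int(as.integer(len), n)))
  })
  sitesGr <- GRanges(factor(unlist(lapply(pieces, `[[`, "chrom")),
                            levels = names(cl)),
                     IRanges(unlist(lapply(pieces, `[[`, "pos")),
                             width = 1L))
  n <- length(sitesGr)
  eps <- 1e-9
  anc <- pmin(pmax(rbeta(n, config@ancestralShape,
                         config@ancestralShape), eps), 1 - eps)
  pools <- names(config@poolSizes)
  poolFreq <- vapply(pools, function(p) .driftDraw(anc, config@driftF),
                     numeric(n))
  if (n == 1L) poolFreq <- matrix(poolFreq, 1L,
                                  dimnames = list(NULL, pools))
  wildFreq <- .driftDraw(anc, config@wildDriftF)

  sweeps <- config@sweeps
  if (length(sweeps)) {
    hit <- findOverlaps(sitesGr, sweeps)
    i <- queryHits(hit)
    if (length(i)) {
      s <- sweeps$s[subjectHits(hit)]
      target <- 1 - as.numeric(wildFreq[i] >= 0.5)
      poolFreq[i, ] <- (1 - s) * poolFreq[i, , drop = FALSE] +
        s * target
    }
  }
  list(sites = sitesGr, ancestral = anc, poolFreq = poolFreq,
       wildFreq = wildFreq, truth = sweeps)
}

#' Simulate pooled reads and wild genotypes from true frequencies
#'
#' Per SNP and pool, read depth is Poisson(`meanDepth`) and alternate
#' reads are Binomial(depth, pool frequency); each wild individual's
#' dosage is Binomial(2, wild frequency), set missing with probability
#' `wildMissingRate`. Random ref/alt alleles and passing-range quality
#' annotations (QUAL, QD, FS, ReadPosRankSum) are attached so the
#' records flow through the variant filters.
#'
#' @param freqs output of [simulateFrequencies()].
#' @param config the same [SweepSimConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return A [PoolSnpSet-class].
#' @export
simulateObservations <- function(freqs, config, seed = config@seed) {
  set.seed(.stageSeed(seed, 2L))
  n <- length(freqs$sites)
  pools <- names(config@poolSizes)
  nPool <- length(pools)
  depth <- matrix(rpois(n * nPool, config@meanDepth), n, nPool,
                  dimnames = list(NULL, pools))
  alt <- matrix(rbinom(n * nPool, as.vector(depth),
                       as.vector(freqs$poolFreq)), n, nPool,
                dimnames = list(NULL, pools))
  ref <- depth - alt

  nW <- config@nWild
  wild <- matrix(rbinom(n * nW, 2L, rep(freqs$wildFreq, nW)), n, nW,
                 dimnames = list(NULL, sprintf("wild%02d", seq_len(nW))))
  if (config@wildMissingRate > 0)
    wild[matrix(runif(n * nW) < config@wildMissingRate, n, nW)] <-
      NA_integer_

  bases <- c("A", "C", "G", "T")
  refAllele <- bases[sample.int(4L, n, replace = TRUE)]
  altAllele <- bases[1L + (match(refAllele, bases) - 1L +
                             sample.int(3L, n, replace = TRUE)) %% 4L]
  qual <- pmax(round(rnorm(n, 800, 120), 1), 30)
  info <- data.frame(QD = round(rnorm(n, 30, 3), 2),
                     FS = round(rexp(n, 1), 3),
                     ReadPosRankSum = round(rnorm(n, 0, 1.5), 3))

  g <- freqs$sites
  mcols(g) <- DataFrame(ref = refAllele, alt = altAllele)
  PoolSnpSet(g, ref, alt, config@poolSizes, wildGeno = wild,
             qual = qual, info = info)
}

#' Simulate a complete sweep-scan dataset
#'
#' Runs [simulateFrequencies()] then [simulateObservations()] from a
#' single global seed.
#'
#' @param config A [SweepSimConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return list with `snps` ([PoolSnpSet-class]), `truth` (sweep
#'   `GRanges`), and `freqs` (the true-frequency list).
#' @export
simulateSweepData <- function(config = sweepSimConfig(),
                              seed = config@seed) {
  freqs <- simulateFrequencies(config, seed)
  snps <- simulateObservations(freqs, config, seed)
  list(snps = snps, truth = freqs$truth, freqs = freqs)
}

#' Score sweep recovery against the planted truth
#'
#' Window-level confusion between reported regions and the planted
#' sweep intervals: sensitivity is the fraction of truth windows (grid
#' windows overlapping a sweep interval) overlapped by at least one
#' reported region; precision is the fraction of reported regions
#' overlapping a sweep interval (`NA` when nothing was reported).
#'
#' @param regions reported region `GRanges`.
#' @param truth planted sweep `GRanges`.
#' @param chromLengths named chromosome lengths of the scene.
#' @param windowSize,step the scan grid (defaults 150 kb / 75 kb).
#' @return list with `sensitivity`, `precision`, `nTruthWindows`,
#'   `nTruthWindowsCovered`, `nRegions`, `nRegionsOverlappingTruth`.
#' @export
recoveryReport <- function(regions, truth, chromLengths,
                           windowSize = 150000L, step = 75000L) {
  grid <- makeWindows(chromLengths, windowSize, step)
  truthWin <- grid[countOverlaps(grid, truth, ignore.strand = TRUE) > 0]
  covered <- countOverlaps(truthWin, regions, ignore.strand = TRUE) > 0
  nReg <- length(regions)
  regHit <- countOverlaps(regions, truth, ignore.strand = TRUE) > 0
  list(sensitivity = if (length(truthWin)) mean(covered) else NA_real_,
       precision = if (nReg) mean(regHit) else NA_real_,
       nTruthWindows = length(truthWin),
       nTruthWindowsCovered = sum(covered),
       nRegions = nReg,
       nRegionsOverlappingTruth = sum(regHit))
}

#' Write a config echo for provenance
#'
#' Serializes a [SweepSimConfig-class] as YAML-style key-value text.
#'
#' @param config A [SweepSimConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfigEcho <- function(config, path) {
  sw <- config@sweeps
  yaml::write_yaml(list(
    chromLengths = as.list(config@chromLengths),
    snpDensity = config@snpDensity,
    poolSizes = as.list(config@poolSizes),
    nWild = config@nWild,
    meanDepth = config@meanDepth,
    ancestralShape = config@ancestralShape,
    driftF = config@driftF,
    wildDriftF = config@wildDriftF,
    sweeps = if (length(sw)) data.frame(
      chrom = as.character(seqnames(sw)), start = start(sw) - 1L,
      end = end(sw), s = sw$s) else list(),
    wildMissingRate = config@wildMissingRate,
    seed = config@seed,
    version = as.character(packageVersion("poolSweeps"))), path)
  invisible(path)
}
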