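#' @include filters.R
NULL

#' Tile chromosomes into sliding windows
#'
#' Builds the fixed window grid of the scan: windows of `windowSize` bp
#' anchored at multiples of `step` from coordinate 0, the last window
#' truncated at the chromosome end. With the 150-kb/75-kb defaults every
#' interior base is covered by exactly two windows.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param windowSize,step window size and slide in bp (`step <=
#'   windowSize`).
#' @return Sorted `GRanges` of windows (1-based, inclusive ends), with
#'   `seqlengths` set.
#' @examples
#' makeWindows(c(chr1 = 300000))
#' @export
makeWindows <- function(chromLengths, windowSize = 150000L,
                        step = 75000L) {
  windowSize <- as.integer(windowSize)
  step <- as.integer(step)
  if (is.na(windowSize) || is.na(step) || windowSize <= 0L || step <= 0L)
    stop("windowSize and step must be positive")
  if (step > windowSize) stop("step must be <= windowSize")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  pieces <- lapply(names(chromLengths), function(chr) {
    len <- as.integer(chromLengths[[chr]])
    starts0 <- seq.int(0L, len - 1L, by = step) # 0-based window starts
    list(chrom = rep(chr, length(starts0)), start = starts0 + 1L,
         end = pmin(starts0 + windowSize, len))
  })
  gr <- GRanges(factor(unlist(lapply(pieces, `[[`, "chrom")),
                       levels = names(chromLengths)),
                IRanges(unlist(lapply(pieces, `[[`, "start")),
                        unlist(lapply(pieces, `[[`, "end"))))
  gr <- sort(gr)
  seqlengths(gr) <- chromLengths[seqlevels(gr)]
  gr
}

#' Assign SNPs to windows
#'
#' Maps each SNP (1-based position p) to every window whose 0-based
#' half-open span [s, e) contains p - 1; interior SNPs fall in exactly
#' two windows of the default grid. SNPs on chromosomes absent from the
#' grid are skipped with a warning.
#'
#' @param windows window `GRanges` from [makeWindows()].
#' @param x A [PoolSnpSet-class] or a `GRanges` of SNP positions.
#' @return A `Hits` object (query = SNP index, subject = window index).
#' @export
assignSnps <- function(windows, x) {
  pos <- if (is(x, "PoolSnpSet")) sites(x) else x
  unknown <- !(as.character(seqnames(pos)) %in%
                 as.character(unique(seqnames(windows))))
  if (any(unknown))
    warning(sum(unknown), " SNP(s) on chromosomes absent from the ",
            "window grid were skipped")
  # seqinfo mismatch is already reported above in our own terms
  suppressWarnings(findOverlaps(pos, windows, ignore.strand = TRUE))
}

#' Polarize read counts into major/minor alleles
#'
#' Within one pool, the major allele at a SNP is the one with more
#' reads; ties are resolved to the reference allele.
#'
#' @param refReads,altReads non-negative read-count vectors.
#' @return list with components `maj`, `min` (counts) and `refMajor`
#'   (logical: reference allele labeled major).
#' @export
polarizeMajorMinor <- function(refReads, altReads) {
  refMajor <- refReads >= altReads
  list(maj = pmax(refReads, altReads),
       min = pmin(refReads, altReads),
       refMajor = refMajor)
}

#' Pooled heterozygosity of one window
#'
#' `Hp = 2 * sum(nMaj) * sum(nMin) / (sum(nMaj) + sum(nMin))^2`, the
#' major/minor allele read counts summed over the member SNPs of a
#' window. Bounded by [0, 0.5], attaining 0.5 iff the summed major and
#' minor counts are equal.
#'
#' @param nMaj,nMin per-SNP major/minor allele counts of the member
#'   SNPs (see [polarizeMajorMinor()]).
#' @return Hp, or `NA` when the window has no reads.
#' @export
windowHp <- function(nMaj, nMin) {
  sMaj <- sum(nMaj)
  sMin <- sum(nMin)
  tot <- sMaj + sMin
  if (tot <= 0) return(NA_real_)
  2 * sMaj * sMin / tot^2
}

#' Per-SNP Fst variance components for two groups
#'
#' Computes the numerator and denominator of a two-population Fst
#' estimator at each SNP, to be combined over a window as a ratio of
#' averages ([windowFst()]). Sample sizes are in chromosomes: for a
#' sequencing pool, `min(read depth, 2 * pool individuals)`; for the
#' wild panel, twice the number of non-missing genotypes.
#'
#' `"wc"` is the Weir-Cockerham (1984) two-population theta in its
#' allele-count ANOVA form: with mean frequency `pbar`, among-group mean
#' square `MSP = n1 (p1-pbar)^2 + n2 (p2-pbar)^2`, within-group mean
#' square `MSG = (n1 p1 q1 + n2 p2 q2) / (n1 + n2 - 2)` and effective
#' size `nc = n - (n1^2 + n2^2)/n`, the variance components are
#' `a = (MSP - MSG) / nc` (among groups) and `b = MSG` (within), and
#' the per-SNP contribution is `a` over `a + b` — the multi-locus
#' combination Weir & Cockerham prescribe. `"hudson"` uses the Bhatia
#' et al. (2013) form: `(p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1)` over
#' `p1 q2 + p2 q1`.
#'
#' SNPs where either group lacks data (sample size < 2 chromosomes) or
#' where the denominator vanishes (both groups monomorphic for the same
#' allele) get components (0, 0) and drop out of the window ratio.
#'
#' @param p1,p2 alternate-allele frequencies in groups 1 and 2.
#' @param n1,n2 sample sizes in chromosomes.
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @return list of numeric vectors `num` and `den`.
#' @export
snpFstComponents <- function(p1, n1, p2, n2,
                             estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  num <- den <- numeric(length(p1))
  if (!any(ok)) return(list(num = num, den = den))
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  q1 <- 1 - p1; q2 <- 1 - p2
  if (estimator == "wc") {
    n <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / n
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * q1 + n2 * p2 * q2) / (n - 2)
    nc <- n - (n1^2 + n2^2) / n
    a <- (msp - msg) / nc
    b <- a + msg
  } else {
    a <- (p1 - p2)^2 - p1 * q1 / (n1 - 1) - p2 * q2 / (n2 - 1)
    b <- p1 * q2 + p2 * q1
  }
  zero <- b == 0
  a[zero] <- 0; b[zero] <- 0
  num[ok] <- a
  den[ok] <- b
  list(num = num, den = den)
}

#' Window Fst as a ratio of averages
#'
#' `sum(num) / sum(den)` over the member SNPs, clamped to [0, 1];
#' negative raw ratios are reported as 0 with the raw value attached as
#' attribute `raw`.
#'
#' @param num,den per-SNP components from [snpFstComponents()].
#' @return Window Fst, or `NA` when no member SNP has a positive
#'   denominator.
#' @export
windowFst <- function(num, den) {
  sd <- sum(den)
  if (sd <= 0) return(NA_real_)
  raw <- sum(num) / sd
  out <- min(max(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Discard windows with too few SNPs
#'
#' @param windows window `GRanges` carrying an `nSnps` metadata column.
#' @param minSnps minimum SNP count retained (inclusive).
#' @return The retained windows; the number discarded is attached as
#'   attribute `nDiscarded`.
#' @export
minSnpFilter <- function(windows, minSnps = 10L) {
  keep <- !is.na(windows$nSnps) & windows$nSnps >= minSnps
  out <- windows[keep]
  attr(out, "nDiscarded") <- sum(!keep)
  out
}

#' Z-transform a windowed statistic
#'
#' Standardizes `z = (x - mu) / sigma` against the genome-wide
#' distribution of the statistic over retained windows. By default mu
#' and sigma are the mean and sample (n-1) standard deviation of
#' `values`; either can be supplied to apply externally calibrated
#' constants.
#'
#' @param values numeric vector (>= 2 finite values unless both
#'   constants are supplied).
#' @param mu,sigma optional normalization constants.
#' @param sdType `"sample"` (n-1, default) or `"population"` (n).
#' @return list with `z` (scores), `mu`, `sigma`, `n`.
#' @export
zTransform <- function(values, mu = NULL, sigma = NULL,
                       sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  v <- values[is.finite(values)]
  n <- length(v)
  if (is.null(mu) || is.null(sigma)) {
    if (n < 2L) stop("need >= 2 finite values to estimate mu and sigma")
    if (is.null(mu)) mu <- mean(v)
    if (is.null(sigma)) {
      sigma <- stats::sd(v)
      if (sdType == "population") sigma <- sigma * sqrt((n - 1) / n)
    }
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0 (constant input?)")
  list(z = (values - mu) / sigma, mu = mu, sigma = sigma, n = n)
}

## Internal: per-group allele data at every SNP.
## Pools: frequency from reads, sample size min(depth, 2N).
## Wild: frequency from dosages, sample size 2 * non-missing.
.groupFreq <- function(x, group, pools = NULL) {
  if (identical(group, "wild")) {
    g <- wildGenotypes(x)
    if (!ncol(g)) stop("no wild genotypes in this PoolSnpSet")
    nChrom <- 2 * rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    list(p = ifelse(nChrom > 0, alt / nChrom, NA_real_),
         n = nChrom,
         refReads = nChrom - alt, altReads = alt)
  } else {
    if (is.null(pools)) pools <- poolNames(x)
    refR <- rowSums(refCounts(x)[, pools, drop = FALSE])
    altR <- rowSums(altCounts(x)[, pools, drop = FALSE])
    depth <- refR + altR
    list(p = ifelse(depth > 0, altR / depth, NA_real_),
         n = pmin(depth, 2 * sum(poolSizes(x)[pools])),
         refReads = refR, altReads = altR)
  }
}

#' Windowed Hp/Fst genome scan
#'
#' Runs the full windowed scan for one comparison: tiles the genome
#' ([makeWindows()]), assigns SNPs to windows, computes pooled
#' heterozygosity for the focal and background groups and the windowed
#' Fst between them (ratio of averages of [snpFstComponents()]),
#' discards windows with fewer than `minSnps` SNPs or without usable
#' data, and Z-transforms both statistics over the retained windows.
#'
#' @param x A filtered [PoolSnpSet-class].
#' @param chromLengths named chromosome lengths (bp).
#' @param focalPools pool names forming the focal group (reads are
#'   summed per SNP); default all pools.
#' @param background `"wild"` (the genotyped outgroup) or a character
#'   vector of pool names whose reads are summed.
#' @param windowSize,step grid parameters in bp.
#' @param minSnps minimum member SNPs for a window to be retained.
#' @param estimator Fst estimator, `"wc"` or `"hudson"`.
#' @param comparison optional label for the scan.
#' @return A [GenomeScan-class].
#' @export
scanGenome <- function(x, chromLengths,
                       focalPools = poolNames(x),
                       background = "wild",
                       windowSize = 150000L, step = 75000L,
                       minSnps = 10L,
                       estimator = c("wc", "hudson"),
                       comparison = NULL) {
  estimator <- match.arg(estimator)
  if (!all(focalPools %in% poolNames(x)))
    stop("unknown focal pool(s): ",
         paste(setdiff(focalPools, poolNames(x)), collapse = ", "))
  bgWild <- identical(background, "wild")
  if (!bgWild) {
    if (!all(background %in% poolNames(x)))
      stop("unknown background pool(s): ",
           paste(setdiff(background, poolNames(x)), collapse = ", "))
    if (length(intersect(focalPools, background)))
      stop("focal pool(s) must not appear in the background")
  }
  if (is.null(comparison))
    comparison <- paste0(paste(focalPools, collapse = "+"), "_vs_",
                         if (bgWild) "wild"
                         else paste(background, collapse = "+"))

  windows <- makeWindows(chromLengths, windowSize, step)
  hits <- assignSnps(windows, x)
  qh <- queryHits(hits)
  sh <- subjectHits(hits)
  nWin <- length(windows)

  foc <- .groupFreq(x, "pools", pools = focalPools)
  bg <- if (bgWild) .groupFreq(x, "wild")
  else .groupFreq(x, "pools", pools = background)

  comp <- snpFstComponents(foc$p, foc$n, bg$p, bg$n, estimator)
  polF <- polarizeMajorMinor(foc$refReads, foc$altReads)
  polB <- polarizeMajorMinor(bg$refReads, bg$altReads)

  sumBy <- function(v) {
    out <- numeric(nWin)
    agg <- rowsum(v[qh], sh)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    out
  }
  nSnps <- tabulate(sh, nbins = nWin)
  majF <- sumBy(polF$maj); minF <- sumBy(polF$min)
  majB <- sumBy(polB$maj); minB <- sumBy(polB$min)
  num <- sumBy(comp$num); den <- sumBy(comp$den)

  hpOf <- function(maj, mn) {
    tot <- maj + mn
    ifelse(tot > 0, 2 * maj * mn / tot^2, NA_real_)
  }
  hpF <- hpOf(majF, minF)
  hpB <- hpOf(majB, minB)
  rawFst <- ifelse(den > 0, num / den, NA_real_)
  fst <- pmin(pmax(rawFst, 0), 1)

  mcols(windows) <- DataFrame(nSnps = nSnps, hpFocal = hpF,
                              hpBackground = hpB, fst = fst,
                              rawFst = rawFst)
  keep <- nSnps >= minSnps & !is.na(hpF) & !is.na(fst)
  retained <- windows[keep]
  nDiscarded <- sum(!keep)
  if (length(retained) < 2L)
    stop("fewer than 2 retained windows; cannot Z-transform")
  zf <- zTransform(retained$fst)
  zh <- zTransform(retained$hpFocal)
  retained$zFst <- zf$z
  retained$zHp <- zh$z

  new("GenomeScan",
      windows = retained,
      zstats = list(
        fst = c(mu = zf$mu, sigma = zf$sigma, n = zf$n),
        hp = c(mu = zh$mu, sigma = zh$sigma, n = zh$n)),
      comparison = comparison,
      estimator = estimator,
      windowSize = as.integer(windowSize),
      step = as.integer(step),
      minSnps = as.integer(minSnps),
      nDiscarded = as.integer(nDiscarded))
}
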