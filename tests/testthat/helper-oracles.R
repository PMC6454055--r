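## Independent brute-force oracles, transcribed directly from the
## defining formulas. Deliberately scalar and literal; they must never
## call the package's own statistic implementations.

## Pooled heterozygosity of one window from per-SNP major/minor counts.
oracle_hp <- function(maj, mn) {
  A <- 0; B <- 0
  for (i in seq_along(maj)) {
    A <- A + maj[i]
    B <- B + mn[i]
  }
  if (A + B == 0) return(NA_real_)
  (2 * A * B) / (A + B)^2
}

## Weir & Cockerham (1984) two-population theta, allele-count ANOVA,
## one SNP: returns the among-group (a) and within-group (b) variance
## components so that theta = a / (a + b). Built stepwise from the
## sums of squares.
oracle_wc_components <- function(p1, n1, p2, n2) {
  if (is.na(p1) || is.na(p2) || n1 < 2 || n2 < 2) return(c(a = 0, ab = 0))
  r <- 2
  ntot <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / ntot
  ssb <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  ssw <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  msb <- ssb / (r - 1)
  msw <- ssw / ((n1 - 1) + (n2 - 1))
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (r - 1)
  a <- (msb - msw) / nc
  b <- msw
  if (a + b == 0) return(c(a = 0, ab = 0))
  c(a = a, ab = a + b)
}

## Hudson estimator (Bhatia et al. 2013), one SNP.
oracle_hudson_components <- function(p1, n1, p2, n2) {
  if (is.na(p1) || is.na(p2) || n1 < 2 || n2 < 2) return(c(a = 0, ab = 0))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(c(a = 0, ab = 0))
  c(a = num, ab = den)
}

## Window Fst by summing per-SNP components (ratio of averages),
## clamped to [0, 1].
oracle_window_fst <- function(p1, n1, p2, n2, estimator = "wc") {
  fun <- if (estimator == "wc") oracle_wc_components
  else oracle_hudson_components
  A <- 0; B <- 0
  for (i in seq_along(p1)) {
    cc <- fun(p1[i], n1[i], p2[i], n2[i])
    A <- A + cc[["a"]]
    B <- B + cc[["ab"]]
  }
  if (B <= 0) return(NA_real_)
  min(max(A / B, 0), 1)
}

## Brute-force windowed scan over a PoolSnpSet: for every grid window
## [s, e) (0-based half-open) pick member SNPs with s < pos <= e and
## recompute Hp (focal pooled reads) and Fst (focal vs wild) from raw
## records with the scalar oracles above.
oracle_scan <- function(x, chromLengths, focalPools = poolNames(x),
                        windowSize = 150000, step = 75000,
                        estimator = "wc") {
  s <- sites(x)
  pos <- GenomicRanges::start(s)
  chrom <- as.character(GenomicRanges::seqnames(s))
  refR <- rowSums(refCounts(x)[, focalPools, drop = FALSE])
  altR <- rowSums(altCounts(x)[, focalPools, drop = FALSE])
  g <- wildGenotypes(x)
  nFocal <- 2 * sum(poolSizes(x)[focalPools])
  rows <- list()
  for (chr in names(chromLengths)) {
    len <- as.integer(chromLengths[[chr]])
    starts <- seq.int(0L, len - 1L, by = as.integer(step))
    for (s0 in starts) {
      e0 <- min(s0 + as.integer(windowSize), len)
      member <- which(chrom == chr & pos > s0 & pos <= e0)
      maj <- mn <- p1 <- n1 <- p2 <- n2 <- numeric(0)
      for (i in member) {
        rr <- refR[i]; aa <- altR[i]
        maj <- c(maj, max(rr, aa))
        mn <- c(mn, min(rr, aa))
        depth <- rr + aa
        p1 <- c(p1, if (depth > 0) aa / depth else NA_real_)
        n1 <- c(n1, min(depth, nFocal))
        gi <- g[i, ]
        nw <- 2 * sum(!is.na(gi))
        p2 <- c(p2, if (nw > 0) sum(gi, na.rm = TRUE) / nw else NA_real_)
        n2 <- c(n2, nw)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start0 = s0, end0 = e0, nSnps = length(member),
        hp = if (length(member)) oracle_hp(maj, mn) else NA_real_,
        fst = if (length(member))
          oracle_window_fst(p1, n1, p2, n2, estimator) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

## The standard genetic code, typed as a literal table.
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

## Quadratic all-pairs region -> gene oracle (overlap else nearest by
## edge distance on the same chromosome; ties all reported).
oracle_annotate <- function(regions, genes) {
  out <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    rc <- as.character(GenomicRanges::seqnames(r))
    rs <- GenomicRanges::start(r); re <- GenomicRanges::end(r)
    ov <- character(0); nearestD <- Inf; nearestG <- character(0)
    for (j in seq_along(genes)) {
      gc <- as.character(GenomicRanges::seqnames(genes[j]))
      if (gc != rc) next
      gs <- GenomicRanges::start(genes[j])
      ge <- GenomicRanges::end(genes[j])
      if (gs <= re && ge >= rs) {
        ov <- c(ov, genes$gene_id[j])
      } else {
        d <- if (gs > re) gs - re - 1 else rs - ge - 1
        if (d < nearestD) { nearestD <- d; nearestG <- genes$gene_id[j] }
        else if (d == nearestD) nearestG <- c(nearestG, genes$gene_id[j])
      }
    }
    hit <- if (length(ov)) ov else nearestG
    out[[i]] <- data.frame(region = i, gene_id = hit,
                           nearestOnly = !length(ov))
  }
  do.call(rbind, out)
}
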