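## Fixture builders shared across the suite.

## Compact PoolSnpSet builder: counts as list(pool = cbind(ref, alt)).
makeSnpSet <- function(pos, counts, poolSizes = NULL, wild = NULL,
                       chrom = "chr1", ref = NULL, alt = NULL,
                       qual = NULL, info = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(poolSizes))
    poolSizes <- setNames(rep(30L, length(counts)), names(counts))
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                              ref = ref, alt = alt)
  refM <- vapply(counts, function(m) m[, 1L], numeric(n))
  altM <- vapply(counts, function(m) m[, 2L], numeric(n))
  if (n == 1L) {
    refM <- matrix(refM, 1L, dimnames = list(NULL, names(counts)))
    altM <- matrix(altM, 1L, dimnames = list(NULL, names(counts)))
  }
  PoolSnpSet(g, refM, altM, poolSizes, wildGeno = wild, qual = qual,
             info = info)
}

## GenomeScan with prescribed window statistics, for the selection and
## merging operations.
makeScan <- function(fst, hp, chrom = "chr1", step = 75000L,
                     windowSize = 150000L) {
  n <- length(fst)
  starts0 <- (seq_len(n) - 1L) * step
  w <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(starts0 + 1L, starts0 + windowSize))
  w$nSnps <- rep(50L, n)
  w$hpFocal <- hp
  w$hpBackground <- hp
  w$fst <- fst
  w$rawFst <- fst
  zf <- zTransform(fst)
  zh <- zTransform(hp)
  w$zFst <- zf$z
  w$zHp <- zh$z
  new("GenomeScan", windows = w,
      zstats = list(fst = c(mu = zf$mu, sigma = zf$sigma, n = zf$n),
                    hp = c(mu = zh$mu, sigma = zh$sigma, n = zh$n)),
      comparison = "fixture", estimator = "wc",
      windowSize = windowSize, step = step, minSnps = 10L,
      nDiscarded = 0L)
}

## GRanges from 0-based half-open coordinate triples.
gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start0 + 1L, end0), ...)
}

toy20VcfPath <- function() {
  system.file("extdata", "toy20.vcf", package = "poolSweeps",
              mustWork = TRUE)
}

toy20PoolSizes <- c(p1 = 10L, p2 = 10L)

## Small simulated scene shared by io round-trip tests.
smallSimConfig <- function(seed = 42L, sweeps = NULL)
  sweepSimConfig(chromLengths = c(chr1 = 2e6), sweeps = sweeps,
                 seed = seed)
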