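test_that("window grid anchors at multiples of the step and truncates at chromosome ends", {
  w <- makeWindows(c(chr1 = 300000))
  expect_equal(start(w) - 1L, c(0L, 75000L, 150000L, 225000L))
  expect_equal(end(w), c(150000L, 225000L, 300000L, 300000L))
  w2 <- makeWindows(c(chr1 = 150000))
  expect_equal(start(w2) - 1L, c(0L, 75000L))
  expect_equal(end(w2), c(150000L, 150000L))
  # beyond the first step, every base is covered by exactly two windows
  cov <- GenomicRanges::coverage(makeWindows(c(chr1 = 600000)))$chr1
  expect_equal(S4Vectors::runValue(cov), c(1L, 2L))
  expect_equal(S4Vectors::runLength(cov)[1L], 75000L)
  expect_error(makeWindows(c(chr1 = 1e6), windowSize = 0), "positive")
  expect_error(makeWindows(c(chr1 = 1e6), step = 2e5), "step")
})

test_that("reported candidate-region bounds sit exactly on the default grid", {
  # e.g. a 116.7-116.85 Mb region is one full window of the grid
  w <- makeWindows(c(chr6 = 120e6))
  hit <- w[start(w) - 1L == 116700000]
  expect_equal(end(hit)[1L], 116850000L)
  bounds <- c(116.7, 50.325, 87.525, 29.175, 68.7, 22.425, 153.975, 53.1) * 1e6
  expect_true(all(bounds %% 75000 == 0))
})

test_that("SNP-to-window assignment uses 0-based half-open membership", {
  w <- makeWindows(c(chr1 = 300000))
  at <- function(p) subjectHits(assignSnps(
    w, GenomicRanges::GRanges("chr1", IRanges::IRanges(p, width = 1L))))
  expect_equal(at(75000L), 1L)          # p-1 = 74999 in [0,150k) only
  expect_equal(at(75001L), c(1L, 2L))   # boundary crossed
  expect_equal(at(1L), 1L)
  expect_warning(
    assignSnps(w, GenomicRanges::GRanges("chrX",
                                         IRanges::IRanges(5, width = 1L))),
    "skipped")
})

test_that("major/minor polarization ties resolve to the reference allele", {
  expect_equal(polarizeMajorMinor(10, 2)[c("maj", "min")],
               list(maj = 10, min = 2))
  expect_equal(polarizeMajorMinor(2, 10)[c("maj", "min")],
               list(maj = 10, min = 2))
  tie <- polarizeMajorMinor(5, 5)
  expect_equal(tie$maj, 5)
  expect_true(tie$refMajor)
})

test_that("window Hp follows the pooled-heterozygosity formula and its bounds", {
  expect_equal(windowHp(10, 10), 0.5)
  expect_equal(windowHp(c(30, 30), c(10, 10)), 0.375)  # 2*60*20/80^2
  expect_equal(windowHp(c(12, 40), c(0, 0)), 0)
  expect_true(is.na(windowHp(numeric(0), numeric(0))))
  set.seed(5)
  for (i in 1:25) {
    ref <- rpois(8, 20); alt <- rpois(8, 10)
    pol <- polarizeMajorMinor(ref, alt)
    hp <- windowHp(pol$maj, pol$min)
    expect_gte(hp, 0); expect_lte(hp, 0.5)
    # invariant under swapping which allele is labeled ref
    polSwap <- polarizeMajorMinor(alt, ref)
    expect_identical(hp, windowHp(polSwap$maj, polSwap$min))
    expect_equal(hp, oracle_hp(pol$maj, pol$min))
  }
})

test_that("per-SNP Fst components match the equation oracles", {
  # no differentiation: equal frequencies, large equal samples
  eq <- snpFstComponents(0.5, 1000, 0.5, 1000)
  expect_equal(eq$num / eq$den, 0, tolerance = 1e-2)
  # fixed difference approaches 1
  fx <- snpFstComponents(1, 1000, 0, 1000)
  expect_equal(fx$num / fx$den, 1, tolerance = 1e-9)
  # pool of 30 individuals (18 ref, 2 alt reads) vs 17 wild genotypes
  p1 <- 2 / 20; n1 <- min(20, 60)
  p2 <- 20 / 34; n2 <- 34
  got <- snpFstComponents(p1, n1, p2, n2)
  want <- oracle_wc_components(p1, n1, p2, n2)
  expect_equal(got$num, unname(want["a"]), tolerance = 1e-12)
  expect_equal(got$den, unname(want["ab"]), tolerance = 1e-12)
  goth <- snpFstComponents(p1, n1, p2, n2, estimator = "hudson")
  wanth <- oracle_hudson_components(p1, n1, p2, n2)
  expect_equal(goth$num, unname(wanth["a"]), tolerance = 1e-12)
  expect_equal(goth$den, unname(wanth["ab"]), tolerance = 1e-12)
  # monomorphic-in-both: zero components, excluded from the ratio
  expect_equal(snpFstComponents(0, 40, 0, 34), list(num = 0, den = 0))
})

test_that("window Fst aggregates as a clamped ratio of averages", {
  set.seed(8)
  for (est in c("wc", "hudson")) {
    for (i in 1:20) {
      k <- sample(3:12, 1)
      p1 <- runif(k); p2 <- runif(k)
      n1 <- sample(10:60, k, replace = TRUE)
      n2 <- rep(34, k)
      comp <- snpFstComponents(p1, n1, p2, n2, estimator = est)
      got <- windowFst(comp$num, comp$den)
      expect_equal(as.numeric(got),
                   oracle_window_fst(p1, n1, p2, n2, est),
                   tolerance = 1e-9)
      # symmetric under group exchange
      comp2 <- snpFstComponents(p2, n2, p1, n1, estimator = est)
      expect_equal(as.numeric(windowFst(comp2$num, comp2$den)),
                   as.numeric(got), tolerance = 1e-9)
    }
  }
  # negative raw ratio clamps to 0 but keeps the raw value
  comp <- snpFstComponents(0.5, 20, 0.5, 20)
  wf <- windowFst(comp$num, comp$den)
  expect_equal(as.numeric(wf), 0)
  expect_lt(attr(wf, "raw"), 0)
  expect_true(is.na(windowFst(0, 0)))
})

test_that("windows with fewer than 10 SNPs are discarded, inclusive at 10", {
  w <- makeWindows(c(chr1 = 450000))
  w$nSnps <- c(9L, 10L, 11L, 0L, 25L, 3L)
  kept <- minSnpFilter(w)
  expect_equal(kept$nSnps, c(10L, 11L, 25L))
  expect_equal(attr(kept, "nDiscarded"), 3L)
  w$nSnps <- rep(0L, 6L)
  expect_length(minSnpFilter(w), 0L)
})

test_that("Z-transformation standardizes to mean 0, sd 1 and honors given constants", {
  zs <- zTransform(c(1, 2, 3))
  expect_equal(zs$z, c(-1, 0, 1))                       # sample sd
  zp <- zTransform(c(1, 2, 3), sdType = "population")
  expect_equal(zp$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  set.seed(2)
  v <- rnorm(500, 0.3, 0.05)
  z <- zTransform(v)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z$z), 1, tolerance = 1e-9)
  expect_error(zTransform(rep(0.4, 10)), "sigma")
  expect_error(zTransform(0.4), "2 finite")
})

test_that("Z-scoring reproduces the printed genome-wide calibration", {
  mu <- 0.232
  sigma <- (0.536 - 0.232) / 3.557
  z <- zTransform(c(0.536, mu), mu = mu, sigma = sigma)
  expect_equal(z$z[1L], 3.557, tolerance = 1e-3)
  expect_equal(z$z[2L], 0)
})

test_that("every retained window equals a brute-force recomputation from raw records", {
  cl <- c(chr1 = 3e6)   # 40 grid windows
  sim <- simulateSweepData(sweepSimConfig(chromLengths = cl,
                                          sweeps = NULL, seed = 17L))
  x <- applySiteFilters(applySnpHardFilters(sim$snps))
  for (est in c("wc", "hudson")) {
    scan <- scanGenome(x, cl, estimator = est)
    w <- scanWindows(scan)
    ora <- oracle_scan(x, cl, estimator = est)
    key <- paste(ora$chrom, ora$start0)
    idx <- match(paste(as.character(seqnames(w)), start(w) - 1L), key)
    expect_false(anyNA(idx))
    expect_equal(w$nSnps, ora$nSnps[idx])
    expect_equal(w$hpFocal, ora$hp[idx], tolerance = 1e-12)
    expect_equal(w$fst, ora$fst[idx], tolerance = 1e-9)
  }
})

test_that("scan retention and Z-constants are computed on retained windows only", {
  cl <- c(chr1 = 3e6)
  sim <- simulateSweepData(sweepSimConfig(chromLengths = cl,
                                          sweeps = NULL, seed = 23L))
  x <- applySiteFilters(applySnpHardFilters(sim$snps))
  scan <- scanGenome(x, cl)
  w <- scanWindows(scan)
  expect_true(all(w$nSnps >= 10L))
  expect_equal(mean(w$zFst), 0, tolerance = 1e-9)
  expect_equal(stats::sd(w$zFst), 1, tolerance = 1e-9)
  expect_equal(zStats(scan)$fst[["mu"]], mean(w$fst))
  expect_true(all(w$fst >= 0 & w$fst <= 1))
  expect_true(all(w$hpFocal >= 0 & w$hpFocal <= 0.5))
})
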