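test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- smallSimConfig(seed = 5L)
  a <- simulateSweepData(cfg)
  b <- simulateSweepData(cfg)
  expect_identical(refCounts(a$snps), refCounts(b$snps))
  expect_identical(wildGenotypes(a$snps), wildGenotypes(b$snps))
  expect_identical(siteQual(a$snps), siteQual(b$snps))
  f1 <- tempfile(); f2 <- tempfile()
  writePoolVcf(a$snps, f1); writePoolVcf(b$snps, f2)
  expect_identical(readLines(f1), readLines(f2))
  c <- simulateSweepData(cfg, seed = 6L)
  expect_false(identical(refCounts(a$snps), refCounts(c$snps)))
})

test_that("zero drift and no sweeps leave pool frequencies at the ancestral value", {
  cfg <- sweepSimConfig(chromLengths = c(chr1 = 5e5), driftF = 0,
                        wildDriftF = 0, sweeps = NULL, seed = 13L)
  fr <- simulateFrequencies(cfg)
  expect_equal(fr$poolFreq[, 1L], fr$ancestral)
  expect_equal(fr$wildFreq, fr$ancestral)
  expect_true(all(fr$ancestral > 0 & fr$ancestral < 1))
})

test_that("observations follow the binomial read model", {
  cfg <- sweepSimConfig(chromLengths = c(chr1 = 5e6),
                        poolSizes = c(p1 = 50L), nWild = 4L,
                        sweeps = NULL, wildMissingRate = 0, seed = 29L)
  fr <- simulateFrequencies(cfg)
  n <- length(fr$sites)
  # fix the truth at f = 0.3 for every SNP and pool
  fr$poolFreq[] <- 0.3
  fr$wildFreq[] <- 0.3
  obs <- simulateObservations(fr, cfg)
  altFrac <- sum(altCounts(obs)) /
    sum(refCounts(obs) + altCounts(obs))
  se <- sqrt(0.3 * 0.7 / sum(refCounts(obs) + altCounts(obs)))
  expect_lt(abs(altFrac - 0.3), 3 * se)
  # f = 0 gives all-reference reads and dosages
  fr$poolFreq[] <- 0
  fr$wildFreq[] <- 0
  obs0 <- simulateObservations(fr, cfg)
  expect_equal(sum(altCounts(obs0)), 0L)
  expect_equal(sum(wildGenotypes(obs0)), 0L)
})

test_that("a full-intensity sweep fixes domestic pools against the wild major allele", {
  sweep <- gr0("chr1", 150000, 600000)
  sweep$s <- 1
  cfg <- sweepSimConfig(chromLengths = c(chr1 = 1.2e6), sweeps = sweep,
                        seed = 37L)
  fr <- simulateFrequencies(cfg)
  inside <- start(fr$sites) > 150000 & start(fr$sites) <= 600000
  expect_true(any(inside))
  target <- 1 - as.numeric(fr$wildFreq[inside] >= 0.5)
  for (p in seq_len(ncol(fr$poolFreq)))
    expect_equal(fr$poolFreq[inside, p], target)
  # outside the sweep, drift leaves most sites segregating
  expect_gt(mean(fr$poolFreq[!inside, 1L] > 0 &
                   fr$poolFreq[!inside, 1L] < 1), 0.5)
  # observed consequence: swept windows have Hp ~ 0 in the pooled domestic
  obs <- simulateObservations(fr, cfg)
  scan <- scanGenome(applySiteFilters(obs), c(chr1 = 1.2e6), minSnps = 5L)
  w <- scanWindows(scan)
  swept <- start(w) - 1L >= 150000 & end(w) <= 600000
  expect_true(all(w$hpFocal[swept] < 0.01))
  expect_true(all(w$fst[swept] > mean(w$fst[!swept])))
})

test_that("sweep-config validation rejects bad intensities and placements", {
  bad <- gr0("chr1", 0, 1e6); bad$s <- 1.5
  expect_error(sweepSimConfig(chromLengths = c(chr1 = 2e6), sweeps = bad),
               "intensities")
  out <- gr0("chr1", 0, 5e6); out$s <- 1
  expect_error(sweepSimConfig(chromLengths = c(chr1 = 2e6), sweeps = out),
               "bounds")
  expect_error(sweepSimConfig(snpDensity = 0), "snpDensity")
})

test_that("recovery reports count truth windows covered by reported regions", {
  cl <- c(chr1 = 3e6)
  truth <- gr0("chr1", 0, 450000)
  perfect <- recoveryReport(truth, truth, cl)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$nTruthWindows, 6L)  # starts 0..375k overlap
  none <- recoveryReport(GenomicRanges::GRanges(), truth, cl)
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$precision))
  # book-ended (not overlapping) report: hand-counted confusion
  shifted <- recoveryReport(gr0("chr1", 450000, 600000), truth, cl)
  expect_equal(shifted$nTruthWindowsCovered, 1L)  # only window [375k,525k)
  expect_equal(shifted$sensitivity, 1 / 6)
  expect_equal(shifted$precision, 0)
})

test_that("a neutral null flags at most the tail capacity of windows", {
  cl <- c(chr1 = 1.5e7)   # 200 windows, capacity ceil(2) = 2
  sim <- simulateSweepData(sweepSimConfig(chromLengths = cl,
                                          sweeps = NULL, seed = 53L))
  x <- applySiteFilters(applySnpHardFilters(sim$snps))
  scan <- scanGenome(x, cl)
  sel <- selectWindows(scan)
  expect_lte(length(sel) / length(scanWindows(scan)), 0.01)
})

test_that("recovery sensitivity is non-decreasing in sweep intensity", {
  cl <- c(chr1 = 4.5e7)
  sens <- vapply(c(0.25, 0.5, 1), function(s) {
    sweep <- gr0("chr1", 22500000, 22950000)
    sweep$s <- s
    sim <- simulateSweepData(sweepSimConfig(chromLengths = cl,
                                            sweeps = sweep, seed = 61L))
    x <- applySiteFilters(applySnpHardFilters(sim$snps))
    scan <- scanGenome(x, cl)
    reg <- mergeWindows(selectWindows(scan))
    recoveryReport(reg, sim$truth, cl)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3L], 0.8)
})

test_that("neutral window Fst is centred on the conditional per-SNP expectation", {
  # Hudson components are conditionally unbiased given the true
  # frequencies, so the mean over windows of (window Fst - the ratio
  # implied by the drawn truth) should be a few standard errors from 0.
  cl <- c(chr1 = 1.5e7)
  cfg <- sweepSimConfig(chromLengths = cl, sweeps = NULL,
                        wildMissingRate = 0, seed = 71L)
  fr <- simulateFrequencies(cfg)
  obs <- simulateObservations(fr, cfg)
  scan <- scanGenome(obs, cl, estimator = "hudson")
  w <- scanWindows(scan)
  # truth-based target per window from the same member SNPs
  grid <- makeWindows(cl)
  hits <- assignSnps(grid, obs)
  p1 <- rowSums(altCounts(obs)) /
    pmax(rowSums(refCounts(obs) + altCounts(obs)), 1)
  tNum <- (fr$poolFreq %*% rep(1 / ncol(fr$poolFreq),
                               ncol(fr$poolFreq)))[, 1L]
  target <- vapply(seq_along(grid), function(i) {
    m <- queryHits(hits)[subjectHits(hits) == i]
    if (!length(m)) return(NA_real_)
    pd <- tNum[m]; pw <- fr$wildFreq[m]
    sum((pd - pw)^2) / sum(pd * (1 - pw) + pw * (1 - pd))
  }, numeric(1))
  idx <- match(paste(as.character(seqnames(w)), start(w)),
               paste(as.character(seqnames(grid)), start(grid)))
  diffs <- w$fst - target[idx]
  diffs <- diffs[is.finite(diffs)]
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})
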