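mkInfo <- function(n, qd = 30, fs = 1, rprs = 0)
  data.frame(QD = rep_len(qd, n), FS = rep_len(fs, n),
             ReadPosRankSum = rep_len(rprs, n))

test_that("mean quality is the arithmetic mean over non-missing QUAL", {
  expect_equal(meanQual(c(30, 30, 30)), 30)
  expect_equal(meanQual(c(10, 20, 60)), 30)
  expect_equal(meanQual(c(20, NA, 40)), 30)
  expect_error(meanQual(c(NA_real_, NA_real_)), "non-missing")
})

test_that("SNP hard filter removes exactly the clause violators, strict bounds", {
  # five records: two violate one clause each (QD boundary, FS)
  x <- makeSnpSet(pos = (1:5) * 100,
                  counts = list(p1 = cbind(rep(20, 5), rep(20, 5))),
                  qual = rep(100, 5),
                  info = data.frame(
                    QD = c(25, 19.9, 30, 30, 20),
                    FS = c(2, 1, 1, 15, 1),
                    ReadPosRankSum = c(0, 0, 0, 0, 0)))
  kept <- applySnpHardFilters(x)
  expect_length(kept, 3L)
  expect_equal(start(sites(kept)), c(100L, 300L, 500L))  # QD=20 passes
  # QUAL floor is the callset mean (30 here): 10 and 20 fall below it
  y <- makeSnpSet(pos = (1:3) * 100,
                  counts = list(p1 = cbind(rep(20, 3), rep(20, 3))),
                  qual = c(10, 20, 60), info = mkInfo(3))
  expect_equal(start(sites(applySnpHardFilters(y))), 300L)
  # a fixed floor keeps everything at or above it
  thrF <- filterThresholds(qualFloorMode = "fixed", qualFloor = 20)
  expect_equal(start(sites(applySnpHardFilters(y, thrF))),
               c(200L, 300L))
})

test_that("missing filter annotations never trigger removal", {
  x <- makeSnpSet(pos = c(100, 200),
                  counts = list(p1 = cbind(c(20, 20), c(20, 20))),
                  qual = c(100, 100),
                  info = data.frame(QD = c(NA, 10), FS = NA_real_,
                                    ReadPosRankSum = NA_real_))
  kept <- applySnpHardFilters(x)
  expect_equal(start(sites(kept)), 100L)
})

test_that("site filters: inclusive MAF bound, per-pool coverage, completeness", {
  wild2 <- function(g1, g2) cbind(w1 = g1, w2 = g2)
  # maf exactly 0.05: 4 alt among 80 observations -> kept
  boundary <- makeSnpSet(pos = 100,
                         counts = list(p1 = cbind(36, 2), p2 = cbind(38, 0)),
                         wild = wild2(1L, 1L))
  expect_length(applySiteFilters(boundary), 1L)
  # one pool at depth 7 -> removed
  lowCov <- makeSnpSet(pos = 100,
                       counts = list(p1 = cbind(4, 3), p2 = cbind(20, 20)),
                       wild = wild2(1L, 1L))
  expect_length(applySiteFilters(lowCov), 0L)
  expect_true(siteFilterFlags(lowCov)[1L, "coverage"])
  # monomorphic -> maf 0 -> removed
  mono <- makeSnpSet(pos = 100,
                     counts = list(p1 = cbind(40, 0), p2 = cbind(40, 0)),
                     wild = wild2(0L, 0L))
  expect_true(siteFilterFlags(mono)[1L, "maf"])
  # half the units missing -> call rate 0.5 < 0.7 -> removed
  sparse <- makeSnpSet(pos = 100,
                       counts = list(p1 = cbind(0, 0), p2 = cbind(20, 20)),
                       wild = wild2(NA_integer_, 1L))
  expect_true(siteFilterFlags(sparse)[1L, "missing"])
})

test_that("filters are idempotent and every removed record violates a clause", {
  sim <- simulateSweepData(smallSimConfig(seed = 9L))
  x <- sim$snps
  floorQ <- meanQual(x)
  h1 <- applySnpHardFilters(x, qualFloor = floorQ)
  expect_identical(length(applySnpHardFilters(h1, qualFloor = floorQ)),
                   length(h1))
  s1 <- applySiteFilters(h1)
  expect_identical(length(applySiteFilters(s1)), length(s1))
  expect_true(length(s1) < length(x))
  # complement check: each removed record violates >= 1 named clause
  removedHard <- setdiff(siteKeys(x), siteKeys(h1))
  hardFlags <- snpHardFilterFlags(x, qualFloor = floorQ)
  expect_true(all(rowSums(hardFlags[siteKeys(x) %in% removedHard, ,
                                    drop = FALSE]) >= 1))
  removedSite <- setdiff(siteKeys(h1), siteKeys(s1))
  siteFlags <- siteFilterFlags(h1)
  expect_true(all(rowSums(siteFlags[siteKeys(h1) %in% removedSite, ,
                                    drop = FALSE]) >= 1))
})

mkIndels <- function(ref, alt, qual = 100, qd = 30, fs = 1, rprs = 0)
  data.frame(chrom = "chr1", pos = seq_along(ref) * 100,
             ref = ref, alt = alt, qual = rep_len(qual, length(ref)),
             QD = rep_len(qd, length(ref)),
             FS = rep_len(fs, length(ref)),
             ReadPosRankSum = rep_len(rprs, length(ref)))

test_that("indel filters enforce the 25-bp bound and hard clauses", {
  del26 <- paste(rep("A", 27), collapse = "")
  del25 <- paste(rep("A", 26), collapse = "")
  ind <- mkIndels(ref = c(del26, del25, "A"),
                  alt = c("A", "A", "AT"),
                  qd = c(30, 30, 1.9))
  kept <- applyIndelFilters(ind)
  expect_equal(kept$pos, 200L)     # 26 bp and QD=1.9 removed
  expect_equal(abs(nchar(kept$ref) - nchar(kept$alt)), 25L)
  empty <- applyIndelFilters(ind[0L, ])
  expect_equal(nrow(empty), 0L)
  # QUAL < 20 clause, with mean floor neutralized by equal quals
  low <- mkIndels(ref = c("A", "A"), alt = c("AT", "ATT"),
                  qual = c(19, 19))
  expect_equal(nrow(applyIndelFilters(low)), 0L)
})

test_that("callset intersection keys on chrom:pos:ref:alt and keeps a's annotations", {
  a <- makeSnpSet(pos = c(100, 200, 300, 400, 500),
                  counts = list(p1 = cbind(rep(10, 5), rep(5, 5))),
                  qual = 1:5 * 10, info = mkInfo(5))
  expect_identical(siteKeys(intersectCallsets(a, a)), siteKeys(a))
  b <- makeSnpSet(pos = c(200, 400, 600),
                  counts = list(p1 = cbind(rep(9, 3), rep(9, 3))))
  shared <- intersectCallsets(a, b)
  expect_equal(start(sites(shared)), c(200L, 400L))
  expect_equal(siteQual(shared), c(20, 40))  # annotations from a
  disjoint <- makeSnpSet(pos = c(700, 800),
                         counts = list(p1 = cbind(c(1, 1), c(1, 1))))
  expect_length(intersectCallsets(a, disjoint), 0L)
  # different alt allele at same position does not match
  c2 <- makeSnpSet(pos = 100, counts = list(p1 = cbind(10, 5)),
                   alt = "T")
  expect_length(intersectCallsets(c2, a), 0L)
})

test_that("overlap patterns partition the union", {
  out <- snpSetOverlap(list(A = "k1", B = "k1"))
  expect_equal(out$count[out$pattern == "A&B"], 1L)
  out2 <- snpSetOverlap(list(A = c("k1", "k2"), B = c("k2", "k3")))
  expect_equal(sort(out2$pattern), c("A", "A&B", "B"))
  expect_equal(out2$count, rep(1L, 3L))
  expect_equal(sum(out2$count), 3L)
  # five simulator-derived sets against brute-force enumeration
  sim <- simulateSweepData(smallSimConfig(seed = 3L))
  keys <- siteKeys(sim$snps)
  set.seed(11)
  sets <- lapply(1:5, function(i) sample(keys, 400))
  names(sets) <- paste0("s", 1:5)
  out5 <- snpSetOverlap(sets)
  expect_equal(sum(out5$count), length(unique(unlist(sets))))
  # brute force: classify every key by its membership pattern
  uni <- unique(unlist(sets))
  brute <- table(vapply(uni, function(k)
    paste(names(sets)[vapply(sets, function(s) k %in% s, TRUE)],
          collapse = "&"), ""))
  expect_equal(setNames(out5$count, out5$pattern)[names(brute)],
               setNames(as.integer(brute), names(brute)))
})

test_that("indel length spectrum counts signed lengths", {
  one <- mkIndels(ref = "A", alt = "ATTG")
  expect_equal(indelLengthSpectrum(one),
               data.frame(length = 3L, count = 1L))
  expect_equal(nrow(indelLengthSpectrum(one[0L, ])), 0L)
  mixed <- mkIndels(ref = c("A", "A", "ACG", "ACG", "A"),
                    alt = c("AT", "AT", "A", "A", "ATTTT"))
  spec <- indelLengthSpectrum(mixed)
  expect_equal(spec$count[spec$length == 1L], 2L)
  expect_equal(spec$count[spec$length == -2L], 2L)
  expect_equal(spec$count[spec$length == 4L], 1L)
  expect_equal(sum(spec$count), 5L)
})
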