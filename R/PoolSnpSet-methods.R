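#' @include AllClasses.R
NULL

#' Construct a PoolSnpSet
#'
#' @param sites `GRanges` of width-1 SNP positions with metadata columns
#'   `ref` and `alt`, or a data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param refCounts,altCounts integer matrices (sites x pools) of reads
#'   supporting each allele; column names are pool names.
#' @param poolSizes named integer vector of diploid individuals per pool
#'   (names must match count-matrix columns).
#' @param wildGeno optional integer matrix (sites x wild individuals) of
#'   alt-allele dosages 0/1/2 with `NA` for missing.
#' @param qual optional numeric site quality vector.
#' @param info optional data.frame/DataFrame of filter annotations
#'   (`QD`, `FS`, `ReadPosRankSum`).
#' @return A [PoolSnpSet-class] with sites sorted by (chrom, pos).
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 205), width = 1),
#'                                 ref = c("A", "C"), alt = c("T", "G"))
#' x <- PoolSnpSet(sites,
#'                 refCounts = cbind(p1 = c(10L, 30L)),
#'                 altCounts = cbind(p1 = c(2L, 15L)),
#'                 poolSizes = c(p1 = 50L))
#' x
#' @export
PoolSnpSet <- function(sites, refCounts, altCounts, poolSizes,
                       wildGeno = NULL, qual = NULL, info = NULL) {
  if (is.data.frame(sites)) {
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                     ref = as.character(sites$ref),
                     alt = as.character(sites$alt))
  }
  n <- length(sites)
  refCounts <- as.matrix(refCounts); storage.mode(refCounts) <- "integer"
  altCounts <- as.matrix(altCounts); storage.mode(altCounts) <- "integer"
  poolSizes <- setNames(as.integer(poolSizes), names(poolSizes))
  if (is.null(colnames(refCounts))) colnames(refCounts) <- names(poolSizes)
  if (is.null(colnames(altCounts))) colnames(altCounts) <- names(poolSizes)
  if (!identical(colnames(refCounts), names(poolSizes)))
    stop("poolSizes names must match count matrix columns")
  if (is.null(wildGeno)) {
    wildGeno <- matrix(integer(), nrow = n, ncol = 0L)
  } else {
    wildGeno <- as.matrix(wildGeno); storage.mode(wildGeno) <- "integer"
  }
  if (is.null(qual)) qual <- rep(NA_real_, n)
  if (is.null(info)) {
    info <- DataFrame(QD = rep(NA_real_, n), FS = rep(NA_real_, n),
                      ReadPosRankSum = rep(NA_real_, n))
  } else {
    info <- as(as.data.frame(info), "DataFrame")
    for (col in c("QD", "FS", "ReadPosRankSum"))
      if (!col %in% colnames(info)) info[[col]] <- rep(NA_real_, n)
  }
  ord <- order(as.factor(seqnames(sites)), start(sites))
  new("PoolSnpSet",
      sites = sites[ord],
      refCounts = refCounts[ord, , drop = FALSE],
      altCounts = altCounts[ord, , drop = FALSE],
      poolSizes = poolSizes,
      wildGeno = wildGeno[ord, , drop = FALSE],
      qual = qual[ord],
      info = info[ord, , drop = FALSE])
}

#' @describeIn PoolSnpSet-class number of SNP sites
#' @param x A `PoolSnpSet`.
#' @export
setMethod("length", "PoolSnpSet", function(x) length(x@sites))

#' Accessors for PoolSnpSet components
#'
#' @param x A [PoolSnpSet-class].
#' @return `sites()` the site `GRanges`; `refCounts()`/`altCounts()` the
#'   read-count matrices; `wildGenotypes()` the dosage matrix;
#'   `poolSizes()` the named size vector; `poolNames()` the pool names;
#'   `siteQual()` the quality vector; `siteInfo()` the annotation
#'   `DataFrame`; `siteKeys()` "chrom:pos:ref:alt" identity keys.
#' @name PoolSnpSet-accessors
NULL

#' @rdname PoolSnpSet-accessors
#' @export
sites <- function(x) x@sites

#' @rdname PoolSnpSet-accessors
#' @export
refCounts <- function(x) x@refCounts

#' @rdname PoolSnpSet-accessors
#' @export
altCounts <- function(x) x@altCounts

#' @rdname PoolSnpSet-accessors
#' @export
wildGenotypes <- function(x) x@wildGeno

#' @rdname PoolSnpSet-accessors
#' @export
poolSizes <- function(x) x@poolSizes

#' @rdname PoolSnpSet-accessors
#' @export
poolNames <- function(x) names(x@poolSizes)

#' @rdname PoolSnpSet-accessors
#' @export
siteQual <- function(x) x@qual

#' @rdname PoolSnpSet-accessors
#' @export
siteInfo <- function(x) x@info

#' @rdname PoolSnpSet-accessors
#' @export
siteKeys <- function(x) {
  s <- x@sites
  paste(as.character(seqnames(s)), start(s), s$ref, s$alt, sep = ":")
}

#' @describeIn PoolSnpSet-class subset sites, preserving all components
#' @param i index vector over sites.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PoolSnpSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, siteKeys(x))
  initialize(x,
             sites = x@sites[i],
             refCounts = x@refCounts[i, , drop = FALSE],
             altCounts = x@altCounts[i, , drop = FALSE],
             wildGeno = x@wildGeno[i, , drop = FALSE],
             qual = x@qual[i],
             info = x@info[i, , drop = FALSE])
})

setMethod("show", "PoolSnpSet", function(object) {
  cat("PoolSnpSet with", length(object), "sites,",
      ncol(object@refCounts), "pools,",
      ncol(object@wildGeno), "wild individuals\n")
  if (ncol(object@refCounts))
    cat("  pools:", paste0(poolNames(object), " (n=", object@poolSizes, ")",
                           collapse = ", "), "\n")
  if (length(object)) {
    s <- head(object@sites, 3)
    cat("  head:", paste(as.character(seqnames(s)), start(s),
                         paste0(s$ref, ">", s$alt), collapse = "; "), "\n")
  }
})

#' @describeIn GenomeScan-class retained windows with their statistics
#' @param scan A `GenomeScan`.
#' @export
scanWindows <- function(scan) scan@windows

#' @describeIn GenomeScan-class Z-normalization constants, a list with
#'   elements `hp` and `fst`, each `c(mu, sigma, n)`
#' @export
zStats <- function(scan) scan@zstats

setMethod("show", "GenomeScan", function(object) {
  cat("GenomeScan:", object@comparison,
      sprintf("(%s estimator)\n", object@estimator))
  cat(sprintf("  %d retained windows (%d discarded; %d-kb windows, %d-kb step, >=%d SNPs)\n",
              length(object@windows), object@nDiscarded,
              object@windowSize %/% 1000L, object@step %/% 1000L,
              object@minSnps))
  z <- object@zstats
  cat(sprintf("  Fst: mu=%.4f sigma=%.4f | Hp: mu=%.4f sigma=%.4f\n",
              z$fst[["mu"]], z$fst[["sigma"]], z$hp[["mu"]], z$hp[["sigma"]]))
})

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds\n")
  cat(sprintf("  SNP hard filter: QD < %g | ReadPosRankSum < %g | FS > %g | QUAL < %s\n",
              object@qdMin, object@readPosMin, object@fsMax,
              if (object@qualFloorMode == "mean") "mean(QUAL)"
              else format(object@qualFloor)))
  cat(sprintf("  site filter: MAF >= %g, call rate >= %g (%s), depth >= %g (%s)\n",
              object@mafMin, object@minCallRate, object@missingScope,
              object@coverageMin, object@coverageScope))
  cat(sprintf("  indels: |len| <= %g, QUAL >= %g, QD >= %g\n",
              object@indelMaxLen, object@indelQualMin, object@indelQdMin))
})

setMethod("show", "SweepSimConfig", function(object) {
  cat("SweepSimConfig:",
      sprintf("%d chromosome(s), %.0f Mb total, density 1/%d bp\n",
              length(object@chromLengths), sum(object@chromLengths) / 1e6,
              round(1 / object@snpDensity)))
  cat(sprintf("  %d pools (%s), %d wild diploids, mean depth %gx\n",
              length(object@poolSizes),
              paste(object@poolSizes, collapse = "/"),
              object@nWild, object@meanDepth))
  cat(sprintf("  drift F: pools %.3f, wild %.3f; ancestral Beta(%g, %g)\n",
              object@driftF, object@wildDriftF,
              object@ancestralShape, object@ancestralShape))
  cat(sprintf("  %d planted sweep(s); seed %d\n",
              length(object@sweeps), object@seed))
})
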