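#' @include windows.R
NULL

#' Select dual-tail outlier windows
#'
#' Applies the scan's selection rule: windows simultaneously in the
#' upper tail of the windowed Fst distribution and the lower tail of
#' the windowed Hp distribution, each tail holding mass `quantile` of
#' the retained windows. Thresholds are the order statistics at
#' `ceiling(quantile * n)` from each end; windows exactly at a
#' threshold are included.
#'
#' @param scan A [GenomeScan-class].
#' @param quantile tail mass per statistic (default 0.01, the top 1%).
#' @return `GRanges` of selected windows (sorted, with the scan's
#'   metadata columns). The resolved cutoffs are recorded in
#'   `metadata()`: `fstThreshold`, `hpThreshold`, their Z equivalents,
#'   `quantile` and `nRetained`.
#' @export
selectWindows <- function(scan, quantile = 0.01) {
  if (quantile <= 0 || quantile >= 0.5)
    stop("quantile must lie in (0, 0.5)")
  w <- scanWindows(scan)
  n <- length(w)
  if (n < ceiling(1 / quantile))
    stop("too few retained windows (", n, ") for a ", quantile,
         " tail; need >= ", ceiling(1 / quantile))
  k <- ceiling(quantile * n)
  fstThr <- sort(w$fst, decreasing = TRUE)[k]
  hpThr <- sort(w$hpFocal)[k]
  sel <- sort(w[w$fst >= fstThr & w$hpFocal <= hpThr])
  z <- zStats(scan)
  metadata(sel) <- list(
    quantile = quantile, nRetained = n,
    fstThreshold = fstThr, hpThreshold = hpThr,
    zFstThreshold = (fstThr - z$fst[["mu"]]) / z$fst[["sigma"]],
    zHpThreshold = (hpThr - z$hp[["mu"]]) / z$hp[["sigma"]])
  sel
}

#' Merge significant windows into candidate regions
#'
#' Coalesces windows that overlap or are book-ended (share a boundary)
#' on the same chromosome into maximal regions; the span of a region is
#' the union of its constituent windows. On the default 150-kb/75-kb
#' grid, a run of k consecutive windows merges to 150 + 75*(k-1) kb.
#'
#' @param windows `GRanges` of significant windows (e.g. from
#'   [selectWindows()]).
#' @return Sorted, non-overlapping region `GRanges` with metadata
#'   columns `nWindows` (constituent count), and, when the windows
#'   carry `fst`/`hpFocal` columns, `meanFst` and `minHp` summaries.
#' @export
mergeWindows <- function(windows) {
  if (!length(windows)) {
    out <- GRanges()
    mcols(out) <- DataFrame(nWindows = integer(), meanFst = numeric(),
                            minHp = numeric())
    return(out)
  }
  red <- reduce(sort(windows), min.gapwidth = 1L, with.revmap = TRUE)
  revmap <- red$revmap
  red$nWindows <- lengths(revmap)
  if (!is.null(windows$fst))
    red$meanFst <- vapply(revmap, function(i)
      mean(sort(windows)$fst[i]), numeric(1))
  if (!is.null(windows$hpFocal))
    red$minHp <- vapply(revmap, function(i)
      min(sort(windows)$hpFocal[i]), numeric(1))
  red$revmap <- NULL
  red
}

#' Intersect candidate-region sets across comparisons
#'
#' Genomic intervals covered by every one of the supplied region sets
#' (e.g. the per-breed candidate regions); empty intersections are
#' dropped and the result is merged and sorted.
#'
#' @param regionSets list (>= 2) of region `GRanges`, each internally
#'   merged/sorted.
#' @return `GRanges` of shared intervals.
#' @export
intersectRegionSets <- function(regionSets) {
  if (!is.list(regionSets) && !is(regionSets, "GRangesList"))
    regionSets <- as.list(regionSets)
  if (length(regionSets) < 2L)
    stop("need >= 2 region sets to intersect")
  sets <- lapply(regionSets, granges)
  lvls <- unique(unlist(lapply(sets, seqlevels)))
  sets <- lapply(sets, function(s) {
    seqlevels(s) <- lvls
    s
  })
  out <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets)
  sort(reduce(out, min.gapwidth = 1L))
}

#' Breed-contrast genome scan
#'
#' Scans one focal pool against either the wild outgroup or the summed
#' reads of all other pools ("focal breed vs. all other breeds").
#'
#' @param x A filtered [PoolSnpSet-class].
#' @param chromLengths named chromosome lengths (bp).
#' @param focalPool single pool name.
#' @param background `"wild"`, `"others"` (all remaining pools,
#'   summed), or an explicit vector of pool names.
#' @param ... passed to [scanGenome()].
#' @return A [GenomeScan-class].
#' @export
breedContrastScan <- function(x, chromLengths, focalPool,
                              background = c("others", "wild"), ...) {
  if (length(focalPool) != 1L || !focalPool %in% poolNames(x))
    stop("focalPool must name exactly one pool of x")
  if (is.character(background) && length(background) == 1L &&
      background %in% c("others", "wild")) {
    background <- match.arg(background)
    if (background == "others") {
      background <- setdiff(poolNames(x), focalPool)
      if (!length(background))
        stop("no other pools available as background")
    }
  }
  if (!identical(background, "wild") && focalPool %in% background)
    stop("focal pool must not appear in the background")
  scanGenome(x, chromLengths, focalPools = focalPool,
             background = background, ...)
}

#' Write regions as BED
#'
#' 0-based half-open BED3(+) output; any numeric metadata columns are
#' appended as extra columns.
#'
#' @param regions region `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L,
                   end = end(regions))
  mc <- mcols(regions)
  for (nm in colnames(mc))
    if (is.numeric(mc[[nm]])) df[[nm]] <- mc[[nm]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
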