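#' @include variant-io.R
NULL

#' Default filtering thresholds
#'
#' Constructor for [FilterThresholds-class]. The defaults are the
#' pipeline's standard callset filters: SNPs are removed when
#' `QD < 20 || ReadPosRankSum < -8 || FS > 10 || QUAL < mean(QUAL)`;
#' sites are then required to have minor allele frequency >= 0.05,
#' call rate >= 0.7 and summed depth >= 8 in every pool; indels are
#' removed when longer than 25 bp or failing
#' `QUAL < 20 || QD < 2 || ReadPosRankSum < -8 || FS > 10 ||
#' QUAL < mean(QUAL)`.
#'
#' @param qdMin,readPosMin,fsMax SNP hard-filter clause thresholds.
#' @param qualFloorMode `"mean"` or `"fixed"`.
#' @param qualFloor floor used when `qualFloorMode = "fixed"`.
#' @param mafMin minimum minor allele frequency (inclusive).
#' @param minCallRate minimum fraction of units with data (inclusive).
#' @param coverageMin minimum summed read depth (inclusive).
#' @param coverageScope `"per-pool"` or `"total"`.
#' @param missingScope `"both"`, `"pools"` or `"wild"`.
#' @param indelMaxLen maximum indel length kept (inclusive).
#' @param indelQualMin,indelQdMin indel hard-filter clause thresholds.
#' @return A [FilterThresholds-class].
#' @export
filterThresholds <- function(qdMin = 20, readPosMin = -8, fsMax = 10,
                             qualFloorMode = c("mean", "fixed"),
                             qualFloor = 0,
                             mafMin = 0.05, minCallRate = 0.7,
                             coverageMin = 8,
                             coverageScope = c("per-pool", "total"),
                             missingScope = c("both", "pools", "wild"),
                             indelMaxLen = 25, indelQualMin = 20,
                             indelQdMin = 2) {
  new("FilterThresholds",
      qdMin = qdMin, readPosMin = readPosMin, fsMax = fsMax,
      qualFloorMode = match.arg(qualFloorMode), qualFloor = qualFloor,
      mafMin = mafMin, minCallRate = minCallRate,
      coverageMin = coverageMin,
      coverageScope = match.arg(coverageScope),
      missingScope = match.arg(missingScope),
      indelMaxLen = indelMaxLen, indelQualMin = indelQualMin,
      indelQdMin = indelQdMin)
}

#' Mean site quality of a callset
#'
#' Arithmetic mean of the QUAL column over all records, computed before
#' any filtering; records with missing quality are excluded from the
#' mean. This is the `$MEANQUAL` floor of the hard filter.
#'
#' @param x A [PoolSnpSet-class], an indel data.frame with a `qual`
#'   column, or a numeric vector of qualities.
#' @return The mean quality (scalar).
#' @export
meanQual <- function(x) {
  q <- if (is(x, "PoolSnpSet")) siteQual(x)
  else if (is.data.frame(x)) x$qual
  else x
  q <- q[!is.na(q)]
  if (!length(q)) stop("no non-missing QUAL values")
  mean(q)
}

## Clause matrix of the SNP hard filter: TRUE where a clause removes the
## record. Missing annotations never trigger removal.
.snpHardFlags <- function(qual, qd, fs, rprs, thr, qualFloor) {
  flag <- function(v) !is.na(v) & v
  cbind(QD = flag(qd < thr@qdMin),
        ReadPosRankSum = flag(rprs < thr@readPosMin),
        FS = flag(fs > thr@fsMax),
        QUAL = flag(qual < qualFloor))
}

#' Per-clause violation flags of the SNP hard filter
#'
#' @param x A [PoolSnpSet-class].
#' @param thresholds A [FilterThresholds-class].
#' @param qualFloor optional precomputed QUAL floor; defaults to
#'   [meanQual()] of `x` (mode `"mean"`) or `thresholds@qualFloor`.
#' @return Logical matrix (sites x clauses `QD`, `ReadPosRankSum`,
#'   `FS`, `QUAL`); a record is removed iff any entry in its row is
#'   `TRUE`.
#' @export
snpHardFilterFlags <- function(x, thresholds = filterThresholds(),
                               qualFloor = NULL) {
  if (is.null(qualFloor))
    qualFloor <- if (thresholds@qualFloorMode == "mean") meanQual(x)
    else thresholds@qualFloor
  info <- siteInfo(x)
  .snpHardFlags(siteQual(x), info$QD, info$FS, info$ReadPosRankSum,
                thresholds, qualFloor)
}

#' Apply the SNP hard filter
#'
#' Removes a record iff any clause holds:
#' `QD < qdMin`, `ReadPosRankSum < readPosMin`, `FS > fsMax`, or
#' `QUAL < floor` (the callset mean quality by default). Records with a
#' missing annotation are not removed on that annotation's account.
#' Order is preserved.
#'
#' @inheritParams snpHardFilterFlags
#' @return The surviving [PoolSnpSet-class].
#' @export
applySnpHardFilters <- function(x, thresholds = filterThresholds(),
                                qualFloor = NULL) {
  if (!length(x)) return(x)
  flags <- snpHardFilterFlags(x, thresholds, qualFloor)
  x[!apply(flags, 1L, any)]
}

## Pooled-observation allele frequency: pools weighted by reads, wild
## individuals by 2 chromosomes each.
.combinedAltFreq <- function(x) {
  altReads <- rowSums(altCounts(x))
  depth <- rowSums(refCounts(x) + altCounts(x))
  g <- wildGenotypes(x)
  wildAlt <- if (ncol(g)) rowSums(g, na.rm = TRUE) else 0
  wildChrom <- if (ncol(g)) 2 * rowSums(!is.na(g)) else 0
  tot <- depth + wildChrom
  ifelse(tot > 0, (altReads + wildAlt) / tot, NA_real_)
}

#' Per-clause violation flags of the site filter
#'
#' @inheritParams applySiteFilters
#' @return Logical matrix (sites x clauses `maf`, `missing`,
#'   `coverage`).
#' @export
siteFilterFlags <- function(x, thresholds = filterThresholds()) {
  depth <- refCounts(x) + altCounts(x)
  g <- wildGenotypes(x)
  f <- .combinedAltFreq(x)
  maf <- pmin(f, 1 - f)
  mafFail <- is.na(maf) | maf < thresholds@mafMin

  nPools <- ncol(depth)
  nWild <- ncol(g)
  poolsWith <- if (nPools) rowSums(depth > 0) else 0
  wildWith <- if (nWild) rowSums(!is.na(g)) else 0
  callRate <- switch(thresholds@missingScope,
    "pools" = if (nPools) poolsWith / nPools else 1,
    "wild"  = if (nWild) wildWith / nWild else 1,
    "both"  = (poolsWith + wildWith) / max(1L, nPools + nWild))
  missFail <- callRate < thresholds@minCallRate

  covFail <- if (thresholds@coverageScope == "per-pool") {
    if (nPools) rowSums(depth < thresholds@coverageMin) > 0 else FALSE
  } else {
    rowSums(depth) < thresholds@coverageMin
  }
  cbind(maf = mafFail, missing = rep_len(missFail, length(x)),
        coverage = rep_len(covFail, length(x)))
}

#' Apply MAF, completeness and coverage site filters
#'
#' Keeps a site iff (i) its minor allele frequency over all observations
#' (pool reads plus wild chromosomes) is at least `mafMin`, (ii) the
#' fraction of units with data (pools with reads; wild individuals with
#' genotypes) is at least `minCallRate`, and (iii) the summed read depth
#' reaches `coverageMin` in every pool (or in total, depending on
#' `coverageScope`). All bounds are inclusive.
#'
#' @param x A [PoolSnpSet-class].
#' @param thresholds A [FilterThresholds-class].
#' @return The surviving [PoolSnpSet-class], order preserved.
#' @export
applySiteFilters <- function(x, thresholds = filterThresholds()) {
  if (!length(x)) return(x)
  flags <- siteFilterFlags(x, thresholds)
  x[!apply(flags, 1L, any)]
}

#' Apply the indel length and hard filters
#'
#' Removes indel records with `|len(ref) - len(alt)| > indelMaxLen` or
#' failing any hard-filter clause (`QUAL < indelQualMin`,
#' `QD < indelQdMin`, `ReadPosRankSum < readPosMin`, `FS > fsMax`,
#' `QUAL < mean QUAL`). Missing annotations do not trigger removal.
#'
#' @param indels data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `QD`, `FS`, `ReadPosRankSum` (see [readVcfIndels()]).
#' @param thresholds A [FilterThresholds-class].
#' @param qualFloor optional precomputed mean-QUAL floor.
#' @return The surviving rows, order preserved.
#' @export
applyIndelFilters <- function(indels, thresholds = filterThresholds(),
                              qualFloor = NULL) {
  if (!nrow(indels)) return(indels)
  if (is.null(qualFloor))
    qualFloor <- if (thresholds@qualFloorMode == "mean") meanQual(indels)
    else thresholds@qualFloor
  flag <- function(v) !is.na(v) & v
  len <- abs(nchar(indels$ref) - nchar(indels$alt))
  bad <- len > thresholds@indelMaxLen |
    flag(indels$qual < thresholds@indelQualMin) |
    flag(indels$QD < thresholds@indelQdMin) |
    flag(indels$ReadPosRankSum < thresholds@readPosMin) |
    flag(indels$FS > thresholds@fsMax) |
    flag(indels$qual < qualFloor)
  indels[!bad, , drop = FALSE]
}

.variantKeys <- function(x) {
  if (is(x, "PoolSnpSet")) return(siteKeys(x))
  if (is.data.frame(x))
    return(paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  as.character(x)
}

#' Intersect two callsets by variant identity
#'
#' Returns the records present in both sets, keyed by
#' (chrom, pos, ref, alt); all annotations are taken from `a`
#' (GATK-concordance style).
#'
#' @param a,b Two [PoolSnpSet-class] objects or indel data.frames.
#' @return Subset of `a` whose keys occur in `b`.
#' @export
intersectCallsets <- function(a, b) {
  keep <- .variantKeys(a) %in% .variantKeys(b)
  if (is(a, "PoolSnpSet")) a[which(keep)] else a[keep, , drop = FALSE]
}

#' Membership-pattern overlap counts across named callsets
#'
#' Venn-style tabulation: for every non-empty membership pattern over
#' the named sets, the number of variant keys showing exactly that
#' pattern. Counts sum to the size of the union.
#'
#' @param sets named list (>= 2 elements) of [PoolSnpSet-class]
#'   objects, indel data.frames, or character key vectors.
#' @return data.frame with one logical column per set, a `pattern`
#'   label, and a `count`.
#' @export
snpSetOverlap <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need a named list of >= 2 sets")
  keys <- lapply(sets, function(s) unique(.variantKeys(s)))
  all <- unique(unlist(keys))
  member <- vapply(keys, function(k) all %in% k, logical(length(all)))
  if (length(all) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  for (nm in names(sets))
    out[[nm]] <- vapply(strsplit(out$pattern, "&", fixed = TRUE),
                        function(p) nm %in% p, logical(1))
  out[order(-out$count, out$pattern), c(names(sets), "pattern", "count")]
}

#' Indel length spectrum
#'
#' Histogram of signed indel lengths (insertions positive, deletions
#' negative), restricted to |length| <= `maxLen`.
#'
#' @param indels indel data.frame with `ref` and `alt` columns.
#' @param maxLen maximum absolute length tabulated.
#' @return data.frame with columns `length` and `count`; total count
#'   equals the number of records within range.
#' @export
indelLengthSpectrum <- function(indels, maxLen = 25L) {
  if (!nrow(indels))
    return(data.frame(length = integer(), count = integer()))
  len <- nchar(indels$alt) - nchar(indels$ref)
  len <- len[abs(len) <= maxLen & len != 0L]
  tab <- table(len)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}
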