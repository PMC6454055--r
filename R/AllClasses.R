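#' @include poolSweeps-package.R
NULL

#' PoolSnpSet: biallelic SNP sites with pooled read counts and wild genotypes
#'
#' Container for the analysis-ready SNP table. Each row is one biallelic
#' site; columns of the count matrices are sequencing pools (one per
#' breed), columns of the genotype matrix are wild diploid individuals.
#' Coordinates are 1-based (GRanges convention).
#'
#' @slot sites [GRanges] of width-1 positions with metadata columns
#'   `ref` and `alt` (single-letter alleles for SNPs).
#' @slot refCounts,altCounts integer matrices (sites x pools) of reads
#'   supporting the reference / alternate allele.
#' @slot poolSizes named integer vector: diploid individuals per pool.
#' @slot wildGeno integer matrix (sites x individuals) of alt-allele
#'   dosages in \{0, 1, 2\}; `NA` marks a missing genotype. May have zero
#'   columns when no wild panel is attached.
#' @slot qual numeric site quality scores (`NA` allowed).
#' @slot info [DataFrame] of filter annotations (`QD`, `FS`,
#'   `ReadPosRankSum`); missing annotations are `NA`.
#'
#' @seealso [PoolSnpSet()], [readVcfPools()], [readSync()]
#' @export
setClass("PoolSnpSet",
  representation(
    sites      = "GRanges",
    refCounts  = "matrix",
    altCounts  = "matrix",
    poolSizes  = "integer",
    wildGeno   = "matrix",
    qual       = "numeric",
    info       = "DataFrame"
  )
)

setValidity("PoolSnpSet", function(object) {
  n <- length(object@sites)
  msg <- character()
  if (!all(width(object@sites) == 1L))
    msg <- c(msg, "all sites must have width 1")
  mc <- mcols(object@sites)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
  else if (any(mc$ref == mc$alt))
    msg <- c(msg, "ref and alt alleles must differ at every site")
  if (nrow(object@refCounts) != n || nrow(object@altCounts) != n)
    msg <- c(msg, "count matrices must have one row per site")
  if (!identical(dim(object@refCounts), dim(object@altCounts)))
    msg <- c(msg, "refCounts and altCounts must have identical dimensions")
  if (ncol(object@refCounts) != length(object@poolSizes))
    msg <- c(msg, "poolSizes must name every count column")
  if (any(object@refCounts < 0, na.rm = TRUE) ||
      any(object@altCounts < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be non-negative")
  if (nrow(object@wildGeno) != n && ncol(object@wildGeno) > 0L)
    msg <- c(msg, "wildGeno must have one row per site")
  g <- object@wildGeno
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "wild genotypes must be dosages in {0,1,2} or NA")
  if (length(object@qual) != n)
    msg <- c(msg, "qual must have one value per site")
  if (nrow(object@info) != n)
    msg <- c(msg, "info must have one row per site")
  if (length(msg)) msg else TRUE
})

#' GenomeScan: windowed Hp/Fst statistics for one comparison
#'
#' Ordered collection of retained genome windows for one focal-vs-
#' background comparison, together with the genome-wide Z-normalization
#' constants (mu, sigma) used to standardize the windowed statistics.
#'
#' @slot windows [GRanges] of retained windows (>= `minSnps` usable
#'   SNPs) with metadata columns `nSnps`, `hpFocal`, `hpBackground`,
#'   `fst`, `zHp`, `zFst`.
#' @slot zstats list with elements `hp` and `fst`, each `c(mu, sigma, n)`.
#' @slot comparison label, e.g. `"domestic_vs_wild"`.
#' @slot estimator `"wc"` (Weir-Cockerham) or `"hudson"`.
#' @slot windowSize,step window grid parameters in bp.
#' @slot minSnps minimum usable SNPs for a window to be retained.
#' @slot nDiscarded number of grid windows dropped by the SNP-count rule
#'   or for having no usable data.
#' @export
setClass("GenomeScan",
  representation(
    windows    = "GRanges",
    zstats     = "list",
    comparison = "character",
    estimator  = "character",
    windowSize = "integer",
    step       = "integer",
    minSnps    = "integer",
    nDiscarded = "integer"
  )
)

#' FilterThresholds: variant filtering parameters
#'
#' Bundles the hard-filter and site-filter thresholds applied to SNP and
#' indel callsets: GATK-style annotation clauses (QD, ReadPosRankSum,
#' FS, QUAL floor), minor-allele-frequency and completeness cutoffs, a
#' per-pool coverage floor, and the maximum indel length.
#'
#' @slot qdMin,readPosMin,fsMax SNP hard-filter clause thresholds
#'   (remove if QD < qdMin, ReadPosRankSum < readPosMin, FS > fsMax).
#' @slot qualFloorMode `"mean"` (floor = mean QUAL of the callset) or
#'   `"fixed"` (floor = `qualFloor`).
#' @slot qualFloor numeric floor used when `qualFloorMode == "fixed"`.
#' @slot mafMin minimum minor allele frequency (inclusive; kept if >=).
#' @slot minCallRate minimum fraction of units with data (inclusive).
#' @slot coverageMin minimum summed read depth (kept if >=).
#' @slot coverageScope `"per-pool"` (every pool) or `"total"`.
#' @slot missingScope units counted for completeness: `"both"`,
#'   `"pools"`, or `"wild"`.
#' @slot indelMaxLen maximum |len(ref) - len(alt)| retained (inclusive).
#' @slot indelQualMin,indelQdMin indel hard-filter clause thresholds.
#' @export
setClass("FilterThresholds",
  representation(
    qdMin         = "numeric",
    readPosMin    = "numeric",
    fsMax         = "numeric",
    qualFloorMode = "character",
    qualFloor     = "numeric",
    mafMin        = "numeric",
    minCallRate   = "numeric",
    coverageMin   = "numeric",
    coverageScope = "character",
    missingScope  = "character",
    indelMaxLen   = "numeric",
    indelQualMin  = "numeric",
    indelQdMin    = "numeric"
  )
)

setValidity("FilterThresholds", function(object) {
  msg <- character()
  num <- c(object@qdMin, object@readPosMin, object@fsMax, object@mafMin,
           object@minCallRate, object@coverageMin, object@indelMaxLen,
           object@indelQualMin, object@indelQdMin)
  if (any(!is.finite(num)))
    msg <- c(msg, "all numeric thresholds must be finite")
  if (object@mafMin < 0 || object@mafMin > 0.5)
    msg <- c(msg, "mafMin must lie in [0, 0.5]")
  if (object@minCallRate < 0 || object@minCallRate > 1)
    msg <- c(msg, "minCallRate must lie in [0, 1]")
  if (!object@qualFloorMode %in% c("mean", "fixed"))
    msg <- c(msg, "qualFloorMode must be 'mean' or 'fixed'")
  if (!object@coverageScope %in% c("per-pool", "total"))
    msg <- c(msg, "coverageScope must be 'per-pool' or 'total'")
  if (!object@missingScope %in% c("both", "pools", "wild"))
    msg <- c(msg, "missingScope must be 'both', 'pools' or 'wild'")
  if (length(msg)) msg else TRUE
})

#' SweepSimConfig: parameters of the pool-seq sweep simulator
#'
#' Describes a simulated study: chromosome lengths, SNP density, pool
#' composition and sequencing depth, the Beta-drift allele-frequency
#' model, and the planted sweep intervals used for recovery scoring.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot snpDensity expected SNPs per bp (Poisson process rate).
#' @slot poolSizes named integer vector of diploid individuals per pool.
#' @slot nWild number of wild diploid individuals.
#' @slot meanDepth mean per-pool read depth per site (Poisson).
#' @slot ancestralShape shape of the symmetric Beta ancestral-frequency
#'   law, truncated to (0, 1).
#' @slot driftF,wildDriftF drift coefficients: each group's frequency is
#'   Beta-distributed with mean equal to the ancestral frequency f and
#'   variance F * f * (1 - f).
#' @slot sweeps [GRanges] of planted sweep intervals with a numeric
#'   metadata column `s` (intensity in (0, 1]).
#' @slot wildMissingRate per-genotype missingness probability.
#' @slot seed integer seed fanned out to per-stage substreams.
#' @export
setClass("SweepSimConfig",
  representation(
    chromLengths    = "numeric",
    snpDensity      = "numeric",
    poolSizes       = "integer",
    nWild           = "integer",
    meanDepth       = "numeric",
    ancestralShape  = "numeric",
    driftF          = "numeric",
    wildDriftF      = "numeric",
    sweeps          = "GRanges",
    wildMissingRate = "numeric",
    seed            = "integer"
  )
)

setValidity("SweepSimConfig", function(object) {
  msg <- character()
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  if (object@snpDensity <= 0) msg <- c(msg, "snpDensity must be > 0")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@ancestralShape <= 0) msg <- c(msg, "ancestralShape must be > 0")
  if (object@driftF < 0 || object@wildDriftF < 0)
    msg <- c(msg, "drift coefficients must be >= 0")
  if (object@wildMissingRate < 0 || object@wildMissingRate >= 1)
    msg <- c(msg, "wildMissingRate must lie in [0, 1)")
  if (length(object@sweeps)) {
    s <- object@sweeps$s
    if (is.null(s) || any(s <= 0) || any(s > 1))
      msg <- c(msg, "sweep intensities 's' must lie in (0, 1]")
    cl <- object@chromLengths
    sc <- as.character(seqnames(object@sweeps))
    if (!all(sc %in% names(cl)))
      msg <- c(msg, "sweeps must lie on declared chromosomes")
    else if (any(end(object@sweeps) > cl[sc]) || any(start(object@sweeps) < 1))
      msg <- c(msg, "sweeps must lie within chromosome bounds")
    if (length(object@sweeps) > 1) {
      red <- reduce(object@sweeps, min.gapwidth = 0L)
      if (length(red) != length(object@sweeps))
        msg <- c(msg, "sweep intervals must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})
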