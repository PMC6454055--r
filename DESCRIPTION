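Package: poolSweeps
Title: Selective Sweep Scans from Pooled Whole-Genome Resequencing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects selective sweep regions from pooled whole-genome
    resequencing data compared against individually genotyped wild
    outgroups. Implements GATK-style hard filtering and site filtering of
    SNP and indel callsets, sliding-window pooled heterozygosity (Hp) and
    Weir-Cockerham or Hudson fixation index (Fst) with genome-wide
    Z-transformation, dual top-quantile outlier selection with window
    merging and cross-population region intersection, candidate-gene and
    coding-variant (HGVS c./p.) annotation with protein-domain membership,
    and a Beta-drift pool-seq simulator with planted sweeps for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'poolSweeps-package.R'
    'AllClasses.R'
    'PoolSnpSet-methods.R'
    'variant-io.R'
    'filters.R'
    'windows.R'
    'sweep-detection.R'
    'annotation.R'
    'simulate.R'
    'pipeline.R'
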