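---
title: "Methods: windowed pool-seq selective-sweep scans"
author: "poolSweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed pool-seq selective-sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolSweeps)
```

## The problem and the data model

Pooled whole-genome resequencing trades individual genotypes for
cheap, deep allele-frequency estimates: DNA from tens of individuals
per population is sequenced as one library, and at each SNP the only
observable is the pair of reference/alternate read counts. A
selective sweep — a beneficial allele driven to high frequency during
domestication or local adaptation — leaves two windowed footprints:
depressed heterozygosity in the selected population and elevated
allele-frequency differentiation against an outgroup that did not
experience the selection. `poolSweeps` detects both footprints
jointly.

The central container, `PoolSnpSet`, holds biallelic SNP sites
(a width-1 `GRanges`), one pair of read-count matrices per sequencing
pool, and an alternate-allele dosage matrix (0/1/2, `NA` for missing)
for the individually genotyped wild panel. All downstream statistics
consume only these counts; no genotype likelihoods or haplotypes are
modeled.

## Variant filtering

SNPs pass a GATK-style hard filter — a record is removed iff
`QD < 20`, `ReadPosRankSum < -8`, `FS > 10`, or `QUAL` below a floor
— followed by site filters: minor allele frequency at least 0.05,
completeness at least 0.7, and summed depth at least 8 in every pool.
Indels are additionally restricted to 25 bp or shorter and use the
laxer `QD < 2`, `QUAL < 20` clauses. Numerical conventions worth
stating explicitly:

- **The QUAL floor is the callset mean** (computed before any
  filtering, genome-wide, over non-missing values); a fixed floor is
  available via `filterThresholds(qualFloorMode = "fixed")`. The
  genome-wide choice keeps the floor independent of chromosome
  composition.
- **Missing annotations never remove a record.** A site without a
  `ReadPosRankSum` value cannot fail the `ReadPosRankSum` clause —
  the usual hard-filter semantics.
- **All site-filter bounds are inclusive** (MAF exactly 0.05 is
  kept), matching the `--maf`/`--max-missing` conventions of vcftools.
- **MAF over mixed observations** combines pool reads (one
  chromosome per read) with wild genotypes (two chromosomes per
  individual). **Completeness** counts units with any data — each
  pool and each wild individual — over all units by default; the
  scope is configurable to pools or wild only, since either reading
  of a shared completeness cutoff is defensible.
- **Depth is judged per pool** (`coverageScope = "per-pool"`):
  a coverage floor is only meaningful within a sequencing library;
  a per-site total is available.

Filtering is order-stable and idempotent, which the suite asserts by
re-applying every filter to its own output.

## Windowed statistics

Chromosomes are tiled into 150-kb windows stepped by 75 kb, anchored
at coordinate 0, the last window truncated at the chromosome end.
Anchoring at step multiples is deliberate: reported candidate-region
boundaries in this kind of scan are multiples of the step, and the
grid guarantees every interior base two chances to be covered by a
significant window. A SNP at 1-based position p belongs to window
[s, e) iff p − 1 ∈ [s, e).

**Pooled heterozygosity.** Within a group, each SNP's reads are
polarized into major/minor counts (ties labeled reference-major, a
deterministic tie-break), summed over the window's member SNPs, and
combined as H_P = 2·Σn_MAJ·Σn_MIN/(Σn_MAJ + Σn_MIN)². The statistic
lives in [0, 0.5] and hits 0.5 only when summed major and minor
counts tie. For the wild panel the same formula runs on allele
dosage counts. Zero-depth SNPs contribute nothing.

**Fixation index.** The F_ST literature offers several estimators
whose windowed Z-scores rank outliers almost identically; the package
defaults to the Weir–Cockerham (1984) two-population θ in its
allele-count (ANOVA) form and offers the Hudson estimator (Bhatia et
al. 2013) as an alternative, labeling the choice in the scan object
and reports. Sample sizes are counted in chromosomes:

- a pool contributes `min(read depth, 2 × individuals)` — read
  resampling cannot yield more information than the 2N chromosomes
  in the pool;
- the wild panel contributes `2 × non-missing individuals`.

Per-SNP variance components are summed over the window and divided
(ratio of averages), the multi-locus combination Weir & Cockerham
prescribe; for WC the components are scaled to the variance level
(a and a + b) so that SNPs with different effective sizes combine
correctly. Negative window ratios — expected under no
differentiation — are clamped to 0 with the raw value retained;
values above 1 clamp to 1. A SNP where either group is monomorphic
with a vanishing denominator, or where a group has fewer than two
chromosomes, contributes (0, 0) and drops out.

**Retention and Z-scores.** Windows with fewer than 10 member SNPs,
or with no usable data for either statistic, are discarded rather
than imputed. μ and σ (sample standard deviation, n − 1; population
σ available) are computed per comparison over the retained windows
only — normalizing after the discard keeps the reference
distribution and the selection universe identical.

## Selection, merging, intersection

A window is selected when it lies simultaneously in the top-quantile
F_ST tail and the bottom-quantile H_P tail (default q = 0.01 per
tail). The empirical threshold is the order statistic at
⌈q·n⌉ from the relevant end, and boundary-equal values are included
— "top 1%" reads most naturally as inclusive, and the choice only
matters under ties. The selected fraction is therefore bounded by
roughly q, the intersection of two dependent tails.

Selected windows merge into regions when they overlap **or are
book-ended**: 75-kb-stepped significant neighbors always overlap, so
book-ended merging only affects truncated chromosome-end windows. A
run of k grid-consecutive windows spans 150 + 75·(k − 1) kb, so a
set of W windows in R maximal runs has total length 75·(W + R) kb —
the telescoping identity the acceptance suite checks at W = 30,
R = 18 (3.6 Mb). Region summaries report the mean constituent F_ST
and minimum constituent H_P. Region sets from different focal
populations intersect on genomic coordinates (the window-level
alternative is a stricter variant; coordinate intersection is what
interval algebra on merged BED-like sets naturally computes), with
empty intersections dropped.

Per-breed contrasts run one focal pool against either the wild panel
or the **summed reads** of all other pools. Summing reads (rather
than averaging pool frequencies) weighs each background pool by its
realized depth, exactly as if the background had been sequenced as
one pool; it is also the only choice that makes a two-pool background
reduce bit-for-bit to the pairwise scan, which the suite checks.

## Candidate annotation

Genes overlapping a region by one or more bp are its candidates; an
overlap-free region falls back to the nearest gene by edge distance
(gap in bp, book-ended = 0) on the same chromosome, unbounded and
flagged `nearestOnly`, with distance ties reporting every tied gene.
Coding arithmetic is transcript-strand 1-based: codon index
⌈cds_pos/3⌉, position-in-codon ((cds_pos − 1) mod 3) + 1, standard
genetic code only (nuclear genes). The coding-change annotator is
validated exhaustively against a literal code table over all 576
single-base codon substitutions. Domain membership is inclusive on
1-based amino-acid spans.

## The simulator: what it emulates and what it does not

The generator produces the statistical structure the scan consumes —
nothing more:

- SNP positions: Poisson process, default density 1/500 bp.
- Ancestral frequencies: symmetric Beta(0.5, 0.5), truncated to the
  open unit interval — a U-shaped spectrum resembling a neutral SFS.
- Drift: each group's frequency is Beta-distributed with mean f and
  variance F·f(1 − f). The default F = 0.23 is calibrated so the
  expected per-SNP F_ST between two independently drifted groups
  (which equals F under this model, by the ratio of expectations)
  matches a genome-wide average differentiation of ≈ 0.23 between
  domestic pools and wild outgroup. Under Beta drift the Hudson
  components are conditionally unbiased given the true frequencies,
  giving closed-form expectations the property tests exploit; a
  coalescent backend is out of scope.
- Observations: per-pool depth Poisson(45), alternate reads
  Binomial(depth, f); wild dosages Binomial(2, f) with 2% missing.
  Passing-range QUAL/QD/FS/ReadPosRankSum annotations are attached so
  records flow through the real filters (the mean-QUAL floor removes
  about half of them, as it must for any unimodal quality law).
- Sweeps: inside a planted interval of intensity s, every domestic
  pool's frequency moves to
  (1 − s)·f_pool + s·(1 − [f_wild ≥ 0.5]) — toward the allele
  opposing the wild major allele, so at s = 1 the pools fix and H_P
  drops to exactly 0 while F_ST rises to the estimator's maximum.

**Scene sizing is a detectability constraint.** The reference scene
uses two 90-Mb chromosomes (≈ 2,400 retained windows) with five
pools of 80/89/50/58/61 individuals, 17 wild diploids and three
450-kb sweeps whose boundaries sit on the 75-kb grid. The dual
top-1% rule can flag at most ⌈0.01·n⌉ windows; three 450-kb sweeps
touch ~21 grid windows, so the genome must contribute at least
~2,100 retained windows for the rule to be able to recover them at
all — a constraint any simulation design for a fixed-quantile scan
must respect. At 2,400 windows the capacity is 24, comfortably above
21, and a full pipeline run stays around ten seconds on one CPU;
property tests that need many replicates scale the same generator
down to 3–45 Mb scenes.

One global seed fans out to per-stage substreams, so
generate → scan → detect is reproducible end to end and stages can
be replayed in isolation.

What passing these tests does **not** show about real data: the
simulator draws free recombination (no linkage, no haplotype
structure around the sweep), no sequencing error beyond binomial
sampling, no reference bias, no correlated drift between breeds
sharing recent history, and sweeps as hard frequency displacements
rather than trajectories. Recovery rates on this generator are upper
bounds on what messy data allow.

## Degenerate inputs and edge policies

- Empty callsets and empty window sets flow through every stage
  (headers-only outputs, empty `GRanges`).
- Constant statistics make σ undefined: `zTransform` refuses rather
  than emitting zeros.
- A selection quantile needs at least ⌈1/q⌉ retained windows.
- Multi-allelic VCF sites are dropped by default (pooled allelic
  depths across more than two alleles are ambiguous); an explicit
  `"split"` mode emits one biallelic record per alternate allele.
- Sync-dialect sites are polarized by inferring the alternate allele
  as the highest-count non-reference base (A,T,C,G order breaking
  ties); monomorphic sites survive parsing and die at the MAF filter.

## Known limitations

Haplotype-based statistics (iHS, XP-EHH), LD, per-SNP outlier
reporting, permutation/FDR significance beyond the empirical
quantile rule, and deleteriousness scoring are out of scope. The
wild panel is treated as one population; substructure there would
inflate F_ST genome-wide (absorbed by the Z-transformation) but can
distort the tails. CDS-coordinate annotation trusts the supplied
transcript; genomic-to-CDS projection is only attempted when CDS
segments are provided.
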