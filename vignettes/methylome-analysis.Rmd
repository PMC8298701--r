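---
title: "Symmetric ApT 6mA methylome analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric ApT 6mA methylome analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methApT)
```

## The biological model

`methApT` analyzes N6-methyldeoxyadenine (6mA) in genomes where the mark
occurs **symmetrically at ApT dinucleotides**: because the reverse
complement of 5'-AT-3' is again 5'-AT-3', both strands present an adenine,
and semiconservative replication leaves each daughter duplex hemimethylated
— the structural basis for heritability of the mark. Single-molecule
sequencing reports one modification call per strand, with a per-strand
coverage, a detection p-value, and an estimated methylated fraction.

In a coenocytic fungus with haploid nuclei (the arbuscular mycorrhizal
fungi are the motivating case), every sequenced molecule derives from one
nucleus. A site's methylation ratio therefore estimates the *fraction of
nuclei* carrying the mark, and the genome-wide ratio distribution is an
among-nucleus heterogeneity profile. This interpretation drives three
design choices:

* both strands of a symmetric site are modeled as sharing one true ratio
  (the mark is either present or absent in a given nucleus; strands differ
  only by binomial sampling);
* the per-site scalar is the coverage-weighted mean of the two strand
  fractions, the minimum-variance combination under that shared-ratio
  model (a min-of-strands alternative was rejected as biased low);
* between-sample comparisons are phrased per site in terms of binomial
  confidence limits, not population-level tests.

## Site calling and filtering

Calls are filtered at per-strand coverage ≥ 25 and detection p ≤ 0.001.
Both thresholds are inclusive: "minimum 25×" reads naturally as ≥ 25, and a
p-value exactly at the cutoff is accepted, matching common caller behavior.
When the caller emits a Phred-scaled identification QV instead of a
p-value, the package converts `p = 10^(-QV/10)`, so the 0.001 threshold
corresponds to QV ≥ 30; an explicit `pValue` attribute takes precedence
when present.

A plus-strand call at forward position *i* pairs with a minus-strand call
at *i + 1* iff the forward bases at (*i*, *i* + 1) are (A, T). The partner
position of any call is unique, so the pairing needs no tie-breaking; a
brute-force oracle that tests every call pair is part of the test suite and
must agree exactly. Leftover calls are labelled *asymmetric-ApT* (an ApT
context methylated on one strand only) or *non-ApT*; calls whose own strand
base is not an adenine (including on N) are excluded with a warning. The
4-mer motif is reported on the forward strand of the ApT: AATT is
self-reverse-complementary, while pairs such as CATT/AATG are reverse
complements of each other and are counted separately, as motif tables in
this field list them.

The percent of adenines methylated uses both strands in the denominator:
forward-strand A plus forward-strand T (each T is a reverse-strand A).

## Heterogeneity and divergence

Ratio distributions are summarized by n, mean, min, max and quartiles, with
quartiles interpolated at `h = (n − 1)p + 1` (R's default type-7 rule,
matching the statistical environment practitioners in this field use).

For two samples, sites are matched by (contig, position); only shared sites
are compared (comparing the union would conflate presence/absence with
ratio divergence — an `adjust`-style extension point is left for the
union). Since the caller reports a fraction rather than a methylated-read
count, the effective count is `k = round(ratio × total coverage)`, an
unavoidable rounding. Each sample gets an exact Clopper–Pearson interval at
the 2.5% and 97.5% limits (via beta quantiles), and a site is *divergent*
iff the intervals are disjoint. This interval-disjointness rule was chosen
over a two-proportion z-test because the quantity of interest is stated in
terms of confidence limits; disjointness of two 95% intervals is
conservative (empirical type-I error well below 5%, which the null
calibration test asserts at 10,000 simulated sites with coverage ~50 per
strand). No multiple-testing correction is applied by default, mirroring
the raw per-site rule; Benjamini–Hochberg on exact Fisher p-values is
available behind `adjust = "BH"`.

## Topology and expression

Gene regions use a 500 bp flank on each side: promoter upstream, downstream
region downstream, mirrored for minus-strand genes. Each site receives
exactly one region; when flank windows of neighboring genes overlap, the
site goes to the gene with the nearest annotated start (leftmost on ties)
and the overlap count is kept in a secondary column. A gene is *methylated*
iff it harbors at least one symmetric site in its annotated body; promoter
sites are counted separately and do not flip the flag by default
(`include_promoter = TRUE` flips this), because harboring a motif is a
statement about the gene body while flanks are a topology statement.
Density divides body-site count by the annotated gene span — without CDS
features the span is the available proxy for coding length.

The density–expression association uses Kendall's tau-b with tie
correction, computed on raw FPKM (rank-based, hence invariant to the
log2(FPKM + 1) transform used for grouping and display). The p-value is the
exact small-sample distribution where available (no ties, n < 50) and the
tie-corrected normal approximation otherwise; full permutation enumeration
is infeasible beyond trivial n, so "exact where exact is possible" is the
operative rule. An O(n²) pair-enumeration oracle in the tests pins the
statistic to 1e-12.

## SV callset comparison

Variants are intervals `[position, position + length)`; insertions use
their SVLEN-derived length, since reciprocal overlap is undefined for point
events (a documented divergence risk against span-only interval tools).
After removing translocations and records with read support below 15
(strict), two callsets are matched one-to-one, greedily in descending
overlap (ties to the leftmost pair), requiring the shared span to reach 80%
of *both* lengths and identical class and contig. Greedy one-to-one
matching reflects that callset comparisons count variants, so no record may
be double-counted. Jaccard distances feed average-linkage clustering;
node support is an ordinary bootstrap over SV-locus presence columns
(resampled with replacement), which approximates — but is not identical
to — multiscale bootstrap tools; supports are comparable, not
interchangeable. TE-relatedness is a breakpoint rule: a variant is
TE-related iff `position` or `position + length` falls inside an annotated
repeat, not merely when the spans overlap.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions the package is built
around:

| parameter | default | rationale |
|---|---|---|
| `n_genes`, `genome_length` | 400 genes, 2.4 Mb | desk-scale genome; the length is sized so ~0.2% of adenines end up methylated, the level typical of the AMF system |
| `frac_methylated_genes` | 0.25 | about a quarter of genes carry the mark |
| `apt_sites_per_gene_mean` | 10 | Poisson mean sites per methylated gene |
| `ratio_beta_alpha/beta` | 2.2 / 1.15 | Beta mean ≈ 0.657 with broad spread; only summary statistics of the real ratio distribution are known, so a two-parameter Beta matching mean and dispersion is the simplest generative law |
| `coverage_mean` | 40 (truncated ≥ 25) | per-strand Poisson coverage clearing the filter |
| `region_weights` | 0.20/0.66/0.07/0.07 | puts ~86% of sites in gene body + promoter |
| `asymmetric_background_rate` | 3e-4 per adenine | a free parameter (no empirical background rate is known); set so ~10% of emitted calls are background |
| `expression_link_slope`, `expression_noise_sd` | 1, 1 | positive monotone density–FPKM link with realistic scatter |
| `divergence_shift`, `divergent_site_frac` | 0.4, 0.05 | planted two-sample contrasts |

The generator plants ApT contexts (AATT-weighted flanks) into the sequence
at chosen loci, draws one true ratio per site shared by both strands, and
emits per-strand calls with binomial sampling. One global seed is split per
stage via fixed offsets, so files are individually and jointly
reproducible; identical configurations give byte-identical output.

What it deliberately does **not** emulate: raw polymerase kinetics and IPD
values (calls are taken as given, with p-values sampled below threshold);
mapping artefacts and reference errors; sequence composition beyond uniform
base usage plus planted contexts; overlapping or nested genes;
isolate-specific gene content (all samples share one annotation); and
nucleus-genotype structure within dikaryons. Passing the recovery tests
therefore shows the downstream arithmetic and inference are correct under
the stated model — not that the model captures every property of real
single-molecule data.

## Numerical choices and problem sizes

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at file boundaries (GFF/VCF are 1-based, BED is native).
* Clopper–Pearson limits come from `qbeta`; k = 0 and k = n collapse to 0
  and 1 exactly.
* Degenerate inputs: empty call sets flow through as empty frames with
  zeroed summaries; a single ratio yields all five summary statistics equal
  to it; zero shared sites between samples is an error, as is a zero LC-MS
  denominator (excluded with a warning when other replicates remain).
* Test problem sizes are chosen to keep the default suite in tens of
  seconds while leaving comfortable statistical margins: 50 random 10-kb
  genomes for the pairing oracle, 10,000 sites for divergence calibration
  and power, 100 random tied datasets (n ≤ 500) for tau-b, the 400-gene
  demo for end-to-end recovery. The region-weight sanity bound (< 0.03) is
  asserted on the mean of three replicate generations, since a single
  ~2000-site multinomial draw sits within ~3 standard errors of that bound.

## Known limitations

* The divergence rule is conservative by construction; its power at small
  shifts and low coverage is limited, and reported divergent fractions are
  not directly comparable across coverage regimes.
* Bootstrap supports from the ordinary locus bootstrap are not multiscale
  supports; treat them as qualitative clade evidence.
* Gene span stands in for coding length in density; densities from
  intron-rich annotations will be biased low relative to CDS-based ones.
* The percent-of-genes-methylated statistic depends on the gene-body-only
  convention; enabling `include_promoter` changes it.
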