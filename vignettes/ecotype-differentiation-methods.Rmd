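---
title: "Detecting ecotype differentiation from population SNP data: models and choices"
author: "EcotypeScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ecotype differentiation from population SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EcotypeScan)
```

# The problem

Upland (dry-land) and irrigated rice are two ecotypes of the same crop
that differ visibly — upland varieties are taller, lower-tillering, and
carry longer, heavier roots — and have diverged genetically under natural
and artificial selection. Given low-coverage re-sequencing of two panels
of accessions (on the order of 84 upland + 82 irrigated samples, with
roughly two thirds of genotypes missing per accession), the analysis task
is to locate the genomic regions where the two ecotypes have been pulled
apart by selection, and the genes and SNPs inside them.

EcotypeScan implements that analysis end to end as reusable, tested R
functions:

1. **Genotyping** — per-sample genotype decision rules for low-coverage
   consensus calls, site filters, allele-frequency estimation with
   missing-data masking.
2. **Differentiation scan** — windowed Nei FST plus a cross-population
   composite-likelihood sweep scan; regions in the top tail of *both*
   scans are called ecotype differentiated regions (EDRs), SNPs inside
   them with an allele-frequency difference above 60% are ecotype
   differentiated SNPs (EDSs), and genes overlapping them are ecotype
   differentiated genes (EDGs).
3. **Per-population sweep scan** — a single-population composite
   likelihood ratio on the site frequency spectrum (SFS), used to assign
   each EDG to the population(s) in which selection acted.
4. **Phylogenetics and structure** — F84 distances, neighbor-joining
   trees with bootstrap consensus, genotype PCA and EM admixture.
5. **Phenotypes and enrichment** — group summaries, difference and
   percentage conventions, Student's t, Pearson correlations, and
   chi-square contingency enrichment of gene categories.

A synthetic-data generator with recorded ground truth stands in for the
(unavailable at desk scale) re-sequencing data, so every stage is
testable.

# The synthetic-data generator

The generator is a first-class module, not a fixture. Its defaults *are*
the study conditions the package is designed around: 84 + 82 samples,
67% missing genotypes, per-site depths in [6, 300], background
between-ecotype FST 0.06, and a 96.4% concordance between raw call
records and true genotypes. Genome size defaults are desk-scale — 2
chromosomes of 1 Mb carrying 10,000 SNPs — chosen so that a full scan
runs in seconds while windows and grids keep their published sizes.

## Frequencies

Background sites follow a Balding–Nichols model: an ancestral
reference-allele frequency `p ~ Uniform(0.05, 0.95)`, and each
population's frequency drawn from `Beta` with mean `p` and dispersion
`c`. A point that matters: for **two** demes drawn independently this
way, the realized between-deme Nei FST is `(c/2)/(1 - c/2)`, not `c`.
The generator therefore uses `c = 2F/(1+F)` so that the *realized*
two-population Nei FST equals the configured `fstBackground` — the
quantity actually reported for real data. Genome-wide FST is summarized
with Nei's multi-locus ratio-of-sums estimator
`sum(HT - HS)/sum(HT)`; the mean of per-site ratios is Jensen-biased
downward (severely so at high differentiation) and is not used.

## Sweeps

Each planted sweep is an interval in which the irrigated population
keeps a low derived-allele frequency `q ~ Uniform(0, 1 - d)` while the
swept population carries `q + d` (so `|p1 - p2| >= d` at every sweep
site by construction), then skewed toward fixation by
`p -> p^(1/sfsSkew)` — a simple, monotone distortion that mimics the
excess of high-frequency derived alleles after a sweep. Sweep widths of
~40 kb are used in tests, matching the order of the median region
lengths reported for real rice scans (≈23–41 kb). This matters for the
intersection logic: the top 5‰ of windows covers only ~0.5% of the
genome, so a sweep much wider than that selected mass cannot be fully
recovered by construction at desk scale.

## What the generator does not emulate

Linkage disequilibrium (sites are drawn independently), recombination
maps, indels/multiallelics, read-level errors, and relatedness between
samples. Passing tests therefore demonstrate correctness of the
estimators and calling logic under the stated generative model, not
robustness to LD or population substructure in real data.

# Genotype decision rules

Raw per-(site, sample) evidence carries the best and second-best base
with their Phred-scale average qualities and a consensus genotype with
its quality. With the score-20 threshold (error rate at most 1%):
best ≥ 20 and second < 20 gives a homozygote of the best base; both
≥ 20 gives the heterozygote; both < 20 but consensus ≥ 20 falls back to
the consensus IUPAC code; anything else is missing. Calls inconsistent
with the site's ref/alt pair are set missing. Site-level filters keep a
site iff quality ≥ 15, copy number ≤ 1.5 and depth in [6, 300] — the
boundary depths are kept, since only strict violations are named.

Frequencies use allele counting (heterozygotes contribute 1 of 2); a
site is masked for a population unless **more than** 10 individuals are
called there. The two printed phrasings of this threshold disagree at
exactly n = 10; the stricter "more than 10" reading is the default and
the threshold is a parameter. The structure-SNP subset analogously keeps
sites called in more than 100 samples.

# The differentiation scans

## Windowed Nei FST

Per site, `FST = (HT - HS)/HT` with `HT = 2*pbar*(1 - pbar)` and
`HS = p1(1-p1) + p2(1-p2)`; monomorphic sites are defined as 0. The
variant is Nei's G\_ST without sample-size correction; called-sample
counts are carried so a corrected estimator can be added behind the same
interface. Windows of 20 kb sliding by 2 kb are tiled from position 1 of
each chromosome; a window's value is the unweighted mean over its SNPs
and empty windows are omitted.

## Cross-population composite likelihood

At each 2-kb grid point, the SNPs within a 0.1-cM window (at most 150,
nearest first; constant 4 cM/Mb map by default — a rice-scale genome
average, overridable with a map file) contribute a composite
log-likelihood of the objective population's frequencies given the
reference population's. Neutrally, `p1 ~ N(p2, (omega + 1/(2*n1))*v)`
with `v = p2(1-p2)` and `omega` a genome-wide method-of-moments drift
inflation. Under a sweep of scale `s` centered at the grid point, a
lineage at map distance `r` escapes with probability
`c = 1 - exp(-r/s)`; with probability `1 - c` it is dragged to the
sweeping haplotype, which inflates the conditional variance to
`v*(c^2*omega + (1-c)^2 + 1/(2*n1))`. The score is twice the maximized
log-likelihood ratio over a log-spaced grid of `s` that includes the
null limit, so it is non-negative and zero when the null fits best.

Two robustness choices replace the LD down-weighting of the full
published model, which is out of scope here: the variance scale `v` is
floored at 0.01 so near-fixed reference sites cannot dominate, and each
site's log-likelihood-ratio contribution is capped at 5 log units.
Without them, the neutral top-quantile threshold was driven by single
ill-conditioned sites and fluctuated across seeds with a CV of 0.3–0.7;
with them the CV is about 0.1 while planted-sweep recovery is
unaffected.

## Calling regions

The top-quantile threshold is the k-th largest statistic with
`k = ceiling(n*q)` (default `q = 0.005`), so exactly k entries — plus
any ties, included deterministically — are selected. Selected windows
or grid points are merged when they overlap, abut, or are separated by
at most one step; EDRs are the *interval intersection* of the FST and
cross-population top regions. The FST quantile is applied over windows
(not SNPs), matching the windowed track the threshold is drawn on. EDSs
are SNPs inside an EDR with `|p1 - p2|` strictly greater than 0.6. EDGs
are genes with any overlap of an EDR, classified by whether their
nearest EDS is genic or within 1 kb of either end (strand ignored — the
flank rule names no strand).

# The single-population scan

The genome-wide empirical SFS — folded by default, since ancestral
states are unknown without an outgroup — is binned into 10 equal-width
minor-allele-frequency bins with a half-count pseudocount. At each 1-kb
grid point, sites within 50 kb contribute
`log(e*bg + (1-e)*spike)` under the sweep model versus `log(bg)` under
the background, where `spike` is a geometric spectrum concentrated on
the extreme-frequency classes and `e = 1 - exp(-d/alpha)` is the escape
probability at distance `d` for sweep scale `alpha` (bp). The scale
grid includes the null limit `alpha -> 0` (escape everywhere), making
the score non-negative. Note the parameterization: escape probability
*increases* with distance — the physically sensible direction — and
small `alpha` means a spatially narrow sweep; the null is nested at
`alpha -> 0`. Top-5% grid points, merged within 2 grid steps, form
sweep regions; a gene is a selection target iff it lies within 10 kb of
a significant grid point (distance zero inside the gene; the 9,999 bp /
10,001 bp boundary is tested). Genes selected in the upland-only,
irrigated-only, both, or neither scan partition the EDG list
exhaustively — the "neither" class exists and is reported as
unassigned.

# Phylogenetics

Pairwise distances use the closed-form F84 estimator from the expected
transition (P) and transversion (Q) mismatch proportions over shared
(pairwise non-missing) sites, with base frequencies estimated from
those same sites. Heterozygous genotypes contribute fractionally via
allele sharing: identical genotypes count 0, opposite homozygotes 1,
heterozygote-versus-homozygote 1/2. This keeps `d(x, x) = 0` (an
independent-allele-draw reading would not) and reduces exactly to the
textbook estimator on homozygous data, where it matches
`ape::dist.dna(model = "F84")` to machine precision. Sites are equally
weighted (a uniform mutation rate is assumed across the genome).

Trees are Saitou–Nei neighbor joining (via ape); negative branch
lengths, possible on non-additive matrices, are clamped to zero with the
deficit moved to the parent branch. The bootstrap resamples sites with
replacement (multinomial site weights), recomputes distances and trees,
and keeps bipartitions present in **more than half** of replicates —
the strict-majority rule — with supports reported as percentages.
Replicate trees are all rooted at the same arbitrary tip before
consensus: ape's clade counting is rooted, and without a common root a
bipartition present in 100% of unrooted trees can be split between its
two rooted representations and spuriously dropped.

# Population structure

PCA uses the standard genotype scaling: per site, mean-imputed, centered
and divided by `sqrt(p(1-p))`, followed by an eigendecomposition of the
sample covariance; explained-variance fractions are reported in
non-increasing order.

Admixture is estimated by EM on the binomial likelihood
`sum_ij [g_ij log(QF)_ij + (2 - g_ij) log(1 - (QF))_ij]` with missing
genotypes skipped. The updates are the standard multiplicative EM for
this model, so the log-likelihood is non-decreasing at every iteration
(asserted in the class validity). Defaults: at most 10,000 iterations,
relative tolerance 1e-6, and 5 random restarts keeping the best
likelihood — the published setting names only the iteration cap, so
tolerance and restarts are this package's choices. `K = 1` returns the
analytic optimum. One caution verified during design: a panel in which
*every* individual shares the same admixture proportions is not
identifiable (the F matrix absorbs the mixing); the generator's
admixture scenario therefore includes pure-source anchor individuals
alongside the admixed ones, which is also how such estimators are
benchmarked in practice.

# Phenotypes and enrichment

Group cells are summarized as mean ± sample sd at one decimal, rounding
halves away from zero. Between ecotypes, the difference is absolute and
the percentage is taken on the irrigated-ecotype mean; between
environments, the change is signed with the irrigated-condition mean as
base. These two conventions reproduce every printed cell of the
reference comparison table from its group means (one cell in the
productive-panicle row is internally inconsistent with its own printed
means and is excluded from the regression test). Student's equal-
variance t is the default two-sample test (Welch behind a flag), with
`t = 0, P = 1` on degenerate zero-variance equal-mean input. Category
enrichment uses the 2x2 Pearson chi-square without continuity
correction, counting each gene once however many differentiated SNPs it
carries, and reports raw P values by default (Benjamini–Hochberg behind
a flag).

# Numerical and scale choices

* Coordinates are 1-based inclusive everywhere inside the package (VCF/
  GFF3 convention); BED output is 0-based half-open, with converters
  that are exact inverses.
* Quantile thresholds use the k-th largest value, `k = ceiling(n*q)`,
  with ties included — deterministic and permutation-invariant.
* Test and example problem sizes (2 x 1 Mb chromosomes, 2,000–10,000
  SNPs, 20–50 replicates, 100 bootstrap replicates) are chosen so the
  whole suite runs in a couple of minutes while every statistic keeps
  its published window, grid, and quantile parameters.
* Determinism: every stochastic routine takes or derives an integer
  seed; identical seeds give bit-identical outputs, which the pipeline
  verifies by checksumming its output manifest.

# Known limitations

* The cross-population scan is a normal-approximation reimplementation
  without LD down-weighting; its scores are comparable within a scan
  (ranks and quantiles) but not numerically to the published
  implementation's.
* The generator's independence across sites understates the spatial
  autocorrelation of real scans; merged-region lengths are therefore
  not comparable to field data.
* Heterozygote handling in distances is a convention (allele sharing),
  as the reference pipeline's behavior on ambiguity codes is not
  specified.
* Enrichment P values depend on external category definitions; only the
  test itself, not any real category's P value, is reproducible here.
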