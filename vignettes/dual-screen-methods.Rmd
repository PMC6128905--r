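---
title: "Methods: dual-screen inference of isoform-specific vulnerabilities"
author: "proxiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-screen inference of isoform-specific vulnerabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiscreen)
```

## The scientific setting

The RAS isoforms KRAS, NRAS and HRAS are nearly identical proteins, yet
they differ strikingly in how often they are mutated in cancer. One route
to isoform-specific drug targets is to ask which *interaction partners*
differ between isoforms, and which of those partners the transformed cell
actually depends on. `proxiscreen` implements the computational arm of that
strategy as a two-stage screen:

1. **Proximity labeling (BioID).** A promiscuous biotin ligase (BirA*)
   fused to each oncogenic RAS isoform biotinylates proteins within ~10 nm
   in living cells. Streptavidin-captured proteins are quantified by
   label-free LC-MS/MS. Enrichment of each protein over cells expressing
   the ligase alone defines the per-isoform interactome.
2. **Pooled CRISPR-Cas9 dropout screen.** The genes encoding the called
   interactome are targeted with five guides each in cells transformed by
   each RAS isoform (plus untransformed vector cells), and guide abundance
   is followed over time. Genes whose loss selectively impairs one
   isoform's proliferation are isoform-specific vulnerabilities.

The package's terminal product is the *dual-assay record*: entities scored
in both arms, flagged when they score at least half as well as a reference
vulnerability in both, together with run metadata capturing every
threshold applied.

## The labeling arm

### Quantification

Peptide tables are collapsed to proteins by **summation**
(`aggregatePeptides()`), the standard label-free choice; the distinct
peptide count per protein is retained because the downstream inclusion rule
requires two or more peptides. Missing peptide intensities are treated as
zero: absence after streptavidin capture is informative, not
missing-at-random.

Three normalization schemes are provided (`normalizeQuant()`), mirroring
the three used in this experimental design:

* `robust_mean` — a 20%-trimmed mean of log nonzero intensities per sample,
  re-exponentiated. The trim fraction is a package choice; the concept
  ("scaling to the robust mean") does not pin an estimator.
* `carboxylase` — per-sample mean of endogenously biotinylated
  carboxylases (pyruvate carboxylase and friends), which ride along in any
  streptavidin capture and therefore control for pull-down efficiency.
* `bira` — per-sample mean of the BirA ligase itself, controlling for
  ligase expression. Implemented as the mean over the annotated BirA
  protein entries; whether the original analysis used a peptide mean or a
  total is not documented, so the choice is surfaced here rather than
  guessed.

Size factors are rescaled to geometric mean 1 so normalization never
changes the overall intensity scale, and the applied factors are stored in
`metadata()$size_factors`. Technical noise is summarized by `qcCV()` as
the mean percent CV across repeated injections of a QC pool (an equal
mixture of all samples), reported for all proteins and for the
2-or-more-peptide subset.

### Interactome calling

`computeEnrichment()` scores each protein per bait as the ratio of bait to
control replicate means (fold change) and a two-sample **pooled-variance
Student t-test on log2 intensities**. Pooled variance is appropriate at
n = 3 per group; log2 rather than raw intensity is the package's choice
(the source analysis does not state the scale) and is recorded in the run
metadata. No multiple-testing correction is applied by default, matching
the original raw p < 0.05 rule; `p.adjust` can of course be applied to the
returned records by the user.

Numerical edge cases are defined, not left to chance:

* zeros are replaced **only at ratio/log time** by a pseudo-intensity of
  half the smallest nonzero value in the matrix (configurable, recorded);
* a zero-variance t-test (all replicates identical) returns p = 1 when the
  means agree and p = 0 when they differ, avoiding NaN propagation while
  staying conservative only under the null;
* all-zero proteins are scored on pseudo-intensities and flagged.

The **stringency is calibrated on positive controls**
(`calibrateThreshold()`): the RAF kinases ARAF, BRAF and RAF1 bind
activated RAS directly, so the least recovered of them sets the fold
threshold — `applied = max(min fold over controls, floor)` with a floor of
2. Every control must itself be significant, otherwise calibration aborts
naming the offender. A single threshold is shared across the three baits
(the original analysis drew one cut for the combined set); per-bait
thresholds would be a one-line change but are deliberately not the
default. `callInteractome()` then requires fold ≥ threshold, p < 0.05 and
≥ 2 peptides, and reports the per-bait sets with their 7-region Venn
partition.

`zscoreCluster()` standardizes each called protein's log2 profile to
z-scores and clusters proteins and samples agglomeratively with
correlation distance (1 − Pearson) and average linkage. The distance and
linkage are package choices; the original figure names only the plotting
software.

## The screen arm

Counts are normalized to pseudocounted reads-per-million
(`normalizeGuideCounts()`; pseudocount 0.5 keeps zero-count guides finite
in log space; the column contract is exact and tested). The per-guide
**depletion metric** is the replicate-averaged log2 ratio of frequencies
between the two later timepoints, `log2(T2/T1)`, so depletion is negative
— the sign convention of a dropout waterfall. T0 enters only
representation QC (`screenQC()`, including a Gini coefficient), not the
metric. The **enrichment score** subtracts the vector-background metric
guide-wise, so a guide's score in the vector background is identically 0
and negative scores mean isoform-selective dropout.

`collapseGenes()` implements the *best three of five* rule per direction:
`pos_score` is the mean of the 3 largest guide scores, `neg_score` of the
3 smallest. Applying the rule per direction is the only reading under
which a gene can be classified as both positively and negatively enriched,
a class the study design explicitly allows. Ties are broken by guide id so
results are deterministic. `classifyGenes()` applies the ±0.4 threshold
(the published rule, itself benchmarked on BRAF); passing a benchmark gene
recalibrates the threshold per background to that gene's negative score.
`rankPercentiles()` flags the top 1% per direction among target-class
genes; control guides are shown for reference but do not compete in the
ranking, matching how the published waterfall treats them.

## Integration

`joinAssays()` merges labeling fold changes with collapsed screen scores
over a strict one-to-one id map, reporting unmapped entities in a sidecar
rather than silently dropping them. `dualHitCall()` flags entities scoring
*at least half as well as a reference* in both assays: labeling fold
change at least half the reference's, and negative screen score at most
half the reference's (i.e. at least half as depleted). Both comparisons
are ratios, so the call is invariant to rescaling either assay. Labeling
is compared on the linear fold scale and the screen on the log2 score
scale — the scales the two assays are natively reported on; both are
recorded in the run metadata. The flag additionally requires interactome
membership in the queried isoform: without that condition the reference
itself would trivially flag in every background in which its null score
happens to dip below zero, and "a dual hit in one isoform only" would not
be a meaningful statement.

`differentialLabeling()` compares a knockout-condition labeling experiment
with its vector control: per protein, the mean log2 difference averaged
with equal weight over knockout lines, with a direction call only beyond
δ = 0.1 on the log2 scale (the published ±0.1 rule does not state its
scale; log2 is the default here and linear is a trivial user-side
transform). The reference protein's own reduction is reported as the
benchmark. `overrepresentation()` provides the one-sided Fisher exact
(hypergeometric tail) test with fold enrichment for user-supplied gene
sets — deliberately generic, with no live annotation-database dependency.
`percentViability()` implements the plate-reader formula
`100 × (treated − blank)/(negative control − blank)` verbatim; values
outside [0, 100] are reported as-is.

## What the simulators emulate

`simulateBioid()` draws protein intensities as
`baseline × fold(bait) × lognormal noise`, split over peptides with fixed
weights so that aggregation is exact. Defaults emulate the profiled
design: triplicate transfections of a control and three RAS baits, 2000
background proteins, 100 spiked interactors per bait at fold 4, replicate
CV 10% (the study's QC pools ran at roughly 8–14%), four QC-pool
injections, carboxylase/BirA references at fold 1, and RAF-like positive
controls at folds 4.5/3.5/2.5 so the weakest (RAF1-like) control sets a
calibrated threshold near 2.5. The per-bait shared fraction of 0.9 makes
about three quarters of the *called union* multi-isoform, the overlap
structure the labeling study reports. Spiked interactors carry at least
two peptides — the truth set represents *detectable* interactors, since
the inclusion rule discards single-peptide identifications by design —
while null proteins include single-peptide cases.

`simulateScreen()` evolves guide frequencies as
`freq ∝ baseline × 2^(fitness × efficacy × generations)` and draws counts
gamma-Poisson at dispersion 0.05 (the standard pooled-screen noise level);
`dispersion = 0` is defined as the deterministic rounded expectation,
giving a noise-free limit for exact tests. Guide efficacy is Beta(5, 2) —
most guides cut well, a minority are weak — which is precisely what
motivates the best-3-of-5 collapse. Cumulative generations default to
(0, 2, 6) for vector and (0, 3, 9) for transformed backgrounds: in low
serum the RAS-transformed lines keep proliferating while vector cells
barely do, and it is this difference in accumulated doublings that makes
essential-gene dropout visible *relative to vector* — with equal growth,
ribosomal controls would deplete identically everywhere and their
enrichment scores would vanish. 500 non-targeting guides (grouped into
pseudo-genes of five so they flow through the collapse) give the null
mean enough precision at dispersion 0.05; per-sample depth jitter is a
free parameter (default CV 0.1) since library-size variation is not
documented for the original data.

Random streams are **keyed per entity**: every protein and guide draws
from its own seeded stream, so identical configurations reproduce
byte-identical tables and appending entities never perturbs existing
draws.

Features of real data deliberately *not* emulated: intensity-dependent
noise (so the simulated multi-peptide subset shows no CV advantage,
whereas real low-abundance single-peptide proteins are noisier),
contaminant and off-target structure, shared peptides between proteins,
guide-level off-target effects, and infection-bottleneck correlation
between timepoints. Passing recovery tests on this generator therefore
demonstrates the pipeline's statistical behavior under its stated model,
not robustness to every artifact of real screens.

## Validation design and problem sizes

The test suite validates each operation against independent oracles: an
exhaustive C(5,3) subset-mean oracle for the gene collapse, brute-force
hypergeometric tail summation for over-representation, the textbook
pooled-variance t formula, group-by re-summation for aggregation, and the
growth model's closed form for the screen. Calibration is checked on a
null simulation of 2000 proteins (the p < 0.05 fraction against its
binomial 99% interval, computed on the aggregated matrix because size
factors estimated from three reference proteins add a small shared
per-sample perturbation that correlates tests across proteins); recovery
on the default 2000-protein / 100-spike labeling design and the default
500-gene screen with a planted KRAS-specific essential gene. The
end-to-end study (`runSyntheticStudy()`) chains both simulators at their
defaults, plants the vulnerability analog among the KRAS-specific
interactors, and checks that it is called, top-ranked, and a dual hit in
KRAS alone. These sizes keep the full suite under a minute or two on one
core while leaving Monte-Carlo error well inside the asserted bands.

One stochastic caveat is worth stating plainly: at dispersion 0.05 a null
gene's `neg_score` crosses −0.4 in roughly one background draw in five,
so a truly null gene can sporadically classify as negative in a
background where nothing was planted — exactly as a third of genes did in
the published screen. Classification specificity for a single gene is
therefore a probabilistic, not deterministic, property of the default
noise model.

## Limitations

The pipeline starts from quantified peptide tables and guide counts;
spectral processing, peptide FDR control, read demultiplexing and
alignment are out of scope, as are live GO/STRING queries and guide-level
negative-binomial differential tests (the depletion-metric procedure is
the published gene-scoring route implemented here). Real-data hit lists
from the original deposited datasets are not reproduced — they require the
raw accessions — and all recovery claims are with respect to the synthetic
generators described above.
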