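# proxiscreen

Dual-screen inference of RAS isoform-specific protein vulnerabilities:
quantify BioID proximity-labeling proteomics, score a pooled CRISPR-Cas9
dropout screen over the called interactome, and integrate the two assays
into reference-benchmarked dual-assay hits.

## The problem

KRAS, NRAS and HRAS are nearly identical GTPases with very different
mutation frequencies in cancer. If an isoform owes part of its oncogenic
activity to isoform-specific interaction partners, those partners are
candidate drug targets. The strategy implemented here:

1. **Label** — BirA* fused to each oncogenic isoform biotinylates nearby
   proteins; enrichment over a ligase-only control, with a
   positive-control-calibrated stringency, defines each isoform's
   interactome:
   pass ⟺ fold ≥ max(min fold over RAF controls, 2) ∧ p < 0.05
   (pooled-variance Student t on log2 intensities) ∧ ≥ 2 peptides.
2. **Screen** — five guides per interactome gene; per-guide depletion
   metric `d = log2(freq_T2 / freq_T1)` (replicates averaged after the
   log-ratio), enrichment score `s = d(background) − d(vector)`, gene
   collapse by the mean of the best 3 of 5 guides per direction, classes
   at ±0.4.
3. **Integrate** — an entity is a dual hit in an isoform when it scores at
   least half as well as a reference vulnerability in both assays there
   (labeling ≥ ½ × reference, negative screen score ≤ ½ × reference).

All of this is exercised end-to-end on synthetic-data generators with
known ground truth (log-normal LFQ intensities with spiked interactors and
carboxylase/BirA/RAF references; gamma-Poisson guide counts under
`freq ∝ 2^(fitness × efficacy × generations)`), so every stage is testable
without any download.

## Worked example

```r
library(proxiscreen)

res <- runSyntheticStudy(seed = 1)

res$calibration$applied      # fold threshold set by the weakest RAF control
#> [1] 2.461146

res$interactome$venn         # isoform sharing of the 123-protein union
#>           HRAS           KRAS KRAS&NRAS&HRAS           NRAS
#>             10             10             93             10

head(subset(res$geneScores, class == "target" & background == "KRAS")[
  order(subset(res$geneScores, class == "target" &
               background == "KRAS")$neg_score), c("gene", "neg_score")], 3)
#>         gene  neg_score
#> 466 PROT0091 -3.3571910
#> 391 PROT0016 -0.6968700
#> 481 PROT0106 -0.6755325

res$analog                   # the planted KRAS-specific vulnerability
#> [1] "PROT0091"
res$dualHits$KRAS$hits       # dual hits benchmarked to it, KRAS only
#> [1] "PROT0091"
res$dualHits$NRAS$hits
#> character(0)
```

The calibrated threshold (2.46) recovers the injected RAF1-like control
fold of 2.5; 93 of the 123 called proteins are labeled by all three
isoforms while 10 are specific to each, mirroring the overlap structure of
RAS interactomes; and the planted KRAS-specific essential gene is the most
negatively enriched gene in the KRAS background (score −3.36, next gene
−0.70) and the sole dual hit — in KRAS and in no other isoform.

Individual stages are exported (`aggregatePeptides`, `normalizeQuant`,
`qcCV`, `computeEnrichment`, `calibrateThreshold`, `callInteractome`,
`zscoreCluster`, `normalizeGuideCounts`, `depletionMetric`,
`enrichmentScore`, `collapseGenes`, `classifyGenes`, `rankPercentiles`,
`joinAssays`, `dualHitCall`, `differentialLabeling`,
`overrepresentation`, `percentViability`), along with TSV/YAML/GMT
readers and writers and a thin command-line wrapper in
`inst/scripts/proxiscreen-cli.R`. The methods vignette
(`vignettes/dual-screen-methods.Rmd`) documents the models, defaults and
design decisions.

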