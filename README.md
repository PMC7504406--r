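# metaboPatterns

Differential metabolite pattern analysis for myeloid differentiation
studies. A progenitor population of CD34⁺ hematopoietic stem and
progenitor cells (HSPC) is compared against three differentiated lineages
— erythrocytes (E), dendritic cells (DC) and neutrophils (N) — on a
targeted metabolomics panel (Biocrates-style, ~514 analytes, n = 3
biological replicates per population). The package answers: *which
metabolites change during differentiation, and is a change unique to one
lineage or common to several?*

It is aimed at analysts of targeted (concentration-based) metabolomics
with small replicate numbers, where per-feature variance estimates need
empirical-Bayes stabilisation and where below-LOD censoring is a routine
nuisance.

## The method

1. **Preprocessing.** Concentrations are log2-transformed; below-LOD
   values (reported as 0 or `< LOD`) would give −∞ and are removed per
   cell with a provenance flag. A (metabolite, contrast) pair is eligible
   only with ≥ 2 observed replicates in both groups.
2. **Moderated statistics.** Per metabolite, a group-means model with one
   pooled residual variance s²_g on d_g df; empirical-Bayes shrinkage
   toward a panel-wide prior (d₀, s₀²) estimated by moment matching on
   log s²_g (digamma/trigamma closed forms, trigamma inverse by
   bisection). Moderated t for each lineage-vs-progenitor contrast:

       t̃ = logFC / (s̃ · √(1/n_lineage + 1/n_progenitor)),
       s̃² = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g),   df = d_g + d₀

   with BH-adjusted p-values per contrast.
3. **Relevance and patterns.** Relevant: |logFC| > 1 and FDR < 0.05
   (strict). With ΔlogFC the absolute difference of two lineages' logFCs,
   metabolites are partitioned into: common to all (all Δ < 1), unique to
   one lineage (its Δ to both others > 1), common to a pair (pair Δ < 1,
   both Δ to the third > 1), relevant-unclassified, or not-relevant.
4. **Overrepresentation.** Fisher's exact one-sided (hypergeometric upper
   tail) test of each annotation term in a query set, fold enrichment
   (k/n)/(K/N), Holm-adjusted.
5. **Synthetic data.** A generator plants lineage-unique, pairwise-common
   and all-common log2 effects with log-normal replicate noise and
   analyte-specific LOD censoring, and reports the ground truth, so
   recovery of every downstream stage is testable end to end.

See the methods vignette (`vignettes/metaboPatterns-methods.Rmd`) for the
model, the estimator details and the design decisions.

## Worked example

Simulate the study design with known planted patterns and run the full
pipeline:

```r
library(metaboPatterns)

cfg <- pipelineConfig(
  simulation = simulationConfig(
    nMetabolites = 514,
    counts = c(unique_E = 20, unique_DC = 15, unique_N = 40,
               common_E_DC = 25),
    replicateSd = 0.3, seed = 11),
  outputDir = tempfile())
res <- runPipeline(cfg)

res$data
#> ConcentrationMatrix: 514 metabolites x 12 samples
#> populations: dendritic (n=3), erythrocyte (n=3), neutrophil (n=3), progenitor (n=3)
#> below-LOD cells: 288 (4.7%)

res$summary$counts
#>              unique_E             unique_DC              unique_N
#>                    20                    15                    37
#>           common_E_DC            common_E_N           common_DC_N
#>                    22                     0                     0
#>            common_all relevant_unclassified          not_relevant
#>                     0                     4                   416

round(res$recovery$sensitivity[c("unique_E", "unique_DC", "unique_N",
                                 "common_E_DC")], 3)
#>    unique_E   unique_DC    unique_N common_E_DC
#>       1.000       1.000       0.925       0.880
```

Reading the output: of the 100 planted pattern metabolites, 94 are
recovered in their true category at this noise level; the handful that are
not were censored below the LOD in their affected lineage (losing
eligibility) — with censoring disabled (`lodQuantile = 0`) recovery is
exact. The per-contrast tables (`res$contrasts`), the assignment table,
the exclusion report and a manifest with content hashes are written to
`outputDir`; identical config + seed reproduce identical hashes.

For file input, `runPipeline` accepts a wide concentration TSV plus a
`sample_id`/`population` metadata TSV (`pipelineConfig(matrixPath = ...,
metadataPath = ...)`), and `inst/scripts/run_pipeline.R` wraps the same
calls for shell use.

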