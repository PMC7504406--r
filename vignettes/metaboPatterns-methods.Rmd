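---
title: "Methods: differential metabolite patterns across myeloid lineages"
author: "metaboPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential metabolite patterns across myeloid lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboPatterns)
```

# The analysis problem

A progenitor population of hematopoietic stem and progenitor cells (HSPC) is
differentiated into three myeloid lineages — erythrocytes (E), dendritic
cells (DC) and neutrophils (N) — and all four populations are profiled on a
targeted metabolomics panel (Biocrates-style, hundreds of analytes,
concentrations in µM, typically n = 3 biological replicates per
population). The scientific question is which metabolites change during
differentiation, and whether a change is *unique* to one lineage or
*common* to several. `metaboPatterns` implements that analysis as a tested,
reusable pipeline: preprocessing, moderated differential statistics,
relevance filtering, ΔlogFC pattern classification, and overrepresentation
testing, plus a synthetic-data generator with planted ground truth so every
stage can be validated without access to any proprietary data set.

# Preprocessing and the limit of detection

Concentrations are log2-transformed before modelling. A targeted panel
reports a value below the analyte's limit of detection (LOD) as zero (or an
explicit `< LOD` token), which would become $-\infty$ after the transform.
These observations are *removed as missing* — per cell, not per metabolite
— and tracked with an explicit provenance flag, so no non-finite value ever
reaches the linear model. Whole-metabolite deletion is available as a
switch (`log2Transform(dropMode = "metabolite")`), but per-cell removal is
the default: a metabolite strongly depleted in one lineage but quantified
in the others is exactly the kind of signal the analysis is after, and
row-wise deletion would discard it.

After removal, a (metabolite, contrast) pair enters the model only if both
the progenitor group and the lineage group retain at least `minPerGroup`
(default 2) observed replicates — two being the minimum for an estimable
within-group variance. Every exclusion is reported with a reason.

No imputation (e.g. LOD/2 substitution) and no normalization are applied;
the analysis operates on the reported concentrations as-is.

# The moderated t model

For each metabolite $g$ a one-way group-means model is fitted on the log2
scale: each population has its own mean, and all four groups share one
residual variance $s_g^2$ with residual degrees of freedom
$d_g = n_{\text{obs}} - \#\{\text{groups with} \ge 1 \text{ observation}\}$
(so a balanced 4 × 3 design gives $d_g = 8$, with no imputation of missing
cells). Sharing one variance across the three contrasts lets them borrow
strength from each other.

With only three replicates per group, per-metabolite variances are noisy;
the empirical-Bayes remedy places a scaled inverse-chi-square prior
$s_0^2 d_0 / \chi^2_{d_0}$ on the true variances and replaces $s_g^2$ with
the posterior

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

which always lies between $s_g^2$ and the prior variance $s_0^2$. The
moderated t for lineage $\ell$ is

$$\tilde t_{g\ell} = \frac{\bar y_{g\ell} - \bar y_{g,\text{prog}}}
  {\tilde s_g \sqrt{1/n_\ell + 1/n_{\text{prog}}}},$$

referred to a t distribution on $d_g + d_0$ degrees of freedom (standard
normal when $d_0 = \infty$). At $d_0 = 0$ this reduces exactly to the
ordinary pooled-variance t — a reduction the test suite checks against an
independent `lm()` route at $10^{-10}$.

## Hyperparameter estimation

$(d_0, s_0^2)$ are estimated by moment matching on $z_g = \log s_g^2$:
writing $e_g = z_g - \psi(d_g/2) + \log(d_g/2)$, the model implies
$\mathrm{E}[e_g] = \log s_0^2 - \psi(d_0/2) + \log(d_0/2)$ and
$\mathrm{Var}[e_g] = \psi'(d_g/2) + \psi'(d_0/2)$. The excess of the
observed variance of $e_g$ over the mean sampling term
$\psi'(d_g/2)$ determines $d_0$ through the trigamma inverse; $s_0^2$ then
follows in closed form. Numerical choices:

* the trigamma inverse is found by bisection on a geometrically widened
  bracket (trigamma is strictly decreasing, so the root is unique), run to
  $10^{-8}$ on the trigamma residual — deterministic, no damping heuristics;
* when the observed dispersion does not exceed what sampling alone
  explains, $d_0 = \infty$ and $s_0^2$ is the arithmetic mean of the
  $s_g^2$ — the pooled common variance (a log-scale estimator is only
  consistent on-model and would be biased upward for near-constant
  variances);
* metabolites with $d_g = 0$ are excluded from the fit but metabolites
  ineligible for some *contrast* still contribute their variance:
  shrinkage pools across the whole panel;
* zero-variance fits (possible only on noise-free input) resolve by the
  limit: $t = 0$ when the contrast is 0, $\pm\infty$ otherwise.

Raw p-values are FDR-adjusted by Benjamini–Hochberg within each contrast
(the default family, matching how a per-contrast `topTable`-style analysis
behaves); a `global` family across all three contrasts is available as a
switch.

# Relevance and pattern classification

A metabolite is **relevant** in lineage $\ell$ when $|\mathrm{logFC}_\ell| >
1$ and its FDR-adjusted p-value is below 0.05 — both inequalities strict,
so a logFC of exactly 1 does not qualify. With
$\Delta(X,Y) = |\mathrm{logFC}_X - \mathrm{logFC}_Y|$, the categories are
assigned in a fixed precedence:

1. **common to all** — all three pairwise $\Delta < 1$ (and relevant
   somewhere);
2. **unique to X** — X relevant and $\Delta(X, \cdot) > 1$ to both others;
3. **common to X, Y** — $\Delta(X,Y) < 1$, both $\Delta$ to the third
   $> 1$, and both X and Y relevant (default; an `any_relevant` switch
   implements the weaker reading — "a change two lineages share" arguably
   ought to be a relevant change in each, which is why the strict reading
   is the default);
4. otherwise **relevant-unclassified** (relevant somewhere, no pattern) or
   **not-relevant**.

Three classification decisions were genuinely open and are resolved as
follows:

* *Precedence.* Common-to-all is tested first: when all deltas are below 1
  no unique rule can fire anyway, and a fixed order makes the partition
  total and order-independent. Unique is tested before pairwise-common;
  a metabolite relevant in all three lineages whose third response is far
  from a close pair is reported as unique to the distant lineage rather
  than common to the pair, since "distinct response" is the stronger
  statement about that lineage.
* *Ties among unique rules.* When all three responses are mutually distant
  and relevant, several unique rules fire at once. The winner is the most
  separated lineage (largest minimum pairwise delta, then largest
  $|\mathrm{logFC}|$). This tie-break is permutation-invariant, so
  relabelling lineages relabels categories — an equivariance the tests
  verify over all six permutations.
* *Boundaries.* $\Delta = 1$ exactly satisfies neither the $> 1$ nor the
  $< 1$ rule; such metabolites stay relevant-unclassified. Metabolites
  ineligible in any contrast have undefined deltas and can never be unique
  or common.

Every metabolite receives exactly one category, so the nine counts always
sum to the panel size.

# Overrepresentation

Categorized sets can be tested against user-supplied term annotations
(two-column TSV; no annotation database is bundled). For a query of size
$n$ against a background of size $N$, a term with $K$ background members
and $k$ query members scores a fold enrichment $(k/n)/(K/N)$ and a
one-sided upper hypergeometric tail $P(X \ge k)$, Holm-adjusted across all
terms in the run. Only the overrepresentation direction is tested; no
parent-term propagation is applied.

# The synthetic-data generator

`simulateConcentrations()` emulates the study design: 4 populations × 3
replicates on a 514-analyte panel. For metabolite $m$ and sample $i$,

$$y_{mi} = b_m + \beta_{m,\ell(i)} + \varepsilon_{mi}, \qquad
  \varepsilon_{mi} \sim N(0, \sigma^2),$$

with concentrations $2^{y_{mi}}$. Defaults, and why:

* `baselineRange = c(-3, 7)` (log2 µM): spans roughly 0.1–130 µM, the
  concentration range of a typical targeted panel;
* `replicateSd = 0.4` log2 units — about a 30% coefficient of variation,
  a realistic biological-replicate spread for cell-culture metabolomics;
* `effectSize = 3`: planted triples are built from the category (e.g.
  unique-E is $(\pm 3, 0, 0)$, common-E-DC is $(\pm 3, \pm 3, 0)$ with a
  shared sign), so every planted metabolite satisfies its category's
  defining inequalities with margin 2;
* default planted counts (20/15/40/25 for unique-E/DC/N and common-E-DC)
  mirror the magnitude of pattern sets a real differentiation panel
  yields;
* `lodQuantile = 0.05`: each analyte's LOD is the 5% quantile of its own
  generating mixture distribution, solved by root-finding on the mixture
  CDF. Tying the LOD to the analyte (not to the cell state) means a
  planted depletion is only partially censored, as on a real panel, and
  the overall censoring fraction equals the configured quantile for any
  effect structure. Below-LOD values are emitted as concentration 0 —
  exactly the artifact the preprocessing stage must handle.

Effects are planted only in lineage populations, never the progenitor,
because every contrast is defined against the progenitor.

What the generator does **not** emulate: analyte-class correlation
structure, batch effects, instrument drift, or heteroscedastic
analyte-specific noise. Passing recovery tests therefore demonstrate that
the statistical machinery is correct under its own assumptions, not that
real panels meet those assumptions.

# Validation strategy and problem sizes

The test suite validates each stage against an independent route: ordinary
pooled t via `lm()` (1,000 metabolites, agreement at $10^{-10}$);
hyperparameter recovery on 5,000 variances drawn from a scaled
inverse-chi-square with $d_0 = 4$, $s_0^2 = 0.25$; type-I calibration on a
10,000-metabolite null panel at $\sigma = 0.4$; classifier agreement with a
brute-force rule evaluator on 10,000 random logFC/relevance draws plus
equivariance; BH/Holm against their step-up/step-down definitions on all
permutations of vectors up to length 8; Fisher tails against exact
hypergeometric enumeration for $N \le 30$; and end-to-end planted-pattern
recovery at the full study design (514 metabolites, planted counts
20/15/40/25, $|\mathrm{logFC}| = 3$, $\sigma = 0.3$), with an exact-count
check in the zero-noise limit. The moderated statistics are additionally
cross-checked against the independent limma implementation of the same
methodology. These sizes keep the whole suite within a few minutes on one
CPU while leaving each check statistically sharp.

One calibration property deserves a caveat: on a null-only panel of
10,000 metabolites, BH declares a (false) discovery whenever the smallest
raw p-value falls below $0.05/10{,}000$, an event with expectation about
0.05 per contrast per run. A handful of false joint-relevant calls across
many seeds is therefore the *correct* behaviour of a calibrated pipeline,
not a defect; the corresponding acceptance check asserts near-zero rather
than exactly-zero false calls only with that caveat in mind.

# Known limitations

* The pipeline assumes log-normal replicate noise; heavy-tailed
  measurement error would call for the robust hyperparameter variants
  deliberately left out of scope.
* Censoring is treated as missingness, which slightly biases means upward
  for analytes near their LOD; no truncated-likelihood correction is
  attempted (and none was used in the original analysis style this
  pipeline follows).
* The unique/common rules operate on point estimates of logFC; no
  uncertainty is propagated into the ΔlogFC comparisons.
* Annotation handling takes term membership as supplied; GO-style
  hierarchy closure is the responsibility of the annotation provider.
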