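---
title: "Methods: statistical workflow for NPX biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical workflow for NPX biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxbio)
```

This vignette documents the statistical model behind each stage of the
pipeline, the defaults and why they were chosen, the numerical conventions,
and what the synthetic-data tests do and do not establish about behaviour on
real cohorts.

## The data model

NPX (normalized protein expression) is a relative abundance on the log2
scale: a between-group difference in mean NPX is a log2 fold change. The
package treats per-assay NPX as approximately Gaussian — the working
assumption behind Welch t-tests and PCA — and carries two masks alongside
the values: *missing* (no measurement) and *below LOD* (a measurement was
reported but sits under the assay's limit of detection). Below-LOD values
are retained at their reported values as a conservative measure; assays with
strictly more than 20 % of their non-missing values below LOD are flagged
(the flag travels into every downstream table) but never removed. QC-failed
samples are likewise flagged and retained. When the same protein is measured
on two panels, the copy detected below LOD in the larger fraction of samples
is dropped; an exact tie keeps the lexicographically first panel and logs a
warning, so the outcome is deterministic.

## Iterative-PCA imputation

Missing entries are completed by an EM-style low-rank fit: initialize
missing cells at column means, then alternate a rank-`ncp` truncated SVD
reconstruction of the (column-centered) matrix with overwriting of *only*
the missing cells, until the summed squared change in the imputed cells
falls below `tol` (default 1e-8) or `max_iter` (1000) is reached.
Observed values are bit-identical before and after — an invariant the tests
assert. The plain EM iteration (no shrinkage of singular values) was chosen
because it is deterministic and has a closed-form oracle: deleting one entry
of a rank-1 matrix must be recovered exactly, which the test suite checks to
1e-6. `ncp` defaults to 2 to match the two-component plane on which the
ordination is interpreted; the rank is a user-visible choice, not a fact
about the data. Non-convergence returns the best iterate with a warning
rather than failing, since downstream PCA is robust to a slightly
unconverged completion.

## Ordination and the centroid permutation test

PCA uses `stats::prcomp` on centered, unit-variance-scaled data (sample SD
with the n−1 divisor). Group centroids are plain arithmetic means of score
vectors. The separation statistic between two groups is the Euclidean
distance between their centroids restricted to `dims` (default components 1
and 2, the plotted plane; the subspace is recorded in the result so other
choices are auditable).

The null distribution permutes the two group labels over the pooled samples,
preserving group sizes, and recomputes the distance on the *fixed* score
matrix. PCA is not refit per permutation: the decomposition is label-blind,
so refitting would reproduce the same scores at roughly a hundredfold cost.
The p-value uses the add-one rule (1 + r)/(1 + n_perm), which cannot return
zero; with the default `n_perm = 9999` the smallest attainable p is 1e-4.
`n_perm` below 99 is refused because the p resolution becomes meaningless.
The test is one-sided in the upper tail (only larger-than-observed
separations count against the null), and rotation of the score plane leaves
it invariant because Euclidean distance does.

Calibration is checked by simulation: over 500 label-independent cohorts
(30 + 12 samples, 200 proteins, 499 permutations each) the empirical type-I
error at the 5 % level must fall inside the 99 % binomial band
[0.027, 0.077], and a 20-protein +1.5 NPX shift in the 12-sample group must
be detected at p ≤ 0.01 in at least 95 of 100 cohorts.

## Differential abundance

Each protein is tested with the Welch unequal-variance t-test (groups of
very different sizes make the equal-variance assumption untenable), with
missing values excluded pairwise per assay — imputation is used only for
PCA, never for testing. FDR control is Benjamini–Hochberg within one
contrast; each contrast is its own family, because each volcano stands alone
as a figure. The BH step-up is verified against a brute-force implementation
on exhaustive small cases. Volcano classes at q < 0.05 follow the sign of
the estimate (group2 − group1 mean NPX). Demographics use the chi-squared
test of independence without continuity correction and the Kruskal–Wallis
H test, matching how such cohort tables are conventionally analysed.

## Shadow-feature (all-relevant) selection

Before selection, NPX is adjusted for age and sex by per-assay ordinary
least squares (sex as an M = 1 indicator; constant covariates are dropped
with a warning), and remaining missing values are median-filled per assay.
Selection then iterates, up to `max_runs` (default 500):

1. permuted ("shadow") copies of **all** original features are appended to
   the design;
2. a random forest (500 trees, `mtry = floor(sqrt(p))` over the combined
   design) is grown on real + shadow features;
3. each feature's importance Z is its mean out-of-bag permutation importance
   divided by the standard error over trees; a Z that is not finite
   (importance constant across trees) is set to 0;
4. an undecided real feature scores a *hit* when its Z exceeds the maximum
   shadow Z;
5. a two-sided binomial test of each undecided feature's hit count against
   Binomial(n_iter, ½), Bonferroni-corrected by the **total** feature
   count, Confirms (significantly many hits) or Rejects (significantly few);
   everything else stays Tentative, and Tentative features are never
   force-resolved.

Three design choices here deserve justification because simpler variants
fail measurably. First, rejected features leave the design but confirmed
ones stay: if strong predictors are removed, noise features that correlate
with the outcome by chance inherit their splits and importance, and
false confirmations multiply. Second, shadows are drawn from the full
original feature set every iteration rather than only from the undecided
set: the max-shadow benchmark must retain the strength of the full null
ensemble for the whole run, otherwise late-surviving features face an
ever-lower bar. Third, the Bonferroni multiplier is the constant total
feature count, not the shrinking undecided count, for the same reason on
the testing side. With these choices, simulations at 100 samples show all
three of three planted +1.5 SD features confirmed with at most one false
confirmation in ≥ 9/10 runs, and on 200 pure-noise features the mean number
of confirmations per run stays ≤ 1.

The decision level `alpha` defaults to 0.05 and is Bonferroni-shared, so a
feature that beats the best shadow in every one of the first *n* iterations
is confirmed as soon as 0.5^n · p < alpha (n = 12 at p = 50 features).
`max_runs` below 8 is refused since no decision is reachable. Note that
in-sample "all-relevant" selection deliberately confirms weak but genuine
associations; on small cohorts some chance associations are genuine
in-sample, which is why the false-confirmation tolerance above is 1, not 0.

## Logistic biomarker models

Models are plain maximum-likelihood logistic regressions
(diagnosis ~ age + marker), fitted by IRLS. No penalization is applied;
quasi-separation — plausible when one group has only a dozen samples — is
detected (glm's boundary warning, non-convergence, or |β| > 15) and flagged
`converged = FALSE` rather than silently corrected, and the stepwise table
keeps emitting the remaining rows. The odds ratio per unit NPX is exp(β)
with Wald 95 % CI exp(β ± 1.96·SEM); published coefficient tables are used
as worked examples in the acceptance tests, reproduced at printed rounding.
The concordance index is Harrell's C on in-sample fitted probabilities
(computed exactly from midranks, so ties count one half and any strictly
increasing transform of the scores leaves it unchanged); in-sample C is
optimistically biased and is reported as such, matching the convention of
single-sample biomarker tables. Nested models are compared by the
likelihood-ratio statistic 2·(llₑₓₜ − llᵦₐₛₑ) on χ² with one degree of
freedom per added marker; Wilks calibration is verified by simulation
(empirical 95th percentile of the null LR within [3.3, 4.4] over 1000
replicates). In a contrast "A vs B" the first-listed group is coded 1.

## Single-cell linkage

Dot-plot statistics summarize an annotated normalized-log expression matrix:
per gene and cell type, the mean expression, the fraction of cells with
expression strictly greater than zero ("expressing" has no minimum
threshold beyond positivity), and the gene-wise Z of the mean vector across
cell types. Standardization uses the population (n-divisor) SD across
types — with ~6–10 cell types the n vs n−1 choice is material, so the
convention is recorded in the summary object. A gene with identical means
in every type gets Z = 0 everywhere. Genes are ranked within a cell type by
mean expression, ties broken alphabetically. UMAP coordinates, when used,
are taken as given; the package computes no embedding.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, with
defaults fixed at the study conditions: group sizes CM 16 / ISM 80 /
AdvSM 12 / PCV 60 (168 samples), three 92-assay panels with IL6 measured on
two of them (276 columns, 275 unique proteins), five QC-failed-but-retained
samples, and per-group age distributions. Per-assay baselines are Gaussian:
an assay-level mean is drawn once per cohort from N(4, 2) NPX and samples
scatter around it with SD `noise_sd` = 1 NPX — a typical inter-individual
spread on the log2 scale; group effects from `effect_table` shift the mean
additively. LOD per assay is a quantile of that baseline (default 2 %, with
a block of heavily censored assays at 30 % so the >20 % flag has real
members, and the duplicated assay censored asymmetrically — 5 % on one
panel, 35 % on the other — so duplicate resolution always has a strict
winner, enforced after sampling). Missingness is uniform at random (2 %).
Ages are triangular with the mode solved so the distribution's median, min
and max match the configured per-group values (only those three numbers are
typically published). Protein–protein correlations are *not* modelled: no
published values exist to emulate, so the baseline is independent across
assays.

Consequences for interpretation: passing tests show the pipeline recovers
known planted structure under Gaussian, independent-assay noise with MCAR
missingness. They do not establish behaviour under correlated proteins,
informative missingness, plate effects, or heavy-tailed NPX — all present in
real Olink data to some degree. The single-cell generator likewise plants
clean fold-elevated markers with uniform dropout; the planted-marker
integrity check runs at dropout 0 so that "fraction expressing = 1" is a
sharp expectation, while other tests keep the default 30 % dropout.

## Problem sizes and runtimes

Test and acceptance simulations are sized for a single CPU: 500 null
cohorts of 42 × 200 with 499 permutations for calibration; 100 cohorts for
power; 10 selection runs of 100 × 53 features (capped at 100 iterations);
1000 logistic replicates of n = 200 for Wilks calibration; one n = 5000 fit
for parameter recovery. The full-pipeline orchestration defaults
(`run_config`) use lighter settings (`boruta_max_runs = 100`,
`n_perm = 999`) than the per-function defaults; final analyses should raise
them (`max_runs = 500`, `n_perm = 9999`).

## Known limitations

- No inter-plate normalization, bridging, or absolute quantification; NPX
  is taken as delivered.
- No moderated/shrinkage t-statistics; with 275 assays and small groups,
  limma-style moderation could add power but changes the published testing
  model.
- In-sample C-index and in-sample all-relevant selection are both
  optimistic; no cross-validation is performed by design.
- Tentative features are left Tentative; there is no rough-fix forcing of
  undecided features.
- The permutation test addresses only pairwise centroid separation, not
  multi-group partitioning of variance.
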