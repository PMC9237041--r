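---
title: "Detecting decanalization of fasting glycemia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting decanalization of fasting glycemia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decanalize)
```

## The scientific question

Canalization is the buffering of a trait's development so that a population
shows low phenotypic variance despite genetic and environmental perturbation;
decanalization is the breakdown of that buffering under unusual or stressful
environments. For a tightly regulated physiological trait such as fasting
blood glucose (healthy range roughly 70–100 mg/dL), decanalization predicts
that stressed subpopulations show a **higher variance** — and therefore more
individuals with extreme values at *both* ends of the distribution — possibly
without any shift in the mean. Mean-oriented tools (regression of individual
glycemia on risk factors, supervised learners) are then the wrong instrument:
the signal is in second moments, locally in covariate space.

`decanalize` implements a variance-first workflow for survey microdata:

1. **Derived variables.** Glycemia is regressed on age (ordinary least
   squares); the *absolute* residuals are grouped as Normal (< 40 mg/dL),
   Outlier (40 ≤ |r| < 80) and Extreme (|r| ≥ 80) — lower-closed,
   upper-open intervals throughout. Monthly household income is categorized
   A (≥ 40,000), B (20,000–40,000), C (10,000–20,000), D (< 10,000 currency
   units); raw glycemia is binned into six ordered levels.
2. **Socioeconomic space.** An optimal-scaling (PRINCALS-style) PCA of the
   explanatory variables — all treated as ordinal except sex — yields object
   scores that place each respondent in a multivariate socioeconomic/
   lifestyle space.
3. **Group tests.** PERMANOVA asks whether the Normal/Outlier/Extreme groups
   occupy different regions of that space, after a multivariate
   homogeneity-of-dispersion check; Bonferroni-adjusted pairwise comparisons
   follow.
4. **Local variance.** A running standard deviation — the k-nearest-neighbour
   analogue of a running average, applied to dispersion — maps where in the
   component space glycemia is most variable, with a permutation test for a
   gradient along a chosen axis.
5. **Frequency analyses.** A G-test of independence between income ×
   education groups and residual categories, with per-cell contributions;
   coefficients of variation (s/x̄, n−1 SD) and glycemia-level frequencies
   per group.

## The synthetic-data generator

Real national-survey microdata cannot ship with the package, so the
generator is a first-class module that encodes the data-generating model the
pipeline is meant to recover:

* a one-dimensional latent disadvantage axis `d ~ N(0, 1)` — the simplest
  structure the socioeconomic PC1 should recover;
* each ordinal covariate j arises by thresholding `loading_j · d + noise_j`
  at the empirical quantiles matching its marginal level frequencies.
  Education (interviewee −0.85, head of household −0.80) and a
  utilities/density pair (∓0.55) carry the axis; working hours (−0.35) load
  moderately; lifestyle covariates (physical activity, diet, salt, alcohol,
  sedentarism, |loading| ≤ 0.10) are nearly orthogonal to it, mirroring the
  empirical finding that lifestyle variables separate from the socioeconomic
  axis;
* income is lognormal with median 20,000 at `d = 0`, log-location falling by
  0.45 per unit disadvantage (marginal mean ≈ 26,000, SD ≈ 21,000 —
  magnitudes typical of the 2018 urban-survey income distribution);
* age is uniform on 18–82.4 years (mean 50.2, adults only) and independent
  of `d` by default so that age adjustment and socioeconomic effects stay
  separable (a config flag can correlate them);
* glycemia is `74 + 0.4 · age + ε`, `ε ~ N(0, σ_i²)` with the **log-linear
  variance model** `σ_i = σ0 · exp(γ · d_i)`, σ0 = 25 mg/dL. The
  multiplicative form guarantees positivity and gives one interpretable
  decanalization effect size; γ = 0 is exactly homoskedastic. σ0 = 25 mg/dL
  makes age-adjusted deviations ≥ 40 mg/dL (the Outlier cut) a ~11% event at
  `d = 0`, a realistic mixture of healthy regulation with diabetic-range
  excursions;
* missingness is completely at random, by default 0.6% per cell, which
  loses about 8% of rows over the 14 variables — the attrition scale of a
  biochemical survey module (about 4,100 complete records from 4,477
  interviews);
* one master seed drives a documented stream-splitting scheme
  (`split_seed()`): latent axis, ages, covariate noise, income, glycemia and
  missingness each consume their own sub-stream, so any stage can be
  reproduced in isolation.

What the generator does **not** emulate: multi-stage sampling weights,
household clustering, type-1-diabetes or pregnancy subpopulations, heavy
non-Gaussian tails in glycemia, and missingness that depends on the data.
Passing parameter-recovery tests therefore demonstrates that the estimators
work under the stated model, not that real survey data satisfy that model.

## Optimal-scaling PCA

`fit_ordinal_pca()` minimizes the Gifi loss
`Σ_j ‖X − q_j a_jᵀ‖² / (np)` over object scores `X` (constrained to
`XᵀX = nI`, columns centred), loadings `a_j`, and category quantifications
`q_j = G_j y_j` (single-rank, one quantification vector per variable), by
alternating least squares:

* quantification update: category means of `X a_j`, followed by weighted
  isotonic regression (pooled-adjacent-violators with category counts as
  weights) for ordinal variables — both monotone directions are fit and the
  better one kept, the direction sign being absorbed into the loading —
  unrestricted means for nominal variables, fixed standardized values for
  numeric ones; quantifications are then renormalized to weighted mean 0 and
  weighted sum of squares n, and the loading refit by projection, so every
  step is a constrained least-squares projection and the loss is
  monotonically non-increasing;
* score update: the orthogonal-Procrustes solution, `X = √n · UVᵀ` from the
  SVD of `Σ_j q_j a_jᵀ`.

Numerical choices: initialization from classical PCA of the integer-coded
standardized data (deterministic, no random restarts); convergence when the
relative loss change drops below 1e-6 (default), at most 200 iterations,
with a non-convergence warning rather than an error; ties in the isotonic
fit pooled by weighted averaging (standard PAVA semantics); component signs
fixed by making each loading column's largest-magnitude entry positive, so
fits are reproducible bit for bit; a quantification that would collapse to
zero variance keeps its previous value for that sweep. Variance accounted
for is reported as the eigenvalue shares of the correlation matrix of the
quantified variables; in the all-numeric limit the procedure reduces exactly
to classical correlation PCA (a test asserts agreement to 1e-6). With
continuous variables declared ordinal (income, age), every distinct value is
its own category — the monotone fit then estimates an arbitrary monotone
transform, which is how the original optimal-scaling analyses treat them.

Eight components are retained by default, configurable; no automatic
retention rule is imposed. Because the normalization variant and iteration
limits of other optimal-scaling implementations differ in detail, numerical
equality with them is not promised — only qualitative agreement (axis
interpretation, variance-accounted magnitude). At default generator
settings the 8-component fit accounts for roughly three quarters of the
quantified variance, with PC1 carried by income/education/utilities/density
and PC2 by sex, age and lifestyle variables — the synthetic analogue of the
published socioeconomic axis.

## The running standard deviation

For each observation, `running_sd()` finds its k nearest neighbours
(Euclidean distance on object scores as produced by the PCA — i.e. biplot
coordinates, no eigenvalue re-weighting; distance ties broken by ascending
row index) and reports the n−1 sample SD of glycemia within the
neighbourhood. Design choices, and why:

* **k-NN rather than fixed radius**: neighbourhood sample size — hence the
  sampling precision of the SD, whose coefficient of variation is about
  `1/√(2k)` — stays constant between dense and sparse regions; sparse
  regions are exactly the disadvantaged margins where the signal lives.
* default `k = max(50, ⌈0.05 n⌉)`: at least 50 observations caps the SD's
  sampling noise at ~10%, while 5% of n keeps neighbourhoods local at survey
  scale.
* `include_self = TRUE` by default: with k ≥ 50 the effect is negligible and
  every observation has defined output.
* the optional two-pass **centre correction** (`center_correct = TRUE`)
  subtracts each observation's running mean before computing the running SD,
  separating local dispersion from local level; it is off by default since
  gradient results are typically insensitive to it, and both passes are
  always reported.
* subspaces default to components (1, 2) and (3, 4) — the socioeconomic and
  lifestyle planes — with any index set available, since published analyses
  are ambiguous about whether 2-D projections or the full retained space was
  used.

`variance_gradient_test()` correlates (Spearman) the running SD with an
axis. Running SDs of overlapping neighbourhoods are strongly autocorrelated,
so naive independence-based inference is invalid; the null instead permutes
the *values over positions*, recomputes the whole running-SD field each
time, and uses the `(1 + exceedances)/(B + 1)` two-sided estimator. The n × n
neighbour search and the batched permutation recomputation are implemented
in C++; the neighbourhood structure is computed once per test.

`smooth_surface()` (a plain loess smooth on a grid) is display-only; no
inference is attached, and collinear score configurations degrade to a 1-D
smooth with a warning.

## Group-level inference

**PERMANOVA** (`permanova()`) uses the squared-Euclidean partition
`SS_total = (1/n) Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d²`,
pseudo-F = `(SS_between/(g−1)) / (SS_within/(n−g))`, with unrestricted
permutation of group labels. It accepts either coordinates (fast path via
group sums) or a distance matrix (the two paths agree to machine precision
and are cross-tested). p-values use `(1 + exceedances)/(B + 1)` — strictly
valid and never zero; B defaults to 999 (a permutation p of 0.001 then means
no permuted statistic reached the observed one). An explicit permutation
matrix can be supplied, which makes exhaustive-enumeration oracles testable.
In one Euclidean dimension the pseudo-F equals the classical ANOVA F
exactly.

**Dispersion check** (`dispersion_test()`): distances to group centroids in
the score space, one-way F on those distances, label permutation of the
distances. This is the centroid variant (no bias-corrected or median
alternatives), matching its role as PERMANOVA's assumption check: PERMANOVA
location differences are only interpretable when dispersions are comparable.

**G-test** (`g_test()`): `G = 2 Σ O ln(O/E)`, df = (r−1)(c−1), chi-square
reference, no Williams/continuity correction; zero cells contribute 0 (the
`x ln x → 0` limit). Per-cell "residuals" are reported as the signed G
contributions `2 O ln(O/E)` — whose sign automatically agrees with `O − E`
and which sum exactly to G — with Pearson residuals `(O−E)/√E` as an
alternative column, since the published heat-map decomposition does not
state its formula. Row groups for the income × education analysis come from
`build_contingency()`, which drops empty combinations with a log entry
(sparse corners such as high income × low education are expected); with all
4 × 3 row groups populated and 3 residual categories the table is 12 × 3 and
df = 22.

Bonferroni (not Holm) adjustment is used for pairwise comparisons, matching
the stated analysis plan.

## Calibration and recovery evidence

The test suite recomputes, at fixed problem sizes chosen as the package's
own desk-scale study conditions:

* exact agreement of `running_sd()` with a brute-force distance-matrix
  oracle (n ≤ 200), of PERMANOVA with exhaustive label enumeration on an
  8-point example, and of the G-test with direct formula evaluation
  (G = 6.796 on [[20,10],[10,20]]);
* PERMANOVA empirical type-I error within (0.03, 0.075) at α = 0.05 over
  500 null simulations (n = 60, three groups, B = 199);
* variance-gradient-test null rejection rate within (0.02, 0.09) over 200
  homoskedastic replicates (n = 4,000, k = 200, B = 199) — the calibration
  embeds observations in a two-dimensional space containing the latent axis,
  isolating the permutation test from PCA estimation error;
* Spearman correlation above 0.8 between the running SD and the true
  per-individual σ under γ = 0.5 (n = 4,000, k = 200), and G-test power of
  at least 80% over 100 replicates at γ = 0.4, n = 4,000;
* reduction limits: all-numeric optimal scaling = classical PCA (1e-6), 1-D
  PERMANOVA = ANOVA (1e-8), G ≈ Pearson X² within 5% when all expected
  counts are ≥ 20. The installed `vegan` implementations (`adonis2`,
  `betadisper`) serve as independent cross-checks in the test suite, never
  as the implementation.

`scripts/acceptance.R` re-runs the full study and these calibrations from a
single seed and writes the resulting numbers as JSON.

## Known limitations and open choices

* The six glycemia levels use standard clinical breakpoints
  (70/100/126/160/200 mg/dL) as configurable defaults; the original
  analysis's exact level definitions live in supplementary material that is
  not redistributed here, so these edges are a documented stand-in, echoed
  in every report.
* Complete-case filtering requires completeness on the response *and* all
  explanatory variables (the strictest reading); which variables the
  original filter covered is not stated.
* The pipeline treats exclusion flags (reported treatment, prior diagnosis)
  independently in sensitivity reruns; whether such subgroups overlap in the
  original data is unknown.
* Only Euclidean dissimilarities and unrestricted permutations are
  implemented; no survey weights, household clustering or geographic
  analysis (the motivating data lack geography).
* Supervised mean-modelling baselines are summarized by a single linear-model
  R² (reported as a diagnostic — at default generator settings it is below
  0.1, the "traditional approach explains little" phenomenon); off-the-shelf
  machine-learning fits are out of scope, though the report structure leaves
  a hook for merging external results.

## Reproducing the original external analysis

The motivating national survey (2018 Argentinian risk-factor survey,
biochemical module) is public but must be downloaded separately from the
INDEC database portal. A desk recipe, untested here by design: export the
respondent-level table with the fasting-glycemia determination and the 13
explanatory variables to CSV; map column names onto a `variable_schema()`
(education as the 3-level ordered attainment factors, working time as the
4-level weekly-hours factor, and so on); then run
`run_study(pipeline_config(mode = "file", input_path = ...))`. Expect about
4.1k complete records and qualitative agreement (socioeconomic PC1,
significant PERMANOVA with null dispersion check, df = 22 G-test); exact
statistics depend on the optimal-scaling normalization variant and are not
promised.
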