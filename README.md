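# decanalize

Variance-first analysis of fasting glycemia in population survey microdata.

## The problem

Canalization keeps tightly regulated physiological traits — fasting blood
glucose is the canonical example, with a healthy range around 70–100 mg/dL —
within a narrow band across a population. Under chronic environmental stress
that buffering can break down (*decanalization*): the affected subpopulation
shows a **higher phenotypic variance**, and therefore more individuals with
extreme values at both tails, possibly with no shift in the mean at all.
Mean-oriented tools (risk regressions, supervised learners) are blind to this
signal; the question is *where in covariate space the variance is inflated*.

`decanalize` is for epidemiologists and quantitative biologists who want to
test decanalization hypotheses on respondent-level survey tables. It
implements:

- **Derived variables** — OLS age adjustment of glycemia; absolute residuals
  categorized Normal (|r| < 40 mg/dL) / Outlier (40 ≤ |r| < 80) / Extreme
  (|r| ≥ 80); household income categories A (≥ 40,000) / B / C / D
  (< 10,000 currency units); six ordered glycemia levels; coefficients of
  variation `CV = s/x̄` by group.
- **Optimal-scaling PCA** (`fit_ordinal_pca()`) — PRINCALS-style alternating
  least squares with monotone (isotonic) category quantifications for ordinal
  variables, giving object scores that embed respondents in a socioeconomic/
  lifestyle space.
- **Running standard deviation** (`running_sd()`) — the local decanalization
  estimator: for each respondent, the SD of glycemia over its k nearest
  neighbours in a component subspace, with a permutation test
  (`variance_gradient_test()`) for a variance gradient along an axis that
  accounts for the autocorrelation of overlapping neighbourhoods.
- **Group tests** — PERMANOVA (`permanova()`, with
  `pseudo-F = (SS_between/(g−1))/(SS_within/(n−g))` on squared Euclidean
  interpoint distances), the multivariate dispersion check
  (`dispersion_test()`), Bonferroni pairwise comparisons, and a G-test of
  independence (`g_test()`, `G = 2 Σ O ln(O/E)`) with signed per-cell
  contributions.
- **A synthetic survey generator** (`simulate_survey()`) with a known latent
  disadvantage axis `d ~ N(0,1)` and a log-linear variance model
  `σ_i = σ0·exp(γ·d_i)`, so every estimator has a parameter-recovery test.
- **A pipeline** (`run_study()`) that chains all stages into a reproducible,
  machine-readable report.

## Worked example

```r
library(decanalize)

cfg <- pipeline_config(
  sim = simulation_config(n_individuals = 2000, gamma = 0.5, seed = 1),
  n_components = 8, B = 199, seed = 1)
report <- run_study(cfg)
print(report)
```

```
Decanalization study report
  records: 2000 input, 1848 complete retained (152 dropped)
  age regression: glycemia = 69.80 + 0.463 * age (mg/dL)
  PCA: 8 components account for 75.4% of quantified variance
  PERMANOVA (residual categories): F(2, 1845) = 20.596, p = 0.005
  dispersion check: F = 0.544, p = 0.545
  running-SD gradient along PC1: Spearman rho = -0.972, p = 0.005
  running SD vs true sigma (synthetic truth): Spearman rho = 0.851
  G-test (income x education vs residual category): G(df = 22) = 289.57, p = 1.581e-48
  baseline linear-model R-squared for glycemia: 0.086
```

Reading the report: the Normal/Outlier/Extreme residual groups occupy
significantly different regions of the component space (PERMANOVA
p = 0.005) while their multivariate dispersions are comparable (p = 0.545),
so the location test is interpretable. The running SD of glycemia falls
steeply along PC1 (Spearman −0.972; PC1 points towards socioeconomic
*advantage* — income, education and utilities load positively):

```r
round(report$pca$loadings[, 1:2], 2)
#>                     PC1   PC2
#> age                0.01  0.38
#> income             0.72 -0.01
#> edu_interviewee    0.78  0.02
#> edu_head           0.75  0.02
#> working_hours      0.44 -0.33
#> density           -0.62 -0.05
#> utilities          0.66 -0.03
#> physical_activity  0.10  0.57
#> ...
```

Because the input is synthetic, the report also scores recovery of the known
truth: the running SD correlates 0.851 (Spearman) with the true
per-individual σ. The G-test (df = 22: twelve income × education groups by
three residual categories) rejects independence, and the plain linear model
on all covariates explains only 8.6% of glycemia variance — the
mean-modelling dead end that motivates the variance-first approach. Real
data are analysed identically with
`pipeline_config(mode = "file", input_path = "survey.csv", ...)`.

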