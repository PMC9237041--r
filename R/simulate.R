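#' Default ordinal covariate specifications
#'
#' Covariates emulating a national risk-factor survey: educational attainment
#' (interviewee and head of household), weekly paid working time, household
#' density, a utilities-access index, physical activity, sedentarism, daily
#' fruit/vegetable portions, salt-adding frequency and alcohol-consumption
#' category. Each covariate is generated by thresholding
#' `loading * d + noise` (with `d` the latent disadvantage axis and
#' `noise ~ N(0, noise_sd^2)`) at its empirical quantiles, so `probs` fixes
#' the marginal level frequencies. Negative loadings mean the covariate
#' decreases with disadvantage (e.g. education, income-like variables);
#' positive loadings increase with it (e.g. household density).
#'
#' Marginal level frequencies default to values typical of an urban adult
#' population (education strongly skewed towards completed high school,
#' mostly non-problematic alcohol consumption, around one fifth of
#' respondents never adding salt).
#'
#' @return a list of covariate specs; each element has fields `name`,
#'   `n_levels`, `loading`, `noise_sd`, `probs` (marginal level
#'   probabilities, summing to 1) and `labels`.
#' @export
default_covariate_specs <- function() {
  spec <- function(name, n_levels, loading, noise_sd, probs = NULL, labels = NULL) {
    if (is.null(probs)) probs <- rep(1 / n_levels, n_levels)
    probs <- probs / sum(probs)
    if (is.null(labels)) labels <- paste0(name, "_", seq_len(n_levels))
    list(name = name, n_levels = n_levels, loading = loading,
         noise_sd = noise_sd, probs = probs, labels = labels)
  }
  edu_labels <- c("elementary_incomplete", "highschool_incomplete",
                  "highschool_complete_plus")
  list(
    spec("edu_interviewee", 3, -0.85, 0.55, c(0.084, 0.339, 0.577), edu_labels),
    spec("edu_head", 3, -0.80, 0.60, c(0.093, 0.354, 0.553), edu_labels),
    spec("working_hours", 4, -0.35, 0.90, c(0.385, 0.222, 0.231, 0.162),
         c("none", "under_35", "35_to_45", "over_45")),
    spec("density", 5, 0.55, 0.80),
    spec("utilities", 5, -0.55, 0.80),
    spec("physical_activity", 3, -0.10, 1.00, c(0.462, 0.368, 0.170),
         c("low", "intermediate", "high")),
    spec("sedentarism", 6, 0.05, 1.00),
    spec("fruit_veg", 6, -0.10, 1.00),
    spec("salt", 4, 0.05, 1.00, c(0.216, 0.508, 0.174, 0.102),
         c("never", "sometimes", "frequently", "always")),
    spec("alcohol", 3, 0.05, 1.00, c(0.830, 0.132, 0.038),
         c("none", "regular_or_episodic", "regular_and_episodic"))
  )
}

#' Configuration for the synthetic survey generator
#'
#' The generator emulates a respondent-level survey table with a known ground
#' truth: a standard-normal latent disadvantage axis `d`, ordinal covariates
#' loading on it, a linear age trend in fasting glycemia, and a glycemia
#' residual standard deviation that is log-linear in disadvantage,
#' `sigma_i = sigma0 * exp(gamma * d_i)`. `gamma = 0` gives a fully
#' homoskedastic (canalized) population; `gamma > 0` produces decanalization
#' concentrated in the disadvantaged region.
#'
#' Defaults describe an urban adult population: ages uniform on 18--82.4
#' years (mean 50.2), glycemia mean `74 + 0.4 * age` mg/dL (about 94 mg/dL at
#' the mean age), baseline residual SD 25 mg/dL, household income lognormal
#' with median 20,000 currency units falling with disadvantage, 58.5% female
#' respondents, and 0.6% of cells missing completely at random (about 8% of
#' rows incomplete over the 14 variables, the attrition typical of the
#' biochemical module of such surveys).
#'
#' @param n_individuals number of respondents interviewed (before
#'   complete-record filtering).
#' @param age_low,age_high uniform age range in years, `age_low < age_high`.
#' @param beta0 glycemia intercept, mg/dL.
#' @param beta1 glycemia age slope, mg/dL per year.
#' @param sigma0 baseline glycemia residual SD, mg/dL, > 0.
#' @param gamma decanalization coefficient (log-SD per unit latent
#'   disadvantage); 0 means homoskedastic.
#' @param covariate_specs list of ordinal covariate specs, see
#'   [default_covariate_specs()].
#' @param sex_prob probability that a respondent is female.
#' @param missing_rate cellwise probability of a missing value (MCAR).
#' @param income_meanlog_base log of the median household income at `d = 0`.
#' @param income_dslope decrease of log-income per unit disadvantage (>= 0).
#' @param income_sdlog residual SD of log-income.
#' @param age_d_cor correlation between age and disadvantage (default 0 so
#'   that age adjustment and socioeconomic effects are separable).
#' @param seed master seed; all sub-draws derive from it via [split_seed()].
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 4477L,
                              age_low = 18, age_high = 82.4,
                              beta0 = 74, beta1 = 0.4,
                              sigma0 = 25, gamma = 0.4,
                              covariate_specs = default_covariate_specs(),
                              sex_prob = 0.585,
                              missing_rate = 0.006,
                              income_meanlog_base = log(20000),
                              income_dslope = 0.45,
                              income_sdlog = 0.55,
                              age_d_cor = 0,
                              seed = 1L) {
  assert_scalar_number(n_individuals, "n_individuals", lower = 1)
  if (n_individuals != round(n_individuals))
    config_error("n_individuals", "must be an integer")
  assert_scalar_number(age_low, "age_low")
  assert_scalar_number(age_high, "age_high")
  if (age_low >= age_high) config_error("age_low", "must satisfy age_low < age_high")
  assert_scalar_number(beta0, "beta0")
  assert_scalar_number(beta1, "beta1")
  assert_scalar_number(sigma0, "sigma0")
  if (sigma0 <= 0) config_error("sigma0", "must be > 0")
  assert_scalar_number(gamma, "gamma")
  assert_scalar_number(sex_prob, "sex_prob", 0, 1)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1)
  assert_scalar_number(age_d_cor, "age_d_cor", -1, 1)
  assert_scalar_number(income_dslope, "income_dslope", lower = 0)
  assert_scalar_number(income_sdlog, "income_sdlog", lower = 0)
  assert_scalar_number(seed, "seed")
  if (!is.list(covariate_specs) || length(covariate_specs) == 0)
    config_error("covariate_specs", "must be a non-empty list")
  for (cs in covariate_specs) {
    if (!all(c("name", "n_levels", "loading", "noise_sd") %in% names(cs)))
      config_error("covariate_specs",
                   "each spec needs name, n_levels, loading, noise_sd")
    if (cs$n_levels < 2)
      config_error(cs$name, "n_levels must be >= 2")
    if (cs$noise_sd < 0)
      config_error(cs$name, "noise_sd must be >= 0")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    age_low = age_low, age_high = age_high,
    beta0 = beta0, beta1 = beta1, sigma0 = sigma0, gamma = gamma,
    covariate_specs = covariate_specs, sex_prob = sex_prob,
    missing_rate = missing_rate,
    income_meanlog_base = income_meanlog_base,
    income_dslope = income_dslope, income_sdlog = income_sdlog,
    age_d_cor = age_d_cor,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

## internal: threshold a latent score into an ordered factor at empirical
## quantiles matching the requested marginal probabilities
threshold_ordinal <- function(z, probs, labels) {
  cuts <- quantile(z, cumsum(probs)[-length(probs)], names = FALSE, type = 7)
  codes <- findInterval(z, cuts, left.open = FALSE) + 1L
  factor(labels[codes], levels = labels, ordered = TRUE)
}

#' Simulate a survey table with known decanalization ground truth
#'
#' Draws a latent disadvantage axis `d_i ~ N(0, 1)`, ordinal covariates by
#' quantile-thresholding `loading * d + noise`, household income as a
#' lognormal with location decreasing in `d`, age uniform on the configured
#' range (independent of `d` unless `age_d_cor != 0`), and fasting glycemia
#' `beta0 + beta1 * age + eps` with `eps ~ N(0, sigma_i^2)` and
#' `sigma_i = sigma0 * exp(gamma * d_i)`. Missing values are inserted
#' completely at random. Identical configurations (including seed) produce
#' bitwise-identical outputs.
#'
#' @param config a [simulation_config()].
#' @return a list of class `survey_sim` with elements
#'   \describe{
#'     \item{table}{a `data.frame`, one row per respondent: `glycemia`,
#'       `age`, `sex`, `income`, and one ordered factor per covariate spec.}
#'     \item{truth}{class `ground_truth`: `d` (latent disadvantage),
#'       `sigma` (true per-individual residual SD, mg/dL) and the generating
#'       parameters; rows align with `table` before any filtering.}
#'   }
#' @export
simulate_survey <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  n <- config$n_individuals
  seeds <- split_seed(config$seed, 6L)

  set.seed(seeds[1]); d <- rnorm(n)
  set.seed(seeds[2]); {
    u <- runif(n)
    if (config$age_d_cor != 0) {
      # Gaussian-copula tilt of the age quantile towards d
      rho <- config$age_d_cor
      u <- pnorm(rho * d + sqrt(1 - rho^2) * qnorm(u))
    }
    age <- config$age_low + u * (config$age_high - config$age_low)
  }
  set.seed(seeds[3])
  covs <- lapply(config$covariate_specs, function(cs) {
    z <- cs$loading * d + rnorm(n, sd = cs$noise_sd)
    threshold_ordinal(z, cs$probs, cs$labels)
  })
  names(covs) <- vapply(config$covariate_specs, `[[`, "", "name")
  set.seed(seeds[4])
  income <- rlnorm(n, meanlog = config$income_meanlog_base -
                     config$income_dslope * d, sdlog = config$income_sdlog)
  set.seed(seeds[5]); {
    sex <- factor(ifelse(runif(n) < config$sex_prob, "female", "male"),
                  levels = c("female", "male"))
    sigma <- config$sigma0 * exp(config$gamma * d)
    glycemia <- config$beta0 + config$beta1 * age + rnorm(n, sd = sigma)
  }

  tab <- data.frame(glycemia = glycemia, age = age, sex = sex,
                    income = income, covs, check.names = FALSE)

  if (config$missing_rate > 0) {
    set.seed(seeds[6])
    miss <- matrix(runif(n * ncol(tab)) < config$missing_rate,
                   nrow = n, ncol = ncol(tab))
    for (j in seq_along(tab)) tab[[j]][miss[, j]] <- NA
  }

  truth <- structure(list(d = d, sigma = sigma,
                          params = config[c("beta0", "beta1", "sigma0", "gamma")],
                          seed = config$seed),
                     class = "ground_truth")
  structure(list(table = tab, truth = truth, config = config),
            class = "survey_sim")
}

#' Re-index the true per-individual SD to an external ordering
#'
#' Pure re-indexing helper for parameter-recovery tests: aligns the ground
#' truth `sigma_i` with an ordering or score vector produced downstream.
#'
#' @param truth a `ground_truth` object from [simulate_survey()].
#' @param ordering integer permutation of `seq_along(truth$sigma)`, or any
#'   vector/matrix whose length/row count equals `length(truth$sigma)` (the
#'   identity ordering is then used and lengths are merely validated).
#' @return numeric vector of true SDs aligned to the ordering.
#' @export
truth_variance_profile <- function(truth, ordering) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- length(truth$sigma)
  if (is.matrix(ordering)) {
    if (nrow(ordering) != n) stop("length mismatch between truth and axis", call. = FALSE)
    return(truth$sigma)
  }
  if (length(ordering) != n)
    stop("length mismatch between truth and ordering", call. = FALSE)
  if (is.numeric(ordering) && all(ordering == round(ordering)) &&
      all(sort(ordering) == seq_len(n))) {
    truth$sigma[ordering]
  } else {
    truth$sigma
  }
}

#' Write a simulated survey (and its ground truth) as delimited text
#'
#' @param sim a `survey_sim` from [simulate_survey()], or a plain data.frame.
#' @param path output path for the respondent table (`.csv` comma-separated,
#'   `.tsv`/`.txt` tab-separated); missing cells are written empty.
#' @param truth_path optional path for the ground-truth sidecar
#'   (`d`, `sigma` per row).
#' @return `path`, invisibly.
#' @export
write_survey <- function(sim, path, truth_path = NULL) {
  tab <- if (inherits(sim, "survey_sim")) sim$table else sim
  utils::write.table(tab, path, sep = delim_for(path), row.names = FALSE,
                     na = "", quote = FALSE)
  if (!is.null(truth_path) && inherits(sim, "survey_sim")) {
    utils::write.table(data.frame(d = sim$truth$d, sigma = sim$truth$sigma),
                       truth_path, sep = delim_for(truth_path),
                       row.names = FALSE, na = "", quote = FALSE)
  }
  invisible(path)
}

#' @export
print.survey_sim <- function(x, ...) {
  cat("Synthetic survey:", nrow(x$table), "respondents,",
      ncol(x$table), "variables\n")
  cat(sprintf("  gamma = %g (sigma range %.1f-%.1f mg/dL), seed = %d\n",
              x$config$gamma, min(x$truth$sigma), max(x$truth$sigma),
              x$config$seed))
  invisible(x)
}
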