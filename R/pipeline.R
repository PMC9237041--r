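#' Configuration for the full decanalization study pipeline
#'
#' Bundles the stage configurations. Exactly one input mode is used:
#' `"synthetic"` (runs [simulate_survey()]) or `"file"` (reads `input_path`
#' with [read_survey()]). All stage seeds derive from the global seed via
#' [split_seed()] unless a stage overrides them.
#'
#' @param mode `"synthetic"` or `"file"`.
#' @param sim a [simulation_config()] (synthetic mode).
#' @param input_path path to a delimited respondent table (file mode).
#' @param schema a [variable_schema()] describing the input.
#' @param n_components components retained by the ordinal PCA (default 8).
#' @param k running-SD neighbourhood size (`NULL` = `max(50, 0.05 n)`).
#' @param subspaces list of component index pairs for the running-SD maps
#'   (default components (1,2) and (3,4)).
#' @param center_correct running-mean correction flag for the running SD.
#' @param B permutation count for all permutation tests (default 999).
#' @param residual_cuts,income_cuts,glycemia_edges derived-variable rules,
#'   see [derive_variables()].
#' @param exclude_flags names of logical columns flagging respondents to drop
#'   in sensitivity reruns (e.g. self-reported treatment or diagnosis); each
#'   present flag triggers an independent rerun of the G-test stage.
#' @param seed global seed.
#' @param outdir optional output directory for stage artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "file"),
                            sim = simulation_config(),
                            input_path = NULL,
                            schema = default_schema(),
                            n_components = 8L,
                            k = NULL,
                            subspaces = list(c(1L, 2L), c(3L, 4L)),
                            center_correct = FALSE,
                            B = 999L,
                            residual_cuts = c(40, 80),
                            income_cuts = c(10000, 20000, 40000),
                            glycemia_edges = c(70, 100, 126, 160, 200),
                            exclude_flags = character(0),
                            seed = 1L,
                            outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "file" && is.null(input_path))
    config_error("input_path", "required in file mode")
  structure(list(mode = mode, sim = sim, input_path = input_path,
                 schema = schema, n_components = as.integer(n_components),
                 k = k, subspaces = subspaces,
                 center_correct = center_correct, B = as.integer(B),
                 residual_cuts = residual_cuts, income_cuts = income_cuts,
                 glycemia_edges = glycemia_edges,
                 exclude_flags = exclude_flags,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Key-value file with nested sections mirroring the [pipeline_config()] and
#' [simulation_config()] arguments; the `sim:` section (if present) is passed
#' to [simulation_config()].
#'
#' @param path path to the YAML config.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(simulation_config, raw$sim)
  if (!is.null(raw$subspaces))
    raw$subspaces <- lapply(raw$subspaces, as.integer)
  do.call(pipeline_config, raw)
}

#' Table-1-style variable summary
#'
#' Mean and SD for continuous variables, percentage per level for categorical
#' ones; percentages sum to 100 per variable.
#'
#' @param table a survey data.frame.
#' @return data.frame with `variable`, `statistic` (level label or
#'   `"mean_sd"`) and `value` (formatted string), plus numeric columns
#'   `mean`, `sd`, `percent`.
#' @export
summarize_table <- function(table) {
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
      data.frame(variable = v, statistic = "mean_sd",
                 value = sprintf("%.2f ± %.2f", m, s),
                 mean = m, sd = s, percent = NA_real_)
    } else {
      x <- factor(x)
      tt <- table(x[!is.na(x)])
      pct <- 100 * as.vector(tt) / sum(tt)
      data.frame(variable = v, statistic = names(tt),
                 value = sprintf("%.2f%%", pct),
                 mean = NA_real_, sd = NA_real_, percent = pct)
    }
  })
  do.call(rbind, rows)
}

#' Relative frequency of glycemia levels per income x education cell
#'
#' @param derived a derived table (see [derive_variables()]).
#' @param row_vars grouping columns (default income category and interviewee
#'   education).
#' @return data.frame with the grouping columns, `n` (cell size) and one
#'   `level_1` .. `level_6` relative-frequency column per glycemia level;
#'   frequencies sum to 1 within each populated cell, empty cells appear with
#'   `n = 0` and `NA` frequencies.
#' @export
level_frequency_table <- function(derived,
                                  row_vars = c("income_category",
                                               "edu_interviewee")) {
  stopifnot(all(c(row_vars, "glycemia_level") %in% names(derived)))
  g <- interaction(derived[, row_vars, drop = FALSE], sep = "-",
                   lex.order = TRUE)
  tab <- table(g, derived$glycemia_level)
  n_cell <- rowSums(tab)
  freq <- sweep(unclass(tab), 1, pmax(n_cell, 1), "/")
  freq[n_cell == 0, ] <- NA_real_
  keys <- do.call(rbind, strsplit(rownames(tab), "-", fixed = TRUE))
  colnames(keys) <- row_vars
  out <- data.frame(keys, n = as.vector(n_cell), freq, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-seq_len(length(row_vars) + 1)] <-
    paste0("level_", colnames(tab))
  rownames(out) <- NULL
  out
}

#' Run the full decanalization study
#'
#' Executes the study stages in order: obtain the respondent table (simulate
#' or read), filter to complete records, derive the age-residual / income /
#' glycemia categories, summarize the covariates, fit the optimal-scaling
#' PCA on the explanatory variables, test whether the residual categories
#' occupy distinct regions of the component space (PERMANOVA + dispersion
#' check + Bonferroni pairwise comparisons), map the running SD of glycemia
#' over the requested component subspaces and test its gradient along the
#' first component, compute CV-by-group tables, run the income x education
#' G-test on residual categories, tabulate glycemia-level frequencies, and
#' report a plain linear-model R-squared of glycemia on all explanatory
#' variables as the "traditional" baseline diagnostic. When ground truth is
#' available (synthetic mode) the Spearman correlation between the running SD
#' and the true per-individual SD is recorded.
#'
#' Identical configurations (including the seed) give identical reports.
#'
#' @param config a [pipeline_config()].
#' @return object of class `study_report`; see the fields in the examples of
#'   [print.study_report()].
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 6L)
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (config$mode == "synthetic") {
      sim <- simulate_survey(config$sim)
      tab0 <- sim$table
      truth <- sim$truth
    } else {
      tab0 <- read_survey(config$input_path, config$schema)
    }
    n_input <- nrow(tab0)

    stage <- "filter_complete"
    required <- intersect(config$schema$name, names(tab0))
    keep_idx <- stats::complete.cases(tab0[, required, drop = FALSE])
    tab <- filter_complete(tab0, required)
    if (!is.null(truth)) {
      truth$d <- truth$d[keep_idx]
      truth$sigma <- truth$sigma[keep_idx]
    }

    stage <- "derive_variables"
    derived <- derive_variables(tab, config$residual_cuts,
                                config$income_cuts, config$glycemia_edges)

    stage <- "summarize"
    summary_tab <- summarize_table(
      tab[, setdiff(names(tab), "glycemia"), drop = FALSE])

    stage <- "ordinal_pca"
    expl <- config$schema$name[config$schema$role == "explanatory"]
    expl <- intersect(expl, names(tab))
    pca <- fit_ordinal_pca(tab[, expl, drop = FALSE],
                           n_components = min(config$n_components,
                                              length(expl)))
    va <- variance_accounted(pca)

    stage <- "permanova"
    perm <- permanova(pca$scores, derived$residual_category,
                      B = config$B, seed = seeds[1])
    disp <- dispersion_test(pca$scores, derived$residual_category,
                            B = config$B, seed = seeds[2])
    pw <- pairwise_permanova(pca$scores, derived$residual_category,
                             B = config$B, seed = seeds[3])

    stage <- "running_sd"
    runsd <- lapply(config$subspaces, function(ix) {
      ix <- ix[ix <= pca$n_components]
      if (length(ix) < 1) return(NULL)
      running_sd(scores_subspace(pca, ix), derived$glycemia, k = config$k,
                 center_correct = config$center_correct)
    })
    names(runsd) <- vapply(config$subspaces,
                           function(ix) paste(ix, collapse = "_"), "")
    runsd <- Filter(Negate(is.null), runsd)
    vgt <- if (length(runsd))
      variance_gradient_test(runsd[[1]], pca$scores[, 1],
                             B = config$B, seed = seeds[4]) else NULL
    # undefined when the truth is homoskedastic (constant sigma)
    truth_spearman <- if (!is.null(truth) && length(runsd) &&
                          var(truth$sigma) > 0)
      cor(runsd[[1]]$sd, truth_variance_profile(truth, seq_len(nrow(tab))),
          method = "spearman") else NA_real_

    stage <- "cv_by_group"
    edu_var <- if ("edu_interviewee" %in% names(derived))
      "edu_interviewee" else expl[1]
    cv_tab <- cv_by_group(derived, c("income_category", edu_var))

    stage <- "g_test"
    cont <- build_contingency(derived, c("income_category", edu_var))
    gt <- g_test(cont)
    sensitivity <- list()
    for (fl in intersect(config$exclude_flags, names(derived))) {
      sub <- derived[!isTRUE_vec(derived[[fl]]), , drop = FALSE]
      sensitivity[[fl]] <- g_test(build_contingency(sub,
                                                    c("income_category", edu_var)))
    }

    stage <- "level_frequencies"
    freq_tab <- level_frequency_table(derived, c("income_category", edu_var))

    stage <- "baseline_lm"
    lm_fit <- lm(stats::reformulate(expl, response = "glycemia"), data = tab)
    baseline_r2 <- summary(lm_fit)$r.squared

    report <- structure(list(
      n_input = n_input,
      n_retained = attr(tab, "n_retained"),
      n_dropped = attr(tab, "n_dropped"),
      summary = summary_tab,
      age_fit = attr(derived, "age_fit"),
      rules = attr(derived, "rules"),
      pca = pca,
      variance_accounted = va,
      permanova = perm,
      dispersion = disp,
      pairwise = pw,
      running_sd = runsd,
      gradient_test = vgt,
      truth_spearman = truth_spearman,
      cv_table = cv_tab,
      contingency = cont,
      g_test = gt,
      sensitivity_g_tests = sensitivity,
      level_frequencies = freq_tab,
      baseline_r2 = baseline_r2,
      derived = derived,
      provenance = list(seed = config$seed, stage_seeds = seeds,
                        mode = config$mode, B = config$B,
                        n_components = pca$n_components,
                        package_version = as.character(
                          utils::packageVersion("decanalize")))
    ), class = "study_report")
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$outdir)) write_study_report(res, config$outdir)
  res
}

## internal: tolerate logical / 0-1 / "yes" flags
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  !is.na(x) & tolower(as.character(x)) %in% c("true", "yes", "1")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Decanalization study report\n")
  cat(sprintf("  records: %d input, %d complete retained (%d dropped)\n",
              x$n_input, x$n_retained, x$n_dropped))
  cat(sprintf("  age regression: glycemia = %.2f + %.3f * age (mg/dL)\n",
              x$age_fit$intercept, x$age_fit$slope))
  cat(sprintf("  PCA: %d components account for %.1f%% of quantified variance\n",
              x$pca$n_components,
              100 * tail(x$variance_accounted$cumulative, 1)))
  cat(sprintf("  PERMANOVA (residual categories): F(%d, %d) = %.3f, p = %.4g\n",
              x$permanova$df_between, x$permanova$df_within,
              x$permanova$F, x$permanova$p_value))
  cat(sprintf("  dispersion check: F = %.3f, p = %.4g\n",
              x$dispersion$F, x$dispersion$p_value))
  if (!is.null(x$gradient_test))
    cat(sprintf("  running-SD gradient along PC1: Spearman rho = %.3f, p = %.4g\n",
                x$gradient_test$rho, x$gradient_test$p_value))
  if (!is.na(x$truth_spearman))
    cat(sprintf("  running SD vs true sigma (synthetic truth): Spearman rho = %.3f\n",
                x$truth_spearman))
  cat(sprintf("  G-test (income x education vs residual category): G(df = %d) = %.2f, p = %.4g\n",
              x$g_test$df, x$g_test$G, x$g_test$p_value))
  cat(sprintf("  baseline linear-model R-squared for glycemia: %.3f\n",
              x$baseline_r2))
  invisible(x)
}

#' Write a study report as structured text artifacts
#'
#' One key-value `report.txt` plus delimited side tables (summary, CV table,
#' contingency and contributions, level frequencies, running SD, scores and
#' loadings).
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c(
    sprintf("n_input: %d", report$n_input),
    sprintf("n_retained: %d", report$n_retained),
    sprintf("age_intercept_mg_dl: %.6f", report$age_fit$intercept),
    sprintf("age_slope_mg_dl_per_year: %.6f", report$age_fit$slope),
    sprintf("residual_cuts: %s", paste(report$rules$residual_cuts, collapse = " ")),
    sprintf("income_cuts: %s", paste(report$rules$income_cuts, collapse = " ")),
    sprintf("glycemia_edges: %s", paste(report$rules$glycemia_edges, collapse = " ")),
    sprintf("pca_vaf_cumulative: %.6f",
            tail(report$variance_accounted$cumulative, 1)),
    sprintf("permanova_F: %.6f", report$permanova$F),
    sprintf("permanova_p: %.6g", report$permanova$p_value),
    sprintf("dispersion_F: %.6f", report$dispersion$F),
    sprintf("dispersion_p: %.6g", report$dispersion$p_value),
    sprintf("gtest_G: %.6f", report$g_test$G),
    sprintf("gtest_df: %d", report$g_test$df),
    sprintf("gtest_p: %.6g", report$g_test$p_value),
    sprintf("baseline_lm_r2: %.6f", report$baseline_r2),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("package_version: %s", report$provenance$package_version)
  )
  if (!is.null(report$gradient_test))
    lines <- c(lines,
               sprintf("runsd_pc1_spearman: %.6f", report$gradient_test$rho),
               sprintf("runsd_pc1_p: %.6g", report$gradient_test$p_value))
  if (!is.na(report$truth_spearman))
    lines <- c(lines,
               sprintf("runsd_truth_spearman: %.6f", report$truth_spearman))
  writeLines(lines, file.path(dir, "report.txt"))
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(report$cv_table, file.path(dir, "cv_table.csv"), row.names = FALSE)
  write.csv(as.data.frame.matrix(report$contingency),
            file.path(dir, "contingency.csv"))
  write.csv(as.data.frame.matrix(report$g_test$contributions),
            file.path(dir, "g_contributions.csv"))
  write.csv(report$level_frequencies, file.path(dir, "level_frequencies.csv"),
            row.names = FALSE)
  write.csv(report$pairwise, file.path(dir, "pairwise_permanova.csv"),
            row.names = FALSE)
  for (nm in names(report$running_sd)) {
    rs <- report$running_sd[[nm]]
    write.csv(data.frame(row = seq_along(rs$sd), running_mean = rs$mean,
                         running_sd = rs$sd),
              file.path(dir, paste0("running_sd_", nm, ".csv")),
              row.names = FALSE)
  }
  write_ordinal_pca(report$pca, file.path(dir, "pca"))
  invisible(dir)
}
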