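#' Declare the variables of a survey table
#'
#' A schema names each variable, its measurement role (`response` or
#' `explanatory`), its scale (`continuous`, `ordinal` or `nominal`), its
#' ordered level labels (categorical variables only) and its units. Exactly
#' one variable must be the response (fasting glycemia, mg/dL).
#'
#' @param name character vector of variable names.
#' @param role character vector, `"response"` or `"explanatory"`.
#' @param scale character vector, `"continuous"`, `"ordinal"` or `"nominal"`.
#' @param levels list of character vectors (level labels, low to high) for
#'   categorical variables, `NULL` entries for continuous ones.
#' @param units character vector of unit strings (may be `""`).
#' @return object of class `variable_schema` (a data.frame with a `levels`
#'   list-column).
#' @export
variable_schema <- function(name, role, scale, levels = NULL, units = "") {
  n <- length(name)
  role <- rep_len(role, n); scale <- rep_len(scale, n)
  units <- rep_len(units, n)
  if (is.null(levels)) levels <- vector("list", n)
  stopifnot(length(levels) == n)
  if (sum(role == "response") != 1L)
    stop("schema must declare exactly one response variable", call. = FALSE)
  if (!all(role %in% c("response", "explanatory")))
    stop("roles must be 'response' or 'explanatory'", call. = FALSE)
  if (!all(scale %in% c("continuous", "ordinal", "nominal")))
    stop("scales must be 'continuous', 'ordinal' or 'nominal'", call. = FALSE)
  for (i in seq_len(n)) {
    if (scale[i] != "continuous") {
      lv <- levels[[i]]
      if (is.null(lv) || anyDuplicated(lv))
        stop(sprintf("variable '%s' needs unique level labels", name[i]),
             call. = FALSE)
    }
  }
  out <- data.frame(name = name, role = role, scale = scale, units = units,
                    stringsAsFactors = FALSE)
  out$levels <- levels
  structure(out, class = c("variable_schema", "data.frame"))
}

#' Default schema matching the synthetic survey generator
#'
#' @param covariate_specs covariate specs as in [default_covariate_specs()].
#' @return a [variable_schema()].
#' @export
default_schema <- function(covariate_specs = default_covariate_specs()) {
  cov_names <- vapply(covariate_specs, `[[`, "", "name")
  cov_levels <- lapply(covariate_specs, `[[`, "labels")
  variable_schema(
    name  = c("glycemia", "age", "sex", "income", cov_names),
    role  = c("response", rep("explanatory", 3 + length(cov_names))),
    scale = c("continuous", "continuous", "nominal", "continuous",
              rep("ordinal", length(cov_names))),
    levels = c(list(NULL, NULL, c("female", "male"), NULL), cov_levels),
    units = c("mg/dL", "years", "", "currency units",
              rep("", length(cov_names)))
  )
}

#' Read a respondent table from delimited text
#'
#' Comma- or tab-separated (auto-detected from the file extension), header
#' row required, column order free. Columns are typed according to the
#' schema; unparseable cells and undeclared category labels become missing.
#'
#' @param path path to the file.
#' @param schema a [variable_schema()].
#' @return a typed `data.frame` with the schema's columns, in schema order.
#' @export
read_survey <- function(path, schema = default_schema()) {
  stopifnot(inherits(schema, "variable_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0) stop("empty survey file: ", path, call. = FALSE)
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(schema)), function(i) {
    x <- raw[[schema$name[i]]]
    if (schema$scale[i] == "continuous") {
      suppressWarnings(as.numeric(x))
    } else {
      factor(x, levels = schema$levels[[i]],
             ordered = schema$scale[i] == "ordinal")
    }
  })
  names(out) <- schema$name
  tab <- data.frame(out, check.names = FALSE)
  message(sprintf("read_survey: %d rows, %d schema variables from %s",
                  nrow(tab), ncol(tab), path))
  tab
}

#' Keep only rows complete on the required variables
#'
#' Mirrors the complete-record filtering step of survey analyses: rows with
#' any missing value among the required variables are dropped; the retained
#' and dropped counts are reported. Idempotent.
#'
#' @param table a survey `data.frame`.
#' @param required variable names that must be observed; defaults to all
#'   columns.
#' @return the filtered `data.frame`, with attributes `n_input`, `n_retained`
#'   and `n_dropped`.
#' @export
filter_complete <- function(table, required = names(table)) {
  bad <- setdiff(required, names(table))
  if (length(bad))
    stop("unknown required variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(table[, required, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no complete records remain", call. = FALSE)
  message(sprintf("filter_complete: retained %d of %d rows (%d dropped)",
                  nrow(out), nrow(table), sum(!keep)))
  structure(out, n_input = nrow(table), n_retained = nrow(out),
            n_dropped = sum(!keep))
}

#' Ordinary least-squares regression of glycemia on age
#'
#' Fits `glycemia ~ age` and returns the residuals used downstream to define
#' the age-adjusted deviation categories.
#'
#' @param table data.frame with numeric `glycemia` and `age` columns and no
#'   missing values in either.
#' @return list with `intercept` (mg/dL), `slope` (mg/dL per year),
#'   `residuals` (signed, mg/dL) and the underlying `lm` fit.
#' @export
age_regression <- function(table) {
  stopifnot(all(c("glycemia", "age") %in% names(table)))
  ok <- stats::complete.cases(table[, c("glycemia", "age")])
  if (sum(ok) < 3) stop("need at least 3 complete (glycemia, age) pairs",
                        call. = FALSE)
  if (any(!ok)) stop("missing glycemia/age values; run filter_complete() first",
                     call. = FALSE)
  if (var(table$age) == 0)
    stop("degenerate design: age is constant", call. = FALSE)
  fit <- lm(glycemia ~ age, data = table)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       residuals = unname(stats::residuals(fit)), fit = fit)
}

#' Categorize age-adjusted residuals as Normal / Outlier / Extreme
#'
#' Absolute residuals are grouped with lower-closed, upper-open intervals:
#' Normal if `|r| < cut_outlier`, Outlier if `cut_outlier <= |r| <
#' cut_extreme`, Extreme if `|r| >= cut_extreme`. Defaults 40 and 80 mg/dL.
#'
#' @param r signed residuals, mg/dL.
#' @param cut_outlier,cut_extreme positive cutpoints, `cut_outlier <
#'   cut_extreme`.
#' @return ordered factor with levels `Normal < Outlier < Extreme`.
#' @export
categorize_residuals <- function(r, cut_outlier = 40, cut_extreme = 80) {
  if (!(cut_outlier > 0 && cut_extreme > cut_outlier))
    config_error("cut_outlier", "need 0 < cut_outlier < cut_extreme")
  a <- abs(r)
  lev <- c("Normal", "Outlier", "Extreme")
  out <- ifelse(a >= cut_extreme, "Extreme",
                ifelse(a >= cut_outlier, "Outlier", "Normal"))
  out[is.na(r)] <- NA
  factor(out, levels = lev, ordered = TRUE)
}

#' Categorize monthly household income into levels D < C < B < A
#'
#' A (high) for `income >= cuts[3]`, B for `cuts[2] <= income < cuts[3]`,
#' C for `cuts[1] <= income < cuts[2]`, D (very low) otherwise. Boundary
#' values go to the upper category. Defaults 10,000 / 20,000 / 40,000
#' currency units.
#'
#' @param income numeric vector, non-negative.
#' @param cuts three strictly increasing positive cutpoints.
#' @return ordered factor with levels `D < C < B < A` (increasing income).
#' @export
categorize_income <- function(income, cuts = c(10000, 20000, 40000)) {
  if (length(cuts) != 3 || any(diff(cuts) <= 0) || any(cuts <= 0))
    config_error("cuts", "must be 3 strictly increasing positive values")
  if (any(income < 0, na.rm = TRUE))
    stop("negative income values are not allowed", call. = FALSE)
  lev <- c("D", "C", "B", "A")
  idx <- findInterval(income, cuts, left.open = FALSE) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Categorize raw fasting glycemia into levels 1..6
#'
#' Half-open bins `[e_k, e_{k+1})`: level 1 below the first edge, level 6 at
#' or above the last. The default edges (70, 100, 126, 160, 200 mg/dL) are
#' standard clinical breakpoints (hypoglycemia, normal fasting, prediabetes,
#' diabetes-range and two severity splits above it); they are configurable
#' and echoed in every pipeline report.
#'
#' @param glycemia mg/dL, positive.
#' @param bin_edges five strictly increasing positive edges.
#' @return ordered factor with levels `"1" .. "6"`.
#' @export
categorize_glycemia <- function(glycemia, bin_edges = c(70, 100, 126, 160, 200)) {
  if (length(bin_edges) != 5 || any(diff(bin_edges) <= 0) || any(bin_edges <= 0))
    config_error("bin_edges", "must be 5 strictly increasing positive values")
  idx <- findInterval(glycemia, bin_edges, left.open = FALSE) + 1L
  factor(as.character(idx), levels = as.character(1:6), ordered = TRUE)
}

#' Coefficient of variation
#'
#' `CV = s / xbar`, with `s` the n-1 sample standard deviation.
#'
#' @param values numeric vector, at least 2 values, mean != 0.
#' @return the CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  sd(values) / m
}

#' Coefficient of variation per group
#'
#' @param table a data.frame.
#' @param by character vector of grouping columns.
#' @param value column whose CV is computed (default `"glycemia"`).
#' @return a data.frame with the grouping columns, `n`, `mean`, `sd` and `cv`
#'   per non-empty cell; singleton cells report `NA` CV with their `n`.
#' @export
cv_by_group <- function(table, by, value = "glycemia") {
  stopifnot(all(c(by, value) %in% names(table)))
  g <- interaction(table[, by, drop = FALSE], drop = TRUE, sep = " / ")
  sp <- split(table[[value]], g)
  rows <- lapply(names(sp), function(nm) {
    v <- sp[[nm]][!is.na(sp[[nm]])]
    data.frame(group = nm, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               cv = if (length(v) >= 2 && mean(v) != 0) sd(v) / mean(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  keys <- do.call(rbind, strsplit(out$group, " / ", fixed = TRUE))
  colnames(keys) <- by
  cbind(as.data.frame(keys, stringsAsFactors = FALSE), out[, -1, drop = FALSE])
}

#' Append all derived variables to a complete survey table
#'
#' Adds the signed age-regression residual, its Normal/Outlier/Extreme
#' category, the income category A--D and the glycemia level 1--6. The age
#' regression is fit on the supplied (already complete-case filtered) rows.
#'
#' @param table complete-case survey data.frame with `glycemia`, `age`,
#'   `income`.
#' @param residual_cuts outlier/extreme cutpoints, mg/dL.
#' @param income_cuts income category cutpoints.
#' @param glycemia_edges glycemia level bin edges, mg/dL.
#' @return the table with columns `age_residual`, `residual_category`,
#'   `income_category`, `glycemia_level` appended; the regression intercept
#'   and slope are stored in attribute `age_fit`, the categorization rules in
#'   attribute `rules`.
#' @export
derive_variables <- function(table,
                             residual_cuts = c(40, 80),
                             income_cuts = c(10000, 20000, 40000),
                             glycemia_edges = c(70, 100, 126, 160, 200)) {
  reg <- age_regression(table)
  out <- table
  out$age_residual <- reg$residuals
  out$residual_category <- categorize_residuals(reg$residuals,
                                                residual_cuts[1], residual_cuts[2])
  out$income_category <- categorize_income(out$income, income_cuts)
  out$glycemia_level <- categorize_glycemia(out$glycemia, glycemia_edges)
  attr(out, "age_fit") <- list(intercept = reg$intercept, slope = reg$slope)
  attr(out, "rules") <- list(residual_cuts = residual_cuts,
                             income_cuts = income_cuts,
                             glycemia_edges = glycemia_edges)
  out
}
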