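make_fixture <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.table(df, f, sep = if (ext == ".csv") "," else "\t",
                     row.names = FALSE, na = "", quote = FALSE)
  f
}

mini_schema <- function() {
  variable_schema(
    name = c("glycemia", "age", "income", "edu"),
    role = c("response", "explanatory", "explanatory", "explanatory"),
    scale = c("continuous", "continuous", "continuous", "ordinal"),
    levels = list(NULL, NULL, NULL, c("low", "mid", "high")))
}

test_that("read_survey types columns, tolerates blanks, and enforces the schema", {
  df <- data.frame(glycemia = c(90, 110, 85), age = c(30, 50, 64),
                   income = c(12000, NA, 30000),
                   edu = c("low", "high", "mid"))
  tab <- quiet(read_survey(make_fixture(df), mini_schema()))
  expect_equal(nrow(tab), 3)
  expect_type(tab$glycemia, "double")
  expect_s3_class(tab$edu, "ordered")
  expect_true(is.na(tab$income[2]))

  # order-free header, tab-separated
  tab2 <- quiet(read_survey(make_fixture(df[, c(3, 1, 4, 2)], ".tsv"),
                            mini_schema()))
  expect_equal(names(tab2), mini_schema()$name)

  expect_error(quiet(read_survey(make_fixture(df[, -1]), mini_schema())),
               "glycemia")
  empty <- tempfile(fileext = ".csv")
  writeLines("glycemia,age,income,edu", empty)
  expect_error(quiet(read_survey(empty, mini_schema())), "empty")
  # undeclared category label becomes missing
  df$edu[1] <- "unheard_of"
  tab3 <- quiet(read_survey(make_fixture(df), mini_schema()))
  expect_true(is.na(tab3$edu[1]))
})

test_that("filter_complete removes exactly the incomplete rows and is idempotent", {
  df <- data.frame(glycemia = c(1:10), age = c(NA, 2:10),
                   income = c(1:9, NA))
  out <- quiet(filter_complete(df))
  expect_equal(nrow(out), 8)
  expect_equal(attr(out, "n_dropped"), 2)
  expect_equal(quiet(filter_complete(out)), out, ignore_attr = TRUE)
  # no missing values: identity
  full <- data.frame(a = 1:5, b = 6:10)
  expect_equal(quiet(filter_complete(full)), full, ignore_attr = TRUE)
  expect_error(quiet(filter_complete(full, "zzz")), "zzz")
  expect_warning(quiet(filter_complete(data.frame(a = c(NA, NA)))),
                 "no complete records")
})

test_that("retained count matches a brute-force row scan on synthetic missingness", {
  sim <- simulate_survey(simulation_config(n_individuals = 1000,
                                           missing_rate = 0.1, seed = 21))
  out <- quiet(filter_complete(sim$table))
  brute <- sum(vapply(seq_len(1000),
                      function(i) !anyNA(unlist(sim$table[i, ])), TRUE))
  expect_equal(nrow(out), brute)
})

test_that("age regression solves the least-squares problem", {
  # exact linear data
  tab <- data.frame(age = c(20, 35, 50, 65), glycemia = 80 + 0.5 * c(20, 35, 50, 65))
  fit <- age_regression(tab)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 80, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 4), tolerance = 1e-10)

  # hand-solved normal equations
  tab2 <- data.frame(age = c(20, 40, 60), glycemia = c(90, 90, 120))
  fit2 <- age_regression(tab2)
  expect_equal(fit2$slope, 0.75)
  expect_equal(fit2$intercept, 70)
  expect_equal(fit2$residuals, c(5, -10, 5))

  # translation equivariance
  tab3 <- tab2; tab3$glycemia <- tab3$glycemia + 17
  fit3 <- age_regression(tab3)
  expect_equal(fit3$residuals, fit2$residuals)
  expect_equal(fit3$intercept, fit2$intercept + 17)

  expect_error(age_regression(data.frame(age = c(40, 40, 40),
                                         glycemia = c(1, 2, 3))), "constant")
  expect_error(age_regression(data.frame(age = c(1, 2), glycemia = c(1, 2))),
               "at least 3")
})

test_that("residuals are centred and orthogonal to age", {
  sim <- sim_complete(3000, gamma = 0.4, seed = 22)
  fit <- age_regression(sim$table)
  scale_ref <- mean(abs(fit$residuals))
  expect_lt(abs(mean(fit$residuals)) / scale_ref, 1e-8)
  expect_lt(abs(cov(fit$residuals, sim$table$age)) /
              (scale_ref * sd(sim$table$age)), 1e-8)
})

test_that("residual categories follow the 40/80 boundary semantics on |r|", {
  r <- c(-39.99, 39.99, 0, 40, -40, 79.99, 80, -80, 200)
  got <- categorize_residuals(r)
  expect_equal(as.character(got),
               c("Normal", "Normal", "Normal", "Outlier", "Outlier",
                 "Outlier", "Extreme", "Extreme", "Extreme"))
  expect_true(is.ordered(got))
  expect_error(categorize_residuals(r, 80, 40), "cut_outlier")
  # partition: every value gets exactly one category
  set.seed(1); rr <- rnorm(500, sd = 60)
  expect_false(anyNA(categorize_residuals(rr)))
})

test_that("income categories use >= boundaries into the upper class", {
  inc <- c(40000, 39999.99, 20000, 19999, 10000, 9999, 0)
  expect_equal(as.character(categorize_income(inc)),
               c("A", "B", "B", "C", "C", "D", "D"))
  expect_error(categorize_income(-5), "negative")
  expect_error(categorize_income(1, cuts = c(3, 2, 1)), "cuts")
})

test_that("glycemia levels bin half-open with the clinical default edges", {
  g <- c(65, 69.99, 70, 99, 100, 125.9, 126, 159, 160, 199, 200, 250)
  expect_equal(as.character(categorize_glycemia(g)),
               c("1", "1", "2", "2", "3", "3", "4", "4", "5", "5", "6", "6"))
  expect_error(categorize_glycemia(100, bin_edges = c(1, 2, 3, 3, 4)),
               "bin_edges")
})

test_that("coefficient of variation matches direct evaluation and is scale-invariant", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  set.seed(3); v <- rlnorm(40)
  expect_equal(coefficient_of_variation(3.7 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("cv_by_group reports per-cell n and NA for singleton cells", {
  df <- data.frame(glycemia = c(2, 4, 6, 100, 90, 50),
                   inc = c("A", "A", "A", "B", "B", "C"),
                   edu = "x")
  out <- cv_by_group(df, c("inc", "edu"))
  expect_equal(out$cv[out$inc == "A"], 0.5)
  expect_equal(out$n[out$inc == "C"], 1)
  expect_true(is.na(out$cv[out$inc == "C"]))
  expect_equal(sum(out$n), 6)
})

test_that("derive_variables appends categories consistent with their definitions", {
  sim <- sim_complete(800, gamma = 0.4, seed = 23)
  d <- derive_variables(sim$table)
  expect_true(all(c("age_residual", "residual_category", "income_category",
                    "glycemia_level") %in% names(d)))
  fit <- attr(d, "age_fit")
  expect_equal(d$age_residual,
               d$glycemia - fit$intercept - fit$slope * d$age,
               tolerance = 1e-8)
  expect_identical(d$residual_category, categorize_residuals(d$age_residual))
  expect_identical(d$income_category, categorize_income(d$income))
  expect_identical(d$glycemia_level, categorize_glycemia(d$glycemia))
})
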