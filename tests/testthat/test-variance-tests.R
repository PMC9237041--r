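test_that("PERMANOVA partitions squared distances like the brute-force formulas", {
  set.seed(51)
  x <- matrix(rnorm(60), ncol = 2)
  g <- rep(c("a", "b", "c"), each = 10)
  fit <- permanova(x, g, B = 99, seed = 1)
  expect_equal(fit$F, brute_permanova_F(x, g), tolerance = 1e-10)
  expect_equal(fit$SS_between + fit$SS_within, fit$SS_total,
               tolerance = 1e-8 * fit$SS_total)
  expect_equal(fit$df_between, 2)
  expect_equal(fit$df_within, 27)
  # distance-matrix input gives the identical statistic and p-value
  fit_d <- permanova(dist(x), g, B = 99, seed = 1)
  expect_equal(fit_d$F, fit$F, tolerance = 1e-10)
  expect_identical(fit_d$p_value, fit$p_value)
})

test_that("identical point clouds give a null PERMANOVA", {
  set.seed(52)
  cloud <- matrix(rnorm(40), ncol = 2)
  x <- rbind(cloud, cloud)
  g <- rep(c("a", "b"), each = 20)
  fit <- permanova(x, g, B = 199, seed = 3)
  expect_lt(fit$F, 1e-20)
  expect_gt(fit$p_value, 0.9)
})

test_that("the printed 8-point example matches exhaustive enumeration", {
  x <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), ncol = 1)
  g <- rep(c("a", "b"), each = 4)
  combos <- combn(8, 4)
  # permutation p with g[p][idx] == "a": every distinct 4-subset labelled "a"
  perms <- t(apply(combos, 2, function(idx) {
    p <- integer(8); p[idx] <- 1:4; p[setdiff(1:8, idx)] <- 5:8; p
  }))
  # drop the identity assignment; p uses the +1 convention over the rest
  identity_row <- which(apply(perms, 1, function(p)
    identical(g[p], g)))
  fit <- permanova(x, g, permutations = perms[-identity_row[1], , drop = FALSE])
  # exact enumeration oracle
  F_all <- apply(perms, 1, function(p) brute_permanova_F(x, g[p]))
  F_obs <- brute_permanova_F(x, g)
  expect_equal(fit$F, F_obs, tolerance = 1e-10)
  expect_equal(fit$p_value, mean(F_all >= F_obs))
  expect_equal(fit$p_value, 2 / 70)  # observed labelling and its mirror
})

test_that("1-D Euclidean PERMANOVA equals the classical ANOVA F", {
  set.seed(53)
  x <- matrix(rnorm(45, mean = rep(c(0, 1, 3), each = 15)), ncol = 1)
  g <- factor(rep(1:3, each = 15))
  fit <- permanova(x, g, B = 19, seed = 1)
  F_aov <- summary(aov(x[, 1] ~ g))[[1]]$`F value`[1]
  expect_equal(fit$F, F_aov, tolerance = 1e-8)
})

test_that("PERMANOVA agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(54)
  x <- matrix(rnorm(80), ncol = 2)
  g <- rep(c("a", "b"), each = 20)
  fit <- permanova(x, g, B = 99, seed = 1)
  ad <- vegan::adonis2(dist(x) ~ g, permutations = 99)
  expect_equal(fit$F, ad$F[1], tolerance = 1e-8)
  expect_equal(fit$SS_between, ad$SumOfSqs[1], tolerance = 1e-8)
})

test_that("PERMANOVA rejects degenerate groupings", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(permanova(x, c("a", rep("b", 9))), "at least 2")
  expect_error(permanova(x, rep("a", 10)), "at least 2 groups")
  expect_error(permanova(x, rep(c("a", "b"), each = 5), B = 0), "B must be")
})

test_that("pairwise PERMANOVA applies the Bonferroni rule over pairs", {
  set.seed(55)
  base <- matrix(rnorm(120), ncol = 2)
  # three identical groups
  g3 <- rep(c("a", "b", "c"), each = 20)
  same <- base[c(1:20, 1:20, 1:20), ]
  pw_same <- pairwise_permanova(same, g3, B = 99, seed = 2)
  expect_true(all(pw_same$p_adjusted > 0.9))
  expect_equal(pw_same$p_adjusted, pmin(1, 3 * pw_same$p_value))
  # one group displaced far away
  shifted <- base
  shifted[41:60, 1] <- shifted[41:60, 1] + 50
  pw <- pairwise_permanova(shifted, g3, B = 199, seed = 2)
  involved <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adjusted[involved] < 0.05))
  expect_true(all(pw$p_adjusted[!involved] > 0.1))
})

test_that("dispersion test separates spread from location", {
  set.seed(56)
  n <- 200
  cloud <- matrix(rnorm(2 * n), ncol = 2)
  # equal spread, translated location: no dispersion signal
  x_loc <- rbind(cloud, sweep(cloud, 2, c(30, -10), "+"))
  g <- rep(c("a", "b"), each = n)
  d_loc <- dispersion_test(x_loc, g, B = 199, seed = 4)
  expect_gt(d_loc$p_value, 0.5)
  # but PERMANOVA sees the location shift
  expect_lt(permanova(x_loc, g, B = 99, seed = 4)$p_value, 0.05)
  # unequal spread is detected
  x_disp <- rbind(cloud, 3 * cloud)
  d_disp <- dispersion_test(x_disp, g, B = 199, seed = 4)
  expect_lt(d_disp$p_value, 0.01)
  expect_gt(d_disp$group_mean_distance[["b"]],
            d_disp$group_mean_distance[["a"]])
})

test_that("dispersion test agrees with vegan::betadisper and survives tiny groups", {
  skip_if_not_installed("vegan")
  set.seed(57)
  x <- matrix(rnorm(100), ncol = 2)
  g <- rep(c("a", "b"), each = 25)
  ours <- dispersion_test(x, g, B = 99, seed = 1)
  bd <- vegan::betadisper(dist(x), g, type = "centroid")
  expect_equal(sort(unname(ours$group_mean_distance)),
               sort(unname(tapply(bd$distances, g, mean))), tolerance = 1e-8)
  F_vegan <- anova(bd)$`F value`[1]
  expect_equal(ours$F, F_vegan, tolerance = 1e-8)
  # minimal group sizes
  tiny <- dispersion_test(matrix(rnorm(8), ncol = 2), rep(c("a", "b"), 2),
                          B = 19, seed = 1)
  expect_true(is.finite(tiny$F))
})

test_that("G-test matches direct evaluation of the log-likelihood formula", {
  even <- matrix(10, 2, 2)
  g0 <- g_test(even)
  expect_equal(g0$G, 0)
  expect_equal(g0$p_value, 1)

  O <- matrix(c(20, 10, 10, 20), 2, 2)
  g1 <- g_test(O)
  expect_equal(g1$G, 6.796, tolerance = 5e-4)
  expect_equal(g1$df, 1)
  expect_equal(unique(as.vector(g1$expected)), 15)
  # doubling every cell doubles G exactly
  g2 <- g_test(2 * O)
  expect_equal(g2$G, 2 * g1$G, tolerance = 1e-12)
})

test_that("G-test decompositions and margins are exact", {
  set.seed(58)
  O <- matrix(rpois(12, 30), 3, 4)
  O[2, 3] <- 0                      # zero cell contributes 0
  fit <- g_test(O)
  expect_equal(sum(fit$contributions), fit$G, tolerance = 1e-10)
  expect_equal(fit$contributions[2, 3], 0)
  expect_equal(rowSums(fit$expected), rowSums(O))
  expect_equal(colSums(fit$expected), colSums(O))
  nz <- O > 0
  expect_true(all(sign(fit$contributions[nz]) ==
                    sign(O[nz] - fit$expected[nz]) |
                    fit$contributions[nz] == 0))
  expect_equal(fit$pearson_residuals,
               (O - fit$expected) / sqrt(fit$expected))
  expect_error(g_test(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(g_test(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)), "margin")
  expect_error(g_test(matrix(1:3, ncol = 1)), "2 x 2")
})

test_that("G approaches the Pearson chi-square for large expected counts", {
  set.seed(59)
  for (rep in 1:5) {
    O <- matrix(rpois(12, 80) + 20, 3, 4)
    fit <- g_test(O)
    X2 <- suppressWarnings(chisq.test(O, correct = FALSE))$statistic
    expect_true(all(fit$expected >= 20))
    expect_lt(abs(fit$G - X2) / X2, 0.05)
  }
})

test_that("contingency builder tallies the derived table exactly", {
  sim <- sim_complete(2000, gamma = 0.4, seed = 60)
  d <- derive_variables(sim$table)
  tab <- build_contingency(d)
  expect_equal(sum(tab), nrow(d))
  # brute-force tally of one arbitrary cell
  cell <- sum(d$income_category == "B" &
                d$edu_interviewee == "highschool_incomplete" &
                d$residual_category == "Normal")
  expect_equal(tab["B-highschool_incomplete", "Normal"], cell)
  # fully populated 4 x 3 row design gives the df = 22 layout
  if (nrow(tab) == 12) expect_equal(g_test(tab)$df, 22)
})

test_that("empty contingency combinations are dropped with a message", {
  d <- data.frame(
    income_category = factor(rep(c("A", "B"), each = 20), levels = c("D", "C", "B", "A")),
    edu_interviewee = factor(rep(c("x", "y"), 20)),
    residual_category = factor(rep(c("Normal", "Outlier"), 10),
                               levels = c("Normal", "Outlier", "Extreme")))
  expect_message(tab <- build_contingency(d), "dropping empty")
  expect_equal(dim(tab), c(4, 2))
  expect_error(build_contingency(d[1, ]), "fewer than 2")
  expect_error(build_contingency(data.frame(a = 1)), "missing")
})

test_that("permutation p-values never reach zero", {
  set.seed(61)
  x <- matrix(c(rnorm(20), rnorm(20, 50)), ncol = 1)
  g <- rep(c("a", "b"), each = 20)
  fit <- permanova(x, g, B = 99, seed = 1)
  expect_gte(fit$p_value, 1 / 100)
  disp <- dispersion_test(cbind(c(rnorm(20), 10 * rnorm(20))), g,
                          B = 99, seed = 1)
  expect_gte(disp$p_value, 1 / 100)
})
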