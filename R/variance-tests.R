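## Group-level inference: PERMANOVA, multivariate dispersion, G-test.

## internal: validate grouping, return factor
check_groups <- function(groups, n, min_size = 2L) {
  g <- factor(groups)
  if (length(g) != n) stop("groups length must match observations", call. = FALSE)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < min_size))
    stop(sprintf("every group needs at least %d observations", min_size),
         call. = FALSE)
  g
}

## internal: is x a distance representation?
is_dist_input <- function(x) {
  inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
       all(abs(diag(x)) < 1e-12))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared Euclidean interpoint distances into
#' between- and within-group components:
#' `SS_total = (1/n) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `SS_between = SS_total - SS_within`, and
#' `pseudo-F = (SS_between/(g-1)) / (SS_within/(n-g))`.
#' Significance comes from unrestricted permutation of the group labels with
#' the strictly valid `(1 + exceedances) / (B + 1)` estimator, so permutation
#' p-values can never be 0. In one Euclidean dimension the pseudo-F equals
#' the classical one-way ANOVA F.
#'
#' @param x an n x p coordinate matrix (Euclidean distance implied), or a
#'   `dist` object / symmetric zero-diagonal distance matrix.
#' @param groups group labels, length n; at least 2 groups of size >= 2.
#' @param B number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @param permutations optional matrix of explicit permutations (one
#'   permutation of `1..n` per row, e.g. an exhaustive enumeration);
#'   overrides `B`/`seed`.
#' @return object of class `permanova` with fields `F`, `df_between`,
#'   `df_within`, `SS_between`, `SS_within`, `SS_total`, `B`, `p_value`,
#'   `seed`.
#' @export
permanova <- function(x, groups, B = 999L, seed = 1L, permutations = NULL) {
  dist_mode <- is_dist_input(x)
  if (dist_mode) {
    D2 <- as.matrix(x)^2
    n <- nrow(D2)
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    n <- nrow(x)
    x <- sweep(x, 2, colMeans(x))             # centre once; SS_total fixed
  }
  g <- check_groups(groups, n)
  ng <- nlevels(g)
  if (is.null(permutations) && B < 1) stop("B must be >= 1", call. = FALSE)

  if (dist_mode) {
    SS_total <- sum(D2) / (2 * n)
    ss_within <- function(gp) {
      idx <- split(seq_len(n), gp)
      sum(vapply(idx, function(i) sum(D2[i, i]) / (2 * length(i)), 0))
    }
    stat <- function(gp) {
      SSW <- ss_within(gp)
      SSB <- SS_total - SSW
      (SSB / (ng - 1)) / (SSW / (n - ng))
    }
  } else {
    SS_total <- sum(x^2)
    stat <- function(gp) {
      S <- rowsum(x, gp)                      # group column sums
      SSB <- sum(rowSums(S^2) / tabulate(gp))
      SSW <- SS_total - SSB
      (SSB / (ng - 1)) / (SSW / (n - ng))
    }
  }

  F_obs <- stat(g)
  if (is.null(permutations)) {
    set.seed(as.integer(seed))
    F_perm <- vapply(seq_len(B), function(b) stat(g[sample.int(n)]), 0)
    nperm <- B
  } else {
    stopifnot(ncol(permutations) == n)
    F_perm <- vapply(seq_len(nrow(permutations)),
                     function(b) stat(g[permutations[b, ]]), 0)
    nperm <- nrow(permutations)
  }
  p <- (1 + sum(F_perm >= F_obs)) / (nperm + 1)

  if (dist_mode) {
    SSW <- ss_within(g); SSB <- SS_total - SSW
  } else {
    S <- rowsum(x, g)
    SSB <- sum(rowSums(S^2) / tabulate(g)); SSW <- SS_total - SSB
  }
  structure(list(F = F_obs, df_between = ng - 1L, df_within = n - ng,
                 SS_between = SSB, SS_within = SSW, SS_total = SS_total,
                 B = nperm, p_value = p, seed = as.integer(seed),
                 n = n, n_groups = ng),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (B = %d)\n",
              x$df_between, x$df_within, x$F, x$p_value, x$B))
  cat(sprintf("  SS between = %.4g, within = %.4g, total = %.4g\n",
              x$SS_between, x$SS_within, x$SS_total))
  invisible(x)
}

#' Bonferroni-adjusted pairwise PERMANOVA comparisons
#'
#' Runs [permanova()] on every pair of groups and applies the Bonferroni
#' correction `p_adj = min(1, m * p)` over the `m` pairs.
#'
#' @inheritParams permanova
#' @return data.frame of class `pairwise_permanova`: one row per pair with
#'   `group1`, `group2`, `F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(x, groups, B = 999L, seed = 1L) {
  g <- factor(groups)
  lev <- levels(g)
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  dist_mode <- is_dist_input(x)
  M <- if (dist_mode) as.matrix(x) else as.matrix(x)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  seeds <- split_seed(seed, m)
  rows <- lapply(seq_len(m), function(i) {
    sel <- g %in% pairs[, i]
    sub <- if (dist_mode) M[sel, sel] else M[sel, , drop = FALSE]
    fit <- permanova(sub, droplevels(g[sel]), B = B, seed = seeds[i])
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               F = fit$F, p_value = fit$p_value,
               p_adjusted = min(1, m * fit$p_value))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}

#' Multivariate homogeneity of dispersion test
#'
#' The equal-spread companion check for PERMANOVA: each observation's
#' Euclidean distance to its group centroid is computed, a one-way ANOVA F
#' statistic is formed on those distances, and significance is assessed by
#' permuting the group labels of the distances and recomputing F
#' (`(1 + exceedances)/(B + 1)` estimator).
#'
#' @param x n x p coordinate matrix, or a distance representation (then
#'   embedded by classical multidimensional scaling first).
#' @inheritParams permanova
#' @return object of class `dispersion_test` with `F`, `df_between`,
#'   `df_within`, `p_value`, `B`, `seed` and `group_mean_distance`.
#' @export
dispersion_test <- function(x, groups, B = 999L, seed = 1L) {
  if (is_dist_input(x)) {
    n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(as.matrix(x))
    x <- stats::cmdscale(x, k = min(n - 1, 10))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  g <- check_groups(groups, n)
  ng <- nlevels(g)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  cent <- rowsum(x, g) / as.vector(table(g))
  z <- sqrt(rowSums((x - cent[as.integer(g), , drop = FALSE])^2))

  f_on <- function(zz, gp) {
    gm <- tapply(zz, gp, mean)
    nn <- tabulate(gp)
    SSB <- sum(nn * (gm - mean(zz))^2)
    SSW <- sum((zz - gm[as.integer(gp)])^2)
    if (SSW == 0) return(if (SSB == 0) 0 else Inf)
    (SSB / (ng - 1)) / (SSW / (n - ng))
  }
  F_obs <- f_on(z, g)
  set.seed(as.integer(seed))
  F_perm <- vapply(seq_len(B), function(b) f_on(z[sample.int(n)], g), 0)
  p <- (1 + sum(F_perm >= F_obs)) / (B + 1)
  structure(list(F = F_obs, df_between = ng - 1L, df_within = n - ng,
                 p_value = p, B = as.integer(B), seed = as.integer(seed),
                 group_mean_distance = tapply(z, g, mean), distances = z),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Multivariate dispersion: F(%d, %d) = %.4g, p = %.4g (B = %d)\n",
              x$df_between, x$df_within, x$F, x$p_value, x$B))
  cat("  mean distance to centroid per group:\n")
  print(round(x$group_mean_distance, 4))
  invisible(x)
}

#' G-test (log-likelihood ratio test) of independence
#'
#' For a contingency table `O` with expected counts
#' `E_ij = row_i * col_j / n`:
#' `G = 2 * sum_{O_ij > 0} O_ij * ln(O_ij / E_ij)` with
#' `df = (r - 1)(c - 1)` and a chi-square upper-tail p-value. Zero observed
#' cells contribute 0 (the `x ln x -> 0` limit). No continuity or Williams
#' correction is applied. Per-cell contributions `2 O ln(O/E)` are reported;
#' their sign agrees with `sign(O - E)` and they sum exactly to G. Pearson
#' residuals `(O - E)/sqrt(E)` are included as an alternative decomposition.
#'
#' @param observed matrix of non-negative integer counts, at least 2 x 2,
#'   with no all-zero row or column.
#' @return object of class `g_test` with `G`, `df`, `p_value`, `observed`,
#'   `expected`, `contributions`, `pearson_residuals`, `n`.
#' @export
g_test <- function(observed) {
  O <- as.matrix(observed)
  if (any(O < 0) || any(O != round(O)))
    stop("observed counts must be non-negative integers", call. = FALSE)
  if (nrow(O) < 2 || ncol(O) < 2)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("all-zero row or column margin", call. = FALSE)
  n <- sum(O)
  E <- outer(rs, cs) / n
  contrib <- matrix(0, nrow(O), ncol(O), dimnames = dimnames(O))
  pos <- O > 0
  contrib[pos] <- 2 * O[pos] * log(O[pos] / E[pos])
  G <- sum(contrib)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(G = G, df = df, p_value = pchisq(G, df, lower.tail = FALSE),
                 observed = O, expected = E, contributions = contrib,
                 pearson_residuals = (O - E) / sqrt(E), n = n),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test of independence: G(df = %d) = %.4g, p = %.4g (n = %d)\n",
              x$df, x$G, x$p_value, x$n))
  invisible(x)
}

#' Build the income x education vs residual-category contingency table
#'
#' Rows are combinations of the row grouping variables (by default income
#' category crossed with the interviewee's educational attainment), columns
#' the age-residual categories. Empty combinations are dropped with a
#' message, since sparse extreme cells (e.g. highest income with lowest
#' education) occur in real surveys.
#'
#' @param derived a derived survey table (see [derive_variables()]).
#' @param row_vars character vector of row grouping columns.
#' @param col_var column variable (default `"residual_category"`).
#' @return integer matrix of counts with informative dimnames and attributes
#'   `row_vars`, `col_var`.
#' @export
build_contingency <- function(derived,
                              row_vars = c("income_category", "edu_interviewee"),
                              col_var = "residual_category") {
  miss <- setdiff(c(row_vars, col_var), names(derived))
  if (length(miss))
    stop("derived columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- interaction(derived[, row_vars, drop = FALSE], sep = "-",
                      lex.order = TRUE)
  tab <- table(rows, derived[[col_var]])
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r))
    message("build_contingency: dropping empty row group(s): ",
            paste(rownames(tab)[empty_r], collapse = ", "))
  if (any(empty_c))
    message("build_contingency: dropping empty column(s): ",
            paste(colnames(tab)[empty_c], collapse = ", "))
  tab <- tab[!empty_r, !empty_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("fewer than 2 non-empty rows or columns", call. = FALSE)
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- c(paste(row_vars, collapse = "-"), col_var)
  attr(out, "row_vars") <- row_vars
  attr(out, "col_var") <- col_var
  out
}
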