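#' Optimal-scaling principal component analysis for ordinal survey data
#'
#' PRINCALS-style categorical PCA by alternating least squares, with
#' single-rank quantifications: each variable's categories receive numeric
#' quantifications (monotone non-decreasing for ordinal variables,
#' unrestricted for nominal, fixed linear for numeric), chosen together with
#' object scores and loadings to minimize the Gifi loss
#' `sum_j ||X - q_j a_j'||^2 / (n p)` subject to `X' X = n I`.
#'
#' The iteration is: (a) given the object scores `X`, update each variable's
#' category quantifications by category-mean projection of `X a_j` followed
#' by weighted isotonic regression (pooled adjacent violators; both monotone
#' directions are fit and the better one kept, the direction sign being
#' absorbed by the loading), then re-estimate the loading `a_j = X' q_j / n`;
#' (b) update `X` as the orthogonal Procrustes solution for
#' `sum_j q_j a_j'`. The loss is non-increasing. Object scores are initialized
#' from classical PCA of the integer-coded, standardized data, so the fit is
#' deterministic. Component signs are fixed by forcing each loading column's
#' largest-magnitude entry positive.
#'
#' Variance accounted for is reported as the eigenvalue shares of the
#' correlation matrix of the quantified variables.
#'
#' @param data data.frame of explanatory variables: factors (ordered or not)
#'   and numerics; no missing values.
#' @param n_components number of components (default `min(8, ncol(data))`).
#' @param scaling named character vector giving each variable's scaling level
#'   (`"ordinal"`, `"nominal"` or `"numeric"`); by default unordered factors
#'   with more than 2 levels are `"nominal"` and everything else `"ordinal"`.
#'   Binary variables are direction-invariant, so nominal and ordinal
#'   treatment coincide for them up to sign.
#' @param max_iter maximum ALS iterations (default 200).
#' @param tol convergence tolerance on the relative loss change
#'   (default 1e-6).
#' @return object of class `ordinal_pca`:
#'   \describe{
#'     \item{scores}{n x n_components object scores, columns centred with
#'       `crossprod(scores) = n I`.}
#'     \item{loadings}{variables x components loading matrix (component
#'       correlations of the quantified variables).}
#'     \item{quantifications}{per variable, a data.frame of category label,
#'       count and quantification (monotone non-decreasing for ordinal
#'       variables).}
#'     \item{vaf}{eigenvalue shares of the quantified correlation matrix
#'       (length = number of variables).}
#'     \item{loss}{loss value per iteration (non-increasing).}
#'     \item{converged, iterations, n_components, scaling}{fit metadata.}
#'   }
#' @export
fit_ordinal_pca <- function(data, n_components = min(8L, ncol(data)),
                            scaling = NULL, max_iter = 200L, tol = 1e-6) {
  stopifnot(is.data.frame(data), ncol(data) >= 1)
  if (anyNA(data))
    stop("missing values present; run filter_complete() first", call. = FALSE)
  p <- ncol(data); n <- nrow(data)
  vars <- names(data)
  if (!is.numeric(n_components) || n_components < 1 || n_components > p)
    config_error("n_components", "must be in 1..ncol(data)")
  ndim <- as.integer(n_components)
  if (tol <= 0) config_error("tolerance", "must be > 0")

  if (is.null(scaling)) {
    scaling <- vapply(data, function(x) {
      if (is.factor(x) && !is.ordered(x) && nlevels(droplevels(x)) > 2)
        "nominal" else "ordinal"
    }, "")
    names(scaling) <- vars
  } else {
    scaling <- scaling[vars]
    if (anyNA(scaling) || !all(scaling %in% c("ordinal", "nominal", "numeric")))
      config_error("scaling",
                   "must name every variable with ordinal/nominal/numeric")
  }

  ## integer category codes, counts, and fixed quantifications where numeric
  codes <- vector("list", p); counts <- vector("list", p)
  labels <- vector("list", p); yq <- vector("list", p)
  for (j in seq_len(p)) {
    x <- data[[j]]
    if (is.factor(x)) {
      x <- droplevels(x)
      f <- as.integer(x)
      labels[[j]] <- levels(x)
    } else {
      ux <- sort(unique(x))
      f <- match(x, ux)
      labels[[j]] <- format(ux, trim = TRUE)
    }
    cnt <- tabulate(f)
    if (length(cnt) < 2)
      stop(sprintf("variable '%s' is constant (single observed category)",
                   vars[j]), call. = FALSE)
    codes[[j]] <- f; counts[[j]] <- cnt
    ## initial / fixed quantifications: standardized category values
    v <- if (scaling[j] == "numeric") {
      if (!is.numeric(data[[j]]))
        config_error("scaling", sprintf("'%s' declared numeric but is a factor",
                                        vars[j]))
      sort(unique(data[[j]]))
    } else seq_along(cnt)
    v <- v - sum(cnt * v) / n
    v <- v / sqrt(sum(cnt * v^2) / n)
    yq[[j]] <- v
  }

  Q <- vapply(seq_len(p), function(j) yq[[j]][codes[[j]]], numeric(n))
  sv0 <- svd(Q, nu = ndim, nv = 0)
  X <- sqrt(n) * sv0$u
  A <- crossprod(Q, X) / n                      # p x ndim

  gifi_loss <- function(A, Q) {
    # ||X - q a'||^2 = n*ndim - 2 a'X'q + n||a||^2 ; X'q = n a at update time,
    # but compute generally
    tot <- 0
    XtQ <- crossprod(X, Q)                      # ndim x p
    for (j in seq_len(p))
      tot <- tot + n * ndim - 2 * sum(A[j, ] * XtQ[, j]) + n * sum(A[j, ]^2)
    tot / (n * p)
  }

  loss <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## (a) quantification + loading updates
    for (j in seq_len(p)) {
      f <- codes[[j]]; w <- counts[[j]]
      if (scaling[j] != "numeric") {
        t_j <- as.vector(rowsum(X %*% A[j, ], f)) / w
        if (scaling[j] == "ordinal") {
          y_up <- cpp_pava(t_j, w)
          y_dn <- cpp_pava(-t_j, w)
          y <- if (sum(w * (t_j - y_up)^2) <= sum(w * (-t_j - y_dn)^2))
            y_up else y_dn
        } else y <- t_j
        y <- y - sum(w * y) / n
        s2 <- sum(w * y^2) / n
        if (s2 > 1e-24) {
          yq[[j]] <- y / sqrt(s2)
          Q[, j] <- yq[[j]][f]
        }
      }
      A[j, ] <- crossprod(X, Q[, j]) / n
    }
    ## (b) object score update (Procrustes under X'X = nI)
    Z <- Q %*% A
    sz <- svd(Z)
    X <- sqrt(n) * sz$u %*% t(sz$v)
    A <- crossprod(Q, X) / n
    loss[it] <- gifi_loss(A, Q)
    if (it > 1 && abs(loss[it - 1] - loss[it]) <
        tol * max(loss[it - 1], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("optimal-scaling ALS did not converge in %d iterations",
                    max_iter), call. = FALSE)

  ## sign convention: largest |loading| entry of each component positive
  for (k in seq_len(ndim)) {
    m <- which.max(abs(A[, k]))
    if (A[m, k] < 0) { A[, k] <- -A[, k]; X[, k] <- -X[, k] }
  }

  R <- crossprod(Q) / n
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  vaf <- ev / p

  quant <- lapply(seq_len(p), function(j)
    data.frame(category = labels[[j]], count = counts[[j]],
               quantification = yq[[j]]))
  names(quant) <- vars
  dimnames(A) <- list(vars, paste0("PC", seq_len(ndim)))
  colnames(X) <- paste0("PC", seq_len(ndim))

  structure(list(scores = X, loadings = A, quantifications = quant,
                 vaf = vaf, loss = loss, converged = converged,
                 iterations = length(loss), n_components = ndim,
                 scaling = scaling, n = n),
            class = "ordinal_pca")
}

#' Extract object scores for a component subspace
#'
#' @param result an `ordinal_pca` fit.
#' @param components integer indices within `1..n_components`, no duplicates.
#' @return n x length(components) score matrix.
#' @export
scores_subspace <- function(result, components = c(1L, 2L)) {
  stopifnot(inherits(result, "ordinal_pca"))
  if (anyDuplicated(components))
    stop("duplicate component indices", call. = FALSE)
  if (any(components < 1 | components > result$n_components))
    stop("component index out of range 1..", result$n_components, call. = FALSE)
  result$scores[, components, drop = FALSE]
}

#' Variance accounted for by the fitted components
#'
#' @param result an `ordinal_pca` fit.
#' @return list with `per_component` (fractions for the retained components),
#'   `cumulative` (non-decreasing), and `all` (eigen shares of the full
#'   quantified correlation matrix, summing to 1).
#' @export
variance_accounted <- function(result) {
  stopifnot(inherits(result, "ordinal_pca"))
  per <- result$vaf[seq_len(result$n_components)]
  list(per_component = per, cumulative = cumsum(per), all = result$vaf)
}

#' @export
print.ordinal_pca <- function(x, ...) {
  va <- variance_accounted(x)
  cat(sprintf("Optimal-scaling PCA: %d observations, %d variables, %d components\n",
              x$n, nrow(x$loadings), x$n_components))
  cat(sprintf("  converged: %s after %d iterations (final loss %.6g)\n",
              x$converged, x$iterations, tail(x$loss, 1)))
  cat(sprintf("  variance accounted for (cumulative, %d components): %.1f%%\n",
              x$n_components, 100 * tail(va$cumulative, 1)))
  cat("  per component:", paste(sprintf("%.1f%%", 100 * va$per_component),
                                collapse = " "), "\n")
  invisible(x)
}

#' Serialize an ordinal PCA result as structured text
#'
#' Writes `scores.csv`, `loadings.csv`, `quantifications.csv` and a key-value
#' `metadata.txt` into a directory.
#'
#' @param result an `ordinal_pca` fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ordinal_pca <- function(result, dir) {
  stopifnot(inherits(result, "ordinal_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(data.frame(variable = rownames(result$loadings), result$loadings),
            file.path(dir, "loadings.csv"), row.names = FALSE)
  qt <- do.call(rbind, lapply(names(result$quantifications), function(v)
    cbind(variable = v, result$quantifications[[v]])))
  write.csv(qt, file.path(dir, "quantifications.csv"), row.names = FALSE)
  va <- variance_accounted(result)
  meta <- c(sprintf("n: %d", result$n),
            sprintf("n_components: %d", result$n_components),
            sprintf("converged: %s", result$converged),
            sprintf("iterations: %d", result$iterations),
            sprintf("vaf_cumulative: %.6f", tail(va$cumulative, 1)),
            sprintf("vaf_per_component: %s",
                    paste(sprintf("%.6f", va$per_component), collapse = " ")))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
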