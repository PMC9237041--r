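## Independent brute-force oracles, deliberately written with different
## primitives than the package implementation.

# running SD by explicit full distance matrix and sort (ties by row index)
brute_running_sd <- function(scores, values, k, include_self = TRUE) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  D <- as.matrix(dist(scores))
  out_sd <- numeric(n)
  out_mean <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    if (!include_self) d[i] <- Inf
    ord <- order(d, seq_len(n))
    nb <- ord[seq_len(k)]
    out_mean[i] <- mean(values[nb])
    out_sd[i] <- sd(values[nb])
  }
  list(mean = out_mean, sd = out_sd)
}

# PERMANOVA pseudo-F from the squared-distance partition formulas, computed
# pair-by-pair
brute_permanova_F <- function(x, groups) {
  x <- as.matrix(x)
  n <- nrow(x)
  g <- factor(groups)
  D2 <- as.matrix(dist(x))^2
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D2[i, j]
  sst <- sst / n
  ssw <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + D2[idx[a], idx[b]]
    }
    ssw <- ssw + acc / length(idx)
  }
  ssb <- sst - ssw
  (ssb / (nlevels(g) - 1)) / (ssw / (n - nlevels(g)))
}

# weighted isotonic regression by enumeration-free R reference (PAVA with
# repeat-until-stable pooling, distinct from the stack version in C++)
ref_pava <- function(y, w) {
  blocks <- lapply(seq_along(y), function(i) list(v = y[i], w = w[i], n = 1L))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(blocks)) {
      if (blocks[[i]]$v > blocks[[i + 1]]$v) {
        tw <- blocks[[i]]$w + blocks[[i + 1]]$w
        blocks[[i]] <- list(
          v = (blocks[[i]]$w * blocks[[i]]$v +
                 blocks[[i + 1]]$w * blocks[[i + 1]]$v) / tw,
          w = tw, n = blocks[[i]]$n + blocks[[i + 1]]$n)
        blocks[[i + 1]] <- NULL
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  unlist(lapply(blocks, function(b) rep(b$v, b$n)))
}

# classical PCA by eigendecomposition of the correlation matrix, with the
# same sign convention as the package (largest-|loading| entry positive)
classical_pca <- function(data, ndim) {
  R <- cor(data)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, seq_len(ndim), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(ndim)]), ndim)
  for (k in seq_len(ndim)) {
    m <- which.max(abs(L[, k]))
    if (L[m, k] < 0) L[, k] <- -L[, k]
  }
  list(loadings = L, shares = e$values / ncol(data))
}

quiet <- function(expr) suppressMessages(expr)

sim_complete <- function(n, gamma, seed, ...) {
  simulate_survey(simulation_config(n_individuals = n, gamma = gamma,
                                    missing_rate = 0, seed = seed, ...))
}
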