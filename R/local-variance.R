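#' Running standard deviation of a trait over a component subspace
#'
#' The local decanalization estimator: for every observation, the sample
#' standard deviation (n-1 denominator) of the trait over its k-nearest
#' neighbourhood in a low-dimensional score space -- the two-dimensional
#' analogue of a running average, applied to dispersion instead of level.
#' Neighbourhoods are k-nearest under Euclidean distance, with distance ties
#' broken by ascending row index. k-NN neighbourhoods (rather than a fixed
#' radius) keep the per-neighbourhood sample size, and therefore the SD
#' precision, constant between dense and sparse regions of the score space.
#'
#' With `center_correct = TRUE` a two-pass variant is used: a first pass
#' computes the running mean, and the SD is then computed on the values minus
#' their own running mean (correcting local dispersion for the local level);
#' both passes are reported. Reported analyses are typically insensitive to
#' this correction, so it is off by default.
#'
#' @param scores n x m numeric matrix of subspace coordinates (typically 2
#'   object-score columns from [scores_subspace()]).
#' @param values trait values (e.g. fasting glycemia, mg/dL, or age-adjusted
#'   residuals), length n, no missing values.
#' @param k neighbourhood size; default `max(50, ceiling(0.05 * n))`. Must
#'   satisfy `k >= 2` when `include_self`, `k >= 1` otherwise, and `k <= n`
#'   (resp. `n - 1`).
#' @param include_self whether the observation belongs to its own
#'   neighbourhood (default `TRUE`).
#' @param center_correct two-pass running-mean correction (default `FALSE`).
#' @return object of class `running_sd`: `sd` (per-observation running SD,
#'   mg/dL; the centred version when `center_correct`), `mean` (running
#'   mean), `sd_raw` (uncentred SD, always present), `k`, `include_self`,
#'   `center_correct`, `values`, `neighbours` (the n x k index matrix) and
#'   `subspace_dim`.
#' @export
running_sd <- function(scores, values, k = NULL, include_self = TRUE,
                       center_correct = FALSE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores)
  if (length(values) != n)
    stop("scores and values must have matching length", call. = FALSE)
  if (anyNA(scores) || anyNA(values))
    stop("missing values are not allowed", call. = FALSE)
  if (is.null(k)) k <- max(50L, ceiling(0.05 * n))
  k <- as.integer(k)
  kmin <- if (include_self) 2L else 1L
  if (k < kmin) config_error("k", sprintf("must be >= %d", kmin))
  avail <- if (include_self) n else n - 1L
  if (k > avail)
    stop(sprintf("k = %d exceeds the %d available neighbours", k, avail),
         call. = FALSE)
  if (all(apply(scores, 2, var) == 0))
    warning("zero-variance subspace: all neighbourhoods are identical",
            call. = FALSE)
  nidx <- cpp_knn(scores, k, include_self)
  st <- cpp_running_stats(nidx, as.numeric(values))
  sd_raw <- st$sd
  sd_used <- sd_raw
  if (center_correct) {
    centred <- as.numeric(values) - st$mean
    sd_used <- cpp_running_stats(nidx, centred)$sd
  }
  structure(list(sd = sd_used, mean = st$mean, sd_raw = sd_raw,
                 k = k, include_self = include_self,
                 center_correct = center_correct,
                 values = as.numeric(values), neighbours = nidx,
                 subspace_dim = ncol(scores)),
            class = "running_sd")
}

#' @export
print.running_sd <- function(x, ...) {
  cat(sprintf("Running SD over a %d-D subspace: n = %d, k = %d%s%s\n",
              x$subspace_dim, length(x$sd), x$k,
              if (x$include_self) " (self included)" else "",
              if (x$center_correct) ", centre-corrected" else ""))
  cat(sprintf("  running SD range: %.2f-%.2f (median %.2f)\n",
              min(x$sd), max(x$sd), stats::median(x$sd)))
  invisible(x)
}

#' Permutation test for a variance gradient
#'
#' Spearman correlation between the running SD and a per-observation
#' covariate (e.g. the first principal component, or a known true SD), with a
#' permutation p-value. Because running SDs of overlapping neighbourhoods are
#' strongly autocorrelated, naive independence-based inference is invalid;
#' the null instead re-assigns the trait values to positions (permuting the
#' values over the fixed neighbourhood structure), recomputes the running SD
#' and the correlation for each of `B` permutations, and uses the
#' `(1 + exceedances) / (B + 1)` two-sided estimator.
#'
#' @param result a [running_sd()] object (carries the values and the
#'   neighbourhood structure).
#' @param axis per-observation covariate, same length.
#' @param B number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @return list with `rho` (observed Spearman correlation), `p_value`, `B`,
#'   `seed` and `rho_null` (the permuted correlations).
#' @export
variance_gradient_test <- function(result, axis, B = 999L, seed = 1L) {
  stopifnot(inherits(result, "running_sd"))
  n <- length(result$sd)
  if (length(axis) != n)
    stop("axis length must match the running SD", call. = FALSE)
  if (var(axis) == 0)
    stop("constant axis: correlation undefined", call. = FALSE)
  if (B < 1) config_error("B", "must be >= 1")
  rho <- cor(result$sd, axis, method = "spearman")
  set.seed(as.integer(seed))
  P <- replicate(B, result$values[sample.int(n)])
  sd_null <- cpp_running_sd_batch(result$neighbours, P)
  ra <- rank(axis)
  rho_null <- as.vector(cor(apply(sd_null, 2, rank), ra)) # Spearman via ranks
  p <- (1 + sum(abs(rho_null) >= abs(rho))) / (B + 1)
  list(rho = rho, p_value = p, B = as.integer(B), seed = as.integer(seed),
       rho_null = rho_null)
}

#' Smooth a running-SD surface onto a regular grid
#'
#' Local-regression (loess) smooth of per-observation values over a
#' two-dimensional score space, evaluated on a rectangular grid covering the
#' score range. Display/reporting helper only; no inference is attached.
#'
#' @param scores n x 2 coordinate matrix.
#' @param values per-observation values (e.g. running SD).
#' @param resolution grid points per axis (default 40).
#' @param span loess span (default 0.75).
#' @param degree loess degree (default 1).
#' @return list with `x`, `y` (grid axes) and `z` (resolution x resolution
#'   matrix of smoothed values); for degenerate (collinear) scores a 1-D
#'   smooth along the first coordinate is returned with a warning (`z` then
#'   has one column).
#' @export
smooth_surface <- function(scores, values, resolution = 40L, span = 0.75,
                           degree = 1L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) == length(values))
  s1 <- scores[, 1]; s2 <- scores[, 2]
  collinear <- var(s2) == 0 ||
    (var(s1) > 0 && abs(cor(s1, s2)) > 1 - 1e-12)
  gx <- seq(min(s1), max(s1), length.out = resolution)
  if (collinear) {
    warning("degenerate (collinear) scores: returning a 1-D smooth",
            call. = FALSE)
    fit <- loess(values ~ s1, span = span, degree = degree,
                 family = "gaussian")
    z <- matrix(predict(fit, data.frame(s1 = gx)), ncol = 1)
    return(list(x = gx, y = mean(s2), z = z))
  }
  gy <- seq(min(s2), max(s2), length.out = resolution)
  fit <- loess(values ~ s1 + s2, span = span, degree = degree,
               family = "gaussian", normalize = FALSE,
               control = stats::loess.control(surface = "direct"))
  grid <- expand.grid(s1 = gx, s2 = gy)
  z <- matrix(predict(fit, grid), nrow = resolution, ncol = resolution)
  list(x = gx, y = gy, z = z)
}
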