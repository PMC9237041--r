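#' @useDynLib decanalize, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm loess pchisq pnorm predict qnorm quantile
#'   rlnorm rnorm runif sd var
#' @importFrom utils write.csv head tail
NULL

#' Split a master seed into reproducible sub-seeds
#'
#' One master seed drives every stochastic stage of the package. Sub-draws
#' (latent axis, ages, covariate noise, glycemia noise, missingness,
#' permutation tests, ...) each get their own seed so a stage can be re-run in
#' isolation and still reproduce exactly. The scheme is: seed the generator
#' with the master seed, then draw `n` integers uniformly from
#' `1 .. .Machine$integer.max`.
#'
#' @param seed master seed, a single integer.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

## internal: stop with a message naming the offending field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  if (x < lower || x > upper)
    config_error(field, sprintf("must be in [%s, %s]", lower, upper))
  invisible(x)
}

## internal: delimiter from file extension (csv -> comma, tsv/txt -> tab)
delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
}
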