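#' @importFrom stats cor dnorm pnorm qnorm rnorm runif quantile sd var
#'   complete.cases dpois rpois prcomp lm coef resid setNames uniroot
#'   optim optimHess qgamma median mahalanobis
#' @importFrom methods as is
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_num <- function(x, name) {
  if (!is.numeric(x)) stop_("`%s` must be numeric", name)
  invisible(x)
}

#' Quantiles of a finite mixture of normal distributions
#'
#' Exact quantiles of sum_g w_g N(mean_g, sd_g^2) by root-finding on the
#' mixture CDF. Used to summarize fixed-effect marginals mixed over the
#' hyperparameter grid.
#'
#' @param p probabilities
#' @param w mixture weights (normalized internally)
#' @param mean,sd component means and standard deviations
#' @return numeric vector of quantiles, one per element of `p`
#' @keywords internal
mixnorm_quantile <- function(p, w, mean, sd) {
  w <- w / sum(w)
  cdf <- function(x) sum(w * pnorm(x, mean, sd))
  lo <- min(mean - 10 * sd)
  hi <- max(mean + 10 * sd)
  vapply(p, function(pp) {
    uniroot(function(x) cdf(x) - pp, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

mixnorm_moments <- function(w, mean, sd) {
  w <- w / sum(w)
  m <- sum(w * mean)
  v <- sum(w * (sd^2 + mean^2)) - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(p, function(pp) x[which(cw >= pp)[1]], numeric(1))
}

## deterministic per-run RNG scoping: functions taking `seed` restore the
## caller's RNG state on exit
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
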