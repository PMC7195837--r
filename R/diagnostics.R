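#' Deviance information criterion
#'
#' DIC = Dhat + 2 pD with pD = Dbar - Dhat: Dbar is the posterior mean of
#' the deviance -2 sum log Poisson(y_i | lambda_i) over joint posterior
#' draws, and Dhat the deviance at the plug-in, here the posterior mean of
#' the latent linear predictor eta (the classical hierarchical-model
#' convention, which keeps pD non-negative in practice; a plug-in at the
#' mean of lambda is a different, non-reported choice). Negative pD is
#' flagged, not hidden.
#'
#' @param fit an `spdepois_fit`
#' @param n_draws deviance draws (Laplace route; MCMC uses stored draws)
#' @param seed integer seed for the deviance draws
#' @return object of class `dic_result`: `dbar`, `dhat`, `pd`, `dic`,
#'   `pd_negative`
#' @export
dic <- function(fit, n_draws = 1000, seed = 20100429) {
  eng <- fit$engine
  dr <- posterior_draws(fit, n_draws, seed = seed)
  eta <- as.matrix(eng$B %*% dr)
  dev <- -2 * colSums(dpois(eng$y, exp(pmin(eta, 30)), log = TRUE))
  dbar <- mean(dev)
  eta_bar <- rowMeans(eta)
  dhat <- -2 * sum(dpois(eng$y, exp(eta_bar), log = TRUE))
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dhat + 2 * pd,
                 pd_negative = pd < 0, n_draws = ncol(dr)),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.1f (Dhat %.1f, pD %.1f%s)\n", x$dic, x$dhat, x$pd,
              if (x$pd_negative) "; WARNING pD < 0" else ""))
  invisible(x)
}

#' DIC difference between two fits
#'
#' @param fit_a,fit_b fits to compare (positive result favours `fit_b`)
#' @param ... forwarded to [dic()]
#' @return dic(fit_a) - dic(fit_b)
#' @export
delta_dic <- function(fit_a, fit_b, ...) {
  dic(fit_a, ...)$dic - dic(fit_b, ...)$dic
}

#' Variance partition of the random effects
#'
#' Share of the overall random-effect variance captured by the structured
#' spatial field: the empirical variance of the posterior-mean field at the
#' plot locations against the empirical variance of the posterior-mean
#' square effects at the plots, reported as
#' 100 * var_structured / (var_structured + var_iid), to 1 decimal.
#'
#' @param fit an `spdepois_fit` with both random components
#'   (`mesh_plus_square`)
#' @return object of class `variance_partition`: `var_structured`,
#'   `var_iid`, `percent_structured`
#' @export
variance_partition <- function(fit) {
  eng <- fit$engine
  if (!(eng$use_mesh && eng$use_sq)) {
    stop_("variance partition needs both random components (structure mesh_plus_square); for single-component models summarize the hyperparameters instead")
  }
  pm <- fit$latent$mean_all
  field_at_plots <- as.numeric(eng$A %*% pm[eng$idx$w])
  u_at_plots <- pm[eng$idx$u][eng$membership]
  vs <- var(field_at_plots)
  vi <- var(u_at_plots)
  pct <- if (vs + vi == 0) NA_real_ else round(100 * vs / (vs + vi), 1)
  structure(list(var_structured = vs, var_iid = vi,
                 percent_structured = pct),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("structured spatial field: %.1f%% of random-effect variance (%.4g vs %.4g iid)\n",
              x$percent_structured, x$var_structured, x$var_iid))
  invisible(x)
}

#' Decile grid of a covariate
#'
#' The 0th, 10th, ..., 100th percentiles (linear-interpolation definition),
#' deduplicated; the grid over which partial effects are predicted.
#'
#' @param values numeric vector with at least 2 distinct values
#' @return strictly increasing numeric vector (11 points when all deciles
#'   are distinct)
#' @export
percentile_grid <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) stop_("percentile grid needs >= 2 distinct values")
  unique(as.numeric(quantile(values, probs = seq(0, 1, 0.1), type = 7)))
}

#' Partial-effect prediction curve
#'
#' Predicted mean response along one covariate with all other covariates
#' set to zero: for each grid value x the posterior of
#' exp(beta0 + beta_cov * x), summarized by its median and 2.5/97.5% band
#' from joint posterior draws of (beta0, beta_cov). Because the other
#' covariates sit at zero (not at their means), the absolute predicted
#' counts are low; the curve's shape and uncertainty are the object of
#' interest.
#'
#' @param fit an `spdepois_fit`
#' @param covariate covariate name
#' @param grid covariate values (default: decile grid of the fitted data)
#' @param n_draws joint posterior draws for the band
#' @param seed integer seed
#' @return object of class `partial_effect`: data frame with `x`, `median`,
#'   `q0.025`, `q0.975`, `mean`
#' @export
partial_effect <- function(fit, covariate, grid = NULL, n_draws = 4000,
                           seed = 20100429) {
  eng <- fit$engine
  j <- match(covariate, eng$spec$covariates)
  if (is.na(j)) {
    stop_("unknown covariate '%s'; available: %s", covariate,
          paste(eng$spec$covariates, collapse = ", "))
  }
  if (is.null(grid)) grid <- percentile_grid(eng$X[, j])
  if (any(diff(grid) <= 0)) stop_("grid must be strictly increasing")
  dr <- posterior_draws(fit, n_draws, seed = seed)
  b0 <- dr[eng$idx$b0, ]
  bc <- dr[eng$idx$beta[j], ]
  curve <- t(vapply(grid, function(x) {
    lp <- exp(b0 + bc * x)
    c(median = median(lp),
      q0.025 = quantile(lp, 0.025, names = FALSE),
      q0.975 = quantile(lp, 0.975, names = FALSE),
      mean = mean(lp))
  }, numeric(4)))
  structure(data.frame(x = grid, curve, check.names = FALSE),
            class = c("partial_effect", "data.frame"),
            covariate = covariate)
}
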