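## One-block Metropolis-Hastings for the latent Gaussian Poisson model.
##
## Each iteration proposes hyperparameters by a random walk scaled to the
## Laplace posterior curvature, then the entire latent field from its
## Gaussian (Laplace) approximation at the proposed hyperparameters, and
## accepts/rejects jointly. Proposing the latent block from the local
## Gaussian approximation removes the strong theta--field dependence that
## cripples single-site updates, and the acceptance ratio corrects the
## approximation error exactly. During burn-in the random-walk scale adapts
## towards ~30% acceptance (Robbins-Monro) and is frozen afterwards, so the
## kept draws come from a valid (non-adaptive) MH chain. Several independent
## chains (`mcmc_chains`) are run and pooled; the potential-scale-reduction
## diagnostic uses the split chains.

fit_mcmc <- function(eng, opt) {
  k <- length(eng$theta_init)
  ## pilot Laplace run supplies the mode, curvature and starting state
  pilot <- fit_laplace(eng, modifyList(opt, list(n_grid = 3L)))
  mode <- pilot$mode
  hess_sd <- pilot$settings$hess_sd
  if (k > 0L && any(!is.finite(hess_sd))) hess_sd[!is.finite(hess_sd)] <- 1

  ## Gaussian-approximation machinery at one theta
  approx_at <- function(theta, x0) {
    names(theta) <- eng$theta_names
    Qp <- eng$qprior(theta)
    nm <- newton_mode(eng, Qp, x0)
    list(theta = theta, Qp = Qp, nm = nm,
         lpri_theta = eng$lprior_theta(theta) + eng$half_logdet_qprior(theta, Qp))
  }
  draw_from <- function(ap) {
    z <- rnorm(eng$p)
    as.numeric(ap$nm$x +
                 as.numeric(Matrix::solve(ap$nm$chol,
                                          Matrix::solve(ap$nm$chol, z, system = "Lt"),
                                          system = "Pt")))
  }
  ## log target (up to consts) and log proposal density of x under ap
  ltarget <- function(ap, x, eta) {
    d <- x - eng$mu_prior
    ap$lpri_theta - 0.5 * as.numeric(Matrix::crossprod(d, ap$Qp %*% d)) +
      loglik_pois(eng$y, eta)
  }
  lprop <- function(ap, x) {
    d <- x - ap$nm$x
    ap$nm$half_logdet_post - 0.5 * as.numeric(Matrix::crossprod(d, ap$nm$Qpost %*% d))
  }

  iter <- opt$mcmc_iter
  burn <- opt$mcmc_burnin
  n_chains <- max(1L, as.integer(opt$mcmc_chains %||% 1L))
  x_init <- if (ncol(pilot$x_star)) pilot$x_star[, which.max(pilot$weights)]

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      sc <- opt$mcmc_scale
      theta <- if (k) mode else numeric(0)
      ap <- approx_at(theta, x_init)
      x <- draw_from(ap)
      eta <- as.numeric(eng$B %*% x)
      lt <- ltarget(ap, x, eta)
      lq <- lprop(ap, x)
      draws <- matrix(0, eng$p, iter - burn)
      theta_draws <- matrix(0, max(k, 1), iter - burn)
      acc <- 0L
      acc_batch <- 0L
      for (it in seq_len(iter)) {
        if (k && it <= burn && it %% 50L == 0L) {
          sc <- min(max(sc * exp(acc_batch / 50 - 0.3), 0.05), 10)
          acc_batch <- 0L
        }
        theta_p <- if (k) theta + sc * hess_sd * rnorm(k) else numeric(0)
        ap_p <- approx_at(theta_p, ap$nm$x)
        x_p <- draw_from(ap_p)
        eta_p <- as.numeric(eng$B %*% x_p)
        lt_p <- ltarget(ap_p, x_p, eta_p)
        lq_p <- lprop(ap_p, x_p)
        lr <- (lt_p - lq_p) - (lt - lq)
        if (is.finite(lr) && log(runif(1)) < lr) {
          theta <- theta_p; ap <- ap_p; x <- x_p; eta <- eta_p
          lt <- lt_p; lq <- lq_p
          acc <- acc + 1L
          acc_batch <- acc_batch + 1L
        }
        if (it > burn) {
          draws[, it - burn] <- x
          if (k) theta_draws[, it - burn] <- theta
        }
      }
      list(draws = draws, theta_draws = theta_draws, acc_rate = acc / iter)
    })
  }

  chains <- lapply(seq_len(n_chains), function(ci) run_chain(opt$seed + 1000L * (ci - 1L)))
  draws <- do.call(cbind, lapply(chains, `[[`, "draws"))
  theta_draws <- do.call(cbind, lapply(chains, `[[`, "theta_draws"))
  acc_rate <- mean(vapply(chains, `[[`, numeric(1), "acc_rate"))
  per_chain <- lapply(chains, `[[`, "draws")
  build_mcmc_fit(eng, opt, draws, theta_draws, acc_rate, k, per_chain)
}

build_mcmc_fit <- function(eng, opt, draws, theta_draws, acc_rate, k,
                           per_chain = NULL) {
  fix_idx <- c(eng$idx$b0, eng$idx$beta)
  coef_names <- c("(Intercept)", eng$spec$covariates)
  qs <- c(0.025, 0.5, 0.975)
  summ <- t(apply(draws[fix_idx, , drop = FALSE], 1, function(v) {
    c(mean = mean(v), sd = sd(v),
      setNames(quantile(v, qs, names = FALSE), c("q0.025", "median", "q0.975")))
  }))
  summary <- data.frame(coefficient = coef_names, summ, check.names = FALSE)
  ## split-chain potential-scale-reduction for the fixed effects
  if (is.null(per_chain)) per_chain <- list(draws)
  rhat <- vapply(fix_idx, function(j) {
    split_rhat(lapply(per_chain, function(d) d[j, ]))
  }, numeric(1))
  converged <- acc_rate > 0.05 && all(is.finite(rhat)) && max(rhat) < 1.1

  hyper <- NULL
  if (k) {
    rownames(theta_draws) <- eng$theta_names
    rows <- list()
    if (eng$use_sq) {
      th2 <- 1 / exp(theta_draws["log_prec_u", ])
      rows$square_var <- c(mean = mean(th2),
                           setNames(quantile(th2, qs, names = FALSE),
                                    c("q0.025", "median", "q0.975")))
    }
    if (eng$use_mesh) {
      rng <- sqrt(8) / exp(theta_draws["log_kappa", ])
      sg <- 1 / sqrt(4 * pi) / exp(theta_draws["log_kappa", ] + theta_draws["log_tau", ])
      rows$matern_range <- c(mean = mean(rng),
                             setNames(quantile(rng, qs, names = FALSE),
                                      c("q0.025", "median", "q0.975")))
      rows$matern_sd <- c(mean = mean(sg),
                          setNames(quantile(sg, qs, names = FALSE),
                                   c("q0.025", "median", "q0.975")))
    }
    hyper <- data.frame(parameter = names(rows), do.call(rbind, rows),
                        check.names = FALSE, row.names = NULL)
  }
  pm <- rowMeans(draws)
  psd <- apply(draws, 1, sd)
  latent <- list(mean_all = pm)
  if (eng$use_sq) {
    latent$u <- data.frame(square = eng$square_levels,
                           mean = pm[eng$idx$u], sd = psd[eng$idx$u])
  }
  if (eng$use_mesh) {
    latent$w <- data.frame(eng$mesh$nodes, mean = pm[eng$idx$w],
                           sd = psd[eng$idx$w])
  }
  structure(list(
    method = "mcmc", spec = eng$spec, summary = summary, hyper = hyper,
    latent = latent, draws = draws, theta_draws = if (k) theta_draws,
    fix_idx = fix_idx, engine = eng, converged = converged,
    acceptance_rate = acc_rate, rhat = rhat,
    settings = list(iter = opt$mcmc_iter, burnin = opt$mcmc_burnin,
                    scale = opt$mcmc_scale,
                    chains = length(per_chain), seed = opt$seed,
                    priors = eng$spec$priors)),
    class = "spdepois_fit")
}

## split-Rhat over a list of chains (each halved), the standard
## multiple-chain potential-scale-reduction statistic
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  halves <- list()
  for (v in chains) {
    n <- floor(length(v) / 2)
    halves <- c(halves, list(v[seq_len(n)], v[n + seq_len(n)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  mu_j <- vapply(halves, mean, numeric(1))
  s2_j <- vapply(halves, var, numeric(1))
  W <- mean(s2_j)
  Bv <- n * var(mu_j)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}
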