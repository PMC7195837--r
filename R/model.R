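#' Prior specification for the hierarchical Poisson model
#'
#' Pinned, reproducible defaults (rather than inheriting any package's
#' version-dependent defaults): fixed effects Gaussian(0, precision 0.001);
#' improper flat intercept (precision 0); square-effect log-precision
#' log-gamma(shape 1, rate 5e-5); wide Gaussians on (log tau, log kappa) of
#' the SPDE field, centred at fit time so the prior median range is 20% of
#' the domain diameter and the prior median marginal sd is 1 (centres can be
#' overridden here).
#'
#' @param beta_mean,beta_prec Gaussian prior on each fixed effect
#' @param intercept_prec precision of the intercept prior (0 = improper flat)
#' @param square_lgamma_shape,square_lgamma_rate log-gamma prior on the iid
#'   square-effect precision
#' @param logtau_mean,logkappa_mean centres for the SPDE parameter priors;
#'   `NULL` derives them from the mesh at fit time
#' @param logtau_sd,logkappa_sd prior standard deviations
#' @return object of class `prior_spec`
#' @export
prior_spec <- function(beta_mean = 0, beta_prec = 0.001,
                       intercept_prec = 0,
                       square_lgamma_shape = 1, square_lgamma_rate = 5e-5,
                       logtau_mean = NULL, logtau_sd = 1.5,
                       logkappa_mean = NULL, logkappa_sd = 1.5) {
  stopifnot(beta_prec > 0, intercept_prec >= 0,
            square_lgamma_shape > 0, square_lgamma_rate > 0,
            logtau_sd > 0, logkappa_sd > 0)
  structure(list(beta_mean = beta_mean, beta_prec = beta_prec,
                 intercept_prec = intercept_prec,
                 square_lgamma_shape = square_lgamma_shape,
                 square_lgamma_rate = square_lgamma_rate,
                 logtau_mean = logtau_mean, logtau_sd = logtau_sd,
                 logkappa_mean = logkappa_mean, logkappa_sd = logkappa_sd),
            class = "prior_spec")
}

#' Model specification
#'
#' Declares the response column, the ordered covariate set, the spatial
#' error structure (one of `mesh_plus_square`, `square_only`, `mesh_only`,
#' `none`), and the priors. The structure variants correspond to: Matern
#' field + iid 1-km square intercepts; iid square intercepts only; Matern
#' field only; plain fixed-effects Poisson regression.
#'
#' @param covariates character vector of covariate column names (order is
#'   preserved in all outputs)
#' @param structure spatial error structure
#' @param response name of the integer count response column
#' @param priors a [prior_spec()]
#' @return object of class `model_spec`
#' @export
model_spec <- function(covariates,
                       structure = c("mesh_plus_square", "square_only",
                                     "mesh_only", "none"),
                       response = "richness",
                       priors = prior_spec()) {
  structure <- match.arg(structure)
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(covariates = covariates, structure = structure,
                 response = response, priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s ~ %s | structure = %s\n", x$response,
              paste(x$covariates, collapse = " + "), x$structure))
  invisible(x)
}

#' Linear predictor of the hierarchical Poisson model
#'
#' eta_i = beta0 + sum_m beta_m X_mi + u_j[i] + (A w)_i, with lambda =
#' exp(eta): global intercept, fixed effects, iid square intercept of the
#' square containing plot i, and the Matern field interpolated to the plot.
#'
#' @param state list with `beta0` (scalar), `beta` (length-M vector), `u`
#'   (square effects, possibly NULL), `w` (mesh-node weights, possibly NULL)
#' @param X design matrix (n x M)
#' @param A projector matrix (n x n_mesh) or NULL
#' @param membership integer vector mapping each plot to its square index in
#'   `u`, or NULL
#' @return numeric vector eta of length n
#' @export
linear_predictor <- function(state, X, A = NULL, membership = NULL) {
  n <- nrow(X)
  eta <- rep(state$beta0, n)
  if (length(state$beta)) {
    if (length(state$beta) != ncol(X)) stop_("beta length != ncol(X)")
    eta <- eta + as.numeric(X %*% state$beta)
  }
  if (!is.null(state$u)) {
    if (is.null(membership)) stop_("square effects given but no membership map")
    if (anyNA(membership) || any(membership < 1) ||
        any(membership > length(state$u))) {
      stop_("plot with unknown square id in membership map")
    }
    eta <- eta + state$u[membership]
  }
  if (!is.null(state$w)) {
    if (is.null(A)) stop_("field weights given but no projector")
    eta <- eta + as.numeric(A %*% state$w)
  }
  eta
}

## -- internal engine shared by the Laplace and MCMC fitters ----------------

## Assembles the latent-Gaussian machinery for one model: response, sparse
## predictor matrix B = [A | Z | 1 | X], block index map, the theta-dependent
## prior precision, and the hyperparameter log-prior.
build_engine <- function(data, spec, mesh = NULL, grid_size = 1000) {
  y <- data[[spec$response]]
  if (is.null(y)) stop_("response column '%s' not found", spec$response)
  if (any(y < 0) || any(y != round(y)) || anyNA(y)) {
    stop_("response must be non-negative integers")
  }
  n <- length(y)
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss)) stop_("missing covariate column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(data[spec$covariates])
  if (anyNA(X)) stop_("design matrix contains missing values; prepare first")
  M <- ncol(X)
  use_mesh <- spec$structure %in% c("mesh_plus_square", "mesh_only")
  use_sq <- spec$structure %in% c("mesh_plus_square", "square_only")

  A <- Z <- NULL
  n_mesh <- n_sq <- 0L
  membership <- NULL
  sqid <- NULL
  if (use_sq || use_mesh) {
    if (is.null(data$easting) || is.null(data$northing)) {
      stop_("spatial structures need easting/northing columns")
    }
  }
  if (use_sq) {
    sqid <- data$square_id %||% square_id(data$easting, data$northing, grid_size)
    sqf <- factor(sqid)
    membership <- as.integer(sqf)
    n_sq <- nlevels(sqf)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = membership, x = 1,
                              dims = c(n, n_sq))
  }
  fem <- NULL
  if (use_mesh) {
    if (is.null(mesh)) stop_("structure '%s' needs a mesh", spec$structure)
    A <- projector(mesh, cbind(data$easting, data$northing))
    fem <- fem_matrices(mesh)
    n_mesh <- mesh$n_nodes
  }
  one <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                              dims = c(n, 1L))
  B <- do.call(cbind, Filter(Negate(is.null), list(A, Z, one, Matrix::Matrix(X, sparse = TRUE))))
  B <- as(B, "CsparseMatrix")
  idx <- list()
  off <- 0L
  if (use_mesh) { idx$w <- off + seq_len(n_mesh); off <- off + n_mesh }
  if (use_sq) { idx$u <- off + seq_len(n_sq); off <- off + n_sq }
  idx$b0 <- off + 1L
  idx$beta <- if (M) off + 1L + seq_len(M) else integer(0)
  p <- off + 1L + M

  pri <- spec$priors
  ## SPDE prior centres derived from the mesh extent when not pinned by hand
  lk0 <- lt0 <- NULL
  if (use_mesh) {
    diam <- sqrt(sum(apply(mesh$nodes, 2, function(v) diff(range(v)))^2))
    k0 <- sqrt(8) / (0.2 * diam)
    lk0 <- pri$logkappa_mean %||% log(k0)
    lt0 <- pri$logtau_mean %||% log(1 / (sqrt(4 * pi) * exp(lk0)))
  }
  theta_names <- c(if (use_sq) "log_prec_u",
                   if (use_mesh) c("log_tau", "log_kappa"))
  theta_init <- c(if (use_sq) log(1 / 0.25^2),
                  if (use_mesh) c(lt0, lk0))
  names(theta_init) <- theta_names

  ## prior precision of the latent vector for hyperparameters theta
  qprior <- function(theta) {
    blocks <- list()
    if (use_mesh) {
      pp <- matern_params(kappa = exp(theta[["log_kappa"]]),
                          tau = exp(theta[["log_tau"]]))
      blocks$w <- matern_precision(fem, pp)
    }
    if (use_sq) {
      blocks$u <- Matrix::Diagonal(n_sq, exp(theta[["log_prec_u"]]))
    }
    blocks$fix <- Matrix::Diagonal(1 + M, c(pri$intercept_prec,
                                            rep(pri$beta_prec, M)))
    Matrix::forceSymmetric(Matrix::bdiag(blocks))
  }
  ## theta-dependent part of log|Qprior|^(1/2) (fixed block is constant)
  half_logdet_qprior <- function(theta, Qp) {
    v <- 0
    if (use_mesh) {
      Qw <- Qp[idx$w, idx$w]
      ch <- Matrix::Cholesky(Qw, LDL = FALSE, perm = TRUE)
      v <- v + as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
    }
    if (use_sq) v <- v + n_sq / 2 * theta[["log_prec_u"]]
    v
  }
  lprior_theta <- function(theta) {
    v <- 0
    if (use_sq) {
      lp <- theta[["log_prec_u"]]
      v <- v + pri$square_lgamma_shape * lp - pri$square_lgamma_rate * exp(lp)
    }
    if (use_mesh) {
      v <- v + dnorm(theta[["log_tau"]], lt0, pri$logtau_sd, log = TRUE) +
        dnorm(theta[["log_kappa"]], lk0, pri$logkappa_sd, log = TRUE)
    }
    v
  }
  ## Gaussian prior mean of the latent vector (fixed-effect means)
  mu_prior <- numeric(p)
  if (M) mu_prior[idx$beta] <- pri$beta_mean

  list(y = y, n = n, X = X, M = M, B = B, idx = idx, p = p,
       use_mesh = use_mesh, use_sq = use_sq, n_mesh = n_mesh, n_sq = n_sq,
       membership = membership, square_levels = if (use_sq) levels(factor(sqid)),
       mesh = mesh, A = A, fem = fem,
       qprior = qprior, half_logdet_qprior = half_logdet_qprior,
       lprior_theta = lprior_theta, mu_prior = mu_prior,
       theta_names = theta_names, theta_init = theta_init,
       spec = spec)
}

loglik_pois <- function(y, eta) sum(dpois(y, exp(eta), log = TRUE))

## Newton maximization of the latent conditional posterior given theta.
## Returns the mode, its Cholesky-factorized posterior precision and the
## quantities needed for the Laplace evidence.
newton_mode <- function(eng, Qp, x0 = NULL, tol = 1e-8, max_iter = 50L) {
  B <- eng$B; y <- eng$y; mu <- eng$mu_prior
  x <- x0 %||% numeric(eng$p)
  f_of <- function(x, eta) {
    loglik_pois(y, eta) - 0.5 * as.numeric(Matrix::crossprod(x - mu, Qp %*% (x - mu)))
  }
  eta <- as.numeric(B %*% x)
  ## guard against overflow from a bad start
  if (max(eta) > 30) { x <- numeric(eng$p); eta <- as.numeric(B %*% x) }
  f <- f_of(x, eta)
  conv <- FALSE
  ch <- NULL
  for (it in seq_len(max_iter)) {
    lam <- exp(pmin(eta, 30))
    g <- as.numeric(Matrix::crossprod(B, y - lam)) - as.numeric(Qp %*% (x - mu))
    Qpost <- Matrix::forceSymmetric(Qp + Matrix::crossprod(B, Matrix::Diagonal(eng$n, lam) %*% B))
    ch <- Matrix::Cholesky(Qpost, LDL = FALSE, perm = TRUE)
    dx <- as.numeric(Matrix::solve(ch, g, system = "A"))
    step <- 1
    repeat {
      xn <- x + step * dx
      etan <- as.numeric(B %*% xn)
      fn <- if (max(etan) > 30) -Inf else f_of(xn, etan)
      if (fn >= f - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    moved <- max(abs(step * dx))
    x <- xn; eta <- etan
    improved <- fn - f
    f <- fn
    if (moved < tol || abs(improved) < tol) { conv <- TRUE; break }
  }
  lam <- exp(pmin(eta, 30))
  Qpost <- Matrix::forceSymmetric(Qp + Matrix::crossprod(B, Matrix::Diagonal(eng$n, lam) %*% B))
  ch <- Matrix::Cholesky(Qpost, LDL = FALSE, perm = TRUE)
  half_logdet_post <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  list(x = x, eta = eta, f = f, chol = ch, Qpost = Qpost,
       half_logdet_post = half_logdet_post, converged = conv)
}

## Laplace approximation to log p(theta | y) up to a constant
log_post_theta <- function(eng, theta, x0 = NULL) {
  Qp <- eng$qprior(theta)
  nm <- newton_mode(eng, Qp, x0)
  lp <- eng$lprior_theta(theta) +
    eng$half_logdet_qprior(theta, Qp) +
    nm$f - nm$half_logdet_post
  list(lp = lp, nm = nm)
}
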