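#' Survey design for the synthetic generator
#'
#' Two layouts mirror the two study designs: `"scattered"` (single plots
#' spread over the domain, with a configurable fraction of 1-km squares
#' holding more than one plot, as in the national stratified survey) and
#' `"clustered"` (sites of `plots_per_site` plots falling within one
#' 100 x 100 m block, as in the deposition-gradient survey of 68 sites x 5
#' plots).
#'
#' @param layout `"scattered"` or `"clustered"`
#' @param n_sites number of sites (scattered: sites = plots)
#' @param plots_per_site plots per clustered site
#' @param domain extent c(xmin, xmax, ymin, ymax) in metres
#' @param grid_size square size in metres
#' @param multi_square_fraction scattered only: fraction of plots placed in
#'   an already-occupied square
#' @return object of class `survey_design`
#' @export
survey_design <- function(layout = c("clustered", "scattered"),
                          n_sites = 68, plots_per_site = 5,
                          domain = c(0, 5e5, 0, 7e5), grid_size = 1000,
                          multi_square_fraction = 0.15) {
  layout <- match.arg(layout)
  stopifnot(n_sites >= 3, plots_per_site >= 1, length(domain) == 4,
            domain[2] > domain[1], domain[4] > domain[3])
  structure(list(layout = layout, n_sites = n_sites,
                 plots_per_site = if (layout == "clustered") plots_per_site else 1L,
                 domain = domain, grid_size = grid_size,
                 multi_square_fraction = multi_square_fraction),
            class = "survey_design")
}

#' Generating truth for the synthetic generator
#'
#' @param beta0 intercept (log expected richness at covariates = 0; note the
#'   covariates are not centred, so this anchors the extrapolated origin)
#' @param beta named vector of fixed effects on the rescaled covariate scale
#' @param covariates named list, one entry per covariate:
#'   `list(lo =, hi =, divisor =)` giving the raw target range and rescaling
#'   divisor (effects and recovery operate on the rescaled scale)
#' @param correlation target correlation matrix of the covariates (Gaussian
#'   copula); must be positive definite
#' @param square_sd sd theta of the iid square effects
#' @param matern_range,matern_sd practical range (m) and marginal sd of the
#'   spatial field; `matern_sd = 0` disables the field
#' @param grazing_probs optional probabilities for a low/medium/high grazing
#'   factor; `beta` must then contain `grazing_medium`/`grazing_high`
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(beta0 = log(20), beta, covariates, correlation = NULL,
                            square_sd = 0.1, matern_range = 1.5e5,
                            matern_sd = 0.35, grazing_probs = NULL) {
  cn <- names(covariates)
  if (is.null(correlation)) correlation <- diag(length(cn))
  if (is.null(dimnames(correlation))) dimnames(correlation) <- list(cn, cn)
  correlation <- correlation[cn, cn, drop = FALSE]
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_("covariate correlation matrix is not positive definite (smallest eigenvalue %.3g)",
          min(ev))
  }
  need <- c(cn, if (!is.null(grazing_probs)) c("grazing_medium", "grazing_high"))
  miss <- setdiff(need, names(beta))
  if (length(miss)) stop_("beta missing entries: %s", paste(miss, collapse = ", "))
  structure(list(beta0 = beta0, beta = beta[need], covariates = covariates,
                 correlation = correlation, square_sd = square_sd,
                 matern_range = matern_range, matern_sd = matern_sd,
                 grazing_probs = grazing_probs),
            class = "synthetic_truth")
}

#' Simulate a gradient survey
#'
#' Draws plot locations per the design; covariates from a Gaussian copula
#' with the target correlation matrix, each column affinely mapped
#' (rank-preserving) onto its raw target range; a Matern field sampled from
#' the SPDE GMRF over a mesh on the occupied squares and projected to plots;
#' iid square effects; and Poisson counts under the log link. The returned
#' table is in the exact input format of the preparation and fitting
#' functions (raw covariate units; rescaling is the preparation step's job).
#'
#' @param design a [survey_design()]
#' @param truth a [synthetic_truth()]
#' @param seed integer seed
#' @param mesh_options options for the field-sampling mesh (list:
#'   `boundary_extension_fraction`, `max_edge`, `max_edge_outer`)
#' @return list with `data` (plot table: plot_id, site_id, easting,
#'   northing, square_id, richness, covariates), `truth` (echo, plus the
#'   realized `u`, `field` and `eta`), `design`, and `mesh` (or NULL)
#' @export
simulate_survey <- function(design, truth, seed = 20100429,
                            mesh_options = list()) {
  stopifnot(inherits(design, "survey_design"), inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    loc <- draw_locations(design)
    n <- nrow(loc)
    cn <- names(truth$covariates)
    L <- chol(truth$correlation)
    Zg <- matrix(rnorm(n * length(cn)), n) %*% L
    raw <- vapply(seq_along(cn), function(j) {
      tg <- truth$covariates[[j]]
      z <- Zg[, j]
      tg$lo + (z - min(z)) / (max(z) - min(z)) * (tg$hi - tg$lo)
    }, numeric(n))
    colnames(raw) <- cn
    Xs <- vapply(seq_along(cn), function(j) {
      raw[, j] / truth$covariates[[j]]$divisor
    }, numeric(n))
    eta <- truth$beta0 + as.numeric(Xs %*% truth$beta[cn])
    graz <- NULL
    if (!is.null(truth$grazing_probs)) {
      graz <- sample(c("low", "medium", "high"), n, replace = TRUE,
                     prob = truth$grazing_probs)
      gz <- expand_grazing(graz)
      eta <- eta + as.numeric(gz %*% truth$beta[c("grazing_medium", "grazing_high")])
    }
    sqid <- square_id(loc[, 1], loc[, 2], design$grid_size)
    usq <- unique(sqid)
    u <- rnorm(length(usq), 0, truth$square_sd)
    names(u) <- usq
    eta <- eta + u[sqid]
    mesh <- NULL
    field <- numeric(n)
    if (truth$matern_sd > 0) {
      mo <- modifyList(list(boundary_extension_fraction = 0.15,
                            max_edge = Inf, max_edge_outer = Inf), mesh_options)
      mesh <- build_mesh(loc, grid_size = design$grid_size,
                         boundary_extension_fraction = mo$boundary_extension_fraction,
                         max_edge = mo$max_edge, max_edge_outer = mo$max_edge_outer)
      fld <- spde_field(mesh, matern_params(range = truth$matern_range,
                                            sigma = truth$matern_sd))
      w <- sample_field(fld, 1, seed = sample.int(2^31 - 1, 1))[, 1]
      field <- as.numeric(projector(mesh, loc) %*% w)
      eta <- eta + field
    }
    y <- rpois(n, exp(eta))
    data <- data.frame(plot_id = sprintf("p%04d", seq_len(n)),
                       site_id = attr(loc, "site"),
                       easting = loc[, 1], northing = loc[, 2],
                       square_id = sqid, richness = y,
                       raw, check.names = FALSE)
    if (!is.null(graz)) data$grazing <- graz
    truth_echo <- truth
    truth_echo$u <- u
    truth_echo$field <- field
    truth_echo$eta <- eta
    list(data = data, truth = truth_echo, design = design, mesh = mesh)
  })
}

draw_locations <- function(design) {
  d <- design$domain
  if (design$layout == "clustered") {
    g <- design$grid_size
    ## one grid square per site; the site's 100 x 100 m block sits wholly
    ## inside it, so plots of a site share their square effect
    ox <- floor(runif(design$n_sites, d[1] / g, d[2] / g)) * g
    oy <- floor(runif(design$n_sites, d[3] / g, d[4] / g)) * g
    bx <- ox + runif(design$n_sites, 0, g - 100)
    by <- oy + runif(design$n_sites, 0, g - 100)
    n <- design$n_sites * design$plots_per_site
    site <- rep(seq_len(design$n_sites), each = design$plots_per_site)
    loc <- cbind(bx[site] + runif(n, 0, 100), by[site] + runif(n, 0, 100))
  } else {
    n <- design$n_sites
    n_extra <- round(design$multi_square_fraction * n)
    n_base <- n - n_extra
    base <- cbind(runif(n_base, d[1], d[2]), runif(n_base, d[3], d[4]))
    host <- base[sample.int(n_base, n_extra, replace = TRUE), , drop = FALSE]
    g <- design$grid_size
    ## extra plots land in the host plot's square
    extra <- cbind(floor(host[, 1] / g) * g + runif(n_extra, 0, g),
                   floor(host[, 2] / g) * g + runif(n_extra, 0, g))
    loc <- rbind(base, extra)
    site <- seq_len(n)
  }
  attr(loc, "site") <- site
  loc
}

#' Synthetic presets emulating the two study designs
#'
#' `"sea04"`: clustered 68 sites x 5 plots (340 plots; `variant =
#' "archived"` keeps a 320-plot subset), pollutant pair correlated at
#' r = 0.83, model-1 covariate set with a grazing factor, default
#' exp(beta_ndep) = 0.99. `"mea10"`: 883 scattered plots, pollutant pair at
#' r = -0.70, default exp(beta_ndep) = 1.01. Ranges and divisors follow the
#' built-in [covariate_catalogue()]; spatial range and sd are plausible
#' synthetic magnitudes (the studies' own field parameters are not archived).
#'
#' @param preset `"sea04"` or `"mea10"`
#' @param variant `"full"` or (sea04 only) `"archived"`
#' @param n_plots override the number of plots (scattered layout only)
#' @param domain domain extent in metres
#' @param exp_beta_ndep multiplicative N-deposition effect per kg ha-1 yr-1
#' @param square_sd,matern_range,matern_sd random-effect scales
#' @return list with `design` and `truth`, ready for [simulate_survey()]
#' @export
survey_preset <- function(preset = c("sea04", "mea10"),
                          variant = c("full", "archived"),
                          n_plots = NULL, domain = c(0, 5e5, 0, 7e5),
                          exp_beta_ndep = NULL, square_sd = 0.1,
                          matern_range = 1.5e5, matern_sd = 0.35) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  if (preset == "sea04") {
    design <- survey_design("clustered", n_sites = 68, plots_per_site = 5,
                            domain = domain)
    cv <- list(
      precip   = list(lo = 604.9, hi = 1773.3, divisor = 250),
      temp_max = list(lo = 11.5, hi = 14.6, divisor = 1),
      temp_min = list(lo = 4.2, hi = 8.1, divisor = 1),
      soil_al  = list(lo = 11.60, hi = 1318.75, divisor = 200),
      sdep_total = list(lo = 3.20, hi = 13.44, divisor = 1),
      ndep_total = list(lo = 7.70, hi = 40.86, divisor = 1),
      soil_ph  = list(lo = 3.69, hi = 5.37, divisor = 0.5),
      altitude = list(lo = 15, hi = 500, divisor = 100)
    )
    R <- diag(8)
    dimnames(R) <- list(names(cv), names(cv))
    R["ndep_total", "sdep_total"] <- R["sdep_total", "ndep_total"] <- 0.83
    R["precip", "altitude"] <- R["altitude", "precip"] <- 0.45
    R["temp_max", "temp_min"] <- R["temp_min", "temp_max"] <- 0.55
    R["temp_max", "altitude"] <- R["altitude", "temp_max"] <- -0.40
    R["soil_ph", "soil_al"] <- R["soil_al", "soil_ph"] <- -0.35
    beta <- c(precip = 0.01, temp_max = 0.02, temp_min = -0.01,
              soil_al = -0.01,
              sdep_total = 0.005,
              ndep_total = log(exp_beta_ndep %||% 0.99),
              soil_ph = 0.02, altitude = -0.03,
              grazing_medium = -0.02, grazing_high = -0.05)
    truth <- synthetic_truth(beta0 = log(20), beta = beta, covariates = cv,
                             correlation = R, square_sd = square_sd,
                             matern_range = matern_range, matern_sd = matern_sd,
                             grazing_probs = c(0.4, 0.4, 0.2))
  } else {
    design <- survey_design("scattered", n_sites = n_plots %||% 883,
                            domain = domain)
    cv <- list(
      ndep_total  = list(lo = 4.9, hi = 40.0, divisor = 1),
      sdep_change = list(lo = -5.36, hi = 0.00, divisor = 1),
      altitude    = list(lo = 0, hi = 975, divisor = 100),
      temp_min_jan = list(lo = -8.16, hi = 0.08, divisor = 1),
      temp_max_jul = list(lo = 14.11, hi = 26.67, divisor = 1),
      precip      = list(lo = 554.33, hi = 3305.80, divisor = 250),
      sheep_change = list(lo = -11.19, hi = 88.47, divisor = 10)
    )
    R <- diag(7)
    dimnames(R) <- list(names(cv), names(cv))
    R["ndep_total", "sdep_change"] <- R["sdep_change", "ndep_total"] <- -0.70
    R["altitude", "precip"] <- R["precip", "altitude"] <- 0.50
    R["temp_min_jan", "temp_max_jul"] <- R["temp_max_jul", "temp_min_jan"] <- 0.45
    R["altitude", "temp_max_jul"] <- R["temp_max_jul", "altitude"] <- -0.45
    beta <- c(ndep_total = log(exp_beta_ndep %||% 1.01),
              sdep_change = 0.01, altitude = -0.03,
              temp_min_jan = 0.02, temp_max_jul = -0.01,
              precip = 0.01, sheep_change = -0.005)
    truth <- synthetic_truth(beta0 = log(20), beta = beta, covariates = cv,
                             correlation = R, square_sd = square_sd,
                             matern_range = matern_range, matern_sd = matern_sd)
  }
  list(design = design, truth = truth, variant = variant, preset = preset)
}

#' Simulate from a preset
#'
#' @param preset output of [survey_preset()] (or a preset name)
#' @param seed integer seed
#' @param ... forwarded to [survey_preset()] when `preset` is a name
#' @return as [simulate_survey()]; the sea04 `"archived"` variant drops a
#'   seeded random subset of 20 plots (320 kept)
#' @export
simulate_preset <- function(preset, seed = 20100429, ...) {
  if (is.character(preset)) preset <- survey_preset(preset, ...)
  sim <- simulate_survey(preset$design, preset$truth, seed = seed)
  if (preset$preset == "sea04" && preset$variant == "archived") {
    keep <- with_seed(seed + 1L, sort(sample.int(nrow(sim$data), 320)))
    sim$data <- sim$data[keep, , drop = FALSE]
    rownames(sim$data) <- NULL
  }
  sim
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulate -> rescale -> fit, and score each fixed effect's
#' posterior against the generating truth: bias and RMSE of the posterior
#' median, and empirical coverage of the 95% credible interval. Replicate
#' fits that fail are recorded, not fatal.
#'
#' @param design a [survey_design()]
#' @param truth a [synthetic_truth()]
#' @param n_replicates number of replicates (>= 2)
#' @param seed integer seed; replicate r uses `seed + r`
#' @param structure spatial error structure for the fits
#' @param method inference method
#' @param mesh_options mesh options for fitting (and field simulation)
#' @param fit_options forwarded to [fit_model()]
#' @return list with `table` (per-parameter bias, rmse, coverage,
#'   mean_posterior_sd), `per_replicate` (long data frame), `failure_rate`
#' @export
recovery_experiment <- function(design, truth, n_replicates = 50,
                                seed = 20100429,
                                structure = "mesh_plus_square",
                                method = "laplace_eb",
                                mesh_options = list(), fit_options = list()) {
  stopifnot(n_replicates >= 2)
  true_beta <- c("(Intercept)" = truth$beta0, truth$beta)
  rows <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      sim <- simulate_survey(design, truth, seed = seed + r,
                             mesh_options = mesh_options)
      dat <- rescale_sim(sim)
      covs <- setdiff(names(true_beta), "(Intercept)")
      mesh <- if (structure %in% c("mesh_plus_square", "mesh_only")) {
        mo <- modifyList(list(boundary_extension_fraction = 0.15,
                              max_edge = Inf, max_edge_outer = Inf),
                         mesh_options)
        build_mesh(cbind(dat$easting, dat$northing),
                   grid_size = design$grid_size,
                   boundary_extension_fraction = mo$boundary_extension_fraction,
                   max_edge = mo$max_edge, max_edge_outer = mo$max_edge_outer)
      }
      spec <- model_spec(covs, structure = structure)
      ft <- fit_model(dat, spec, mesh = mesh, method = method,
                      options = modifyList(list(seed = seed + r), fit_options))
      s <- ft$summary
      data.frame(replicate = r, parameter = s$coefficient,
                 truth = as.numeric(true_beta[s$coefficient]),
                 median = s$median, sd = s$sd,
                 lo = s$q0.025, hi = s$q0.975,
                 covered = s$q0.025 <= true_beta[s$coefficient] &
                   true_beta[s$coefficient] <= s$q0.975)
    }, error = function(e) e)
    if (inherits(res, "error")) failures <- failures + 1L else rows[[length(rows) + 1L]] <- res
  }
  per <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(per, per$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               truth = d$truth[1],
               bias = mean(d$median - d$truth),
               rmse = sqrt(mean((d$median - d$truth)^2)),
               coverage = mean(d$covered),
               mean_posterior_sd = mean(d$sd))
  }))
  rownames(tab) <- NULL
  list(table = tab, per_replicate = per,
       failure_rate = failures / n_replicates)
}

#' Rescale a simulated survey onto the analysis scale
#'
#' Applies the truth's divisors to every covariate column and expands a
#' grazing factor, mirroring what [prepare_design()] does for real tables;
#' the result is ready for [fit_model()].
#'
#' @param sim output of [simulate_survey()] or [simulate_preset()]
#' @return the plot table with rescaled covariates
#' @export
rescale_sim <- function(sim) {
  dat <- sim$data
  for (nm in names(sim$truth$covariates)) {
    dat[[nm]] <- dat[[nm]] / sim$truth$covariates[[nm]]$divisor
  }
  if (!is.null(dat$grazing)) {
    gz <- expand_grazing(dat$grazing)
    dat$grazing_medium <- gz[, 1]
    dat$grazing_high <- gz[, 2]
  }
  dat
}
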