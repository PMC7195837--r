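## Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## small clustered survey with a spatial field and two correlated covariates
small_truth <- function(square_sd = 0.15, matern_sd = 0.4, beta = c(a = 0.2, b = -0.1)) {
  synthetic_truth(
    beta0 = log(15), beta = beta,
    covariates = list(a = list(lo = -2, hi = 2, divisor = 1),
                      b = list(lo = -2, hi = 2, divisor = 1)),
    correlation = matrix(c(1, 0.5, 0.5, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
    square_sd = square_sd, matern_range = 6e4, matern_sd = matern_sd)
}

small_design <- function(n_sites = 30) {
  survey_design("clustered", n_sites = n_sites, plots_per_site = 5,
                domain = c(0, 2e5, 0, 2e5))
}

small_sim <- function() {
  memo("small_sim", simulate_survey(small_design(), small_truth(), seed = 7))
}

small_mesh <- function() {
  memo("small_mesh", {
    dat <- small_sim()$data
    build_mesh(cbind(dat$easting, dat$northing),
               boundary_extension_fraction = 0.2, max_edge = Inf)
  })
}

small_fit <- function() {
  memo("small_fit", {
    dat <- small_sim()$data
    fit_model(dat, model_spec(c("a", "b"), structure = "mesh_plus_square"),
              mesh = small_mesh(), options = list(seed = 3))
  })
}

## a fixed unit-square toy mesh for projector/FEM checks
toy_grid_mesh <- function() {
  memo("toy_grid_mesh", {
    g <- as.matrix(expand.grid(x = 0:9, y = 0:9)) * 1.0
    build_mesh(g, snap_to_grid = FALSE, boundary_extension_fraction = 0,
               max_edge = Inf)
  })
}
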