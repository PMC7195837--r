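test_that("counts follow the intended Poisson mean when all effects are off", {
  tr <- synthetic_truth(beta0 = log(20), beta = c(a = 0, b = 0),
                        covariates = list(a = list(lo = -1, hi = 1, divisor = 1),
                                          b = list(lo = -1, hi = 1, divisor = 1)),
                        square_sd = 0, matern_sd = 0)
  sim <- simulate_survey(small_design(60), tr, seed = 12)
  n <- nrow(sim$data)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(sim$data$richness) - 20), 3 * se)
})

test_that("clustered presets have the documented plot counts and layout", {
  sim <- simulate_preset("sea04", seed = 1)
  expect_equal(nrow(sim$data), 340L)  # 68 sites x 5 plots
  expect_equal(length(unique(sim$data$site_id)), 68L)
  ## plots of one site fall within one 100 x 100 m block
  sp <- split(sim$data, sim$data$site_id)
  expect_true(all(vapply(sp, function(d) {
    diff(range(d$easting)) <= 100 && diff(range(d$northing)) <= 100
  }, logical(1))))
  arch <- simulate_preset("sea04", seed = 1, variant = "archived")
  expect_equal(nrow(arch$data), 320L)
  mea <- survey_preset("mea10")
  expect_equal(mea$design$n_sites, 883L)
  ## some squares hold multiple plots in the scattered design
  sm <- simulate_survey(survey_design("scattered", n_sites = 200,
                                      domain = c(0, 5e5, 0, 5e5)),
                        small_truth(matern_sd = 0), seed = 2)
  expect_gt(nrow(sm$data), length(unique(sm$data$square_id)))
})

test_that("copula covariates hit their target ranges and correlations", {
  ps <- survey_preset("sea04")
  sim <- simulate_preset("sea04", seed = 5)
  d <- sim$data
  for (nm in names(ps$truth$covariates)) {
    tg <- ps$truth$covariates[[nm]]
    expect_equal(min(d[[nm]]), tg$lo, tolerance = 1e-9)
    expect_equal(max(d[[nm]]), tg$hi, tolerance = 1e-9)
  }
  r <- cor(d$ndep_total, d$sdep_total)
  expect_true(r > 0.76 && r < 0.89)  # sampling band at n = 320-340
  rm <- cor(simulate_preset("mea10", seed = 5, n_plots = 600)$data[, c("ndep_total", "sdep_change")])[1, 2]
  expect_true(rm > -0.78 && rm < -0.62)
  ## non-PD correlation target is rejected with the offending eigenvalue
  badR <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(synthetic_truth(beta = c(a = 0, b = 0, c = 0),
                               covariates = list(a = list(lo = 0, hi = 1, divisor = 1),
                                                 b = list(lo = 0, hi = 1, divisor = 1),
                                                 c = list(lo = 0, hi = 1, divisor = 1)),
                               correlation = badR),
               "positive definite")
})

test_that("simulation is deterministic given the seed and round-trips through I/O", {
  s1 <- simulate_preset("sea04", seed = 33)
  s2 <- simulate_preset("sea04", seed = 33)
  expect_identical(s1$data, s2$data)
  path <- file.path(tempdir(), "rt_plots.csv")
  write_plot_table(s1$data, path)
  back <- read_plot_table(path)
  for (nm in names(s1$data)) expect_equal(back[[nm]], s1$data[[nm]])
})

test_that("recovery experiments are deterministic and score coverage sensibly", {
  des <- small_design(12)
  tr <- small_truth(matern_sd = 0.3)
  r1 <- recovery_experiment(des, tr, n_replicates = 2, seed = 50)
  r2 <- recovery_experiment(des, tr, n_replicates = 2, seed = 50)
  expect_identical(r1$table, r2$table)
  expect_setequal(r1$table$parameter, c("(Intercept)", "a", "b"))
  expect_true(all(r1$table$coverage >= 0 & r1$table$coverage <= 1))
  expect_equal(r1$failure_rate, 0)
})

test_that("an absent spatial field leaves square-only and mesh+square fits agreeing", {
  tr <- small_truth(matern_sd = 0, square_sd = 0.15)
  sim <- simulate_survey(small_design(25), tr, seed = 44)
  dat <- sim$data
  mesh <- build_mesh(cbind(dat$easting, dat$northing),
                     boundary_extension_fraction = 0.2, max_edge = Inf)
  f_sq <- fit_model(dat, model_spec(c("a", "b"), structure = "square_only"),
                    options = list(seed = 1))
  f_ms <- fit_model(dat, model_spec(c("a", "b"), structure = "mesh_plus_square"),
                    mesh = mesh, options = list(seed = 1))
  dd <- abs(f_sq$summary$median - f_ms$summary$median) / f_sq$summary$sd
  expect_lt(max(dd[-1]), 0.2)  # fixed effects; intercept shares the bound
  expect_lt(dd[1], 0.2)
})
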