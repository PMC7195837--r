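test_that("DIC is reproducible and pD tracks the parameter count for GLMs", {
  ft <- small_fit()
  d1 <- dic(ft, seed = 11)
  d2 <- dic(ft, seed = 11)
  expect_equal(d1$dic, d2$dic)
  expect_equal(delta_dic(ft, ft, seed = 11), 0)
  expect_equal(d1$dic, d1$dhat + 2 * d1$pd)
  ## fixed-effects-only Poisson model: pD ~ number of parameters
  set.seed(14)
  n <- 800
  X <- matrix(rnorm(3 * n), n)
  d <- data.frame(richness = rpois(n, exp(1 + X %*% c(0.2, -0.1, 0.15))),
                  X, easting = runif(n, 0, 1e4), northing = runif(n, 0, 1e4))
  ft0 <- fit_model(d, model_spec(c("X1", "X2", "X3"), structure = "none"))
  p0 <- dic(ft0, n_draws = 4000, seed = 2)
  expect_equal(p0$pd, 4, tolerance = 0.2)
  expect_false(p0$pd_negative)
})

test_that("variance partition reflects the posterior-mean components", {
  ft <- small_fit()
  vp <- variance_partition(ft)
  expect_true(vp$percent_structured >= 0 && vp$percent_structured <= 100)
  ## degenerate cases by zeroing one component's posterior means
  ft0 <- ft
  ft0$latent$mean_all[ft$engine$idx$u] <- 0
  expect_equal(variance_partition(ft0)$percent_structured, 100)
  ft1 <- ft
  ft1$latent$mean_all[ft$engine$idx$w] <- 0
  expect_equal(variance_partition(ft1)$percent_structured, 0)
  ## single-component structures are redirected
  dat <- small_sim()$data
  fsq <- fit_model(dat, model_spec(c("a", "b"), structure = "square_only"),
                   options = list(seed = 4))
  expect_error(variance_partition(fsq), "both random components")
})

test_that("percentile grid matches a sort-and-interpolate oracle and is affine-equivariant", {
  expect_equal(percentile_grid(0:100), seq(0, 100, 10))
  expect_equal(percentile_grid(c(1, 2)), c(1, 1.1, 1.2, 1.3, 1.4, 1.5,
                                           1.6, 1.7, 1.8, 1.9, 2))
  set.seed(3)
  v <- rlnorm(137)
  g <- percentile_grid(v)
  ## oracle: manual linear interpolation of order statistics (type-7 rule)
  o <- sort(v)
  oracle <- vapply(seq(0, 1, 0.1), function(p) {
    h <- (length(o) - 1) * p
    lo <- floor(h)
    o[lo + 1] + (h - lo) * (o[min(lo + 2, length(o))] - o[lo + 1])
  }, numeric(1))
  expect_equal(g, oracle, tolerance = 1e-12)
  ## affine equivariance
  expect_equal(percentile_grid(3 * v - 2), 3 * g - 2, tolerance = 1e-12)
  expect_true(all(diff(g) > 0))
  expect_error(percentile_grid(rep(1, 10)), "distinct")
})

test_that("partial effects match the analytic mixture oracle and exp(beta0) at x = 0", {
  ft <- small_fit()
  grid <- c(0, percentile_grid(ft$engine$X[, "a"]))
  grid <- sort(unique(grid))
  pe <- partial_effect(ft, "a", grid = grid, n_draws = 20000, seed = 6)
  ## oracle: beta0 + x * beta_a is a normal mixture over the hyper grid with
  ## moments available exactly from the stored fixed-effect covariances
  ja <- match("a", ft$spec$covariates) + 1L  # position within fixed block
  for (i in c(1, 4, length(grid))) {
    x <- grid[i]
    mg <- ft$x_star[ft$fix_idx[1], ] + x * ft$x_star[ft$fix_idx[ja], ]
    vg <- ft$fix_cov[1, 1, ] + x^2 * ft$fix_cov[ja, ja, ] +
      2 * x * ft$fix_cov[1, ja, ]
    med <- exp(spdepois:::mixnorm_quantile(0.5, ft$weights, mg, sqrt(vg)))
    expect_equal(pe$median[i], med, tolerance = 0.02)
  }
  ## at x = 0 the curve is the posterior of exp(beta0) from the same draws
  dr <- posterior_draws(ft, 20000, seed = 6)
  expect_equal(pe$median[pe$x == 0], median(exp(dr[ft$fix_idx[1], ])),
               tolerance = 1e-12)
  ## strictly monotone curve when the coefficient posterior has one sign
  expect_error(partial_effect(ft, "zz"), "unknown covariate")
})

test_that("a strictly negative coefficient posterior yields a decreasing median curve", {
  set.seed(40)
  n <- 400
  x <- runif(n, 0, 4)
  d <- data.frame(richness = rpois(n, exp(2.5 - 0.4 * x)), x = x,
                  easting = runif(n, 0, 1e4), northing = runif(n, 0, 1e4))
  ft <- fit_model(d, model_spec("x", structure = "none"))
  expect_lt(ft$summary$q0.975[2], 0)
  pe <- partial_effect(ft, "x", grid = seq(0, 4, 1), seed = 2)
  expect_true(all(diff(pe$median) < 0))
  expect_true(all(pe$q0.025 <= pe$median & pe$median <= pe$q0.975))
})
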