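test_that("linear predictor matches a dense loop-based oracle", {
  set.seed(21)
  n <- 20; M <- 3; nsq <- 5; nw <- 7
  X <- matrix(rnorm(n * M), n)
  A <- matrix(0, n, nw)
  for (i in 1:n) A[i, sample(nw, 3)] <- runif(3)
  A <- A / rowSums(A)
  member <- sample(nsq, n, replace = TRUE)
  st <- list(beta0 = 0.4, beta = rnorm(M), u = rnorm(nsq), w = rnorm(nw))
  eta <- linear_predictor(st, X, Matrix::Matrix(A, sparse = TRUE), member)
  oracle <- numeric(n)
  for (i in 1:n) {
    oracle[i] <- st$beta0 + sum(st$beta * X[i, ]) + st$u[member[i]] +
      sum(A[i, ] * st$w)
  }
  expect_equal(eta, oracle, tolerance = 1e-12)
  ## zero state -> eta = 0 (lambda = 1); no random terms -> GLM predictor
  st0 <- list(beta0 = 0, beta = rep(0, M), u = NULL, w = NULL)
  expect_equal(linear_predictor(st0, X), rep(0, n))
  expect_error(linear_predictor(list(beta0 = 0, beta = rnorm(M),
                                     u = rnorm(2), w = NULL),
                                X, NULL, c(1, 3)), "unknown square")
})

test_that("intercept-only fit with constant counts recovers log the mean", {
  d <- data.frame(richness = rep(3L, 400),
                  easting = runif(400, 0, 1000),
                  northing = runif(400, 0, 1000))
  ft <- fit_model(d, model_spec(character(0), structure = "none"))
  expect_lt(abs(ft$summary$median[1] - log(3)), 0.05)
})

test_that("structure-none fits agree with the IRLS (glm) oracle", {
  set.seed(33)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(richness = rpois(n, exp(1.2 + 0.25 * x1 - 0.15 * x2)),
                  x1 = x1, x2 = x2,
                  easting = runif(n, 0, 1e4), northing = runif(n, 0, 1e4))
  ft <- fit_model(d, model_spec(c("x1", "x2"), structure = "none"))
  g <- glm(richness ~ x1 + x2, poisson, d)
  expect_equal(ft$summary$median, unname(coef(g)), tolerance = 1e-2)
  ## well within 2 posterior sds
  expect_true(all(abs(ft$summary$median - coef(g)) < 2 * ft$summary$sd))
  ## rejects a non-count response
  d$richness[1] <- -1
  expect_error(fit_model(d, model_spec("x1", structure = "none")),
               "non-negative")
})

test_that("posterior quantiles are ordered for every coefficient", {
  ft <- small_fit()
  s <- ft$summary
  expect_true(all(s$q0.025 <= s$median & s$median <= s$q0.975))
  expect_equal(nrow(s), 3L)  # intercept + both covariates
  expect_true(all(c("a", "b") %in% s$coefficient))
  ## hyperparameters come back on interpretable scales, quantiles ordered
  hy <- ft$hyper
  expect_setequal(hy$parameter, c("square_var", "matern_range", "matern_sd"))
  expect_true(all(hy$q0.025 <= hy$median & hy$median <= hy$q0.975))
})

test_that("summarize_exp is the exact monotone transform of linear quantiles", {
  ft <- small_fit()
  e <- summarize_exp(ft, "a")
  i <- match("a", ft$summary$coefficient)
  expect_equal(unname(e), round(exp(unlist(
    ft$summary[i, c("q0.025", "median", "q0.975")])), 2),
    ignore_attr = TRUE)
  expect_error(summarize_exp(ft, "nope"), "available")
  ## a null-effect coefficient maps to 1.00 and ln(1.01) to 1.01
  fake <- ft
  fake$summary[i, c("q0.025", "median", "q0.975")] <- c(0, 0, log(1.01))
  e2 <- summarize_exp(fake, "a")
  expect_equal(unname(e2), c(1.00, 1.00, 1.01), ignore_attr = TRUE)
})

test_that("Laplace and MCMC return the same result shape", {
  dat <- small_sim()$data
  spec <- model_spec(c("a", "b"), structure = "square_only")
  fl <- fit_model(dat, spec, options = list(seed = 4))
  fm <- fit_model(dat, spec, method = "mcmc",
                  options = list(seed = 4, mcmc_iter = 400, mcmc_burnin = 100))
  expect_equal(names(fl$summary), names(fm$summary))
  expect_equal(fl$summary$coefficient, fm$summary$coefficient)
  expect_true(all(c("acceptance_rate", "rhat") %in% names(fm)))
  expect_true(is.finite(fm$acceptance_rate) && fm$acceptance_rate > 0)
  ## square-effect variance reported by both
  expect_true("square_var" %in% fl$hyper$parameter)
  expect_true("square_var" %in% fm$hyper$parameter)
})
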