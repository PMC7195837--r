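test_that("divisor rescaling reproduces catalogue range endpoints and is linear", {
  cat <- covariate_catalogue()
  for (i in seq_len(nrow(cat))) {
    sp <- covariate_spec(cat$name[i], divisor = cat$divisor[i],
                         role = cat$role[i])
    got <- rescale_covariate(c(cat$orig_lo[i], cat$orig_hi[i]), sp)
    expect_equal(got, c(cat$resc_lo[i], cat$resc_hi[i]),
                 info = paste(cat$name[i], cat$study[i]))
  }
  ## linearity before rounding
  sp <- covariate_spec("altitude", divisor = 100, role = "terrain")
  v <- c(12.3, 975, 0.07)
  expect_equal(rescale_covariate(3 * v, sp, decimals = Inf),
               3 * rescale_covariate(v, sp, decimals = Inf))
  ## divisor 1 is the identity
  expect_equal(rescale_covariate(v, covariate_spec("x", 1), decimals = Inf), v)
  expect_error(rescale_covariate(c(1, Inf), sp), "non-finite")
  expect_error(covariate_spec("x", divisor = 0), "positive")
})

test_that("correlation screening reports strong pairs and never drops columns", {
  set.seed(42)
  x <- rnorm(100)
  X <- cbind(p = x, q = x, r = -x, s = rnorm(100))
  out <- correlation_screen(X, 0.7)
  expect_true(all(abs(out$r) > 0.7))
  expect_equal(out$r[out$var1 == "p" & out$var2 == "q"], 1.0)
  expect_equal(out$r[out$var1 == "p" & out$var2 == "r"], -1.0)
  ## sorted descending by |r|
  expect_true(all(diff(abs(out$r)) <= 1e-12))
  ## independent columns produce no pairs at a high threshold
  set.seed(1)
  Z <- matrix(rnorm(2e4), ncol = 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(nrow(correlation_screen(Z, 0.5)), 0L)
  ## zero-variance columns are reported, not crashed on
  W <- cbind(const = rep(1, 50), ok = rnorm(50), ok2 = rnorm(50))
  expect_equal(attr(correlation_screen(W, 0.7), "zero_variance"), "const")
})

test_that("mean imputation fills gaps with the observed mean and nothing else", {
  expect_equal(as.numeric(mean_impute(c(2, 4, NA))), c(2, 4, 3))
  v <- c(1.5, 2.5, 9)
  expect_equal(as.numeric(mean_impute(v)), v)
  ## 15 of 320 missing, all observed equal to c: imputed value is c
  x <- rep(7.7, 320)
  x[sample(320, 15)] <- NA
  out <- mean_impute(x, "pet")
  expect_equal(as.numeric(out), rep(7.7, 320))
  expect_equal(attr(out, "n_imputed"), 15L)
  expect_error(mean_impute(c(NA_real_, NA_real_), "pet"), "pet")
})

test_that("climate PCA standardizes, fixes signs, and matches an eigen oracle", {
  set.seed(11)
  n <- 200
  base <- rnorm(n)
  Z <- cbind(pet1 = base + rnorm(n, sd = 0.3),
             tmax = 2 * base + rnorm(n, sd = 0.4),
             tmin = -base + rnorm(n, sd = 0.5),
             pet2 = base + rnorm(n, sd = 0.3))
  out <- climate_pca(Z)
  expect_equal(colnames(out$scores), c("Climate PC1", "Climate PC2"))
  expect_lt(abs(cor(out$scores[, 1], out$scores[, 2])), 1e-10)
  ## oracle: eigendecomposition of the correlation matrix
  ev <- eigen(cor(Z), symmetric = TRUE)
  Zs <- scale(Z)
  for (j in 1:2) {
    oracle <- as.numeric(Zs %*% ev$vectors[, j])
    expect_equal(abs(cor(out$scores[, j], oracle)), 1, tolerance = 1e-10)
  }
  expect_equal(out$variance_fractions, ev$values / 4, tolerance = 1e-12)
  ## sign convention: loading of the first input column is non-negative
  expect_true(all(out$loadings[1, ] >= 0))
  ## row-order invariance (up to nothing: scores permute with the rows)
  perm <- sample(n)
  out2 <- climate_pca(Z[perm, ])
  expect_equal(out2$scores[order(perm), ], out$scores, tolerance = 1e-9)
  ## two perfectly correlated columns duplicated to four
  out3 <- climate_pca(cbind(base, 2 * base, base, -base))
  expect_equal(out3$variance_fractions[1], 1, tolerance = 1e-12)
  expect_equal(out3$variance_fractions[2], 0, tolerance = 1e-12)
  expect_error(climate_pca(cbind(rep(1, 10), rnorm(10))), "constant")
})

test_that("VIF matches its closed form, its definition, and flags collinearity", {
  ## mutually orthogonal columns
  X <- qr.Q(qr(matrix(rnorm(200 * 4), 200)))
  colnames(X) <- letters[1:4]
  expect_equal(unname(vif(X)), rep(1, 4), tolerance = 1e-4)
  ## two-predictor closed form 1/(1 - r^2)
  set.seed(5)
  z <- rnorm(300)
  a <- z + rnorm(300, sd = 0.6)
  b <- z + rnorm(300, sd = 0.6)
  r <- cor(a, b)
  expect_equal(unname(vif(cbind(a = a, b = b))), rep(1 / (1 - r^2), 2),
               tolerance = 1e-8)
  ## oracle on random instances: diagonal of the inverse correlation matrix
  for (rep in 1:5) {
    n <- sample(20:50, 1); M <- sample(3:6, 1)
    X <- matrix(rnorm(n * M), n) %*% (diag(M) + 0.4)
    colnames(X) <- paste0("x", 1:M)
    expect_equal(unname(vif(X)), unname(diag(solve(cor(X)))),
                 tolerance = 1e-8)
  }
  ## duplicated column: infinite VIF
  Xd <- cbind(u = a, v = a, w = b)
  expect_true(all(is.infinite(vif(Xd)[c("u", "v")])))
})

test_that("grazing expands to treatment-coded indicators with low as reference", {
  g <- expand_grazing(c("low", "medium", "high", "low"))
  expect_equal(unname(g[, "grazing_medium"]), c(0, 1, 0, 0))
  expect_equal(unname(g[, "grazing_high"]), c(0, 0, 1, 0))
  expect_error(expand_grazing(c("low", "none")), "low/medium/high")
})

test_that("prepare_design assembles a complete design matrix with provenance", {
  sim <- simulate_preset("sea04", seed = 99)
  dat <- sim$data
  dat$precip[1:15] <- NA
  specs <- catalogue_specs("sea04")
  specs <- specs[names(specs) %in% names(dat)]
  prep <- prepare_design(dat, specs,
                         pca_columns = c("precip", "temp_max", "temp_min"),
                         impute_columns = "precip",
                         grazing_column = "grazing",
                         group = dat$square_id)
  expect_false(anyNA(prep$X))
  expect_true(all(c("Climate PC1", "Climate PC2", "grazing_medium",
                    "grazing_high") %in% colnames(prep$X)))
  expect_true(any(grepl("imputed 15", prep$log)))
  ## the collinear pollutant pair is screened but retained
  expect_true("ndep_total" %in% colnames(prep$X))
  expect_true("sdep_total" %in% colnames(prep$X))
  pair <- prep$screen
  expect_true(any((pair$var1 == "ndep_total" & pair$var2 == "sdep_total") |
                    (pair$var1 == "sdep_total" & pair$var2 == "ndep_total")))
  expect_true(all(prep$vifs >= 1))
})
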