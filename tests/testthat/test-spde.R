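test_that("FEM matrices satisfy their structural identities", {
  m <- toy_grid_mesh()
  fem <- fem_matrices(m)
  ## constants are in the null space of the stiffness matrix
  expect_lt(max(abs(Matrix::rowSums(fem$G))), 1e-9)
  ## lumped mass partitions the total area
  expect_equal(sum(Matrix::diag(fem$C)), 81, tolerance = 1e-9)
  expect_equal(as.matrix(fem$G), t(as.matrix(fem$G)))
  ## single unit right triangle: hand-computed cotangent entries
  m1 <- build_mesh(cbind(c(0, 1, 0), c(0, 0, 1)), snap_to_grid = FALSE,
                   boundary_extension_fraction = 0, max_edge = Inf)
  G1 <- as.matrix(fem_matrices(m1)$G)
  o <- order(m1$nodes[, 1], m1$nodes[, 2])  # (0,0), (0,1), (1,0)
  expect_equal(G1[o, o],
               matrix(c(1, -0.5, -0.5, -0.5, 0.5, 0, -0.5, 0, 0.5), 3),
               tolerance = 1e-12)
})

test_that("Matern parameterization is self-consistent and Q scales as tau^2", {
  p <- matern_params(range = 3, sigma = 1.4)
  expect_equal(p$range, sqrt(8) / p$kappa)
  expect_equal(p$sigma, 1 / sqrt(4 * pi * p$kappa^2 * p$tau^2))
  ## doubling tau halves the marginal sd
  p2 <- matern_params(kappa = p$kappa, tau = 2 * p$tau)
  expect_equal(p2$sigma, p$sigma / 2)
  ## and scales the precision exactly by 4
  m <- toy_grid_mesh()
  fem <- fem_matrices(m)
  Q1 <- matern_precision(fem, p)
  Q2 <- matern_precision(fem, p2)
  expect_lt(max(abs(Q2 - 4 * Q1)), 1e-9 * max(abs(Q1)))
  ## SPD on a small mesh
  ev <- eigen(as.matrix(Q1), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(matern_params(kappa = -1, tau = 1), "positive")
})

test_that("projector rows are barycentric: indicators at nodes, affine-exact", {
  m <- toy_grid_mesh()
  ## location exactly at a node -> indicator row
  A <- projector(m, m$nodes[c(5, 50), , drop = FALSE])
  expect_equal(Matrix::rowSums(A != 0), c(1, 1), ignore_attr = TRUE)
  expect_equal(Matrix::rowSums(A), c(1, 1), ignore_attr = TRUE)
  ## generic locations: rows sum to one, affine functions reproduce exactly
  set.seed(2)
  loc <- cbind(runif(50, 0, 9), runif(50, 0, 9))
  A <- projector(m, loc)
  expect_lt(max(abs(Matrix::rowSums(A) - 1)), 1e-12)
  f <- function(x, y) 2.5 + 3 * x - 1.5 * y
  expect_lt(max(abs(as.numeric(A %*% f(m$nodes[, 1], m$nodes[, 2])) -
                      f(loc[, 1], loc[, 2]))), 1e-9)
  expect_error(projector(m, cbind(50, 50)), "outside")
})

test_that("field sampling is seeded, zero-mean, and matches Q^-1 variances", {
  m <- toy_grid_mesh()
  fld <- spde_field(m, matern_params(range = 3, sigma = 1))
  s1 <- sample_field(fld, 3, seed = 5)
  s2 <- sample_field(fld, 3, seed = 5)
  expect_identical(s1, s2)
  S <- solve(as.matrix(fld$Q))
  draws <- sample_field(fld, 10000, seed = 9)
  ## fixed interior node: sample variance vs dense-inverse oracle
  ctr <- which.min(rowSums(sweep(m$nodes, 2, c(4.5, 4.5))^2))
  expect_equal(var(draws[ctr, ]), S[ctr, ctr], tolerance = 0.05)
  expect_lt(abs(mean(draws[ctr, ])), 4 * sqrt(S[ctr, ctr] / 10000))
  ## correlation decays with distance; ~0.13 at the practical range
  expect_equal(matern_correlation(3, sqrt(8) / 3), 0.1397, tolerance = 1e-3)
  d <- seq(0.5, 6, by = 0.5)
  expect_true(all(diff(matern_correlation(d, sqrt(8) / 3)) < 0))
})
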