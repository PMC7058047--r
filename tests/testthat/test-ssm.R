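test_that("identical hips give an empty mode set", {
  X <- matrix(1.5, 10, 30)
  sm <- build_shape_model(X)
  expect_equal(length(sm$eigenvalues), 0)
  expect_equal(ncol(sm$modes), 0)
})

test_that("planted orthogonal modes are recovered (subspace and spectrum)", {
  set.seed(7)
  V3 <- 120; n <- 400
  Q <- qr.Q(qr(matrix(rnorm(V3 * 3), V3, 3)))
  scores <- cbind(rnorm(n, 0, 3), rnorm(n, 0, 2), rnorm(n, 0, 1))
  X <- scores %*% t(Q) + matrix(rnorm(n * V3, 0, 0.05), n, V3)
  sm <- build_shape_model(X)
  expect_equal(sm$eigenvalues[1:3], c(9, 4, 1), tolerance = 0.25)
  # principal angles between planted and recovered subspaces < 5 degrees
  sv <- svd(t(Q) %*% sm$modes[, 1:3])$d
  angles <- acos(pmin(sv, 1)) * 180 / pi
  expect_lt(max(angles), 5)
  # oracle: eigendecomposition of the noise-free covariance
  ev_free <- eigen(cov(scores %*% t(Q)))$values[1:3]
  expect_equal(sm$eigenvalues[1:3], ev_free, tolerance = 0.1)
})

test_that("shape model invariants: orthonormality, centring, reconstruction, diagonal scores", {
  set.seed(8)
  X <- matrix(rnorm(40 * 60), 40, 60) %*% diag(rep(c(3, 1), 30))
  sm <- build_shape_model(X)
  K <- length(sm$eigenvalues)
  expect_lt(max(abs(crossprod(sm$modes) - diag(K))), 1e-8)
  expect_lt(max(abs(colMeans(sm$coefficients))), 1e-8)
  # full-rank reconstruction to machine precision
  Xc <- sweep(X, 2, sm$mean)
  expect_lt(max(abs(sm$coefficients %*% t(sm$modes) - Xc)), 1e-8)
  # coefficient covariance is diagonal with the eigenvalues
  cc <- cov(sm$coefficients)
  expect_equal(unname(diag(cc)), unname(sm$eigenvalues), tolerance = 1e-6)
  expect_lt(max(abs(cc - diag(diag(cc)))) / max(diag(cc)), 1e-6)
  # deterministic signs on repeated runs
  sm2 <- build_shape_model(X)
  expect_identical(sm$modes, sm2$modes)
})

test_that("tidy/glance/autoplot expose the eigenstructure", {
  set.seed(1)
  sm <- build_shape_model(matrix(rnorm(30 * 45), 30, 45))
  td <- tidy(sm)
  expect_equal(td$cumulative_variance[nrow(td)], 1, tolerance = 1e-12)
  gl <- glance(sm)
  expect_equal(gl$n_hips, 30)
  expect_s3_class(autoplot(sm), "ggplot")
})

test_that("Horn retains nothing on pure noise and the planted rank on signal", {
  set.seed(2)
  noise <- matrix(rnorm(80 * 40), 80, 40)
  expect_equal(as.integer(horns_parallel_analysis(noise, n_perm = 120, seed = 1)), 0)
  # rank-5 signal well above noise
  Q <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
  X <- matrix(rnorm(80 * 5), 80, 5) %*% diag(c(8, 7, 6, 5, 4)) %*% t(Q) +
    matrix(rnorm(80 * 40), 80, 40) * 0.2
  expect_equal(as.integer(horns_parallel_analysis(X, n_perm = 120, seed = 1)), 5)
})

test_that("mode point clouds and group mean shapes behave linearly", {
  can <- tiny_canonical()
  set.seed(3)
  fields <- matrix(rnorm(20 * 3 * n_vertices(can), 0, 0.5), 20)
  sm <- build_shape_model(fields)
  pc0 <- mode_point_cloud(sm, can, 1, sd_multiplier = 0)
  expect_equal(pc0$plus, pc0$minus)
  pc <- mode_point_cloud(sm, can, 1, sd_multiplier = 3)
  mid <- (pc$plus + pc$minus) / 2
  expect_lt(max(abs(mid - pc0$plus)), 1e-9)
  expect_error(mode_point_cloud(sm, can, 99), "out of range")

  g <- group_mean_shape(fields, rep(c("a", "b"), each = 10), can, exaggeration = 3)
  expect_named(g, c("a", "b"))
  g1 <- group_mean_shape(fields, rep("a", 20), can, exaggeration = 1)
  mu <- colMeans(fields)
  expect_equal(g1$a, can$vertices + matrix(mu, ncol = 3, byrow = TRUE),
               tolerance = 1e-12)
  # identical groups give identical clouds
  g2 <- group_mean_shape(rbind(fields, fields),
                         rep(c("a", "b"), each = 20), can)
  expect_equal(g2$a, g2$b)
})

test_that("paired-hip averaging is the vertex-wise mean per individual", {
  vals <- rbind(c(1, 2), c(3, 4), c(10, 20))
  av <- average_paired_maps(vals, c("i1", "i1", "i2"))
  expect_equal(unname(av$values), rbind(c(2, 3), c(10, 20)))
  expect_equal(av$individual_id, c("i1", "i2"))
})
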