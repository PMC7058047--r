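reduced_canonical <- function() canonical_surface(n_theta = 12, n_phi = 12)

test_that("vertex-wise GLM equals explicit per-vertex normal equations", {
  set.seed(1)
  n <- 40; V <- 25
  design <- data.frame(thr = rbinom(n, 1, 0.4), SM1 = rnorm(n), SM2 = rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_vertexwise_glm(Y, design, effect = "thr")
  X <- cbind(1, as.matrix(design))
  for (v in sample(V, 8)) {
    b <- solve(crossprod(X), crossprod(X, Y[, v]))
    r1 <- Y[, v] - X %*% b
    X0 <- X[, -2]
    b0 <- solve(crossprod(X0), crossprod(X0, Y[, v]))
    r0 <- Y[, v] - X0 %*% b0
    Fv <- (sum(r0^2) - sum(r1^2)) / (sum(r1^2) / (n - ncol(X)))
    expect_equal(fit$F[v], Fv, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[2, v]), unname(b[2]), tolerance = 1e-8)
  }
  # perfect linear response leaves zero residuals
  Yp <- X %*% matrix(rnorm(4 * V), 4, V)
  fp <- fit_vertexwise_glm(Yp, design, effect = "thr")
  expect_lt(max(abs(fp$residuals)), 1e-9)
  # F is invariant to affine rescaling of confounders
  design2 <- design
  design2$SM1 <- design2$SM1 * 13 + 5
  f2 <- fit_vertexwise_glm(Y, design2, effect = "thr")
  expect_equal(fit$F, f2$F, tolerance = 1e-8)
  # rank deficiency errors naming a column
  design3 <- design
  design3$dup <- design3$SM1
  expect_error(fit_vertexwise_glm(Y, design3, effect = "thr"), "collinear")
})

test_that("null p-values are uniform (KS) under a permuted effect", {
  set.seed(2)
  n <- 60
  mesh <- grid_mesh(12, 12, 1)
  V <- n_vertices(mesh)
  pv <- c()
  for (r in 1:10) {
    Y <- matrix(rnorm(n * V), n, V)
    design <- data.frame(thr = sample(rep(0:1, n / 2)), SM1 = rnorm(n))
    pv <- c(pv, fit_vertexwise_glm(Y, design, effect = "thr")$p)
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("smoothness estimation recovers a known kernel FWHM within 15%", {
  set.seed(3)
  mesh <- grid_mesh(40, 40, 1)
  n <- 30
  for (fw in c(4, 6)) {
    E <- t(smooth_surface_scalar(mesh, t(matrix(rnorm(n * n_vertices(mesh)),
                                                n)), fw))
    E <- E - rowMeans(E)  # mimic residualisation
    sm <- estimate_smoothness(E, mesh)
    expect_lt(abs(sm$fwhm_mm - fw) / fw, 0.15)
  }
  # unsmoothed noise: FWHM at the mesh edge scale
  E0 <- matrix(rnorm(n * n_vertices(mesh)), n)
  sm0 <- estimate_smoothness(E0, mesh)
  expect_lt(sm0$fwhm_mm, 2.5)
  # resel count scales as area / FWHM^2: doubling the smoothing bandwidth
  # quarters the 2D resels (up to discretisation)
  E4 <- t(smooth_surface_scalar(mesh, t(matrix(rnorm(60 * n_vertices(mesh)), 60)), 4))
  E8 <- t(smooth_surface_scalar(mesh, t(matrix(rnorm(60 * n_vertices(mesh)), 60)), 8))
  r4 <- estimate_smoothness(E4 - rowMeans(E4), mesh)$resels[3]
  r8 <- estimate_smoothness(E8 - rowMeans(E8), mesh)$resels[3]
  expect_lt(abs(r4 / r8 - 4) / 4, 0.3)
  expect_error(estimate_smoothness(matrix(0, n, n_vertices(mesh)), mesh),
               "zero-variance")
})

test_that("RFT: corrected p >= uncorrected p; single-vertex limit is the F test", {
  Fv <- c(0.5, 2, 8, 20)
  rc <- rft_correct(Fv, df = c(1, 50), resels = c(1, 3, 40), alpha = 0.05)
  expect_true(all(rc$p_corrected >= rc$p_uncorrected - 1e-12))
  expect_true(all(rc$roi == (rc$p_corrected < 0.05)))
  # one-vertex search region: no multiplicity, corrected == uncorrected
  rc1 <- rft_correct(10, df = c(1, 30), resels = c(1, 0, 0), alpha = 0.05)
  expect_equal(rc1$p_corrected, pf(10, 1, 30, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(rft_correct(Fv, c(1, 50), resels = c(0, 0, 0)), "resel")
})

test_that("spm_jsw detects the planted superior narrowing with a faithful mean map", {
  can <- reduced_canonical()
  sim <- simulate_cohort(cohort_spec(), can, seed = 11, with_fields = FALSE)
  res <- spm_jsw(sim$maps, sim$cohort, sim$coefficients, can)
  expect_s3_class(res, "spm_result")
  # ROI overlaps the planted superior region (Dice > 0.5)
  truth <- sim$truth$superior_window >= 0.5
  dice <- 2 * sum(res$roi & truth) / (sum(res$roi) + sum(truth))
  expect_gt(dice, 0.5)
  # group difference magnitude near the planted 1 mm at the narrowing peak
  expect_lt(abs(min(res$mean_diff) - (-1)), 0.35)
  expect_output(print(res), "ROI vertices")
  expect_s3_class(autoplot(res), "ggplot")
  gl <- glance(res)
  expect_equal(gl$n, 267)
})

test_that("side-difference SPM: zero maps give no ROI, planted asymmetry is found", {
  can <- reduced_canonical()
  sim <- simulate_cohort(cohort_spec(), can, seed = 12, with_fields = FALSE)
  sd_maps <- side_difference_map(sim$maps, sim$cohort, seed = 1)
  meta <- dplyr::summarise(dplyr::group_by(sim$cohort, individual_id),
                           thr = as.integer(any(thr == 1)), .groups = "drop")
  meta <- meta[match(sd_maps$individual_id, meta$individual_id), ]
  design <- data.frame(thr = meta$thr)
  res <- side_difference_spm(sd_maps$diff, design, can)
  # posterior widening planted on the replaced hip appears with + sign
  post <- sim$truth$posterior_window >= 0.5
  expect_gt(mean(res$mean_diff[post]), 0.3)
  sup <- sim$truth$superior_window >= 0.5
  expect_lt(mean(res$mean_diff[sup]), -0.3)
  # all-zero maps: F ~ 0, empty ROI
  res0 <- side_difference_spm(matrix(rnorm(length(meta$thr) *
                                             n_vertices(can), 0, 1e-6),
                                     ncol = n_vertices(can)),
                              design, can, smooth_fwhm_mm = 0)
  expect_false(any(res0$roi))
})

test_that("permutation max-F agrees with RFT on an obvious effect and a null", {
  set.seed(4)
  can <- reduced_canonical()
  n <- 60; V <- n_vertices(can)
  thr <- rep(0:1, n / 2)
  # strong localised effect
  Y <- matrix(rnorm(n * V), n, V)
  bump <- as.numeric(can$channels$theta < 0.4)
  Y <- Y + outer(thr, bump * 2)
  design <- data.frame(thr = thr)
  pm <- permutation_max_f(Y, design, n_perm = 99, seed = 1)
  expect_lt(pm$p_fwer, 0.02)
  glm_fit <- fit_vertexwise_glm(Y, design, effect = "thr")
  sm <- estimate_smoothness(glm_fit$residuals, can)
  rc <- rft_correct(glm_fit$F, glm_fit$df, sm$resels)
  expect_true(any(rc$roi))
  # null: both say nothing
  Y0 <- matrix(rnorm(n * V), n, V)
  pm0 <- permutation_max_f(Y0, design, n_perm = 99, seed = 1)
  expect_gt(pm0$p_fwer, 0.05)
})
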