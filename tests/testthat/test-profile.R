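test_that("extract_profile interpolates trilinearly", {
  # constant field -> constant profile
  vol <- jsm_volume(array(7.5, c(10, 10, 10)), voxel_size_mm = c(1, 1, 1))
  pr <- extract_profile(vol, c(4, 4, 4), c(0, 0, 1), half_length_mm = 3,
                        spacing_mm = 0.5)
  expect_true(all(pr$values == 7.5))
  expect_equal(diff(pr$offsets_mm), rep(0.5, length(pr$offsets_mm) - 1))

  # field equal to world x-coordinate -> unit slope along an x-aligned line
  arr <- array(0, c(12, 10, 10))
  for (i in 1:12) arr[i, , ] <- (i - 1)  # voxel size 1 => world x
  vol2 <- jsm_volume(arr, voxel_size_mm = c(1, 1, 1))
  pr2 <- extract_profile(vol2, c(5, 4, 4), c(1, 0, 0), half_length_mm = 3,
                         spacing_mm = 0.25)
  fit <- lm(pr2$values ~ pr2$offsets_mm)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-10)
})

test_that("off-grid samples equal the hand-computed trilinear combination", {
  set.seed(42)
  arr <- array(rnorm(27), c(3, 3, 3))
  vol <- jsm_volume(arr, voxel_size_mm = c(1, 1, 1))
  for (rep in 1:5) {
    p <- runif(3, 0.1, 0.9)  # inside the first cell, world coords
    f <- p  # voxel fractional offsets (voxel size 1, 0-based origin)
    manual <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      manual <- manual + w * arr[1 + dx, 1 + dy, 1 + dz]
    }
    expect_equal(interp_volume(vol, matrix(p, 1)), manual, tolerance = 1e-12)
  }
})

test_that("fit_profile recovers the generating model exactly without noise", {
  for (gap in c(1.5, 3, 5)) for (sigma in c(0.6, 1.2)) {
    pr <- model_profile(gap, sigma)
    ft <- fit_profile(pr, y_c = 1000)
    expect_true(ft$converged)
    expect_lt(abs(ft$model$e2 - 0), 1e-3)
    expect_lt(abs(ft$model$e3 - gap), 1e-3)
    expect_lt(abs(ft$jsw_mm - gap), 1e-3)
  }
})

test_that("monotone identifiability: noise-free gaps >= 0.5 sigma come back exactly", {
  for (sigma in c(0.5, 1.0, 1.5)) {
    for (gap in pmax(0.5 * sigma, c(0.5, 0.8, 1.2, 2, 4))) {
      ft <- fit_profile(model_profile(gap, sigma), y_c = 1000)
      expect_lt(abs(ft$jsw_mm - gap), 1e-3)
    }
  }
})

test_that("sub-PSF gap with noise is fit to within 0.15 mm and matches the grid oracle", {
  set.seed(11)
  pr <- model_profile(1.2, 1.0, noise_sd = 12.5)  # noise 1.25% of plateau
  ft <- fit_profile(pr, y_c = 1000)
  expect_true(ft$converged)
  expect_lt(abs(ft$jsw_mm - 1.2), 0.15)
  gr <- fit_profile_grid(pr, y_c = 1000, sigma = ft$model$sigma_mm,
                         plate_mm = ft$model$e2 - ft$model$e1)
  expect_lt(abs(gr$jsw_mm - ft$jsw_mm), 0.1)
})

test_that("deconvolution beats half-plateau full-width on sub-PSF gaps", {
  set.seed(5)
  sigma <- 1.2
  errs_fit <- errs_naive <- c()
  for (gap in c(1.4, 1.8, 2.2)) for (r in 1:4) {  # all gaps < 2 sigma
    pr <- model_profile(gap, sigma, noise_sd = 12.5)
    ft <- fit_profile(pr, y_c = 1000)
    errs_fit <- c(errs_fit, ft$jsw_mm - gap)
    errs_naive <- c(errs_naive, naive_halfwidth_jsw(pr, 1000) - gap)
  }
  expect_lt(mean(abs(errs_fit)), mean(abs(errs_naive)))
})

test_that("patch density estimation is a robust median of first-pass plateaus", {
  set.seed(3)
  profs <- lapply(1:30, function(i) model_profile(3, 0.8, noise_sd = 8))
  est <- estimate_patch_density(profs, min_converged = 10)
  expect_lt(abs(est$y_c - 1000) / 1000, 0.02)
  # degenerate: identical profiles give that plateau back
  profs_same <- lapply(1:12, function(i) model_profile(3, 0.8))
  est2 <- estimate_patch_density(profs_same, min_converged = 10)
  expect_lt(abs(est2$y_c - 1000), 1)
  # outlier robustness: inject gross outliers into 10% of profiles
  profs_out <- profs
  for (i in 1:3) profs_out[[i]]$values <- profs_out[[i]]$values * 2
  est3 <- estimate_patch_density(profs_out, min_converged = 10)
  expect_lt(abs(est3$y_c - est$y_c) / est$y_c, 0.03)
  # too few convergences errors with the count
  expect_error(estimate_patch_density(profs[1:3], min_converged = 10),
               "first-pass fits converged")
})

test_that("non-convergence is reported, never thrown", {
  junk <- structure(list(offsets_mm = seq(-1, 1, 0.2),
                         values = rep(0, 11)), class = "density_profile")
  ft <- fit_profile(junk, y_c = 1000)
  expect_false(ft$converged)
  expect_true(is.na(ft$jsw_mm))
})
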