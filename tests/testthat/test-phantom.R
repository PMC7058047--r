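test_that("unblurred noiseless flat slab reproduces the piecewise densities", {
  sp <- phantom_spec(gap_mm = 3, psf_sigma_mm = 0, noise_sd = 0)
  ph <- make_phantom_volume(sp, seed = 1)
  vals <- sort(unique(as.vector(ph$volume$data)))
  expect_true(all(vals %in% c(sp$background_density, sp$gap_density, sp$plate_density)))
  # gap voxels present along z around the recorded gap start
  z <- (seq_len(dim(ph$volume$data)[3]) - 1) * sp$voxel_size_mm[3]
  mid <- which(z > ph$gap_start_mm & z < ph$gap_start_mm + sp$gap_mm)
  expect_true(all(ph$volume$data[5, 5, mid] == sp$gap_density))
})

test_that("flat-slab edge positions are voxel-accurate without blur or noise", {
  sp <- phantom_spec(gap_mm = 2.5, psf_sigma_mm = 0, noise_sd = 0)
  ph <- make_phantom_volume(sp, seed = 1)
  z <- (seq_len(dim(ph$volume$data)[3]) - 1) * sp$voxel_size_mm[3]
  prof <- ph$volume$data[3, 3, ]
  gap_idx <- which(prof == sp$gap_density)
  # each interface lies between the flanking voxel centres, i.e. within half
  # a voxel of the midpoint estimate
  lo_est <- (z[min(gap_idx) - 1] + z[min(gap_idx)]) / 2
  hi_est <- (z[max(gap_idx)] + z[max(gap_idx) + 1]) / 2
  expect_lt(abs(lo_est - ph$gap_start_mm), sp$voxel_size_mm[3] / 2 + 1e-9)
  expect_lt(abs(hi_est - (ph$gap_start_mm + sp$gap_mm)),
            sp$voxel_size_mm[3] / 2 + 1e-9)
})

test_that("spherical-shell radial profile matches a dense radial convolution oracle", {
  sp <- phantom_spec(gap_mm = 3, psf_sigma_mm = 1.0, noise_sd = 0,
                     geometry = "spherical-shell", head_radius_mm = 18)
  ph <- make_phantom_volume(sp, seed = 1)
  ctr <- ph$center
  d <- dim(ph$volume$data)
  vs <- sp$voxel_size_mm
  # voxel-centre samples along +x through the (nearest-voxel) centre
  j0 <- which.min(abs((seq_len(d[2]) - 1) * vs[2] - ctr[2]))
  k0 <- which.min(abs((seq_len(d[3]) - 1) * vs[3] - ctr[3]))
  oy <- (j0 - 1) * vs[2] - ctr[2]; oz <- (k0 - 1) * vs[3] - ctr[3]
  xw <- (seq_len(d[1]) - 1) * vs[1]
  rr <- sqrt((xw - ctr[1])^2 + oy^2 + oz^2)
  sel <- which(xw - ctr[1] > 12 & xw - ctr[1] < 27)
  vals <- ph$volume$data[sel, j0, k0]
  # oracle: dense numerical 1D (radial) convolution of the step model with
  # the Gaussian kernel in spherical geometry,
  #   (G * f)(r) = (1/r) int r' f(r') [g(r - r') - g(r + r')] dr',
  # with the voxel-box and discrete-tap variances folded into sigma
  sig <- sqrt(sp$psf_sigma_mm^2 + 2 * vs[1]^2 / 12)
  rp <- seq(0.01, 45, by = 0.01)
  f <- jsmapr:::plate_profile(sp, rp - sp$head_radius_mm)
  oracle <- vapply(rr[sel], function(r) {
    w <- (rp / r) * (dnorm(r - rp, 0, sig) - dnorm(r + rp, 0, sig))
    sum(f * w) * 0.01
  }, numeric(1))
  expect_gt(cor(vals, oracle), 0.995)
  expect_lt(max(abs(vals - oracle)),
            0.05 * (sp$plate_density - sp$gap_density))
})

test_that("default phantom uses the study voxel sizes and seeds reproduce", {
  sp <- phantom_spec()
  expect_equal(sp$voxel_size_mm, c(0.977, 0.977, 1.0))
  a <- make_phantom_volume(sp, seed = 7)
  b <- make_phantom_volume(sp, seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  c <- make_phantom_volume(sp, seed = 8)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("too-small volumes error naming the limiting dimension", {
  sp <- phantom_spec(gap_mm = 3, psf_sigma_mm = 1.5)
  expect_error(make_phantom_volume(sp, seed = 1, dim_vox = c(30, 30, 6)),
               "along z")
  sp2 <- phantom_spec(geometry = "spherical-shell", head_radius_mm = 18)
  expect_error(make_phantom_volume(sp2, seed = 1, dim_vox = c(20, 60, 60)),
               "along x")
  expect_error(phantom_spec(gap_mm = -1))
  expect_error(phantom_spec(plate_density = 10, gap_density = 50))
})
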