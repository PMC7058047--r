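can <- small_canonical()

test_that("ICP: self-registration is the identity", {
  tr <- icp_similarity(can, can)
  expect_equal(tr$scale, 1, tolerance = 1e-6)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(tr$rms, 1e-8)
})

test_that("ICP recovers a known similarity to 1e-3 relative", {
  ang <- 10 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  tgt <- can
  tgt$vertices <- sweep(1.1 * can$vertices %*% t(R), 2, c(5, -3, 2), `+`)
  tgt$normals <- jsmapr:::vertex_normals(tgt)
  tr <- icp_similarity(can, tgt)
  expect_lt(abs(tr$scale - 1.1) / 1.1, 1e-3)
  expect_lt(max(abs(tr$rotation - R)), 1e-3)
  expect_lt(max(abs(tr$translation - c(5, -3, 2))) / 6.2, 1e-3)
  # oracle: closed-form Procrustes on the true correspondences
  or <- jsmapr:::umeyama(can$vertices, tgt$vertices)
  expect_lt(abs(tr$scale - or$scale) / or$scale, 1e-3)
  # pure scaling recovered exactly
  tgt2 <- can; tgt2$vertices <- 2 * can$vertices
  tr2 <- icp_similarity(can, tgt2)
  expect_equal(tr2$scale, 2, tolerance = 1e-6)
})

test_that("TPS reproduces an affine map with non-coplanar controls (zero bending)", {
  set.seed(4)
  A <- diag(3) + matrix(rnorm(9, 0, 0.04), 3)
  b <- c(1, -2, 0.5)
  ctrl <- can$vertices[sample(n_vertices(can), 60), ]
  disp <- sweep(ctrl %*% t(A), 2, b, `+`) - ctrl
  sol <- jsmapr:::tps_solve(ctrl, disp)
  got <- jsmapr:::tps_eval(sol, can$vertices)
  truth <- sweep(can$vertices %*% t(A), 2, b, `+`) - can$vertices
  expect_lt(max(abs(got - truth)), 1e-6)
  expect_lt(max(abs(sol$w)), 1e-8)  # zero bending: kernel weights vanish
  # interpolation property at the controls
  expect_lt(max(abs(jsmapr:::tps_eval(sol, ctrl) - disp)), 1e-9)
})

test_that("tps_warp with identical surfaces is (near) zero displacement", {
  rp <- rim_correspondence(can, can, n_pairs = 40)
  expect_lt(max(abs(rp$source - rp$target)), 1e-9)
  wf <- tps_warp(can, can, rp)
  expect_lt(max(abs(wf$displacement)), 1e-6)
})

test_that("full registration recovers known warps of the canonical fixture", {
  set.seed(1)
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  tgt <- can
  tgt$vertices <- sweep(can$vertices %*% t(A), 2, c(1, -2, 0.5), `+`)
  tgt$normals <- jsmapr:::vertex_normals(tgt)
  reg <- register_hip(can, tgt)
  # point-to-plane distance to the target surface (correspondence itself is
  # ill-posed under tangential sliding)
  nn <- jsmapr:::nearest_vertex(tgt$vertices, reg$warped)
  d <- abs(rowSums((reg$warped - tgt$vertices[nn, ]) * tgt$normals[nn, ]))
  expect_lt(sqrt(mean(d^2)), 0.1)

  # a known smooth TPS warp of the canonical surface
  set.seed(3)
  ctrl <- can$vertices[sample(n_vertices(can), 12), ]
  sol <- jsmapr:::tps_solve(ctrl, matrix(rnorm(36, 0, 1), 12, 3))
  tgt2 <- can
  tgt2$vertices <- can$vertices + jsmapr:::tps_eval(sol, can$vertices)
  tgt2$normals <- jsmapr:::vertex_normals(tgt2)
  reg2 <- register_hip(can, tgt2)
  nn2 <- jsmapr:::nearest_vertex(tgt2$vertices, reg2$warped)
  d2 <- abs(rowSums((reg2$warped - tgt2$vertices[nn2, ]) * tgt2$normals[nn2, ]))
  expect_lt(sqrt(mean(d2^2)), 0.1)
})

test_that("scalar transfer matches brute-force nearest neighbour and preserves constants", {
  set.seed(2)
  src <- can
  src$vertices <- can$vertices + matrix(rnorm(3 * n_vertices(can), 0, 0.1),
                                        ncol = 3)
  vals <- rnorm(n_vertices(src))
  got <- transfer_scalars(src, vals, can, fwhm_mm = 0)
  # brute-force oracle
  for (i in sample(n_vertices(can), 25)) {
    d <- colSums((t(src$vertices) - can$vertices[i, ])^2)
    expect_identical(got[i], vals[which.min(d)])
  }
  const <- transfer_scalars(src, rep(4.2, n_vertices(src)), can, fwhm_mm = 5)
  expect_lt(max(abs(const - 4.2)), 1e-9)
  # identical surfaces copy values verbatim before smoothing
  expect_identical(transfer_scalars(can, vals, can, fwhm_mm = 0), vals)
})

test_that("mirroring is an involution, keeps normals outward, right is identity", {
  m2 <- mirror_hip(mirror_hip(can, "left"), "left")
  expect_lt(max(abs(m2$vertices - can$vertices)), 1e-12)
  expect_identical(mirror_hip(can, "right"), can)
  expect_error(mirror_hip(can, "up"), "unknown side")
  ml <- mirror_hip(can, "left")
  ctr <- colMeans(ml$vertices)
  out_frac <- mean(rowSums(ml$normals * sweep(ml$vertices, 2, ctr)) > 0)
  expect_gt(out_frac, 0.95)
})

test_that("side-difference maps follow the replaced-minus-opposite rule", {
  V <- 30
  meta <- tibble::tibble(individual_id = rep(c("a", "b", "c"), each = 2),
                         side = rep(c("left", "right"), 3),
                         thr = c(0, 1, 1, 1, 0, 0))  # a: right THR; b: bilateral; c: control
  maps <- matrix(rep(c(3, 2, 5, 4, 6, 6), each = V), nrow = 6, byrow = TRUE)
  sd1 <- side_difference_map(maps, meta, seed = 9)
  # a: replaced (right, value 2) minus opposite (3) = -1 everywhere
  expect_equal(unname(sd1$diff[sd1$individual_id == "a", ]), rep(-1, V))
  # c: identical sides -> zero
  expect_equal(unname(sd1$diff[sd1$individual_id == "c", ]), rep(0, V))
  # determinism under the same seed, including random choices for b
  sd2 <- side_difference_map(maps, meta, seed = 9)
  expect_identical(sd1$diff, sd2$diff)
  # missing side excluded
  sd3 <- side_difference_map(maps[-1, ], meta[-1, ], seed = 1)
  expect_true("a" %in% sd3$excluded)
})
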