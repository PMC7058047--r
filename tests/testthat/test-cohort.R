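test_that("simulation is reproducible and honours expected group sizes", {
  can <- tiny_canonical()
  a <- simulate_cohort(cohort_spec(), can, seed = 1)
  b <- simulate_cohort(cohort_spec(), can, seed = 1)
  expect_identical(a$maps, b$maps)
  expect_identical(a$cohort, b$cohort)
  expect_false(identical(a$maps, simulate_cohort(cohort_spec(), can, seed = 2)$maps))
  # expected case fraction ~ 80/267 across seeds
  frac <- sapply(1:12, function(s) {
    sim <- simulate_cohort(cohort_spec(), can, seed = s, with_maps = FALSE,
                           with_fields = FALSE)
    mean(dplyr::summarise(dplyr::group_by(sim$cohort, individual_id),
                          case = any(thr == 1), .groups = "drop")$case)
  })
  expect_lt(abs(mean(frac) - 80 / 267), 0.03)
})

test_that("cohort table has the contract columns with ordinal KL", {
  sim <- simulate_cohort(cohort_spec(), tiny_canonical(), seed = 2)
  co <- make_cohort_table(sim)
  expect_named(co, c("individual_id", "side", "thr", "hp", "kl", "min2d_mm",
                     "age", "sex", "bmi"))
  expect_true(all(co$kl %in% 0:4))
  expect_true(all(co$side %in% c("left", "right")))
  expect_equal(nrow(co), 2 * 267)
  # min2D correlates with superior-region narrowing (noisy surrogate)
  sup <- rowMeans(sim$maps[, sim$truth$superior_window > 0.25])
  expect_gt(cor(co$min2d_mm, sup), 0.5)
})

test_that("side correlation of coefficients matches the specified R", {
  spec <- cohort_spec(side_correlation_R = 0.5)
  Rs <- sapply(1:8, function(s) {
    sim <- simulate_cohort(spec, tiny_canonical(), seed = s,
                           with_maps = FALSE, with_fields = FALSE)
    l <- sim$coefficients[sim$cohort$side == "left", 1]
    r <- sim$coefficients[sim$cohort$side == "right", 1]
    cor(l, r)
  })
  expect_lt(abs(mean(Rs) - 0.5), 0.06)
})

test_that("null narrowing gives no group difference; planted effect converges ~1/sqrt(n)", {
  can <- tiny_canonical()
  null_spec <- cohort_spec(narrowing_max_mm = 0, widening_post_mm = 0,
                           mode_log_or = 0)
  sim <- simulate_cohort(null_spec, can, seed = 3)
  case <- sim$cohort$thr == 1
  diff0 <- colMeans(sim$maps[case, , drop = FALSE]) -
    colMeans(sim$maps[!case, , drop = FALSE])
  se <- sqrt(var(sim$maps[1, ]) / sum(case))
  expect_lt(max(abs(diff0)), 8 * se + 0.3)
  # planted 1 mm narrowing: Monte-Carlo mean difference at the peak ~ -1
  spec <- cohort_spec()
  diffs <- sapply(1:6, function(s) {
    sm <- simulate_cohort(spec, can, seed = s + 10)
    am <- average_paired_maps(sm$maps, sm$cohort$individual_id)
    ind_case <- sapply(am$individual_id, function(id)
      any(sm$cohort$thr[sm$cohort$individual_id == id] == 1))
    min(colMeans(am$values[ind_case, ]) - colMeans(am$values[!ind_case, ]))
  })
  expect_lt(abs(mean(diffs) - (-1)), 0.2)
})

test_that("paired hip surfaces: mirrored lefts, planted truth field, degeneracy guard", {
  spec <- cohort_spec(n_cases = 2, n_controls = 2)
  hips <- make_paired_hip_surfaces(spec, n_individuals = 4, n_theta = 10,
                                   n_phi = 20, seed = 4)
  expect_equal(nrow(hips), 8)
  # right and left cups of one individual mirror in geometry scale
  h1 <- hips[hips$individual_id == "I003", ]   # a control: no planted effect
  r <- h1$acetabulum[h1$side == "right"][[1]]
  l <- h1$acetabulum[h1$side == "left"][[1]]
  expect_equal(dim(l$vertices), dim(r$vertices))
  expect_equal(sort(abs(l$vertices[, 1])), sort(abs(r$vertices[, 1])),
               tolerance = 0.5)
  # truth field equals cup-to-head distance along radii by construction
  fem <- h1$femur[h1$side == "right"][[1]]
  r_head <- sqrt(sum(fem$vertices[1, ]^2))
  cup_r <- sqrt(rowSums(r$vertices^2))
  expect_equal(cup_r - r_head, h1$jsw_truth[h1$side == "right"][[1]],
               tolerance = 1e-9)
  # degenerate geometry errors
  bad <- cohort_spec(base_jsw_mm = 0.1, narrowing_max_mm = 1.5)
  expect_error(make_paired_hip_surfaces(bad, n_individuals = 2, seed = 1),
               "degenerate")
})

test_that("patch size at study-like resolution falls in the reported range", {
  spec <- cohort_spec(n_cases = 0, n_controls = 1)
  hips <- make_paired_hip_surfaces(spec, n_individuals = 1, n_theta = 24,
                                   n_phi = 72, seed = 5)
  fem <- hips$femur[[1]]; cup <- hips$acetabulum[[1]]
  patch <- extract_joint_patch(fem, cup, max_gap_mm = 10)
  expect_gte(n_vertices(patch), 1250)
  expect_lte(n_vertices(patch), 3500)
})
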