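test_that("min3D is min over ROI divided by global mean", {
  jsw <- c(2, 4, 6, 4)
  expect_equal(min3d_feature(jsw, roi = c(1, 2)), 2 / 4)
  expect_equal(min3d_feature(rep(3, 10), roi = 1:3), 1)
  set.seed(1)
  v <- runif(50, 1, 6); roi <- sample(50, 12)
  expect_equal(min3d_feature(v, roi), min(v[roi]) / mean(v))
  expect_error(min3d_feature(v, integer(0)), "empty ROI")
})

test_that("AUC is the midrank Mann-Whitney statistic (pair-count oracle, pROC)", {
  # printed toy: all case scores above all control scores
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  # total ties -> 0.5
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  set.seed(2)
  sc <- rnorm(60); y <- rbinom(60, 1, 0.5)
  got <- roc_auc(sc, y)$auc
  # exhaustive pair counting
  pairs <- outer(sc[y == 1], sc[y == 0], `-`)
  oracle <- mean((pairs > 0) + 0.5 * (pairs == 0))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-12)
  # monotone-transform invariance
  expect_equal(roc_auc(exp(sc * 2), y)$auc, got, tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(1, 60)), "both")
})

test_that("LOO scores: separable data give AUC 1, label shuffles give ~0.5", {
  set.seed(3)
  n <- 60
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  y <- rep(c(0, 1), each = n / 2)
  sc <- loo_cv_scores(data.frame(x = x), y)
  expect_equal(roc_auc(sc, y)$auc, 1)
  # null calibration over label shuffles; pooled LOO scores are known to be
  # slightly pessimistic at finite n (the held-out sample's own class is
  # under-represented in its fold), so the band allows a small downward shift
  n2 <- 300
  aucs <- replicate(25, {
    ys <- sample(rep(0:1, n2 / 2))
    roc_auc(loo_cv_scores(data.frame(x = rnorm(n2)), ys), ys)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("LOO AUC approaches the closed-form binormal value", {
  set.seed(4)
  n <- 800; d <- 1
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n, mean = d * y)
  sc <- loo_cv_scores(data.frame(x = x), y)
  expect_lt(abs(roc_auc(sc, y)$auc - pnorm(d / sqrt(2))), 0.03)
})

test_that("model ladder reports AUCs and relative improvement vs min2D", {
  can <- tiny_canonical()
  sim <- simulate_cohort(cohort_spec(), can, seed = 6, with_fields = FALSE)
  co <- sim$cohort
  # individual-level feature table
  am <- average_paired_maps(sim$maps, co$individual_id)
  ac <- average_paired_maps(sim$coefficients, co$individual_id)
  meta <- dplyr::summarise(dplyr::group_by(co, individual_id),
                           thr = as.integer(any(thr == 1)), hp = max(hp),
                           kl = max(kl), min2d = min(min2d_mm),
                           .groups = "drop")
  meta <- meta[match(am$individual_id, meta$individual_id), ]
  roi <- sim$truth$superior_window >= 0.5
  feats <- data.frame(hp = meta$hp, kl = meta$kl, min2d = meta$min2d,
                      min3d = apply(am$values, 1, min3d_feature, roi = roi),
                      ac$values[, 1:7])
  rep_tab <- model_comparison_report(feats, meta$thr)
  expect_true(all(c("HP", "KL", "min2D", "SM", "min3D", "3D + KL") %in%
                    rep_tab$model))
  expect_true(all(rep_tab$auc[rep_tab$model != "HP"] > 0.55))
  expect_gt(rep_tab$auc[rep_tab$model == "3D + KL"], rep_tab$auc[rep_tab$model == "SM"])
  expect_equal(rep_tab$improvement_vs_min2d_pct[rep_tab$model == "min2D"], 0)
  # missing column skips with warning
  expect_warning(model_comparison_report(feats[, -1], meta$thr), "skipping")
})

test_that("the improvement convention reproduces printed arithmetic", {
  expect_equal(auc_improvement_pct(0.86, 0.73), 18)
  expect_equal(auc_improvement_pct(0.5, 0.5), 0)
})
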