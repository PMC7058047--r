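#' Relative minimum 3D JSW feature (min3D)
#'
#' The single 3D severity parameter carried into prediction: the minimum JSW
#' within the SPM-significant region of interest divided by the global mean
#' JSW over the whole map.
#'
#' @param jsw values per canonical vertex (vector), or a `jsw_map`.
#' @param roi logical/integer vertex subset (nonempty).
#' @return scalar min(ROI) / mean(all).
#' @export
min3d_feature <- function(jsw, roi) {
  if (inherits(jsw, "jsw_map")) jsw <- jsw$jsw_mm
  if (is.logical(roi)) roi <- which(roi)
  if (!length(roi)) stop("empty ROI")
  min(jsw[roi]) / mean(jsw)
}

#' Leave-one-out cross-validated risk scores
#'
#' For each individual, a logistic regression is fitted on all other
#' individuals and the held-out one is scored; deterministic given the data.
#' Quasi-separation (non-finite or exploding ML fit) falls back to a ridge
#' penalised fit for that fold, flagged in the result.
#'
#' @param features data frame of predictors (one row per individual).
#' @param outcome binary vector (0/1).
#' @param feature_subset character vector of columns to use (default all).
#' @return numeric scores (linear predictor) with attribute `"penalised"`
#'   marking folds that needed the fallback.
#' @export
loo_cv_scores <- function(features, outcome, feature_subset = names(features)) {
  stopifnot(length(feature_subset) > 0)
  X <- as.data.frame(features)[, feature_subset, drop = FALSE]
  n <- nrow(X)
  stopifnot(n >= 10, length(outcome) == n)
  Xm <- as.matrix(X)
  scores <- numeric(n)
  pen <- logical(n)
  for (i in seq_len(n)) {
    xtr <- Xm[-i, , drop = FALSE]; ytr <- outcome[-i]
    fit <- suppressWarnings(stats::glm.fit(cbind(1, xtr), ytr,
                                           family = stats::binomial()))
    cf <- fit$coefficients
    if (any(!is.finite(cf)) || max(abs(cf)) > 50) {
      cf <- ridge_logit(cbind(1, xtr), ytr, lambda = 1e-3)
      pen[i] <- TRUE
    }
    # score without the fold intercept: under leave-one-out the intercept
    # carries a class-imbalance artifact (the held-out sample's own class is
    # under-represented in its training fold) that drags pooled null AUC
    # well below 0.5; the covariate part is what ranks individuals
    scores[i] <- sum(Xm[i, ] * cf[-1])
  }
  structure(scores, penalised = pen)
}

# Small ridge-penalised logistic fit by Newton iterations (separation
# fallback; lambda on all but the intercept).
ridge_logit <- function(X, y, lambda = 1e-3, max_iter = 100) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(as.vector(X %*% beta))
    W <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X, X * W) + pen
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' AUC is the midrank Mann-Whitney estimate (ties counted half), with the
#' full sensitivity/specificity curve over the observed thresholds.
#'
#' @param scores numeric risk scores.
#' @param outcome binary labels (0/1), both classes present.
#' @return a `roc_result`: list with `auc`, `thresholds`, `sensitivity`,
#'   `specificity`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[outcome == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[outcome == 0] < t), numeric(1))
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 specificity = spec, n_cases = n1, n_controls = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d cases, %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' @rdname roc_auc
#' @param x a `roc_result`.
#' @param ... unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @rdname roc_auc
#' @param object a `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Cross-validated AUC ladder across feature sets
#'
#' Evaluates the standard model ladder — hip pain; KL grade; minimum 2D JSW;
#' shape modes SM1-7; min3D; the combined 3D set (min3D + shape modes); and
#' 3D + KL — each by leave-one-out cross-validated logistic regression, and
#' reports each model's AUC with its relative improvement (%) over the
#' minimum-2D-JSW baseline: `round(100 * (auc - auc_min2d) / auc_min2d)`.
#'
#' @param features per-individual data frame with columns `hp`, `kl`,
#'   `min2d`, `min3d` and `SM1..SM7` (missing columns skip their models with
#'   a warning).
#' @param outcome binary vector.
#' @param models optional named list of character vectors overriding the
#'   ladder.
#' @return tibble: `model`, `features`, `auc`,
#'   `improvement_vs_min2d_pct`.
#' @export
model_comparison_report <- function(features, outcome, models = NULL) {
  sm_cols <- grep("^SM[0-9]+$", names(features), value = TRUE)
  if (is.null(models))
    models <- list(
      HP = "hp", KL = "kl", min2D = "min2d", SM = sm_cols, min3D = "min3d",
      `3D (min3D + SM)` = c("min3d", sm_cols),
      `3D + KL` = c("min3d", sm_cols, "kl"))
  out <- list()
  for (nm in names(models)) {
    cols <- models[[nm]]
    if (!all(cols %in% names(features))) {
      warning("skipping model ", nm, ": missing column(s) ",
              paste(setdiff(cols, names(features)), collapse = ", "))
      next
    }
    sc <- loo_cv_scores(features, outcome, cols)
    out[[nm]] <- tibble::tibble(model = nm,
                                features = paste(cols, collapse = "+"),
                                auc = roc_auc(sc, outcome)$auc)
  }
  res <- dplyr::bind_rows(out)
  base <- res$auc[res$model == "min2D"]
  res$improvement_vs_min2d_pct <- if (length(base) == 1)
    round(100 * (res$auc - base) / base) else NA_real_
  res
}

#' Relative improvement between two AUC values
#'
#' The reporting convention used throughout: percent improvement of a model
#' AUC over a baseline AUC, rounded to the nearest integer.
#'
#' @param auc_model,auc_baseline AUC values.
#' @return integer percent.
#' @export
auc_improvement_pct <- function(auc_model, auc_baseline) {
  round(100 * (auc_model - auc_baseline) / auc_baseline)
}
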