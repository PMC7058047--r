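#' Effective SD of a coefficient under paired-hip clustering
#'
#' Two hips from one individual are correlated, so `n` hips carry fewer than
#' `n` independent observations. Each hip is weighted `1/(1 + R)`, where `R`
#' is the correlation between the left and right coefficients within
#' individuals: with `R = 0` hips count fully (weight 1), with `R = 1` a pair
#' counts as one hip (weight 1/2). The adjusted SD uses the weighted
#' effective sample size `n_eff = sum(w)` in its denominator:
#' `adjusted_sd = sqrt(sum((x - mean(x))^2) / (n_eff - 1))`.
#'
#' @param coefficients numeric vector, one value per hip.
#' @param individual_ids individual identifier per hip.
#' @param sides `"left"`/`"right"` per hip.
#' @return list: `raw_sd`, `R`, `weight` (= 1/(1+R)), `n_eff`, `adjusted_sd`.
#' @export
effective_sd <- function(coefficients, individual_ids, sides) {
  x <- coefficients
  raw_sd <- stats::sd(x)
  df <- tibble::tibble(x = x, id = individual_ids, side = sides)
  wide <- tidyr::pivot_wider(df, id_cols = "id", names_from = "side",
                             values_from = "x", values_fn = mean)
  complete <- !is.na(wide$left) & !is.na(wide$right)
  if (sum(complete) < 3) {
    warning("no (or too few) complete left/right pairs; using raw SD")
    return(list(raw_sd = raw_sd, R = NA_real_, weight = 1,
                n_eff = length(x), adjusted_sd = raw_sd))
  }
  R <- stats::cor(wide$left[complete], wide$right[complete])
  R <- max(min(R, 1), 0)
  w <- 1 / (1 + R)
  n_eff <- w * length(x)
  adjusted_sd <- sqrt(sum((x - mean(x))^2) / (n_eff - 1))
  list(raw_sd = raw_sd, R = R, weight = w, n_eff = n_eff,
       adjusted_sd = adjusted_sd)
}

# Logistic GEE with exchangeable working correlation and robust (sandwich)
# covariance. Written out directly: iterate quasi-scoring updates for beta,
# re-estimating the exchangeable correlation alpha from Pearson residuals.
gee_logit <- function(X, y, id, max_iter = 50, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
  clusters <- split(seq_along(y), id)
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    r <- (y - mu) / sqrt(v)
    # exchangeable alpha: average product of within-cluster residual pairs
    num <- 0; npairs <- 0
    for (cl in clusters) {
      if (length(cl) > 1) {
        rc <- r[cl]
        num <- num + (sum(rc)^2 - sum(rc^2)) / 2
        npairs <- npairs + choose(length(cl), 2)
      }
    }
    alpha <- if (npairs > p) num / (npairs - p) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    U <- numeric(p)
    H <- matrix(0, p, p)
    for (cl in clusters) {
      ni <- length(cl)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Ai <- sqrt(v[cl])
      D <- X[cl, , drop = FALSE] * v[cl]
      Vinv <- solve(Ri * tcrossprod(Ai))
      U <- U + crossprod(D, Vinv %*% (y[cl] - mu[cl]))
      H <- H + crossprod(D, Vinv %*% D)
    }
    step <- solve(H, U)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  # robust sandwich covariance
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  H <- matrix(0, p, p); M <- matrix(0, p, p)
  for (cl in clusters) {
    ni <- length(cl)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Ai <- sqrt(v[cl])
    D <- X[cl, , drop = FALSE] * v[cl]
    Vinv <- solve(Ri * tcrossprod(Ai))
    ui <- crossprod(D, Vinv %*% (y[cl] - mu[cl]))
    M <- M + tcrossprod(ui)
    H <- H + crossprod(D, Vinv %*% D)
  }
  Hinv <- solve(H)
  # small-sample cluster correction m/(m - p) on the sandwich
  m <- length(clusters)
  vcov <- Hinv %*% M %*% Hinv * m / max(m - p, 1)
  list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
       vcov = vcov, alpha = alpha, converged = iter < max_iter, n_iter = iter)
}

#' GEE odds ratios for future THR per adjusted-SD of shape-mode coefficients
#'
#' Fits a logit-link generalised estimating equation with exchangeable
#' working correlation and robust standard errors: one row per hip, clusters
#' are individuals, outcome is THR within follow-up, covariates are age, BMI
#' and the first `n_modes` shape-mode coefficients. Each mode is scaled by
#' its paired-hip adjusted SD ([effective_sd()]), so its OR is per
#' adjusted-SD increment. Significance is Bonferroni-corrected:
#' `p < alpha / bonferroni_factor` (default 0.05/18, i.e. p < 0.003 for 16
#' modes plus age and BMI).
#'
#' Sex is excluded by default: it is strongly collinear with the leading
#' scale mode, whose coefficient therefore carries its effect.
#'
#' @param cohort tibble with one row per hip: `individual_id`, `side`, `thr`
#'   (0/1), `age`, `bmi` (and anything else, ignored).
#' @param coefficients matrix/data frame of shape-mode coefficients
#'   (`SM1..SMK`), rows aligned with `cohort`.
#' @param covariates character vector of cohort columns to adjust for.
#' @param n_modes number of leading modes to report.
#' @param alpha nominal significance level.
#' @param bonferroni_factor number of tests corrected for.
#' @param include_sex add `sex` to the covariates.
#' @return a `gee_or` object; `tidy()` gives the Table-2-style tibble with
#'   columns `term`, `or`, `lo95`, `hi95`, `p_value`, `significant`.
#' @export
gee_odds_ratios <- function(cohort, coefficients, covariates = c("age", "bmi"),
                            n_modes = 7, alpha = 0.05, bonferroni_factor = 18,
                            include_sex = FALSE) {
  coefficients <- as.matrix(coefficients)
  stopifnot(nrow(cohort) == nrow(coefficients))
  if (include_sex) covariates <- union(covariates, "sex")
  n_modes <- min(n_modes, ncol(coefficients))
  sm_names <- colnames(coefficients)[seq_len(n_modes)]
  if (is.null(sm_names)) sm_names <- paste0("SM", seq_len(n_modes))
  sds <- lapply(seq_len(n_modes), function(k)
    effective_sd(coefficients[, k], cohort$individual_id, cohort$side))
  Xs <- sapply(seq_len(n_modes), function(k)
    (coefficients[, k] - mean(coefficients[, k])) / sds[[k]]$adjusted_sd)
  colnames(Xs) <- sm_names
  Z <- as.matrix(cohort[, covariates, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, Z, Xs)
  fit <- gee_logit(X, cohort$thr, cohort$individual_id)
  se <- sqrt(diag(fit$vcov))
  est <- fit$coefficients
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  keep <- setdiff(names(est), "(Intercept)")
  thr_p <- alpha / bonferroni_factor
  res <- tibble::tibble(
    term = keep,
    or = exp(est[keep]),
    lo95 = exp(est[keep] - 1.96 * se[keep]),
    hi95 = exp(est[keep] + 1.96 * se[keep]),
    p_value = pv[keep],
    significant = pv[keep] < thr_p
  )
  structure(list(results = res, fit = fit, effective_sds = sds,
                 alpha = alpha, bonferroni_factor = bonferroni_factor,
                 threshold = thr_p, n = nrow(cohort),
                 n_individuals = length(unique(cohort$individual_id))),
            class = "gee_or")
}

#' @export
print.gee_or <- function(x, ...) {
  cat(sprintf("<gee_or> %d hips / %d individuals; significance p < %.4g\n",
              x$n, x$n_individuals, x$threshold))
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-12s %.2f (%.2f-%.2f)  p=%.3g%s\n", r$term[i], r$or[i],
                r$lo95[i], r$hi95[i], r$p_value[i],
                if (r$significant[i]) " *" else ""))
  invisible(x)
}

#' @rdname gee_odds_ratios
#' @param x a `gee_or` object.
#' @param ... unused.
#' @export
tidy.gee_or <- function(x, ...) x$results

#' @rdname gee_odds_ratios
#' @export
glance.gee_or <- function(x, ...) {
  tibble::tibble(n_hips = x$n, n_individuals = x$n_individuals,
                 alpha = x$alpha, bonferroni_factor = x$bonferroni_factor,
                 threshold = x$threshold,
                 working_correlation = x$fit$alpha,
                 converged = x$fit$converged)
}

#' Odds-ratio forest plot
#' @param object a `gee_or` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gee_or <- function(object, ...) {
  d <- object$results
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo95, xmax = .data$hi95),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio per adjusted SD (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
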