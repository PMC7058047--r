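#' Cohort simulation specification
#'
#' Describes the synthetic nested case-control cohort: expected group sizes,
#' planted regional JSW effects, between-side correlation, planted shape-mode
#' structure and per-SD log odds ratios for the outcome. Defaults follow the
#' clinical study the pipeline targets: 80 expected THR case individuals and
#' 187 controls, superior narrowing up to 1 mm in cases, posterior widening
#' of 0.75 mm on the replaced side, and per-SD odds ratios for the first
#' seven shape modes of 1.43, 1.75, 1.37, 1.02, 0.88, 1.39, 1.18.
#'
#' @param n_cases,n_controls expected numbers of case / control individuals.
#' @param frac_bilateral fraction of case individuals with both hips replaced
#'   (used by the quota-based surface generator).
#' @param narrowing_max_mm peak case-vs-control narrowing of the
#'   individual-averaged superior joint space (mm). The replaced hip carries
#'   1.5x this peak and the contralateral case hip 0.5x, so the averaged
#'   group difference and the replaced-minus-opposite asymmetry both attain
#'   the stated peak.
#' @param widening_post_mm posterior widening planted on the replaced hip
#'   only (mm), so it appears at full size in side-difference maps.
#' @param side_correlation_R within-individual left/right correlation of hip
#'   level quantities (shape coefficients and JSW fields).
#' @param n_shape_modes_signal number of supra-noise planted shape modes.
#' @param mode_log_or log odds ratios per adjusted-SD increment (the scale
#'   the association stage reports) for the leading modes; zero beyond its
#'   length.
#' @param mode_sd1 SD of the first shape-mode coefficient (mm).
#' @param mode_decay geometric decay ratio of successive mode variances;
#'   0.72 puts about 90% of the total variance in the first 7 of 16 modes.
#' @param base_jsw_mm mean joint space width (mm).
#' @param field_sd_mm SD of the smooth between-subject JSW field variation.
#' @param vertex_noise_mm SD of independent per-vertex measurement noise.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 80, n_controls = 187,
                        frac_bilateral = 17 / 80,
                        narrowing_max_mm = 1.0, widening_post_mm = 0.75,
                        side_correlation_R = 0.5,
                        n_shape_modes_signal = 16,
                        mode_log_or = log(c(1.43, 1.75, 1.37, 1.02, 0.88, 1.39, 1.18)),
                        mode_sd1 = 6, mode_decay = 0.72,
                        base_jsw_mm = 4.0, field_sd_mm = 0.5,
                        vertex_noise_mm = 0.2, seed = 1L) {
  stopifnot(side_correlation_R >= 0, side_correlation_R <= 1,
            n_cases >= 0, n_controls >= 0, narrowing_max_mm >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# Mode coefficient SDs. Two-block variance spectrum: geometric decay over
# the leading 7 modes, which by construction hold 90% of the signal
# variance, and a flat supra-noise tail for the remaining signal modes —
# weak enough to stay out of the leading block, strong enough that parallel
# analysis separates all signal modes from the noise floor.
mode_sds <- function(spec) {
  K <- spec$n_shape_modes_signal
  k7 <- min(7, K)
  lam_head <- spec$mode_sd1^2 * spec$mode_decay^(seq_len(k7) - 1)
  lam <- lam_head
  if (K > k7) lam <- c(lam_head, rep(sum(lam_head) / 9 / (K - k7), K - k7))
  sqrt(lam)
}

# Raised-cosine regional windows on the cap parameterisation. Superior:
# polar cone about the apex. Posterior: azimuth band about phi = pi at
# mid-polar angles.
superior_window <- function(theta, phi, theta_max = 40 * pi / 180) {
  ifelse(theta < theta_max, 0.5 * (1 + cos(pi * theta / theta_max)), 0)
}

posterior_window <- function(theta, phi, phi0 = pi, half_width = 50 * pi / 180,
                             theta_range = c(40, 85) * pi / 180) {
  dphi <- atan2(sin(phi - phi0), cos(phi - phi0))
  wphi <- ifelse(abs(dphi) < half_width, 0.5 * (1 + cos(pi * dphi / half_width)), 0)
  tmid <- mean(theta_range); thw <- diff(theta_range) / 2
  wth <- ifelse(abs(theta - tmid) < thw, 0.5 * (1 + cos(pi * (theta - tmid) / thw)), 0)
  wphi * wth
}

# Smooth random field on the cap: low-order Fourier basis in (theta, phi)
# with standard normal coefficients, normalised to unit pointwise SD.
smooth_field_basis <- function(theta, phi, theta_max) {
  u <- theta / theta_max
  B <- cbind(1, cos(pi * u), cos(2 * pi * u),
             sin(theta) * cos(phi), sin(theta) * sin(phi),
             sin(theta) * cos(2 * phi), sin(theta) * sin(2 * phi),
             cos(pi * u) * cos(phi), cos(pi * u) * sin(phi))
  sweep(B, 2, sqrt(colMeans(B^2)) + 1e-12, `/`)
}

#' Simulate a full synthetic cohort on the canonical surface
#'
#' Generates, per hip: a JSW map on the canonical cap (smooth between-subject
#' variation shared within individuals at the specified side correlation,
#' plus planted case narrowing/widening and vertex noise), shape-mode
#' coefficients with the planted variance spectrum and side correlation, a
#' per-hip displacement field realising those coefficients on an orthonormal
#' smooth mode basis, and the covariate table. The hip-level THR outcome is
#' Bernoulli from the logistic model
#' `logit P = b0 + sum_k gamma_k c_k / sd_k`, with `b0` solved so the
#' expected fraction of case individuals matches the spec.
#'
#' @param spec a [cohort_spec()].
#' @param canonical canonical [surface_mesh()] (must carry `theta`/`phi`
#'   channels, as [canonical_surface()] does).
#' @param seed overrides `spec$seed` when given.
#' @param with_maps,with_fields switch off JSW map / displacement field
#'   generation when only the coefficients and outcomes are needed (e.g.
#'   association-stage simulations); the corresponding elements are `NULL`.
#' @return list with `cohort` (tibble, one row per hip), `maps`
#'   (`hips x V` JSW matrix), `coefficients` (`hips x K`), `fields`
#'   (`hips x 3V` displacement matrix), `truth` (planted per-vertex case
#'   effect fields), `canonical`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), canonical = canonical_surface(),
                            seed = NULL, with_maps = TRUE, with_fields = TRUE) {
  set.seed(as.integer(if (is.null(seed)) spec$seed else seed))
  th <- canonical$channels$theta; ph <- canonical$channels$phi
  if (is.null(th)) stop("canonical surface must carry theta/phi channels")
  V <- n_vertices(canonical)
  n_ind <- spec$n_cases + spec$n_controls
  R <- spec$side_correlation_R
  K <- spec$n_shape_modes_signal
  sds <- mode_sds(spec)
  gam <- rep(0, K)
  gam[seq_along(spec$mode_log_or)] <- spec$mode_log_or
  # shape coefficients: individual latent + side-specific, mixed for target R
  z_ind <- matrix(stats::rnorm(n_ind * K), n_ind, K)
  z_l <- matrix(stats::rnorm(n_ind * K), n_ind, K)
  z_r <- matrix(stats::rnorm(n_ind * K), n_ind, K)
  mix <- function(zs) sqrt(R) * z_ind + sqrt(1 - R) * zs
  c_l <- sweep(mix(z_l), 2, sds, `*`)
  c_r <- sweep(mix(z_r), 2, sds, `*`)
  # hip-level outcome: logistic in standardised coefficients; intercept set
  # so the expected case-individual fraction matches the spec. mode_log_or
  # is defined per ADJUSTED SD (the scale the association stage reports);
  # the adjusted SD exceeds the raw SD by ~sqrt(1+R), so the per-raw-SD
  # slope is scaled down accordingly.
  gam_raw <- gam / sqrt(1 + R)
  lin_l <- as.vector(sweep(c_l, 2, sds, `/`) %*% gam_raw)
  lin_r <- as.vector(sweep(c_r, 2, sds, `/`) %*% gam_raw)
  target <- spec$n_cases / n_ind
  b0 <- stats::uniroot(function(b) {
    p_l <- stats::plogis(b + lin_l); p_r <- stats::plogis(b + lin_r)
    mean(1 - (1 - p_l) * (1 - p_r)) - target
  }, c(-15, 5))$root
  thr_l <- stats::rbinom(n_ind, 1, stats::plogis(b0 + lin_l))
  thr_r <- stats::rbinom(n_ind, 1, stats::plogis(b0 + lin_r))
  case <- thr_l | thr_r
  # JSW maps: base + smooth correlated field + planted effects + noise
  B <- smooth_field_basis(th, ph, max(th))
  nb <- ncol(B)
  w_sup <- superior_window(th, ph)
  w_post <- posterior_window(th, ph)
  f_ind <- matrix(stats::rnorm(n_ind * nb), n_ind, nb)
  mk_side <- function(zs) sqrt(R) * f_ind + sqrt(1 - R) * zs
  coefs_l <- mk_side(matrix(stats::rnorm(n_ind * nb), n_ind, nb))
  coefs_r <- mk_side(matrix(stats::rnorm(n_ind * nb), n_ind, nb))
  field_l <- spec$field_sd_mm / sqrt(nb) * coefs_l %*% t(B)
  field_r <- spec$field_sd_mm / sqrt(nb) * coefs_r %*% t(B)
  effect <- function(thr_this, case_ind) {
    # replaced hip: 1.5x narrowing + full widening; contralateral case hip:
    # 0.5x narrowing; controls: none
    narrow <- ifelse(thr_this == 1, 1.5, ifelse(case_ind, 0.5, 0))
    widen <- ifelse(thr_this == 1, 1, 0)
    list(narrow = narrow, widen = widen)
  }
  e_l <- effect(thr_l, case); e_r <- effect(thr_r, case)
  if (with_maps) {
    map_l <- spec$base_jsw_mm + field_l -
      outer(e_l$narrow * spec$narrowing_max_mm, w_sup) +
      outer(e_l$widen * spec$widening_post_mm, w_post) +
      matrix(stats::rnorm(n_ind * V, 0, spec$vertex_noise_mm), n_ind, V)
    map_r <- spec$base_jsw_mm + field_r -
      outer(e_r$narrow * spec$narrowing_max_mm, w_sup) +
      outer(e_r$widen * spec$widening_post_mm, w_post) +
      matrix(stats::rnorm(n_ind * V, 0, spec$vertex_noise_mm), n_ind, V)
  }
  if (with_fields) {
    # displacement fields realising the coefficients on a smooth orthonormal
    # mode basis, plus a small isotropic noise floor
    M <- planted_mode_basis(canonical, K)
    noise_sd <- 0.05
    fld_l <- c_l %*% t(M) + matrix(stats::rnorm(n_ind * 3 * V, 0, noise_sd), n_ind)
    fld_r <- c_r %*% t(M) + matrix(stats::rnorm(n_ind * 3 * V, 0, noise_sd), n_ind)
  } else M <- NULL
  # covariates
  age <- stats::rnorm(n_ind, 74.3, 4.9)
  bmi <- stats::rnorm(n_ind, 27.6, 4.2)
  sex_lat <- sqrt(0.7) * (z_ind[, 1]) + sqrt(0.3) * stats::rnorm(n_ind)
  sex <- ifelse(sex_lat > stats::qnorm(1 - 0.37), 1L, 0L)  # ~37% male
  hp <- stats::rbinom(n_ind, 1, stats::plogis(-1.95 + 1.55 * case))
  # per-hip KL and min2D correlated with the planted superior state
  if (with_maps) {
    sup_mean_l <- rowMeans(map_l[, w_sup > 0.25, drop = FALSE])
    sup_mean_r <- rowMeans(map_r[, w_sup > 0.25, drop = FALSE])
  } else {
    mw <- mean(w_sup[w_sup > 0.25])
    sup_lat <- function(e) spec$base_jsw_mm -
      e$narrow * spec$narrowing_max_mm * mw +
      stats::rnorm(n_ind, 0, 0.35 * spec$field_sd_mm)
    sup_mean_l <- sup_lat(e_l); sup_mean_r <- sup_lat(e_r)
  }
  kl_grade <- function(sup_mean) {
    lat <- spec$base_jsw_mm - sup_mean + stats::rnorm(n_ind, 0, 0.45)
    as.integer(cut(lat, c(-Inf, 0.25, 0.7, 1.1, 1.5, Inf))) - 1L
  }
  min2d <- function(map, sup_mean) {
    if (is.null(map)) return(sup_mean - 0.4 + stats::rnorm(n_ind, 0, 0.3))
    apply(map[, w_sup > 0.25, drop = FALSE], 1, min) + stats::rnorm(n_ind, 0, 0.3)
  }
  hip_row <- function(side, thr_s, map_sup) {
    tibble::tibble(individual_id = sprintf("I%03d", seq_len(n_ind)),
                   side = side, thr = as.integer(thr_s), hp = hp,
                   kl = kl_grade(map_sup), min2d_mm = NA_real_,
                   age = age, sex = sex, bmi = bmi)
  }
  tab_l <- hip_row("left", thr_l, sup_mean_l)
  tab_l$min2d_mm <- min2d(if (with_maps) map_l else NULL, sup_mean_l)
  tab_r <- hip_row("right", thr_r, sup_mean_r)
  tab_r$min2d_mm <- min2d(if (with_maps) map_r else NULL, sup_mean_r)
  ord <- order(rep(seq_len(n_ind), 2), rep(c(1, 2), each = n_ind))
  cohort <- dplyr::bind_rows(tab_l, tab_r)[ord, ]
  maps <- if (with_maps) rbind(map_l, map_r)[ord, ] else NULL
  coefficients <- rbind(c_l, c_r)[ord, ]
  colnames(coefficients) <- paste0("SM", seq_len(K))
  fields <- if (with_fields) rbind(fld_l, fld_r)[ord, ] else NULL
  truth <- list(
    narrowing = -spec$narrowing_max_mm * w_sup,
    widening = spec$widening_post_mm * w_post,
    superior_window = w_sup, posterior_window = w_post,
    mode_basis = M, mode_sds = sds, mode_log_or = gam, b0 = b0
  )
  list(cohort = tibble::as_tibble(cohort), maps = maps,
       coefficients = coefficients, fields = fields, truth = truth,
       canonical = canonical)
}

# Orthonormal planted mode basis (3V x K): smooth low-order displacement
# patterns orthonormalised by QR.
planted_mode_basis <- function(canonical, K) {
  th <- canonical$channels$theta; ph <- canonical$channels$phi
  V <- n_vertices(canonical)
  tmax <- max(th)
  raw <- list()
  fns <- list(
    function(t, p) cbind(sin(t) * cos(p), sin(t) * sin(p), cos(t)),     # scale
    function(t, p) cbind(cos(t), 0 * t, -sin(t) * cos(p)),
    function(t, p) cbind(0 * t, cos(t), sin(t) * sin(p))
  )
  k <- 0
  for (m in 0:3) for (n in 0:2) for (f in 1:3) {
    k <- k + 1
    if (k > 3 * K) break
    base <- fns[[f]](th, ph)
    modul <- cos(m * ph + n * pi * th / tmax)
    raw[[k]] <- as.vector(t(base * modul))
  }
  A <- do.call(cbind, raw)
  Q <- qr.Q(qr(A))
  Q <- Q[, seq_len(K), drop = FALSE]
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Cohort covariate table from an existing simulation
#'
#' Convenience accessor matching the pipeline's file interface: the per-hip
#' covariate/outcome table of a [simulate_cohort()] result, ready to write as
#' CSV.
#'
#' @param sim a [simulate_cohort()] result.
#' @return tibble with columns `individual_id, side, thr, hp, kl, min2d_mm,
#'   age, sex, bmi`.
#' @export
make_cohort_table <- function(sim) sim$cohort
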