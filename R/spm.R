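#' Vertex-wise general linear model with an F test for one term
#'
#' Ordinary least squares at every canonical vertex of
#' `response ~ design`, with a partial F test of the effect columns against
#' the reduced model containing the remaining (confounder) columns. Written
#' in matrix form over all vertices at once; numerically identical to an
#' independent per-vertex OLS fit.
#'
#' @param responses matrix `n x V` (one row per individual, paired hips
#'   already averaged).
#' @param design data frame / matrix of covariates, `n` rows; an intercept is
#'   added automatically.
#' @param effect name(s) of the tested column(s) (e.g. `"thr"`).
#' @return list: `F` (per-vertex), `p` (uncorrected, upper-tail F),
#'   `df` (c(df1, df2)), `coefficients` (`p x V`), `residuals` (`n x V`),
#'   `effect_mean_diff` (per-vertex effect coefficient).
#' @export
fit_vertexwise_glm <- function(responses, design, effect = "thr") {
  Y <- as.matrix(responses)
  Xd <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(design)))
  n <- nrow(Y)
  stopifnot(nrow(Xd) == n)
  if (qr(Xd)$rank < ncol(Xd)) {
    qrx <- qr(Xd)
    bad <- colnames(Xd)[qrx$pivot[seq(qrx$rank + 1, ncol(Xd))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eff_idx <- which(colnames(Xd) %in% effect)
  if (!length(eff_idx)) stop("effect column not in design: ", effect)
  if (n <= ncol(Xd)) stop("more design columns than individuals")
  q <- length(eff_idx)
  df2 <- n - ncol(Xd)
  fit_full <- qr(Xd)
  beta <- qr.coef(fit_full, Y)
  res <- Y - Xd %*% beta
  rss1 <- colSums(res^2)
  X0 <- Xd[, -eff_idx, drop = FALSE]
  res0 <- qr.resid(qr(X0), Y)
  rss0 <- colSums(res0^2)
  Fv <- ((rss0 - rss1) / q) / (rss1 / df2)
  pv <- stats::pf(Fv, q, df2, lower.tail = FALSE)
  list(F = Fv, p = pv, df = c(q, df2), coefficients = beta,
       residuals = res, effect_mean_diff = beta[eff_idx[1], ],
       design = Xd, effect = effect)
}

#' Residual smoothness (FWHM) and resel counts on a mesh
#'
#' Estimates the smoothness of the residual field from normalised-residual
#' differences along mesh edges: with `u_v` the unit-normalised residual
#' vector at vertex `v`, the second spectral moment is
#' `lambda = mean(|u_i - u_j|^2 / d_ij^2)` over edges and
#' `FWHM = sqrt(4 log 2 / lambda)`. Resel counts follow the surface case:
#' `R2 = area / FWHM^2`, `R1 = half boundary length / FWHM`, `R0` the Euler
#' characteristic of the mesh.
#'
#' Smoothness on real meshes is rarely stationary (vertex density and
#' smoothing reach vary over the surface), so the 2D resel count is
#' accumulated locally, per face, from the face's own edge roughness —
#' `R2 = sum_f area_f * mean(lambda_edges(f)) / (4 log 2)` — rather than from
#' one global FWHM. The reported `fwhm_mm` is the global summary.
#'
#' @param residuals `n x V` residual matrix from [fit_vertexwise_glm()].
#' @param mesh the canonical [surface_mesh()].
#' @return list: `fwhm_mm` (global), `resels` (length 3: R0, R1, R2 with R2
#'   locally accumulated), `lambda` (global mean).
#' @export
estimate_smoothness <- function(residuals, mesh) {
  E <- as.matrix(residuals)
  V <- ncol(E)
  stopifnot(V == n_vertices(mesh))
  norms <- sqrt(colSums(E^2))
  if (any(norms == 0)) stop("zero-variance residuals at some vertex")
  U <- sweep(E, 2, norms, `/`)
  ed <- mesh_edges(mesh)
  len <- edge_lengths(mesh, ed)
  dU2 <- colSums((U[, ed[, 1], drop = FALSE] - U[, ed[, 2], drop = FALSE])^2)
  lam_e <- dU2 / len^2
  lambda <- mean(lam_e)
  fwhm <- sqrt(4 * log(2) / lambda)
  areas <- mesh_area(mesh)
  f <- mesh$faces
  ekey <- paste(ed[, 1], ed[, 2])
  eid <- function(a, b) match(paste(pmin(a, b), pmax(a, b)), ekey)
  lam_f <- (lam_e[eid(f[, 1], f[, 2])] + lam_e[eid(f[, 2], f[, 3])] +
              lam_e[eid(f[, 3], f[, 1])]) / 3
  r2 <- sum(areas * lam_f) / (4 * log(2))
  be <- boundary_edges(mesh)
  blen <- if (nrow(be)) sum(sqrt(rowSums(
    (mesh$vertices[be[, 1], , drop = FALSE] -
       mesh$vertices[be[, 2], , drop = FALSE])^2))) else 0
  # boundary resels from the boundary edges' own roughness
  r1 <- if (nrow(be)) {
    lam_b <- lam_e[eid(be[, 1], be[, 2])]
    sum(sqrt(rowSums((mesh$vertices[be[, 1], , drop = FALSE] -
                        mesh$vertices[be[, 2], , drop = FALSE])^2)) *
          sqrt(lam_b / (4 * log(2)))) / 2
  } else 0
  chi <- n_vertices(mesh) - nrow(ed) + nrow(mesh$faces)
  resels <- c(chi, r1, r2)
  list(fwhm_mm = fwhm, resels = resels, lambda = lambda, boundary_mm = blen)
}

# Euler characteristic densities of an F field with (k, v) df, per resel
# dimension 0..2 (unit-FWHM normalisation folded into the resel counts).
ec_density_f <- function(t, k, v) {
  t <- pmax(t, 0)
  a <- 4 * log(2) / (2 * pi)
  lg <- function(x) lgamma(x)
  kt <- k * t / v
  rho0 <- stats::pf(t, k, v, lower.tail = FALSE)
  rho1 <- sqrt(a) * exp(lg((v + k - 1) / 2) - lg(v / 2) - lg(k / 2)) * sqrt(2) *
    kt^((k - 1) / 2) * (1 + kt)^(-(v + k - 2) / 2)
  rho2 <- a * exp(lg((v + k - 2) / 2) - lg(v / 2) - lg(k / 2)) *
    kt^((k - 2) / 2) * (1 + kt)^(-(v + k - 2) / 2) * ((v - 1) * kt - (k - 1))
  rbind(rho0, rho1, rho2)
}

#' Random field theory correction for a surface F map
#'
#' Peak-level familywise-corrected p-values via the expected Euler
#' characteristic of an F field over the surface:
#' `p_corr(t) = sum_d R_d rho_d(t)` with the resel counts `R_d` from
#' [estimate_smoothness()]. Corrected p is clamped to be at least the
#' uncorrected p (the one-test limit), so a single-vertex mesh degenerates
#' to the ordinary F test.
#'
#' @param F_map per-vertex F values.
#' @param df length-2 numerator/denominator degrees of freedom.
#' @param resels length-3 resel counts.
#' @param alpha familywise level for the ROI.
#' @return list: `p_corrected`, `p_uncorrected`, `roi` (logical per vertex),
#'   `alpha`.
#' @export
rft_correct <- function(F_map, df, resels, alpha = 0.05) {
  if (resels[length(resels)] < 0 || all(resels <= 0))
    stop("non-positive resel counts")
  rho <- ec_density_f(F_map, df[1], df[2])
  p_unc <- rho[1, ]
  ec <- as.vector(resels %*% rho)
  p_corr <- pmin(1, pmax(ec, p_unc))
  list(p_corrected = p_corr, p_uncorrected = p_unc,
       roi = p_corr < alpha, alpha = alpha)
}

#' Surface statistical parametric mapping of JSW on THR status
#'
#' The full SPM stage: average paired hips per individual, fit the
#' vertex-wise GLM `JSW ~ 1 + THR + SM1 + ... + SM7` (confounding on the
#' leading shape modes; age/BMI excluded by default as they do not alter
#' results), estimate residual smoothness, apply random field theory and
#' return the significant region of interest with the group mean-difference
#' map.
#'
#' @param maps `hips x V` JSW matrix on the canonical surface (or already
#'   per-individual if `individual_ids` is NULL).
#' @param cohort per-hip tibble with `individual_id`, `thr` (and covariates).
#' @param coefficients per-hip shape-mode coefficient matrix.
#' @param mesh canonical [surface_mesh()].
#' @param n_modes number of confounder modes.
#' @param smooth_fwhm_mm pre-analysis smoothing of the maps (mm; 0 = none).
#' @param alpha familywise level.
#' @param covariates optional extra per-individual covariate columns (e.g.
#'   `c("age", "bmi")`).
#' @param individual_level set `TRUE` when `maps` rows are already one per
#'   individual and `cohort` has one row per individual.
#' @return an `spm_result`: per-vertex `F`, `p_uncorrected`, `p_corrected`,
#'   `roi`, `mean_diff` (case minus control, mm), `fwhm_mm`, `resels`, `df`.
#' @export
spm_jsw <- function(maps, cohort, coefficients, mesh, n_modes = 7,
                    smooth_fwhm_mm = 5, alpha = 0.05,
                    covariates = character(0), individual_level = FALSE) {
  maps <- as.matrix(maps)
  coefficients <- as.matrix(coefficients)
  if (!individual_level) {
    am <- average_paired_maps(maps, cohort$individual_id)
    ac <- average_paired_maps(coefficients, cohort$individual_id)
    meta <- dplyr::distinct(
      dplyr::summarise(dplyr::group_by(cohort, .data$individual_id),
                       thr = as.integer(any(.data$thr == 1)),
                       dplyr::across(dplyr::any_of(c("age", "bmi", "sex")), mean),
                       .groups = "drop"))
    meta <- meta[match(am$individual_id, meta$individual_id), ]
    Y <- am$values
    C <- ac$values
  } else {
    meta <- cohort
    Y <- maps
    C <- coefficients
  }
  if (smooth_fwhm_mm > 0)
    Y <- t(smooth_surface_scalar(mesh, t(Y), smooth_fwhm_mm))
  n_modes <- min(n_modes, ncol(C))
  design <- data.frame(thr = meta$thr, C[, seq_len(n_modes), drop = FALSE])
  colnames(design) <- c("thr", paste0("SM", seq_len(n_modes)))
  for (cv in covariates) design[[cv]] <- meta[[cv]]
  glm_fit <- fit_vertexwise_glm(Y, design, effect = "thr")
  sm <- estimate_smoothness(glm_fit$residuals, mesh)
  rc <- rft_correct(glm_fit$F, glm_fit$df, sm$resels, alpha = alpha)
  structure(list(F = glm_fit$F, p_uncorrected = rc$p_uncorrected,
                 p_corrected = rc$p_corrected, roi = rc$roi,
                 mean_diff = glm_fit$effect_mean_diff, df = glm_fit$df,
                 fwhm_mm = sm$fwhm_mm, resels = sm$resels, alpha = alpha,
                 mesh = mesh, n = nrow(Y)),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> n=%d, df=(%d,%d), FWHM %.1f mm, %d/%d ROI vertices (alpha %.2f)\n",
              x$n, x$df[1], x$df[2], x$fwhm_mm, sum(x$roi), length(x$roi), x$alpha))
  if (any(x$roi))
    cat(sprintf("  mean difference in ROI: %.2f to %.2f mm\n",
                min(x$mean_diff[x$roi]), max(x$mean_diff[x$roi])))
  invisible(x)
}

#' Tidy an SPM result into a per-vertex tibble
#' @param x an `spm_result`.
#' @param ... unused.
#' @export
tidy.spm_result <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$F), F = x$F,
                 p_uncorrected = x$p_uncorrected,
                 p_corrected = x$p_corrected, roi = x$roi,
                 mean_diff_mm = x$mean_diff)
}

#' @rdname tidy.spm_result
#' @export
glance.spm_result <- function(x, ...) {
  tibble::tibble(n = x$n, df1 = x$df[1], df2 = x$df[2], fwhm_mm = x$fwhm_mm,
                 resels_2d = x$resels[3], n_roi = sum(x$roi),
                 min_mean_diff_mm = min(x$mean_diff),
                 max_mean_diff_mm = max(x$mean_diff))
}

#' Flat-map plot of an SPM result
#'
#' Polar projection of the canonical cap (apex at the centre) coloured by
#' the group mean difference, with the significant ROI outlined.
#'
#' @param object an `spm_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spm_result <- function(object, ...) {
  th <- object$mesh$channels$theta; ph <- object$mesh$channels$phi
  d <- tibble::tibble(x = th * cos(ph), y = th * sin(ph),
                      diff = object$mean_diff, roi = object$roi)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$diff), size = 1.6) +
    ggplot2::geom_point(data = d[d$roi, ], shape = 1, size = 2.4) +
    ggplot2::scale_colour_gradient2(low = "firebrick", high = "navy",
                                    name = "mean diff (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "JSW difference map (circled: significant ROI)") +
    ggplot2::theme_minimal()
}

#' SPM of side-difference JSW maps
#'
#' Applies the same GLM / F / random-field machinery to per-individual signed
#' left-right difference maps (replaced minus opposite side).
#'
#' @param diff_maps `individuals x V` signed difference matrix (from
#'   [side_difference_map()]).
#' @param design per-individual data frame of confounders (may be just the
#'   shape-mode coefficients); a `thr` column is the tested effect.
#' @param mesh canonical [surface_mesh()].
#' @param smooth_fwhm_mm,alpha as in [spm_jsw()].
#' @return an `spm_result`.
#' @export
side_difference_spm <- function(diff_maps, design, mesh, smooth_fwhm_mm = 5,
                                alpha = 0.05) {
  Y <- as.matrix(diff_maps)
  if (smooth_fwhm_mm > 0) Y <- t(smooth_surface_scalar(mesh, t(Y), smooth_fwhm_mm))
  glm_fit <- fit_vertexwise_glm(Y, design, effect = "thr")
  sm <- estimate_smoothness(glm_fit$residuals, mesh)
  rc <- rft_correct(glm_fit$F, glm_fit$df, sm$resels, alpha = alpha)
  structure(list(F = glm_fit$F, p_uncorrected = rc$p_uncorrected,
                 p_corrected = rc$p_corrected, roi = rc$roi,
                 mean_diff = glm_fit$effect_mean_diff, df = glm_fit$df,
                 fwhm_mm = sm$fwhm_mm, resels = sm$resels, alpha = alpha,
                 mesh = mesh, n = nrow(Y)),
            class = "spm_result")
}

#' Permutation max-F familywise test (validation backend)
#'
#' Freedman-Lane style permutation of the tested column against the maximum
#' F statistic over vertices: the nonparametric reference against which the
#' random field theory correction is validated. Returns the familywise
#' p-value of the observed max F and the permutation distribution.
#'
#' @param responses `n x V` matrix.
#' @param design covariate data frame (intercept added).
#' @param effect tested column name.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: `p_fwer` (permutation p of max F), `max_F_obs`,
#'   `max_F_perm` (vector).
#' @export
permutation_max_f <- function(responses, design, effect = "thr",
                              n_perm = 199, seed = 1L) {
  Y <- as.matrix(responses)
  Xd <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(design)))
  eff_idx <- which(colnames(Xd) %in% effect)
  stopifnot(length(eff_idx) == 1)
  n <- nrow(Y)
  X0 <- Xd[, -eff_idx, drop = FALSE]
  q0 <- qr(X0)
  E0 <- qr.resid(q0, Y)               # reduced-model residuals
  rss0 <- colSums(E0^2)
  z <- qr.resid(q0, Xd[, eff_idx])    # effect column orthogonalised to X0
  df2 <- n - ncol(Xd)
  f_of <- function(zv) {
    num <- as.vector(crossprod(zv, E0))^2 / sum(zv^2)
    num / ((rss0 - num) / df2)
  }
  Fobs <- f_of(z)
  set.seed(as.integer(seed))
  maxs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    zp <- qr.resid(q0, z[sample.int(n)])
    maxs[b] <- max(f_of(zp))
  }
  p <- (1 + sum(maxs >= max(Fobs))) / (n_perm + 1)
  list(p_fwer = p, max_F_obs = max(Fobs), max_F_perm = maxs)
}
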