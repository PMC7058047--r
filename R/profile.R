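#' Extract a 1D density profile along a surface normal
#'
#' Samples the image volume by trilinear interpolation at uniformly spaced
#' offsets along a line through `vertex` in direction `direction` — the
#' measurement line of joint space mapping. Offset 0 is at the vertex;
#' positive offsets run along `direction` (the outward femoral normal, i.e.
#' into the joint space).
#'
#' @param volume a [jsm_volume()].
#' @param vertex length-3 world coordinate (mm).
#' @param direction length-3 direction vector (normalised internally).
#' @param half_length_mm half the sampled line length (mm).
#' @param spacing_mm sample spacing (mm); should not exceed the smallest voxel
#'   dimension.
#' @param min_length_mm minimum usable line length before an error is raised
#'   when the line exits the volume.
#' @return a `density_profile` list with `offsets_mm`, `values`, `direction`,
#'   `vertex`, and `truncated` flag.
#' @export
extract_profile <- function(volume, vertex, direction, half_length_mm = 10,
                            spacing_mm = 0.2, min_length_mm = 4) {
  direction <- direction / sqrt(sum(direction^2))
  off <- seq(-half_length_mm, half_length_mm, by = spacing_mm)
  pts <- outer(off, direction) + matrix(vertex, length(off), 3, byrow = TRUE)
  val <- interp_volume(volume, pts)
  ok <- !is.na(val)
  truncated <- !all(ok)
  if (truncated) {
    run <- range(which(ok))
    off <- off[run[1]:run[2]]; val <- val[run[1]:run[2]]
    if (any(is.na(val)) || diff(range(off)) < min_length_mm)
      stop("profile line leaves the volume; usable length below minimum")
  }
  structure(list(offsets_mm = off, values = val, direction = direction,
                 vertex = vertex, truncated = truncated),
            class = "density_profile")
}

# Four-interface Gaussian-blurred step model. x: offsets; e: interface
# positions (femoral plate [e1,e2], gap [e2,e3], acetabular plate [e3,e4]).
profile_model_values <- function(x, e1, e2, e3, e4, y_bg1, y_gap, y_bg2, y_c, sigma) {
  P <- function(e) stats::pnorm((x - e) / sigma)
  y_bg1 + (y_c - y_bg1) * P(e1) + (y_gap - y_c) * P(e2) +
    (y_c - y_gap) * P(e3) + (y_bg2 - y_c) * P(e4)
}

# Initial interface guesses from the two strongest opposite-signed gradient
# extrema: density falls at the femoral edge (e2), rises at the acetabular
# edge (e3 > e2). The sample vertex sits on the femoral subchondral edge, so
# the fall is sought near offset 0 (within `window` mm) and the rise within
# `reach` mm beyond it — this keeps the far plate-to-background drop, which
# can be steeper than a narrow-gap dip, from hijacking the initialisation.
init_edges <- function(x, y, window = 2.5, reach = 8) {
  cand <- init_edge_candidates(x, y, window, reach)
  if (!length(cand)) return(NULL)
  cand[[1]]
}

# Up to `k` candidate (e2, e3) pairs. Fall candidates are local minima of the
# gradient within `window` of offset 0 (strongest first): when the gap is
# narrow relative to the blur its dip can be weaker than the far
# plate-to-background drop, so more than one basin must be tried.
init_edge_candidates <- function(x, y, window = 2.5, reach = 8, k = 2) {
  g <- diff(y) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  near <- which(abs(xm) <= window & is.finite(g))
  if (!length(near)) return(list())
  loc_min <- near[vapply(near, function(i) {
    gl <- if (i > 1) g[i - 1] else Inf
    gr <- if (i < length(g)) g[i + 1] else Inf
    is.finite(g[i]) && g[i] <= gl && g[i] <= gr && g[i] < 0
  }, logical(1))]
  if (!length(loc_min)) loc_min <- near[which.min(g[near])]
  loc_min <- loc_min[order(g[loc_min])]
  out <- list()
  for (i_fall in utils::head(loc_min, k)) {
    after <- which(xm > xm[i_fall] & xm <= xm[i_fall] + reach)
    if (!length(after)) next
    i_rise <- after[which.max(g[after])]
    out[[length(out) + 1]] <- c(e2 = xm[i_fall], e3 = xm[i_rise])
  }
  # The sample line starts on the femoral subchondral edge, so e2 = 0 is a
  # legitimate prior even when blur hides the gap dip entirely.
  out[[length(out) + 1]] <- c(e2 = 0, e3 = 1)
  out
}

#' Fit the constrained deconvolution model to a density profile
#'
#' Least-squares fit of a Gaussian-blurred four-interface step model
#' `y(x) = y_bg1 + (y_c - y_bg1) * Phi((x-e1)/sigma) + (y_gap - y_c) * Phi((x-e2)/sigma)
#' + (y_c - y_gap) * Phi((x-e3)/sigma) + (y_bg2 - y_c) * Phi((x-e4)/sigma)`,
#' where `Phi` is the standard normal CDF. The cortical plateau `y_c` is
#' fixed (the patch-local density constraint); plate widths are parameterised
#' as positive increments so the interface ordering `e1 < e2 < e3 < e4` is
#' maintained by construction; `sigma` is bounded. JSW is the fitted gap
#' `e3 - e2` between the joint-facing subchondral edges.
#'
#' Optimiser failure never raises: the fit is returned with
#' `converged = FALSE` and is expected to be infilled from neighbours by
#' [map_jsw()].
#'
#' @param profile a [extract_profile()] result (or list with `offsets_mm`,
#'   `values`).
#' @param y_c fixed cortical plateau density; `NULL` lets the optimiser
#'   estimate it (the unconstrained first-pass fit used by
#'   [estimate_patch_density()]).
#' @param init optional named list overriding initial values
#'   (`e1,e2,e3,e4,y_bg1,y_gap,y_bg2,sigma`).
#' @param sigma_bounds lower/upper bounds for the PSF SD (mm) when sigma is
#'   fitted.
#' @param sigma_fixed when given, the PSF SD is held at this value instead of
#'   being fitted: the blur is a property of the scanner, not of one sample
#'   line, and freeing it per profile lets narrow sub-PSF gaps trade width
#'   against blur into far-off solutions. [map_jsw()] fixes it at the
#'   patch-level profile-likelihood estimate from
#'   [estimate_patch_density()].
#' @param gap_density_frac upper bound on the joint-space density as a
#'   fraction of the fixed cortical plateau (constrained fits only). A
#'   blurred dip pins down little more than the product of gap width and
#'   density deficit, so without this physical prior — the joint space holds
#'   cartilage and fluid, far less dense than subchondral bone — a narrow
#'   deep gap and a wide shallow one are near-equivalent.
#' @return a `profile_fit` list: `jsw_mm`, `model` (named parameter list),
#'   `residual_sse`, `converged`.
#' @export
fit_profile <- function(profile, y_c = NULL, init = NULL,
                        sigma_bounds = c(0.3, 2.5), sigma_fixed = NULL,
                        gap_density_frac = 0.4) {
  x <- profile$offsets_mm; y <- profile$values
  fail <- function() structure(list(jsw_mm = NA_real_, model = NULL,
                                    residual_sse = Inf, converged = FALSE),
                               class = "profile_fit")
  if (length(x) < 12 || all(!is.finite(y))) return(fail())
  cands <- init_edge_candidates(x, y)
  if (!length(cands)) return(fail())
  ed <- cands[[1]]
  lo_y <- min(y); hi_y <- max(y)
  free_sigma <- is.null(sigma_fixed)
  start <- list(e1 = ed[["e2"]] - 2, w1 = 2, w2 = max(ed[["e3"]] - ed[["e2"]], 0.2),
                w3 = 2, y_bg1 = stats::quantile(y, 0.1, names = FALSE),
                y_gap = stats::quantile(y, 0.1, names = FALSE),
                y_bg2 = stats::quantile(y, 0.1, names = FALSE))
  if (free_sigma) start$sigma <- mean(sigma_bounds)
  start$e1 <- ed[["e2"]] - start$w1
  free_yc <- is.null(y_c)
  if (free_yc) start$y_c <- hi_y
  if (!is.null(init)) start[names(init)] <- init
  pnames <- names(start)
  # subchondral plates are sub-millimetre to a few millimetres thick; the
  # lower bound keeps the optimiser from dissolving a plate to explain a
  # blurred dip as a wide shallow gap
  lower <- c(e1 = min(x) - 2, w1 = 0.8, w2 = 0.05, w3 = 0.8,
             y_bg1 = lo_y - abs(lo_y), y_gap = lo_y - abs(lo_y),
             y_bg2 = lo_y - abs(lo_y), sigma = sigma_bounds[1])
  y_gap_max <- if (free_yc) hi_y else gap_density_frac * y_c
  upper <- c(e1 = max(x), w1 = 8, w2 = 25, w3 = 8,
             y_bg1 = hi_y, y_gap = y_gap_max, y_bg2 = hi_y,
             sigma = sigma_bounds[2])
  start$y_gap <- min(start$y_gap, y_gap_max)
  if (free_yc) {
    # blur only attenuates the plateau, so the true cortical density is at
    # least the observed peak; bounding below keeps the optimiser from
    # swapping the plateau and background roles
    lower <- c(lower, y_c = 0.9 * hi_y)
    upper <- c(upper, y_c = 3 * hi_y)
  }
  resid_fn <- function(p) {
    p <- stats::setNames(p, pnames)
    yc <- if (free_yc) p[["y_c"]] else y_c
    sg <- if (free_sigma) p[["sigma"]] else sigma_fixed
    e1 <- p[["e1"]]; e2 <- e1 + p[["w1"]]; e3 <- e2 + p[["w2"]]; e4 <- e3 + p[["w3"]]
    profile_model_values(x, e1, e2, e3, e4, p[["y_bg1"]], p[["y_gap"]],
                         p[["y_bg2"]], yc, sg) - y
  }
  # Multi-start over gap width and PSF SD: narrow gaps blurred below the PSF
  # produce shallow dips with nearby local minima, so a single start is not
  # reliable. Best SSE wins.
  starts <- list(start)
  sig_starts <- if (free_sigma) c(0.6, 1.0, 1.8) else NA
  for (ed_i in cands) for (w2 in unique(c(0.3, 1.5, 3,
                                           max(ed_i[["e3"]] - ed_i[["e2"]], 0.2)))) {
    for (sg in sig_starts) {
      s <- start
      s$e1 <- ed_i[["e2"]] - s$w1
      s$w2 <- w2
      if (free_sigma) s$sigma <- min(max(sg, sigma_bounds[1]), sigma_bounds[2])
      starts[[length(starts) + 1]] <- s
    }
  }
  if (!free_yc) {
    # coarse global scan of the two joint-facing interfaces (densities
    # profiled out) seeds one more start: gradient heuristics alone can miss
    # the right basin on noisy, heavily blurred profiles
    gsig <- if (free_sigma) 1.0 else sigma_fixed
    gseed <- tryCatch(
      fit_profile_grid(profile, y_c = y_c, sigma = gsig,
                       e2_range = c(-2.5, 2.5),
                       e3_range = c(-2, min(9, max(x) - 1)), step = 0.1),
      error = function(e) NULL)
    if (!is.null(gseed) && is.finite(gseed$sse)) {
      s <- start
      s$e1 <- gseed$e2 - 2
      s$w1 <- 2
      s$w2 <- max(gseed$jsw_mm, 0.1)
      s$w3 <- 2
      if (free_sigma) s$sigma <- gsig
      starts[[length(starts) + 1]] <- s
    }
  }
  fit <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = unlist(s), lower = lower[pnames],
                         upper = upper[pnames], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || sum(f$fvec^2) < sum(fit$fvec^2)))
      fit <- f
  }
  if (is.null(fit)) return(fail())
  p <- stats::setNames(fit$par, pnames)
  yc <- if (free_yc) p[["y_c"]] else y_c
  model <- list(e1 = p[["e1"]], e2 = p[["e1"]] + p[["w1"]],
                e3 = p[["e1"]] + p[["w1"]] + p[["w2"]],
                e4 = p[["e1"]] + p[["w1"]] + p[["w2"]] + p[["w3"]],
                y_bg1 = p[["y_bg1"]], y_gap = p[["y_gap"]], y_bg2 = p[["y_bg2"]],
                y_c = yc,
                sigma_mm = if (free_sigma) p[["sigma"]] else sigma_fixed)
  sse <- sum(fit$fvec^2)
  conv <- fit$info %in% 1:4 && is.finite(sse) && model$e3 > model$e2
  structure(list(jsw_mm = if (conv) model$e3 - model$e2 else NA_real_,
                 model = model, residual_sse = sse, converged = conv),
            class = "profile_fit")
}

#' Patch-local cortical density estimate
#'
#' First-pass unconstrained fits (plateau density free) on a subsample of
#' profiles; the robust location (median) of the fitted plateau densities is
#' the single fixed `y_c` used for every second-pass constrained fit in the
#' patch. Estimating the plateau from subchondral bone local to the joint —
#' rather than the whole femur — keeps the constraint representative of the
#' bone actually being measured.
#'
#' @param profiles list of [extract_profile()] results.
#' @param min_converged minimum number of successful first-pass fits required.
#' @param y_c supply the plateau density directly (e.g. a scanner-calibrated
#'   value) instead of estimating it; the patch PSF width is still profiled.
#' @return list: `y_c` (median plateau), `sigma_mm` (patch PSF SD by shared
#'   profile likelihood), `sigma_first_pass`, `n_converged`.
#' @export
estimate_patch_density <- function(profiles, min_converged = 10, y_c = NULL) {
  fits <- lapply(profiles, fit_profile, y_c = NULL)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < min_converged)
    stop(sprintf("only %d of %d first-pass fits converged (need >= %d)",
                 sum(ok), length(fits), min_converged))
  yc_known <- !is.null(y_c)
  if (!yc_known) {
    ycs <- vapply(fits[ok], function(f) f$model$y_c, numeric(1))
    y_c <- stats::median(ycs)
  }
  # patch-level PSF width (and plateau refinement) by joint profile
  # likelihood over shared values: the blur and the cortical density are
  # common to the whole scan, and per-profile estimates of either are
  # dragged off by the width-density confound on narrow gaps
  sig_first <- stats::median(vapply(fits[ok], function(f) f$model$sigma_mm,
                                    numeric(1)))
  sub <- profiles[ok][seq_len(min(12, sum(ok)))]
  sig_grid <- seq(0.4, 2.35, by = 0.15)
  yc_grid <- if (yc_known) y_c else y_c * c(0.9, 1.0, 1.1, 1.2, 1.35)
  tot <- matrix(NA_real_, length(sig_grid), length(yc_grid))
  for (si in seq_along(sig_grid)) for (yi in seq_along(yc_grid)) {
    sses <- vapply(sub, function(p) {
      g <- tryCatch(fit_profile_grid(p, y_c = yc_grid[yi], sigma = sig_grid[si],
                                     e2_range = c(-2.5, 2.5),
                                     e3_range = c(-2, 9), step = 0.1),
                    error = function(e) list(sse = NA_real_))
      g$sse
    }, numeric(1))
    # median across profiles: grossly corrupted profiles must not steer
    # the patch-level estimates
    tot[si, yi] <- stats::median(sses, na.rm = TRUE)
  }
  if (all(!is.finite(tot))) {
    sigma_hat <- sig_first
  } else {
    best <- arrayInd(which.min(tot), dim(tot))
    sigma_hat <- sig_grid[best[1]]
    y_c <- yc_grid[best[2]]
  }
  list(y_c = y_c, sigma_mm = sigma_hat, sigma_first_pass = sig_first,
       n_converged = sum(ok))
}

#' Exhaustive grid-search fit (validation backend)
#'
#' Brute-force minimiser of the same profile model used as an independent
#' check on [fit_profile()]: scans the two joint-facing interface positions
#' `(e2, e3)` on a regular grid (default 0.01 mm), with the three background
#' densities profiled out by exact linear least squares at each candidate and
#' `e1`, `e4`, `sigma` held at supplied values. Slow by design; not for
#' production mapping.
#'
#' @param profile a [extract_profile()] result.
#' @param y_c fixed plateau density.
#' @param sigma PSF SD held fixed (mm).
#' @param e2_range,e3_range search intervals (mm); `NULL` brackets each
#'   interface 1.5 mm either side of the corresponding gradient extremum.
#' @param step grid step (mm).
#' @param plate_mm,plate2_mm assumed plate thicknesses for the outer
#'   interfaces (`e1 = e2 - plate_mm`, `e4 = e3 + plate2_mm`; `plate2_mm`
#'   defaults to `plate_mm`).
#' @return list `jsw_mm`, `e2`, `e3`, `sse`.
#' @export
fit_profile_grid <- function(profile, y_c, sigma, e2_range = NULL,
                             e3_range = NULL, step = 0.01, plate_mm = 2,
                             plate2_mm = plate_mm, gap_density_frac = 0.4) {
  y_gap_max <- gap_density_frac * y_c
  x <- profile$offsets_mm; y <- profile$values
  ed <- init_edges(x, y)
  if (is.null(e2_range)) e2_range <- ed[["e2"]] + c(-1.5, 1.5)
  if (is.null(e3_range)) e3_range <- ed[["e3"]] + c(-1.5, 1.5)
  e2s <- seq(e2_range[1], e2_range[2], by = step)
  e3s <- seq(e3_range[1], e3_range[2], by = step)
  P <- function(e) stats::pnorm(outer(x, e, `-`) / sigma)
  P2 <- P(e2s); P3 <- P(e3s)
  P1 <- P(e2s - plate_mm); P4 <- P(e3s + plate2_mm)
  A1 <- 1 - P1                            # column i: basis of y_bg1
  best <- list(sse = Inf)
  # Densities enter linearly:
  #   y = y_bg1 (1 - P1) + y_gap (P2 - P3) + y_bg2 P4 + y_c (P1 - P2 + P3 - P4)
  # so at each (e2, e3) candidate the three free densities are profiled out by
  # a closed-form 3x3 normal-equation solve, vectorised over the e2 grid.
  g11 <- colSums(A1 * A1)
  for (j in seq_along(e3s)) {
    valid <- e2s < e3s[j]
    if (!any(valid)) next
    A2 <- P2 - P3[, j]                    # n x K2
    a3 <- P4[, j]
    b <- (y - y_c * (P3[, j] - a3)) - y_c * (P1 - P2)
    g12 <- colSums(A1 * A2); g13 <- colSums(A1 * a3)
    g22 <- colSums(A2 * A2); g23 <- colSums(A2 * a3)
    g33 <- sum(a3 * a3)
    r1 <- colSums(A1 * b); r2 <- colSums(A2 * b); r3 <- colSums(a3 * b)
    # Cramer's rule on the 3x3 Gram systems
    det <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
      g13 * (g12 * g23 - g22 * g13)
    det[abs(det) < 1e-12] <- NA
    c1 <- (r1 * (g22 * g33 - g23^2) - g12 * (r2 * g33 - g23 * r3) +
             g13 * (r2 * g23 - g22 * r3)) / det
    c2 <- (g11 * (r2 * g33 - g23 * r3) - r1 * (g12 * g33 - g23 * g13) +
             g13 * (g12 * r3 - r2 * g13)) / det
    c3 <- (g11 * (g22 * r3 - r2 * g23) - g12 * (g12 * r3 - r2 * g13) +
             r1 * (g12 * g23 - g22 * g13)) / det
    bb <- colSums(b * b)
    sse <- bb - (c1 * r1 + c2 * r2 + c3 * r3)
    # cap the gap density at the soft-tissue bound (active-set re-solve of
    # the two backgrounds with y_gap fixed at the cap)
    over <- which(is.finite(c2) & c2 > y_gap_max)
    if (length(over)) {
      r1p <- r1[over] - y_gap_max * g12[over]
      r3p <- r3[over] - y_gap_max * g23[over]
      det2 <- g11[over] * g33 - g13[over]^2
      c1p <- (r1p * g33 - g13[over] * r3p) / det2
      c3p <- (g11[over] * r3p - g13[over] * r1p) / det2
      bbp <- bb[over] - 2 * y_gap_max * r2[over] + y_gap_max^2 * g22[over]
      sse[over] <- bbp - (c1p * r1p + c3p * r3p)
    }
    sse[!valid | !is.finite(sse)] <- Inf
    i <- which.min(sse)
    if (sse[i] < best$sse)
      best <- list(sse = sse[i], e2 = e2s[i], e3 = e3s[j],
                   jsw_mm = e3s[j] - e2s[i])
  }
  best[c("jsw_mm", "e2", "e3", "sse")]
}

#' Naive thresholded full-width JSW measurement
#'
#' The comparator the deconvolution is judged against: the width of the gap
#' dip below half the plateau level (midway between the plateau and the dip
#' floor), with linear interpolation at the crossings. Ignores the blur
#' entirely, so it inflates sub-PSF gaps.
#'
#' @param profile a [extract_profile()] result.
#' @param y_c plateau (cortical) density.
#' @param window offsets searched for the dip minimum (mm).
#' @return gap width estimate (mm).
#' @export
jsw_halfwidth <- function(profile, y_c, window = c(-2, 8)) {
  x <- profile$offsets_mm; y <- profile$values
  win <- which(x > window[1] & x < window[2])
  if (!length(win)) stop("empty search window")
  i_min <- win[which.min(y[win])]
  thr <- (y_c + y[i_min]) / 2
  below <- y < thr
  l <- i_min; while (l > 1 && below[l - 1]) l <- l - 1
  r <- i_min; while (r < length(y) && below[r + 1]) r <- r + 1
  cross <- function(i0, i1) {
    if (i0 < 1 || i1 < 1 || i0 > length(y) || i1 > length(y) ||
        y[i1] == y[i0]) return(x[min(max(i0, 1), length(y))])
    x[i0] + (thr - y[i0]) / (y[i1] - y[i0]) * (x[i1] - x[i0])
  }
  cross(r, r + 1) - cross(l, l - 1)
}
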