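#' Map 3D joint space width over a joint space patch
#'
#' Runs the whole measurement chain at every patch vertex: extract a density
#' profile along the outward normal, estimate the patch-local cortical
#' plateau from first-pass unconstrained fits on a subsample, refit every
#' profile with the plateau fixed, infill non-converged vertices from valid
#' neighbours (up to three rings), and smooth the result.
#'
#' @param volume a [jsm_volume()].
#' @param patch a [surface_mesh()] with outward normals (see
#'   [extract_joint_patch()]).
#' @param half_length_mm,spacing_mm profile sampling geometry (mm).
#' @param fwhm_mm smoothing bandwidth applied to the finished map (mm).
#' @param density_sample first-pass subsample size for
#'   [estimate_patch_density()].
#' @param max_fail_frac error out when more than this fraction of vertices
#'   fails to converge (data unusable).
#' @param seed seed for the first-pass subsample.
#' @return a `jsw_map`: list with `mesh`, `jsw_mm` (per-vertex), `valid`
#'   (logical; all-true after infill unless isolated vertices had no valid
#'   neighbours), `y_c`, `smoothed`.
#' @export
map_jsw <- function(volume, patch, half_length_mm = 10, spacing_mm = 0.2,
                    fwhm_mm = 5, density_sample = 100, max_fail_frac = 0.5,
                    seed = 1L) {
  nv <- n_vertices(patch)
  if (nv == 0) stop("empty patch")
  profiles <- vector("list", nv)
  for (i in seq_len(nv)) {
    profiles[[i]] <- tryCatch(
      extract_profile(volume, patch$vertices[i, ], patch$normals[i, ],
                      half_length_mm = half_length_mm, spacing_mm = spacing_mm),
      error = function(e) NULL)
  }
  has_prof <- !vapply(profiles, is.null, logical(1))
  set.seed(as.integer(seed))
  sub <- sample(which(has_prof), min(density_sample, sum(has_prof)))
  dens <- estimate_patch_density(profiles[sub])
  jsw <- rep(NA_real_, nv)
  sse <- rep(NA_real_, nv)
  for (i in which(has_prof)) {
    # second pass: plateau density and PSF width both fixed at their
    # patch-level estimates (the blur belongs to the scan, not the line)
    ft <- fit_profile(profiles[[i]], y_c = dens$y_c,
                      sigma_fixed = dens$sigma_mm)
    if (ft$converged) {
      jsw[i] <- ft$jsw_mm
      sse[i] <- ft$residual_sse
    }
  }
  # declare high-residual fits failed (5x the patch median SSE)
  med_sse <- stats::median(sse, na.rm = TRUE)
  bad <- !is.na(sse) & sse > 5 * med_sse
  jsw[bad] <- NA_real_
  valid <- !is.na(jsw)
  if (mean(!valid) > max_fail_frac)
    stop(sprintf("%.0f%% of vertices failed to converge; data unusable",
                 100 * mean(!valid)))
  inf <- infill_neighbours(patch, jsw, valid)
  smoothed <- smooth_surface_scalar(patch, ifelse(inf$valid, inf$values, 0), fwhm_mm)
  structure(list(mesh = patch, jsw_mm = smoothed, valid = inf$valid,
                 raw_jsw_mm = jsw, y_c = dens$y_c, fwhm_mm = fwhm_mm,
                 smoothed = fwhm_mm > 0),
            class = "jsw_map")
}

#' @export
print.jsw_map <- function(x, ...) {
  cat(sprintf("<jsw_map> %d vertices, mean JSW %.2f mm (%.0f%% fitted directly)\n",
              length(x$jsw_mm), mean(x$jsw_mm[x$valid]),
              100 * mean(!is.na(x$raw_jsw_mm))))
  invisible(x)
}

#' Tidy a JSW map into a per-vertex tibble
#'
#' @param x a `jsw_map`.
#' @param ... unused.
#' @return tibble with `vertex`, `jsw_mm`, `raw_jsw_mm`, `valid`.
#' @export
tidy.jsw_map <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$jsw_mm), jsw_mm = x$jsw_mm,
                 raw_jsw_mm = x$raw_jsw_mm, valid = x$valid)
}

#' Write a JSW map as PLY plus CSV
#'
#' The mesh goes to `<path>.ply` with the JSW as a named per-vertex channel;
#' the per-vertex table goes to `<path>.csv`.
#'
#' @param map a `jsw_map`.
#' @param path output path stem (no extension).
#' @return invisibly, the two paths written.
#' @export
write_jsw_map <- function(map, path) {
  mesh <- map$mesh
  mesh$channels$jsw_mm <- map$jsw_mm
  p1 <- write_mesh(mesh, paste0(path, ".ply"))
  tab <- tibble::tibble(vertex_id = seq_along(map$jsw_mm),
                        jsw_mm = map$jsw_mm, valid = map$valid)
  readr::write_csv(tab, paste0(path, ".csv"))
  invisible(c(paste0(path, ".ply"), paste0(path, ".csv")))
}
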