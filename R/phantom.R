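#' Phantom specification
#'
#' Describes a voxelized two-plate joint phantom: two parallel (or concentric
#' spherical) subchondral plates of fixed density separated by a joint gap,
#' blurred by an isotropic Gaussian point spread function and degraded by
#' additive Gaussian noise. This is the forward model that the constrained
#' deconvolution in [fit_profile()] inverts.
#'
#' Default voxel sizes follow a typical clinical CT acquisition for the hip
#' (0.977 x 0.977 mm pixels, 1 mm slices).
#'
#' @param gap_mm true joint space width (mm), > 0.
#' @param plate_thickness_mm thickness of each subchondral plate (mm).
#' @param plate_density cortical plateau value (HU-like).
#' @param background_density trabecular / soft-tissue value.
#' @param gap_density value inside the joint space.
#' @param psf_sigma_mm Gaussian blur SD (mm), >= 0.
#' @param noise_sd additive Gaussian noise SD (HU-like).
#' @param voxel_size_mm length-3 voxel dimensions (mm).
#' @param geometry `"flat-slab"` (plates normal to z) or `"spherical-shell"`
#'   (plates concentric about the volume centre).
#' @param head_radius_mm inner-plate outer radius for the spherical geometry.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(gap_mm = 3, plate_thickness_mm = 2,
                         plate_density = 1000, background_density = 150,
                         gap_density = 50, psf_sigma_mm = 0.8, noise_sd = 10,
                         voxel_size_mm = c(0.977, 0.977, 1.0),
                         geometry = c("flat-slab", "spherical-shell"),
                         head_radius_mm = 18) {
  geometry <- match.arg(geometry)
  stopifnot(gap_mm > 0, psf_sigma_mm >= 0, plate_density > gap_density,
            all(voxel_size_mm > 0), plate_thickness_mm > 0)
  structure(list(gap_mm = gap_mm, plate_thickness_mm = plate_thickness_mm,
                 plate_density = plate_density,
                 background_density = background_density,
                 gap_density = gap_density, psf_sigma_mm = psf_sigma_mm,
                 noise_sd = noise_sd, voxel_size_mm = voxel_size_mm,
                 geometry = geometry, head_radius_mm = head_radius_mm),
            class = "phantom_spec")
}

# Signed-coordinate step profile of the two-plate model: s = distance past the
# joint-facing edge of the inner plate (s = 0 at the femoral subchondral edge,
# gap occupies [0, gap]).
plate_profile <- function(spec, s) {
  t <- spec$plate_thickness_mm; g <- spec$gap_mm
  val <- rep(spec$background_density, length(s))
  val[s > -t & s <= 0] <- spec$plate_density
  val[s > 0 & s <= g] <- spec$gap_density
  val[s > g & s <= g + t] <- spec$plate_density
  val
}

# Exact Gaussian blur of the 1D step profile (closed form with the normal CDF).
blurred_profile <- function(spec, s, sigma = spec$psf_sigma_mm) {
  if (sigma <= 0) return(plate_profile(spec, s))
  t <- spec$plate_thickness_mm; g <- spec$gap_mm
  P <- function(e) stats::pnorm((s - e) / sigma)
  spec$background_density +
    (spec$plate_density - spec$background_density) * P(-t) +
    (spec$gap_density - spec$plate_density) * P(0) +
    (spec$plate_density - spec$gap_density) * P(g) +
    (spec$background_density - spec$plate_density) * P(g + t)
}

#' Generate a phantom volume with known joint space width
#'
#' Voxelizes the piecewise-constant two-plate density field, convolves it with
#' an isotropic Gaussian of SD `psf_sigma_mm` and adds i.i.d. Gaussian noise.
#' For the flat-slab geometry the blur is applied in closed form along the
#' plate normal; the spherical shell is voxelized radially and blurred by a
#' separable discrete Gaussian.
#'
#' The volume must contain both plates plus at least a 5-sigma blur margin on
#' each side; too small a requested volume errors naming the limiting
#' dimension.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed (noise realisation).
#' @param dim_vox volume dimensions in voxels; `NULL` picks the smallest
#'   adequate size.
#' @return list with elements `volume` (a [jsm_volume()]), `truth_mm` (the
#'   generating gap), and geometry metadata (`center`, `head_radius_mm` or
#'   `gap_start_mm`: world position of the femoral subchondral edge).
#' @export
make_phantom_volume <- function(spec, seed = 1L, dim_vox = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size_mm
  margin <- 5 * spec$psf_sigma_mm
  extent_needed <- 2 * spec$plate_thickness_mm + spec$gap_mm + 2 * margin
  if (is.null(dim_vox)) {
    if (spec$geometry == "flat-slab") {
      side <- ceiling((extent_needed + 10) / vs)
      dim_vox <- pmax(c(24, 24, 24), side)
    } else {
      need <- 2 * (spec$head_radius_mm + spec$plate_thickness_mm + spec$gap_mm +
                     spec$plate_thickness_mm + margin + 2)
      dim_vox <- ceiling(need / vs)
    }
  }
  dim_vox <- as.integer(round(dim_vox))
  ext <- dim_vox * vs
  if (spec$geometry == "flat-slab") {
    if (ext[3] < extent_needed)
      stop(sprintf("volume too small along z: %.1f mm < %.1f mm needed", ext[3], extent_needed))
  } else {
    need <- 2 * (spec$head_radius_mm + spec$plate_thickness_mm + spec$gap_mm + margin)
    lim <- which.min(ext)
    if (min(ext) < need)
      stop(sprintf("volume too small along %s: %.1f mm < %.1f mm needed",
                   c("x", "y", "z")[lim], ext[lim], need))
  }
  set.seed(as.integer(seed))
  if (spec$geometry == "flat-slab") {
    zc <- (seq_len(dim_vox[3]) - 1) * vs[3]
    gap_start <- ext[3] / 2 - spec$gap_mm / 2
    prof <- blurred_profile(spec, zc - gap_start)
    arr <- array(rep(prof, each = dim_vox[1] * dim_vox[2]), dim = dim_vox)
    meta <- list(gap_start_mm = gap_start)
  } else {
    center <- (dim_vox - 1) * vs / 2
    # anti-aliased voxelization: average the radial field over a 3x3x3
    # subsample of each voxel, otherwise the staircased sphere leaves
    # discretization artifacts comparable to the blur itself
    sub <- c(-1, 0, 1) / 3
    arr <- array(0, dim = dim_vox)
    for (ox in sub) for (oy in sub) for (oz in sub) {
      xs <- (seq_len(dim_vox[1]) - 1 + ox) * vs[1] - center[1]
      ys <- (seq_len(dim_vox[2]) - 1 + oy) * vs[2] - center[2]
      zs <- (seq_len(dim_vox[3]) - 1 + oz) * vs[3] - center[3]
      r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
      arr <- arr + array(plate_profile(spec, sqrt(r2) - spec$head_radius_mm),
                         dim = dim_vox)
    }
    arr <- arr / length(sub)^3
    if (spec$psf_sigma_mm > 0) arr <- gaussian_blur3(arr, spec$psf_sigma_mm / vs)
    meta <- list(center = center)
  }
  if (spec$noise_sd > 0)
    arr <- arr + array(stats::rnorm(prod(dim_vox), 0, spec$noise_sd), dim = dim_vox)
  c(list(volume = jsm_volume(arr, voxel_size_mm = vs), truth_mm = spec$gap_mm,
         head_radius_mm = spec$head_radius_mm, spec = spec), meta)
}

# Separable discrete Gaussian blur; sigma_vox per axis (in voxel units).
# Kernel taps are cell-integrated Gaussians so narrow kernels stay accurate.
gaussian_blur3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::pnorm((seq(-r, r) + 0.5) / s) - stats::pnorm((seq(-r, r) - 0.5) / s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along one axis with replicate padding, via apply over slices.
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  pad_top <- m[rep(1, r), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = da[1], ncol = ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + da[1] - 1L), , drop = FALSE]
  a <- array(out, dim = da)
  aperm(a, order(perm))
}
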