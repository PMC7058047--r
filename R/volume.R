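#' Image volume with world affine
#'
#' A 3D voxel array plus the 4x4 voxel-to-world affine (millimetre units).
#' Index convention: world position of voxel `(i, j, k)` (1-based) is
#' `affine %*% c(i - 1, j - 1, k - 1, 1)`, i.e. the affine maps 0-based voxel
#' indices, matching the NIfTI convention.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix (mm), or `NULL` for an axis-aligned
#'   affine built from `voxel_size_mm`.
#' @param voxel_size_mm length-3 voxel edge lengths, used when `affine` is NULL.
#' @return An object of class `jsm_volume`.
#' @export
jsm_volume <- function(data, affine = NULL, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(affine)) {
    stopifnot(all(voxel_size_mm > 0))
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine), class = "jsm_volume")
}

#' @export
print.jsm_volume <- function(x, ...) {
  cat(sprintf("<jsm_volume> %s voxels, voxel size %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_sizes(x), 4), collapse = "x")))
  invisible(x)
}

# Voxel edge lengths in mm (column norms of the linear part).
voxel_sizes <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

world_to_voxel <- function(vol, pts) {
  inv <- solve(vol$affine)
  h <- cbind(pts, 1) %*% t(inv)
  h[, 1:3, drop = FALSE] + 1  # back to 1-based fractional indices
}

#' Trilinear interpolation of a volume
#'
#' Samples the volume at arbitrary world-space points by trilinear
#' interpolation of the eight surrounding voxels. Points outside the grid
#' return `NA`.
#'
#' @param vol a [jsm_volume()].
#' @param pts `n x 3` matrix of world coordinates (mm).
#' @return numeric vector of interpolated values.
#' @export
interp_volume <- function(vol, pts) {
  idx <- world_to_voxel(vol, as.matrix(pts))
  d <- dim(vol$data)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # fold exact upper-boundary samples into the last cell
  hi <- x >= d[1] & x <= d[1] + 1e-9; x0[hi] <- d[1] - 1; fx[hi] <- 1
  hi <- y >= d[2] & y <= d[2] + 1e-9; y0[hi] <- d[2] - 1; fy[hi] <- 1
  hi <- z >= d[3] & z <= d[3] + 1e-9; z0[hi] <- d[3] - 1; fz[hi] <- 1
  ok <- x0 >= 1 & y0 >= 1 & z0 >= 1 & x0 + 1 <= d[1] & y0 + 1 <= d[2] & z0 + 1 <= d[3]
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  at <- function(i, j, k) vol$data[cbind(i, j, k)]
  i0 <- x0[ok]; j0 <- y0[ok]; k0 <- z0[ok]
  gx <- fx[ok]; gy <- fy[ok]; gz <- fz[ok]
  out[ok] <-
    at(i0,     j0,     k0)     * (1 - gx) * (1 - gy) * (1 - gz) +
    at(i0 + 1, j0,     k0)     * gx       * (1 - gy) * (1 - gz) +
    at(i0,     j0 + 1, k0)     * (1 - gx) * gy       * (1 - gz) +
    at(i0,     j0,     k0 + 1) * (1 - gx) * (1 - gy) * gz       +
    at(i0 + 1, j0 + 1, k0)     * gx       * gy       * (1 - gz) +
    at(i0 + 1, j0,     k0 + 1) * gx       * (1 - gy) * gz       +
    at(i0,     j0 + 1, k0 + 1) * (1 - gx) * gy       * gz       +
    at(i0 + 1, j0 + 1, k0 + 1) * gx       * gy       * gz
  out
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving the mm-unit affine exactly.
#' `read_volume()` errors when the file carries no usable affine or when its
#' spatial units are not millimetres.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [jsm_volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = "matrix")
  if (any(!is.finite(aff)) || abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("volume has a missing or singular affine: ", path)
  units <- RNifti::niftiHeader(img)$xyzt_units %% 8
  if (!units %in% c(0, 2)) stop("volume units are not millimetres: ", path)
  # RNifti xforms map 0-based indices; sign conventions preserved as stored
  jsm_volume(array(as.numeric(img), dim = dim(img)[1:3]), affine = aff)
}

#' @param vol a [jsm_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
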