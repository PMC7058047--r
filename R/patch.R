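#' Extract the joint space patch from the femoral surface
#'
#' The perimeter of the joint space is the shadow of the acetabulum projected
#' back onto the femoral surface: a femoral vertex belongs to the patch when
#' the ray along its outward normal intersects the acetabular surface within
#' `max_gap_mm`. The result is filtered to its largest connected component.
#'
#' @param femur,acetabulum [surface_mesh()] objects with outward normals.
#' @param max_gap_mm maximum normal-ray travel to the acetabulum (mm).
#' @return a [surface_mesh()] patch; attribute `"parent_index"` maps patch
#'   vertices back to femoral vertex indices.
#' @export
extract_joint_patch <- function(femur, acetabulum, max_gap_mm = 10) {
  hit <- ray_mesh_distance(femur$vertices, femur$normals, acetabulum)
  keep <- which(is.finite(hit) & hit >= 0 & hit <= max_gap_mm)
  if (!length(keep))
    stop("no femoral normal ray reaches the acetabulum within max_gap_mm = ",
         max_gap_mm, "; increase max_gap_mm")
  keep <- largest_component(femur, keep)
  sm <- submesh(femur, keep)
  patch <- sm$mesh
  patch$normals <- femur$normals[sm$index, , drop = FALSE]
  attr(patch, "parent_index") <- sm$index
  patch
}

# For each ray (origin o_i, direction d_i) the smallest positive distance to
# any triangle of `mesh` (Moller-Trumbore, vectorised over rays per face).
ray_mesh_distance <- function(origins, dirs, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(origins)
  best <- rep(Inf, n)
  eps <- 1e-9
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    e1 <- b - a; e2 <- c_ - a
    pv <- cbind(dirs[, 2] * e2[3] - dirs[, 3] * e2[2],
                dirs[, 3] * e2[1] - dirs[, 1] * e2[3],
                dirs[, 1] * e2[2] - dirs[, 2] * e2[1])
    det <- pv[, 1] * e1[1] + pv[, 2] * e1[2] + pv[, 3] * e1[3]
    ok <- abs(det) > eps
    if (!any(ok)) next
    tv <- sweep(origins, 2, a)
    u <- (tv[, 1] * pv[, 1] + tv[, 2] * pv[, 2] + tv[, 3] * pv[, 3]) / det
    qv <- cbind(tv[, 2] * e1[3] - tv[, 3] * e1[2],
                tv[, 3] * e1[1] - tv[, 1] * e1[3],
                tv[, 1] * e1[2] - tv[, 2] * e1[1])
    w <- (dirs[, 1] * qv[, 1] + dirs[, 2] * qv[, 2] + dirs[, 3] * qv[, 3]) / det
    tt <- (e2[1] * qv[, 1] + e2[2] * qv[, 2] + e2[3] * qv[, 3]) / det
    hit <- ok & u >= -eps & w >= -eps & (u + w) <= 1 + eps & tt > eps
    upd <- hit & tt < best
    best[upd] <- tt[upd]
  }
  best
}

#' Smooth a per-vertex scalar field on a mesh
#'
#' Iterated neighbour-weighted (heat-kernel) diffusion on the mesh graph,
#' calibrated so that a point impulse spreads to approximately the requested
#' geodesic full width at half maximum. The one-step operator uses Gaussian
#' edge weights and is made doubly stochastic (Sinkhorn balancing), so a
#' constant field and the surface integral of any field are both preserved;
#' `fwhm_mm = 0` is the identity. The fractional remainder of the step count
#' is applied as a blended partial step so small bandwidths are honoured.
#'
#' @param mesh a [surface_mesh()].
#' @param values numeric per-vertex vector (or matrix, columns smoothed
#'   together).
#' @param fwhm_mm requested smoothing kernel FWHM in mm.
#' @return smoothed values, same shape as the input.
#' @export
smooth_surface_scalar <- function(mesh, values, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(values)
  vec <- is.null(dim(values))
  vmat <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  stopifnot(nrow(vmat) == n_vertices(mesh))
  op <- smoothing_operator(mesh)
  sigma_target <- fwhm_mm / sqrt(8 * log(2))
  t_steps <- sigma_target^2 / op$step_var
  n_full <- floor(t_steps)
  frac <- t_steps - n_full
  S <- op$S
  if (n_full > 0) for (i in seq_len(n_full)) vmat <- as.matrix(S %*% vmat)
  if (frac > 0) vmat <- (1 - frac) * vmat + frac * as.matrix(S %*% vmat)
  if (vec) vmat[, 1] else vmat
}

# One-step smoothing operator: Gaussian weights over 1-ring neighbours (plus
# self), Sinkhorn-balanced to doubly stochastic. step_var is the mean one-step
# kernel variance per tangent dimension, used to convert a target kernel SD
# into a step count.
smoothing_operator <- function(mesh) {
  key <- digest_light(mesh)
  cached <- .jsm_cache[[key]]
  if (!is.null(cached)) return(cached)
  e <- mesh_edges(mesh)
  len <- edge_lengths(mesh, e)
  h <- stats::median(len)
  w <- exp(-len^2 / (2 * h^2))
  n <- n_vertices(mesh)
  W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(n)),
                            j = c(e[, 2], e[, 1], seq_len(n)),
                            x = c(w, w, rep(1, n)), dims = c(n, n))
  # symmetric Sinkhorn balancing: find s with s_i * (W s)_i = 1, making
  # diag(s) W diag(s) doubly stochastic (constants and sums both preserved)
  s <- rep(1, n)
  for (it in 1:200) {
    r <- as.vector(W %*% s)
    if (max(abs(s * r - 1)) < 1e-13) break
    s <- sqrt(s / r)
  }
  S <- Matrix::Diagonal(x = s) %*% W %*% Matrix::Diagonal(x = s)
  d2 <- len^2
  sw <- s[e[, 1]] * w * s[e[, 2]]
  num <- rowsum_full(c(sw * d2, sw * d2), c(e[, 1], e[, 2]), n)
  den <- rowsum_full(c(sw, sw), c(e[, 1], e[, 2]), n) + s^2
  step_var <- mean(num / den) / 2   # per tangent dimension
  out <- list(S = S, step_var = step_var, mean_edge = h)
  assign(key, out, envir = .jsm_cache)
  out
}

rowsum_full <- function(val, idx, n) {
  out <- numeric(n)
  sm <- rowsum(val, idx)
  out[as.integer(rownames(sm))] <- sm[, 1]
  out
}

# Small fingerprint for operator caching (vertex count + coordinate checksum).
digest_light <- function(mesh) {
  v <- mesh$vertices
  sprintf("m%d_%d_%.6e", nrow(v), nrow(mesh$faces), sum(v * rep(c(1, 2.7, 5.3), each = nrow(v))))
}

.jsm_cache <- new.env(parent = emptyenv())

# Neighbour-average infill: invalid vertices take the mean of valid 1-ring
# neighbours, repeated up to `rings` times.
infill_neighbours <- function(mesh, values, valid, rings = 3) {
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  for (r in seq_len(rings)) {
    if (all(valid)) break
    vals_new <- values; valid_new <- valid
    for (i in which(!valid)) {
      nb <- adj[[as.character(i)]]
      nb <- nb[valid[nb]]
      if (length(nb)) {
        vals_new[i] <- mean(values[nb])
        valid_new[i] <- TRUE
      }
    }
    values <- vals_new; valid <- valid_new
  }
  list(values = values, valid = valid)
}
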