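#' Similarity registration by iterative closest point
#'
#' Registers the canonical surface to a target surface with a similarity
#' transform (scale, rotation, translation) estimated by iterated
#' closest-vertex correspondence and closed-form Procrustes (Umeyama) updates.
#' RMS closest-point distance is tracked; if it fails to decrease the
#' best-so-far transform is returned with `converged = FALSE`.
#'
#' @param canonical,target [surface_mesh()] objects.
#' @param max_iter maximum ICP iterations.
#' @param tol relative RMS change convergence threshold.
#' @return a `similarity_transform`: list with `scale`, `rotation` (3x3),
#'   `translation`, `rms`, `iterations`, `converged`.
#' @export
icp_similarity <- function(canonical, target, max_iter = 100, tol = 1e-9,
                           n_sample = 1200, n_starts = 8) {
  src_full <- canonical$vertices
  dst <- target$vertices
  if (!nrow(src_full) || !nrow(dst)) stop("empty mesh")
  src <- src_full
  if (nrow(src) > n_sample) {
    set.seed(0)
    src <- src[sort(sample(nrow(src), n_sample)), , drop = FALSE]
  }
  # centroid/spread alignment gives scale and translation; rotation basins
  # are probed by multiple starts about the source's own axis (a cup is
  # nearly a surface of revolution, so azimuthal local minima are real)
  s0 <- sqrt(mean(rowSums(sweep(dst, 2, colMeans(dst))^2)) /
               mean(rowSums(sweep(src, 2, colMeans(src))^2)))
  ax_s <- oriented_axis(src)
  ax_d <- oriented_axis(dst)
  R_ax <- rotation_between(ax_s, ax_d)
  coarse <- src[seq(1, nrow(src), length.out = min(300, nrow(src))), , drop = FALSE]
  # dense azimuth scan about the aligned axis, then short ICP from the best
  # few angles: a cup is close to a surface of revolution, so azimuthal
  # local minima are the failure mode worth paying for up front
  n_scan <- max(n_starts, 72)
  angles <- 2 * pi * (seq_len(n_scan) - 1) / n_scan
  scan_rms <- vapply(angles, function(a) {
    R0 <- axis_rotation(ax_d, a) %*% R_ax
    tr0 <- list(scale = s0, rotation = R0,
                translation = colMeans(dst) - s0 * as.vector(R0 %*% colMeans(src)))
    cur <- apply_similarity(tr0, coarse)
    nn <- nearest_vertex(dst, cur)
    sqrt(mean(rowSums((cur - dst[nn, , drop = FALSE])^2)))
  }, numeric(1))
  best_start <- NULL
  for (a in angles[order(scan_rms)[1:3]]) {
    R0 <- axis_rotation(ax_d, a) %*% R_ax
    tr0 <- list(scale = s0, rotation = R0,
                translation = colMeans(dst) - s0 * as.vector(R0 %*% colMeans(src)))
    probe <- icp_iterate(coarse, dst, tr0, max_iter = 15, tol = 1e-8)
    if (is.null(best_start) || probe$rms < best_start$rms) best_start <- probe
  }
  out <- icp_iterate(src, dst, best_start[c("scale", "rotation", "translation")],
                     max_iter = max_iter, tol = tol)
  if (!out$converged)
    warning("ICP did not converge within max_iter; returning best transform")
  structure(out, class = "similarity_transform")
}

# Smallest-variance principal axis with sign fixed by the skew of the
# point distribution along it (a cap's apex side), so source and target
# axes orient consistently.
oriented_axis <- function(pts) {
  c0 <- colMeans(pts)
  ax <- svd(sweep(pts, 2, c0))$v[, 3]
  proj <- as.vector(sweep(pts, 2, c0) %*% ax)
  if (mean(proj^3) < 0) ax <- -ax
  ax
}

rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b)
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(a, p); v <- v / sqrt(sum(v^2))
    return(axis_rotation(v, pi))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cc) / s^2)
}

axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

icp_iterate <- function(src, dst, tr, max_iter, tol) {
  best <- NULL
  rms_prev <- Inf
  for (it in seq_len(max_iter)) {
    cur <- apply_similarity(tr, src)
    nn <- nearest_vertex(dst, cur)
    corr <- dst[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((cur - corr)^2)))
    if (is.null(best) || rms < best$rms)
      best <- c(tr, list(rms = rms, iterations = it))
    if (is.finite(rms_prev) && (rms_prev - rms) / max(rms_prev, 1e-30) < tol) {
      best$converged <- rms <= rms_prev + 1e-12
      return(best)
    }
    rms_prev <- rms
    tr <- umeyama(src, corr)
  }
  best$converged <- FALSE
  best
}

# Closed-form similarity Procrustes (least-squares scale/rotation/translation
# mapping x onto y given row correspondence).
umeyama <- function(x, y) {
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / nrow(x)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- mean(rowSums(xc^2))
  scale <- sum(sv$d * c(1, 1, d)) / var_x
  list(scale = scale, rotation = R, translation = as.vector(my - scale * R %*% mx))
}

#' Apply a similarity transform to points
#' @param tr a `similarity_transform` (or list with `scale`, `rotation`,
#'   `translation`).
#' @param pts `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_similarity <- function(tr, pts) {
  sweep(tr$scale * pts %*% t(tr$rotation), 2, tr$translation, `+`)
}

#' Thin-plate-spline warp of the canonical surface onto a target
#'
#' Interpolating 3D thin plate spline (biharmonic kernel `U(r) = r`) whose
#' control points are the supplied rim correspondences plus a farthest-point
#' subsample of interior canonical vertices paired with their closest target
#' vertices. Control displacements are interpolated exactly; the returned
#' field is the per-canonical-vertex displacement onto the target surface.
#'
#' @param canonical [surface_mesh()] already similarity-aligned to the target.
#' @param target [surface_mesh()].
#' @param rim_pairs list with matrices `source` and `target` (`k x 3` each) of
#'   ordered rim correspondences, e.g. from [rim_correspondence()].
#' @param n_interior number of interior control points.
#' @return a `warp_field`: list with `displacement` (`V x 3`), `warped`
#'   (`V x 3` positions), `control_source`, `control_target`, `regularised`.
#' @export
tps_warp <- function(canonical, target, rim_pairs, n_interior = 200) {
  V <- canonical$vertices
  rim_idx <- integer(0)
  ctrl_src <- ctrl_dst <- NULL
  if (!is.null(rim_pairs)) {
    ctrl_src <- rim_pairs$source
    ctrl_dst <- rim_pairs$target
    rim_idx <- nearest_vertex(V, ctrl_src)
  }
  interior <- setdiff(seq_len(nrow(V)), rim_idx)
  pick <- farthest_point_sample(V[interior, , drop = FALSE],
                                min(n_interior, length(interior)))
  ip <- interior[pick]
  nn <- nearest_vertex(target$vertices, V[ip, , drop = FALSE])
  ctrl_src <- rbind(ctrl_src, V[ip, , drop = FALSE])
  ctrl_dst <- rbind(ctrl_dst, target$vertices[nn, , drop = FALSE])
  sol <- tps_solve(ctrl_src, ctrl_dst - ctrl_src)
  disp <- tps_eval(sol, V)
  structure(list(displacement = disp, warped = V + disp,
                 control_source = ctrl_src, control_target = ctrl_dst,
                 regularised = sol$regularised),
            class = "warp_field")
}

# Solve the TPS system for displacement data d at points p (kernel U = |r|).
tps_solve <- function(p, d, lambda = 0) {
  k <- nrow(p)
  K <- as.matrix(stats::dist(p))
  P <- cbind(1, p)
  A <- rbind(cbind(K + diag(lambda, k), P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(d, matrix(0, 4, 3))
  regularised <- FALSE
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    sol <- solve(A + diag(1e-8, nrow(A)), rhs)
    regularised <- TRUE
    warning("degenerate TPS control points; regularised solve used")
  }
  list(points = p, w = sol[1:k, , drop = FALSE],
       a = sol[(k + 1):(k + 4), , drop = FALSE], regularised = regularised)
}

tps_eval <- function(sol, q) {
  U <- sqrt(pmax(outer(rowSums(q^2), rowSums(sol$points^2), `+`) -
                   2 * q %*% t(sol$points), 0))
  U %*% sol$w + cbind(1, q) %*% sol$a
}

# Greedy farthest-point subsample (first point: farthest from centroid).
farthest_point_sample <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) return(seq_len(n))
  ctr <- colMeans(pts)
  sel <- integer(k)
  sel[1] <- which.max(rowSums(sweep(pts, 2, ctr)^2))
  dmin <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  for (i in seq_len(k - 1)) {
    sel[i + 1] <- which.max(dmin)
    dmin <- pmin(dmin, rowSums(sweep(pts, 2, pts[sel[i + 1], ])^2))
  }
  sel
}

#' Rim correspondence along the boundary loops
#'
#' Extracts the boundary loop (rim) of each open mesh, samples the source rim
#' at equal arc length, and pairs each sample with its closest point on the
#' target rim polyline. The surfaces are assumed already similarity-aligned
#' (the residual deformation small against the rim radius), so closest-point
#' projection onto the rim curve is a faithful correspondence; the arc-length
#' parameterisation spreads control points evenly.
#'
#' @param source,target open [surface_mesh()] objects (canonical and subject).
#' @param n_pairs number of correspondences along the rim.
#' @return list with `source` and `target` (`n_pairs x 3` matrices).
#' @export
rim_correspondence <- function(source, target, n_pairs = 50) {
  ls <- orient_loop(source)
  lt <- orient_loop(target)
  n_pairs <- min(n_pairs, nrow(ls))  # denser sampling than the rim itself
                                     # only produces near-duplicate controls
  ss <- seq(0, 1, length.out = n_pairs + 1)[-(n_pairs + 1)]
  src <- loop_point(ls, ss)
  list(source = src, target = project_on_loop(lt, src))
}

# Closest point on the closed polyline for each query row.
project_on_loop <- function(pts, query) {
  seg_a <- pts
  seg_b <- pts[c(2:nrow(pts), 1), , drop = FALSE]
  d <- seg_b - seg_a
  len2 <- pmax(rowSums(d^2), 1e-30)
  out <- matrix(NA_real_, nrow(query), 3)
  for (i in seq_len(nrow(query))) {
    q <- query[i, ]
    t <- pmin(pmax(rowSums(-sweep(seg_a, 2, q, `-`) * d) / len2, 0), 1)
    proj <- seg_a + d * t
    d2 <- rowSums(sweep(proj, 2, q)^2)
    out[i, ] <- proj[which.min(d2), ]
  }
  out
}

# Ordered rim points with canonical orientation/start. Start: maximum heading
# along the rim's first principal axis; orientation: counter-clockwise about
# the outward mean normal.
orient_loop <- function(mesh) {
  loop <- rim_loop(mesh)
  pts <- mesh$vertices[loop, , drop = FALSE]
  ctr <- colMeans(pts)
  pc <- svd(sweep(pts, 2, ctr))$v
  ax1 <- pc[, 1]; nrm <- pc[, 3]
  # consistent normal sign: align with mean vertex normal of the rim
  mn <- colMeans(mesh$normals[loop, , drop = FALSE])
  if (sum(nrm * mn) < 0) nrm <- -nrm
  if (sum(ax1) < 0) ax1 <- -ax1
  start <- which.max(sweep(pts, 2, ctr) %*% ax1)
  ord <- c(start:nrow(pts), seq_len(start - 1))
  pts <- pts[ord, , drop = FALSE]
  # winding about nrm must be positive; flip if not
  rel <- sweep(pts, 2, ctr)
  ang <- 0
  for (i in seq_len(nrow(pts))) {
    j <- if (i == nrow(pts)) 1 else i + 1
    cr <- cross3(rel[i, ], rel[j, ])
    ang <- ang + atan2(sum(cr * nrm), sum(rel[i, ] * rel[j, ]))
  }
  if (ang < 0) pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
  pts
}

# Point on the closed polyline at normalised arc length s in [0, 1).
loop_point <- function(pts, s) {
  seg <- rbind(pts, pts[1, , drop = FALSE])
  d <- sqrt(rowSums(diff(seg)^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  tpos <- s * total
  idx <- findInterval(tpos, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(seg)] <- nrow(seg) - 1
  frac <- (tpos - cum[idx]) / pmax(d[idx], 1e-30)
  seg[idx, , drop = FALSE] + frac * (seg[idx + 1, , drop = FALSE] - seg[idx, , drop = FALSE])
}

#' Register a hip to the canonical surface
#'
#' Full canonical-to-subject registration: similarity ICP, rim matching, then
#' the rim-constrained thin plate spline. The returned displacement field
#' (canonical vertex to final warped position, in mm) is the per-hip input to
#' the statistical shape model.
#'
#' @param canonical,subject [surface_mesh()] objects (subject already
#'   mirrored to right-hip convention if needed, see [mirror_hip()]).
#' @param n_rim,n_interior control-point counts.
#' @param n_tps number of warp passes: after each thin plate spline the
#'   closest-point correspondences are recomputed from the warped positions,
#'   so correspondence errors of order one mesh edge shrink geometrically.
#' @return list with `transform`, `warp` (last pass), `displacement`
#'   (`V x 3`, canonical vertex to final position), `warped`.
#' @export
register_hip <- function(canonical, subject, n_rim = 50, n_interior = 200,
                         n_tps = 3) {
  tr <- icp_similarity(canonical, subject)
  aligned <- canonical
  aligned$vertices <- apply_similarity(tr, canonical$vertices)
  wf <- NULL
  for (pass in seq_len(n_tps)) {
    aligned$normals <- vertex_normals(aligned)
    rp <- rim_correspondence(aligned, subject, n_pairs = n_rim)
    wf <- tps_warp(aligned, subject, rp, n_interior = n_interior)
    aligned$vertices <- wf$warped
  }
  # settle the warped vertices onto the subject surface: project each onto
  # the tangent plane of its nearest subject vertex (second-order accurate)
  nn <- nearest_vertex(subject$vertices, aligned$vertices)
  dvec <- aligned$vertices - subject$vertices[nn, , drop = FALSE]
  nrm <- subject$normals[nn, , drop = FALSE]
  aligned$vertices <- aligned$vertices - nrm * rowSums(dvec * nrm)
  list(transform = tr, warp = wf,
       displacement = aligned$vertices - canonical$vertices,
       warped = aligned$vertices)
}

#' Transfer a per-vertex scalar field to the canonical surface
#'
#' Each canonical vertex takes the value at the Euclidean-closest source
#' vertex (after registration has brought the surfaces into alignment), then
#' the transferred field is smoothed.
#'
#' @param source [surface_mesh()] carrying the data.
#' @param source_values per-vertex values on `source`.
#' @param canonical_warped [surface_mesh()] (or `warp_field` `warped` matrix
#'   wrapped in the canonical mesh) giving canonical vertex positions in the
#'   source frame.
#' @param fwhm_mm post-transfer smoothing bandwidth (0 = none).
#' @return per-canonical-vertex values.
#' @export
transfer_scalars <- function(source, source_values, canonical_warped,
                             fwhm_mm = 0) {
  nn <- nearest_vertex(source$vertices, canonical_warped$vertices)
  vals <- source_values[nn]
  if (fwhm_mm > 0) vals <- smooth_surface_scalar(canonical_warped, vals, fwhm_mm)
  vals
}

#' Mirror a left hip into right-hip convention
#'
#' Left hips are reflected through the sagittal (`x = 0`) plane with triangle
#' winding flipped so outward normals stay outward; right hips pass through
#' unchanged. All hips can then share one right-sided canonical surface.
#'
#' @param mesh a [surface_mesh()].
#' @param side `"left"` or `"right"`.
#' @return a [surface_mesh()].
#' @export
mirror_hip <- function(mesh, side) {
  if (!side %in% c("left", "right")) stop("unknown side label: ", side)
  if (side == "right") return(mesh)
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  surface_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], channels = mesh$channels)
}

#' Per-individual side-difference maps
#'
#' Forms the signed left-right JSW asymmetry map for each individual on the
#' canonical surface: for cases with one replaced hip, replaced minus
#' opposite; for bilateral cases, a seeded-random side minus the other; for
#' controls, a random side matching the convention used in cases. Individuals
#' missing a side are excluded (with a message in the result).
#'
#' @param maps matrix `hips x V` of canonical-surface JSW values.
#' @param meta tibble/data.frame aligned with `maps` rows: columns
#'   `individual_id`, `side` (`"left"`/`"right"`), `thr` (0/1 per hip:
#'   replaced within follow-up).
#' @param seed integer seed for the random side choices.
#' @return list: `diff` (matrix `individuals x V`), `individual_id`,
#'   `excluded` (ids lacking both sides).
#' @export
side_difference_map <- function(maps, meta, seed = 1L) {
  stopifnot(nrow(maps) == nrow(meta))
  set.seed(as.integer(seed))
  ids <- unique(meta$individual_id)
  rows <- list(); kept <- character(0); excluded <- character(0)
  for (id in ids) {
    i <- which(meta$individual_id == id)
    if (length(i) != 2 || !all(c("left", "right") %in% meta$side[i])) {
      excluded <- c(excluded, as.character(id))
      next
    }
    l <- i[meta$side[i] == "left"]; r <- i[meta$side[i] == "right"]
    thr_l <- meta$thr[l] == 1; thr_r <- meta$thr[r] == 1
    if (thr_l && !thr_r) d <- maps[l, ] - maps[r, ]
    else if (thr_r && !thr_l) d <- maps[r, ] - maps[l, ]
    else {
      # bilateral case or control: seeded random side first
      first_left <- stats::runif(1) < 0.5
      d <- if (first_left) maps[l, ] - maps[r, ] else maps[r, ] - maps[l, ]
    }
    rows[[length(rows) + 1]] <- d
    kept <- c(kept, as.character(id))
  }
  list(diff = do.call(rbind, rows), individual_id = kept, excluded = excluded)
}
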