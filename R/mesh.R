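#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates in millimetres, an `m x 3` integer matrix of 1-based
#' vertex indices per triangle, and optional named per-vertex data channels
#' (numeric vectors of length `n`, e.g. a JSW map). Outward per-vertex
#' normals are computed on demand and cached.
#'
#' @param vertices numeric matrix `n x 3` (mm).
#' @param faces integer matrix `m x 3`, 1-based, counter-clockwise winding
#'   seen from outside.
#' @param channels named list of per-vertex numeric vectors (optional).
#' @param normals optional `n x 3` matrix of unit vertex normals; computed
#'   from face geometry when absent.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, channels = list(), normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  for (ch in channels) stopifnot(length(ch) == nrow(vertices))
  m <- structure(
    list(vertices = vertices, faces = faces, channels = channels,
         normals = normals),
    class = "surface_mesh"
  )
  if (is.null(m$normals)) m$normals <- vertex_normals(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (length(x$channels)) cat("; channels:", paste(names(x$channels), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a [surface_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# Area-weighted outward vertex normals from face cross products.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  if (nrow(f) > 0) {
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    for (k in 1:3) {
      n[, 1] <- n[, 1] + tabulate_add(f[, k], fn[, 1], nrow(v))
      n[, 2] <- n[, 2] + tabulate_add(f[, k], fn[, 2], nrow(v))
      n[, 3] <- n[, 3] + tabulate_add(f[, k], fn[, 3], nrow(v))
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Undirected edge list (i < j), one row per unique edge.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# Edge lengths (mm) aligned with mesh_edges().
edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] - mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# Total surface area (mm^2) and per-face areas.
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# Boundary edges: edges used by exactly one face (directed count).
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  once <- names(tab)[tab == 1]
  e[key %in% once, , drop = FALSE]
}

#' Boundary loop (rim) of an open mesh
#'
#' Returns the ordered vertex indices of the longest boundary loop of an open
#' triangulated surface — for an acetabular patch this is the rim. The loop is
#' oriented consistently with the face winding.
#'
#' @param mesh a [surface_mesh()].
#' @return integer vector of vertex indices forming a closed loop
#'   (first vertex not repeated at the end).
#' @export
rim_loop <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) stop("mesh is closed: no boundary loop")
  nxt <- be[, 2]
  names(nxt) <- be[, 1]
  loops <- list()
  used <- rep(FALSE, nrow(be))
  starts <- be[, 1]
  while (any(!used)) {
    i0 <- starts[which(!used)[1]]
    loop <- integer(0)
    cur <- i0
    repeat {
      loop <- c(loop, cur)
      used[match(cur, starts)] <- TRUE
      cur <- unname(nxt[as.character(cur)])
      if (is.na(cur) || cur == i0) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops[[which.max(lengths(loops))]]
}

# Extract the sub-mesh induced by a vertex subset, keeping faces whose three
# corners survive; channels are subset too. Returns also the index map.
submesh <- function(mesh, keep) {
  keep <- sort(unique(keep))
  idx <- integer(n_vertices(mesh))
  idx[keep] <- seq_along(keep)
  f <- mesh$faces
  fk <- f[rowSums(matrix(f %in% keep, nrow(f), 3)) == 3, , drop = FALSE]
  fk <- matrix(idx[fk], ncol = 3)
  ch <- lapply(mesh$channels, function(c) c[keep])
  list(mesh = surface_mesh(mesh$vertices[keep, , drop = FALSE], fk, ch),
       index = keep)
}

# Largest connected component of a vertex subset (by mesh edges).
largest_component <- function(mesh, keep) {
  e <- mesh_edges(mesh)
  ink <- e[, 1] %in% keep & e[, 2] %in% keep
  g <- igraph::graph_from_edgelist(e[ink, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_vertices(mesh) - igraph::vcount(g)))
  comp <- igraph::components(g)
  mem <- comp$membership[keep]
  keep[mem == names(sort(table(mem), decreasing = TRUE))[1]]
}

#' Spherical cap mesh
#'
#' Builds a UV-parameterised triangulated cap of a sphere: an apex vertex at
#' polar angle 0 plus `n_theta` rings of `n_phi` vertices down to
#' `theta_max`. The open boundary ring at `theta_max` is the rim. Used for the
#' synthetic acetabular cup and the canonical surface; with
#' `theta_max = pi` minus a small cap it approximates a full sphere.
#'
#' @param radius sphere radius in mm (scalar, or function of `(theta, phi)`
#'   returning per-vertex radii for perturbed shapes).
#' @param theta_max polar extent of the cap in radians.
#' @param n_theta,n_phi grid resolution (rings, points per ring).
#' @param center sphere centre (length-3, mm).
#' @param axis unit vector of the polar axis (default `+z`, the superior
#'   direction in the package's hip convention).
#' @return a [surface_mesh()] with channels `theta` and `phi` storing the cap
#'   parameterisation.
#' @export
cap_mesh <- function(radius, theta_max = pi / 2, n_theta = 24, n_phi = 48,
                     center = c(0, 0, 0), axis = c(0, 0, 1)) {
  th <- seq(0, theta_max, length.out = n_theta + 1L)[-1]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = ph, theta = th)
  theta <- c(0, grid$theta)
  phi <- c(0, grid$phi)
  r <- if (is.function(radius)) radius(theta, phi) else rep(radius, length(theta))
  pts <- cbind(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi), r * cos(theta))
  R <- rotation_to_axis(axis)
  pts <- pts %*% t(R)
  pts <- sweep(pts, 2, center, `+`)
  faces <- cap_faces(n_theta, n_phi)
  surface_mesh(pts, faces, channels = list(theta = theta, phi = phi))
}

# Triangulation of the UV cap grid: fan at the apex, quads elsewhere;
# winding chosen so normals point outward (away from the sphere centre).
cap_faces <- function(n_theta, n_phi) {
  id <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  f <- list()
  for (j in 1:n_phi) f[[length(f) + 1L]] <- c(1L, id(1, j + 1), id(1, j))
  for (i in 1:(n_theta - 1L)) for (j in 1:n_phi) {
    a <- id(i, j); b <- id(i, j + 1); c <- id(i + 1, j); d <- id(i + 1, j + 1)
    f[[length(f) + 1L]] <- c(a, d, b)
    f[[length(f) + 1L]] <- c(a, c, d)
  }
  do.call(rbind, f)
}

# Rotation matrix carrying +z onto the given axis.
rotation_to_axis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2)); c_ <- sum(z * axis)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Flat rectangular grid mesh
#'
#' Regular triangulated grid in the `z = 0` plane, used for smoothing and
#' smoothness-estimation checks against planar Gaussian theory.
#'
#' @param nx,ny number of vertices along x and y.
#' @param spacing grid spacing in mm.
#' @return a [surface_mesh()].
#' @export
grid_mesh <- function(nx = 30, ny = 30, spacing = 1) {
  g <- expand.grid(x = (seq_len(nx) - 1) * spacing, y = (seq_len(ny) - 1) * spacing)
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1L) * nx + i
  f <- list()
  for (j in 1:(ny - 1L)) for (i in 1:(nx - 1L)) {
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    f[[length(f) + 1L]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  surface_mesh(v, do.call(rbind, f))
}

#' Canonical acetabular surface
#'
#' The fixed template cup onto which every hip is registered so that vertices
#' correspond across subjects. Generated as a right-hip hemispherical cap of
#' about 2,300 vertices (apex pointing superiorly), the size of the template
#' used in hip joint-space analyses.
#'
#' @param n_theta,n_phi resolution; defaults give 2,305 vertices.
#' @param radius mean cup radius in mm.
#' @param theta_max polar extent in radians.
#' @details The template is deliberately not a surface of revolution: a fixed
#'   low-order modulation of the radius breaks rotational symmetry (as a real
#'   acetabulum does), which keeps ICP rotations and rim starting points
#'   well defined.
#' @return a [surface_mesh()].
#' @export
canonical_surface <- function(n_theta = 48, n_phi = 48, radius = 28,
                              theta_max = 100 * pi / 180) {
  shape <- function(theta, phi) {
    radius * (1 + 0.06 * cos(phi) * sin(theta) + 0.04 * sin(2 * phi) * sin(theta)^2 +
                0.03 * cos(theta))
  }
  cap_mesh(shape, theta_max = theta_max, n_theta = n_theta, n_phi = n_phi)
}

# Brute-force nearest-vertex lookup: for each row of `query`, index of the
# closest row of `ref`. Chunked to bound memory.
nearest_vertex <- function(ref, query, chunk = 512L) {
  out <- integer(nrow(query))
  r2 <- rowSums(ref^2)
  for (s in seq(1, nrow(query), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q^2), r2, `+`) - 2 * q %*% t(ref)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}
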