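#' Read and write surface meshes
#'
#' `write_mesh()` emits ASCII PLY (with any per-vertex data channels as named
#' float properties) or ASCII STL (geometry only — asking for channels with
#' STL is an error, the format cannot carry them). `read_mesh()` accepts both
#' formats and recovers PLY per-vertex channels by name; normals are
#' recomputed from the geometry when not stored.
#'
#' @param mesh a [surface_mesh()].
#' @param path output/input file path; format chosen by extension
#'   (`.ply` / `.stl`).
#' @return `read_mesh()` returns a [surface_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_ply(mesh, path)
  else if (ext == "stl") write_stl(mesh, path)
  else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path)
  else if (ext == "stl") read_stl(path)
  else stop("unsupported mesh format: .", ext)
}

write_ply <- function(mesh, path) {
  ch <- mesh$channels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment jsmapr surface",
    sprintf("element vertex %d", n_vertices(mesh)),
    "property float x", "property float y", "property float z",
    sprintf("property float %s", names(ch)),
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"), con)
  vt <- cbind(mesh$vertices, do.call(cbind, unname(ch)))
  utils::write.table(format(vt, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  ft <- cbind(3L, mesh$faces - 1L)
  utils::write.table(ft, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path)
  endh <- which(lines == "end_header")[1]
  head <- lines[1:endh]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", head, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", head, value = TRUE)))
  vstart <- grep("^element vertex", head)
  vend <- grep("^element (face|end)", head)
  vend <- min(vend[vend > vstart], endh)
  props <- sub("^property \\S+ ", "", grep("^property (float|double)", head[vstart:vend], value = TRUE))
  vt <- utils::read.table(text = lines[(endh + 1):(endh + nv)])
  names(vt) <- props
  ft <- utils::read.table(text = lines[(endh + nv + 1):(endh + nv + nf)])
  extra <- setdiff(props, c("x", "y", "z"))
  channels <- stats::setNames(lapply(extra, function(p) vt[[p]]), extra)
  surface_mesh(as.matrix(vt[, c("x", "y", "z")]), as.matrix(ft[, 2:4]) + 1L,
               channels = channels)
}

write_stl <- function(mesh, path) {
  if (length(mesh$channels))
    stop("STL cannot carry per-vertex channels; write PLY instead")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid jsmapr", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    n <- n / max(sqrt(sum(n^2)), 1e-30)
    writeLines(c(
      sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "  outer loop",
      sprintf("    vertex %.17g %.17g %.17g", tri[, 1], tri[, 2], tri[, 3]),
      "  endloop", "endfacet"), con)
  }
  writeLines("endsolid jsmapr", con)
}

read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4])))
  key <- apply(round(m, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  verts <- m[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
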