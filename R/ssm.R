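#' Build a statistical shape model from displacement fields
#'
#' Principal component analysis of per-hip canonical-vertex displacement
#' fields (each hip a `3V`-vector: the registration displacement of every
#' canonical vertex). The mean field is removed, a thin SVD supplies the
#' orthonormal shape modes and their variances, and each hip's coefficients
#' are the projections of its centred field on the modes. Mode signs are
#' fixed deterministically by making each mode's largest-magnitude loading
#' positive, so coefficient directions are reproducible run to run.
#'
#' @param displacement_fields numeric matrix `hips x 3V` (each row a
#'   flattened displacement field), or a list of `V x 3` matrices.
#' @param ids optional hip identifiers for the coefficient rows.
#' @param tol relative eigenvalue threshold below which trailing modes are
#'   dropped as numerically zero.
#' @return a `shape_model`: list with `mean` (3V), `modes` (`3V x K`,
#'   orthonormal columns), `eigenvalues` (descending variances),
#'   `coefficients` (`hips x K`, named `SM1..SMK`), `variance_explained`
#'   (cumulative fractions), `ids`.
#' @export
build_shape_model <- function(displacement_fields, ids = NULL, tol = 1e-10) {
  X <- fields_to_matrix(displacement_fields)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 hips to build a shape model")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  keep <- which(ev > tol * max(ev, .Machine$double.eps))
  if (max(ev) <= 0 || !length(keep)) {
    return(structure(list(mean = mu, modes = matrix(0, ncol(X), 0),
                          eigenvalues = numeric(0),
                          coefficients = matrix(0, n, 0),
                          variance_explained = numeric(0), ids = ids),
                     class = "shape_model"))
  }
  modes <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest |loading| positive per mode
  for (k in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  coef <- Xc %*% modes
  ev <- ev[keep]
  structure(list(mean = mu, modes = modes, eigenvalues = ev,
                 coefficients = structure(coef, dimnames = list(
                   ids, paste0("SM", seq_along(ev)))),
                 variance_explained = cumsum(ev) / sum(ev), ids = ids),
            class = "shape_model")
}

fields_to_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(f) as.vector(t(f))))
  as.matrix(x)
}

#' @export
print.shape_model <- function(x, ...) {
  k7 <- min(7, length(x$eigenvalues))
  cat(sprintf("<shape_model> %d hips, %d modes; first %d modes explain %.1f%% of variance\n",
              nrow(x$coefficients), length(x$eigenvalues), k7,
              100 * x$variance_explained[k7]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy shape-model eigenstructure
#'
#' @param x a `shape_model`.
#' @param ... unused.
#' @return tibble with `mode`, `eigenvalue`, `sd`, `variance_fraction`,
#'   `cumulative_variance`.
#' @export
tidy.shape_model <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(mode = paste0("SM", seq_along(ev)), eigenvalue = ev,
                 sd = sqrt(ev), variance_fraction = ev / sum(ev),
                 cumulative_variance = cumsum(ev) / sum(ev))
}

#' @rdname tidy.shape_model
#' @return `glance()`: one-row tibble with `n_hips`, `n_modes`,
#'   `variance_first7`.
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(n_hips = nrow(x$coefficients),
                 n_modes = length(x$eigenvalues),
                 variance_first7 = x$variance_explained[min(7, length(x$eigenvalues))])
}

#' Scree plot of a shape model
#'
#' @param object a `shape_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shape_model <- function(object, ...) {
  d <- tidy(object)
  d$mode_index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode_index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$variance_fraction), fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_variance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_variance)) +
    ggplot2::labs(x = "shape mode", y = "variance fraction (bars), cumulative (line)") +
    ggplot2::theme_minimal()
}

#' Horn's parallel analysis for mode retention
#'
#' Compares each observed eigenvalue with the distribution of eigenvalues
#' obtained after independently permuting every column of the data matrix
#' (destroying inter-feature correlation while keeping marginals). Modes are
#' retained from the first while their eigenvalue exceeds the chosen quantile
#' of the corresponding permuted eigenvalue.
#'
#' @param data_matrix numeric `n x p` matrix (hips by features).
#' @param n_perm number of permutations (>= 100).
#' @param quantile retention quantile (default 0.95).
#' @param seed RNG seed.
#' @return integer: number of retained leading modes. The per-mode thresholds
#'   are attached as attribute `"thresholds"`.
#' @export
horns_parallel_analysis <- function(data_matrix, n_perm = 200, quantile = 0.95,
                                    seed = 1L) {
  stopifnot(n_perm >= 100)
  X <- as.matrix(data_matrix)
  n <- nrow(X); p <- ncol(X)
  k <- min(n - 1, p)
  # eigenvalues via the smaller Gram matrix (values only)
  ev_of <- function(M) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    G <- if (n <= p) tcrossprod(Mc) else crossprod(Mc)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values / (n - 1)
    pmax(ev[seq_len(k)], 0)
  }
  obs <- ev_of(X)
  set.seed(as.integer(seed))
  perm_ev <- matrix(0, n_perm, k)
  for (b in seq_len(n_perm)) {
    # independent within-column shuffles in one radix sort
    ord <- order(rep.int(seq_len(p), rep.int(n, p)), stats::runif(n * p))
    perm_ev[b, ] <- ev_of(matrix(X[ord], n, p))
  }
  thr <- apply(perm_ev, 2, stats::quantile, probs = quantile)
  above <- obs > thr
  retained <- if (all(above)) k else which.min(above) - 1L
  structure(as.integer(retained), thresholds = thr, observed = obs)
}

#' Shape-mode point clouds at +/- k SD
#'
#' Displaces the canonical vertices by the mean field plus and minus
#' `sd_multiplier` standard deviations of one shape mode — the conventional
#' visualisation of what a mode does.
#'
#' @param model a `shape_model`.
#' @param canonical the canonical [surface_mesh()].
#' @param mode_index which mode (1-based).
#' @param sd_multiplier displacement amplitude in mode SDs (default 3).
#' @return list of two `V x 3` matrices, `plus` and `minus`.
#' @export
mode_point_cloud <- function(model, canonical, mode_index, sd_multiplier = 3) {
  if (mode_index < 1 || mode_index > length(model$eigenvalues))
    stop("mode index out of range: ", mode_index)
  V <- canonical$vertices
  base <- V + vec3(model$mean)
  amp <- sd_multiplier * sqrt(model$eigenvalues[mode_index])
  dir <- vec3(model$modes[, mode_index])
  list(plus = base + amp * dir, minus = base - amp * dir)
}

vec3 <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Group mean shapes with exaggerated differences
#'
#' Mean displacement field per group applied to the canonical vertices, with
#' the vector magnitudes multiplied by `exaggeration` (default 3) to make
#' group differences visible.
#'
#' @param fields `hips x 3V` displacement matrix (or list of `V x 3`).
#' @param group_labels factor/vector, one per hip.
#' @param canonical the canonical [surface_mesh()].
#' @param exaggeration magnification of the mean displacement vectors.
#' @return named list of `V x 3` point clouds, one per group level.
#' @export
group_mean_shape <- function(fields, group_labels, canonical, exaggeration = 3) {
  X <- fields_to_matrix(fields)
  stopifnot(length(group_labels) == nrow(X))
  lv <- unique(group_labels)
  out <- list()
  for (g in lv) {
    rows <- which(group_labels == g)
    if (!length(rows)) stop("empty group: ", g)
    mu <- colMeans(X[rows, , drop = FALSE])
    out[[as.character(g)]] <- canonical$vertices + exaggeration * vec3(mu)
  }
  out
}

#' Average paired-hip coefficients (or maps) per individual
#'
#' Vertex-wise/column-wise mean over the available hips of each individual —
#' the clustering control used before surface statistics: one row per
#' individual.
#'
#' @param values matrix `hips x p`.
#' @param individual_ids vector, one id per hip row.
#' @return list: `values` (`individuals x p`), `individual_id`.
#' @export
average_paired_maps <- function(values, individual_ids) {
  values <- as.matrix(values)
  ids <- unique(individual_ids)
  out <- matrix(NA_real_, length(ids), ncol(values))
  for (i in seq_along(ids)) {
    rows <- which(individual_ids == ids[i])
    out[i, ] <- colMeans(values[rows, , drop = FALSE])
  }
  colnames(out) <- colnames(values)
  list(values = out, individual_id = ids)
}
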