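#' Generate paired synthetic hip surfaces with known JSW fields
#'
#' Mesh-level cohort generator: each hip is a hemispherical femoral head
#' (bone surface, radius `head_radius_mm` with small between-subject scale
#' variation) and a concentric acetabular cup whose per-vertex radius is the
#' head radius plus the planted JSW field, so the true head-to-cup distance
#' along the head normals equals the planted field by construction. Left
#' hips are exact sagittal mirror images of their right-hip geometry before
#' side-specific field noise. Case individuals (the first `n_cases`, with
#' replaced side(s) assigned by quota) carry the same superior narrowing /
#' posterior widening scheme as [simulate_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @param n_individuals how many individuals to generate (default the full
#'   cohort; geometry-level tests normally use far fewer).
#' @param n_theta,n_phi cup mesh resolution.
#' @param head_radius_mm mean femoral head (bone surface) radius.
#' @param cup_theta_max cup polar extent (radians).
#' @param seed overrides `spec$seed`.
#' @return tibble with one row per hip: `individual_id`, `side`, `case`,
#'   `thr`, and list-columns `femur`, `acetabulum` ([surface_mesh()]),
#'   `jsw_truth` (per-cup-vertex mm).
#' @export
make_paired_hip_surfaces <- function(spec = cohort_spec(), n_individuals = NULL,
                                     n_theta = 20, n_phi = 40,
                                     head_radius_mm = 24,
                                     cup_theta_max = 95 * pi / 180,
                                     seed = NULL) {
  set.seed(as.integer(if (is.null(seed)) spec$seed else seed))
  n_ind <- if (is.null(n_individuals)) spec$n_cases + spec$n_controls else n_individuals
  n_cases <- min(spec$n_cases, n_ind)
  R <- spec$side_correlation_R
  template <- cap_mesh(1, theta_max = cup_theta_max, n_theta = n_theta, n_phi = n_phi)
  th <- template$channels$theta; ph <- template$channels$phi
  w_sup <- superior_window(th, ph)
  w_post <- posterior_window(th, ph)
  B <- smooth_field_basis(th, ph, max(th))
  nb <- ncol(B)
  rows <- list()
  for (i in seq_len(n_ind)) {
    is_case <- i <= n_cases
    bilateral <- is_case && stats::runif(1) < spec$frac_bilateral
    replaced_side <- if (!is_case) NA_character_
      else if (bilateral) "both" else sample(c("left", "right"), 1)
    r_head <- head_radius_mm + stats::rnorm(1, 0, 0.8)
    f_ind <- stats::rnorm(nb)
    for (side in c("right", "left")) {
      f_side <- sqrt(R) * f_ind + sqrt(1 - R) * stats::rnorm(nb)
      field <- spec$field_sd_mm / sqrt(nb) * as.vector(B %*% f_side)
      thr <- is_case && replaced_side %in% c(side, "both")
      narrow <- if (thr) 1.5 else if (is_case) 0.5 else 0
      widen <- if (thr) 1 else 0
      g <- spec$base_jsw_mm + field -
        narrow * spec$narrowing_max_mm * w_sup +
        widen * spec$widening_post_mm * w_post
      if (min(g) <= 0.2)
        stop("degenerate geometry: cup radius would not clear the head")
      cup <- cap_mesh(function(t, p) r_head + g, theta_max = cup_theta_max,
                      n_theta = n_theta, n_phi = n_phi)
      head <- cap_mesh(r_head, theta_max = 130 * pi / 180,
                       n_theta = round(n_theta * 1.4), n_phi = n_phi)
      if (side == "left") {
        cup <- mirror_hip(cup, "left")
        head <- mirror_hip(head, "left")
      }
      cup$channels$jsw_truth <- g
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual_id = sprintf("I%03d", i), side = side,
        case = is_case, thr = as.integer(thr),
        femur = list(head), acetabulum = list(cup), jsw_truth = list(g))
    }
  }
  dplyr::bind_rows(rows)
}
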