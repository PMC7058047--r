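# Shared fixtures: small meshes and profile builders used across test files.

small_canonical <- function() canonical_surface(n_theta = 12, n_phi = 12)

tiny_canonical <- function() canonical_surface(n_theta = 8, n_phi = 10)

# Closed-form blurred profile of a two-plate phantom, as a density_profile.
model_profile <- function(gap, sigma, noise_sd = 0, spacing = 0.2,
                          half_len = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- phantom_spec(gap_mm = gap, psf_sigma_mm = sigma, noise_sd = noise_sd)
  x <- seq(-half_len, half_len, by = spacing)
  y <- jsmapr:::blurred_profile(sp, x)
  if (noise_sd > 0) y <- y + rnorm(length(x), 0, noise_sd)
  structure(list(offsets_mm = x, values = y, direction = c(0, 0, 1),
                 vertex = c(0, 0, 0), truncated = FALSE),
            class = "density_profile")
}

# Naive thresholded full-width comparator (package function, short alias).
naive_halfwidth_jsw <- function(profile, y_c) jsw_halfwidth(profile, y_c)
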