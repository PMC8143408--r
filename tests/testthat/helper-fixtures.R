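# Shared fixtures, built in code at test time.

default_surface <- function(...) retina_surface_params(...)

# closed-form surface value, written independently of surface_thickness_at()
surface_formula <- function(p, r) {
  p$plateau_thickness_um +
    p$dome_amplitude_um *
      exp(-(r - p$dome_radius_mm)^2 / (2 * (p$dome_radius_mm / 2)^2)) -
    p$pit_depth_um * exp(-r^2 / (2 * p$pit_width_mm^2))
}

small_map <- function(n = 32, params = default_surface()) {
  simulate_thickness_surface(params, n, n)
}

# distinct-valued QC indicator table
indicator_table <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    scan_id = sprintf("s%05d", seq_len(n)),
    image_quality = runif(n, 30, 70),
    ilm_indicator = runif(n, 0, 100),
    valid_count = runif(n),
    min_motion_correlation = runif(n, -1, 1),
    max_motion_delta = runif(n, 0, 50),
    max_motion_factor = runif(n, 0, 0.2)
  ))
}
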