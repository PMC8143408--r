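#' Parameters of the parametric macular thickness surface
#'
#' The macula has a valley-like morphology: total retinal thickness is roughly
#' constant peripherally, rises slightly over a parafoveal rim, and dips
#' sharply at the fovea. `retina_surface_params()` bundles the five knobs of
#' the generative surface used by the simulator:
#'
#' \deqn{T(x, y) = P + A \exp\left(-\frac{(r - R)^2}{2 (R/2)^2}\right)
#'              - D \exp\left(-\frac{r^2}{2 w^2}\right)}
#'
#' where `r` is the distance (mm) from the scan centre, `P` the plateau
#' thickness, `D`/`w` the foveal pit depth and Gaussian width, and `A`/`R` the
#' parafoveal rim (dome) amplitude and radius. A shallow pit (`D` near 0)
#' emulates foveal hypoplasia; the default `D = 75` gives a pronounced pit.
#'
#' @param plateau_thickness_um Peripheral total retinal thickness, micrometres
#'   (positive).
#' @param pit_depth_um Central pit amplitude, micrometres (non-negative; must
#'   be strictly less than `plateau_thickness_um`).
#' @param pit_width_mm Gaussian scale of the pit, millimetres (positive).
#' @param dome_amplitude_um Parafoveal rim bump amplitude, micrometres.
#' @param dome_radius_mm Radius of the rim, millimetres (positive).
#'
#' @return A list of class `"retina_surface_params"`.
#' @examples
#' p <- retina_surface_params(pit_depth_um = 40)
#' map <- simulate_thickness_surface(p, n_bscan = 32, n_ascan = 32)
#' @export
retina_surface_params <- function(plateau_thickness_um = 300,
                                  pit_depth_um = 75,
                                  pit_width_mm = 0.6,
                                  dome_amplitude_um = 20,
                                  dome_radius_mm = 1.5) {
  stopifnot(is.numeric(plateau_thickness_um), length(plateau_thickness_um) == 1,
            is.numeric(pit_depth_um), length(pit_depth_um) == 1)
  if (plateau_thickness_um <= 0) {
    abort("`plateau_thickness_um` must be positive.")
  }
  if (pit_depth_um < 0) {
    abort("`pit_depth_um` must be non-negative.")
  }
  if (pit_width_mm <= 0 || dome_radius_mm <= 0) {
    abort("`pit_width_mm` and `dome_radius_mm` must be positive.")
  }
  if (plateau_thickness_um - pit_depth_um <= 0) {
    abort("Central thickness must stay positive: need plateau_thickness_um - pit_depth_um > 0.")
  }
  structure(
    list(plateau_thickness_um = plateau_thickness_um,
         pit_depth_um = pit_depth_um,
         pit_width_mm = pit_width_mm,
         dome_amplitude_um = dome_amplitude_um,
         dome_radius_mm = dome_radius_mm),
    class = "retina_surface_params"
  )
}

#' Evaluate the parametric surface at given radii
#'
#' Closed-form evaluation of the thickness surface at radial distance `r_mm`
#' from the scan centre. Exposed so that tests and users can compare a derived
#' map against the generating formula.
#'
#' @param params A [retina_surface_params()] object.
#' @param r_mm Numeric vector of radial distances in millimetres.
#' @return Numeric vector of thicknesses in micrometres.
#' @export
surface_thickness_at <- function(params, r_mm) {
  stopifnot(inherits(params, "retina_surface_params"))
  dome_sd <- params$dome_radius_mm / 2
  params$plateau_thickness_um +
    params$dome_amplitude_um *
      exp(-(r_mm - params$dome_radius_mm)^2 / (2 * dome_sd^2)) -
    params$pit_depth_um * exp(-r_mm^2 / (2 * params$pit_width_mm^2))
}

#' Construct a thickness map object
#'
#' A thickness map is the per-(B-scan, A-scan) total retinal thickness in
#' micrometres over the scanned field, with a validity mask and the physical
#' extent of the raster.
#'
#' @param thickness_um Numeric matrix (B-scans in rows, A-scans in columns).
#' @param valid Logical matrix of the same dimension (default all `TRUE`).
#' @param extent_mm Side length of the (square) scanned field, millimetres.
#' @return An object of class `"thickness_map"`.
#' @export
new_thickness_map <- function(thickness_um, valid = NULL, extent_mm = 6) {
  stopifnot(is.matrix(thickness_um))
  if (is.null(valid)) {
    valid <- !is.na(thickness_um)
  }
  stopifnot(is.logical(valid), all(dim(valid) == dim(thickness_um)))
  structure(
    list(thickness_um = thickness_um, valid = valid, extent_mm = extent_mm),
    class = "thickness_map"
  )
}

#' Simulate a macular total-thickness surface
#'
#' Evaluates the parametric pit-and-rim surface on a regular raster covering
#' the scanned field (6 x 6 mm by default), emulating the thickness matrix
#' that boundary segmentation of a macular volume scan produces.
#'
#' @param params A [retina_surface_params()] object.
#' @param n_bscan,n_ascan Raster dimensions (rows = B-scans, columns =
#'   A-scans). Defaults are desk-scale (64 x 64); clinical hardware uses
#'   128 x 512.
#' @param extent_mm Side length of the scanned field in millimetres.
#' @return A [new_thickness_map()] object; `attr(, "params")` carries the
#'   generating parameters.
#' @examples
#' map <- simulate_thickness_surface(retina_surface_params())
#' range(map$thickness_um)
#' @export
simulate_thickness_surface <- function(params,
                                       n_bscan = 64,
                                       n_ascan = 64,
                                       extent_mm = 6) {
  stopifnot(inherits(params, "retina_surface_params"),
            n_bscan >= 2, n_ascan >= 2, extent_mm > 0)
  half <- extent_mm / 2
  yb <- seq(-half, half, length.out = n_bscan)
  xa <- seq(-half, half, length.out = n_ascan)
  r <- sqrt(outer(yb^2, xa^2, `+`))
  thickness <- surface_thickness_at(params, r)
  if (any(thickness <= 0)) {
    abort("Surface parameters produce non-positive thickness.")
  }
  out <- new_thickness_map(thickness, extent_mm = extent_mm)
  attr(out, "params") <- params
  out
}

#' @export
print.thickness_map <- function(x, ...) {
  d <- dim(x$thickness_um)
  cat(sprintf("<thickness_map> %d B-scans x %d A-scans over %.1f mm\n",
              d[1], d[2], x$extent_mm))
  ok <- x$valid
  cat(sprintf("  valid: %.1f%%; thickness %.1f-%.1f um\n",
              100 * mean(ok),
              suppressWarnings(min(x$thickness_um[ok])),
              suppressWarnings(max(x$thickness_um[ok]))))
  invisible(x)
}

#' Grid coordinates of a thickness map
#'
#' @param map A `thickness_map`.
#' @return List with `y_mm` (B-scan axis) and `x_mm` (A-scan axis) coordinate
#'   vectors, centred on 0.
#' @export
map_coordinates <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  d <- dim(map$thickness_um)
  half <- map$extent_mm / 2
  list(y_mm = seq(-half, half, length.out = d[1]),
       x_mm = seq(-half, half, length.out = d[2]))
}

#' Tidy a thickness map into a tibble
#'
#' One row per raster point with physical coordinates, thickness and validity.
#'
#' @param x A `thickness_map`.
#' @param ... Unused.
#' @return A tibble with columns `bscan`, `ascan`, `y_mm`, `x_mm`,
#'   `thickness_um`, `valid`.
#' @export
tidy.thickness_map <- function(x, ...) {
  co <- map_coordinates(x)
  d <- dim(x$thickness_um)
  tibble(
    bscan = rep(seq_len(d[1]), times = d[2]),
    ascan = rep(seq_len(d[2]), each = d[1]),
    y_mm = rep(co$y_mm, times = d[2]),
    x_mm = rep(co$x_mm, each = d[1]),
    thickness_um = as.vector(x$thickness_um),
    valid = as.vector(x$valid)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a thickness map as a filled raster
#'
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thickness_map <- function(object, ...) {
  df <- tidy.thickness_map(object)
  df$thickness_um[!df$valid] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Thickness (µm)",
                                  na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
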