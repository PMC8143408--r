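#' Macula 6 grid specification
#'
#' A six-subfield partition of the square macular field: a central circle
#' (excluded from analysis) surrounded by superior/inferior halves of three
#' concentric zones (inner, middle, outer annuli). The outer zone extends to
#' the field corners so the six included regions tile everything outside the
#' central circle. All radii are configurable, so alternative published
#' layouts can be substituted.
#'
#' @param central_radius_mm Radius of the excluded central circle.
#' @param inner_radius_mm,middle_radius_mm Outer radii of the inner and
#'   middle annuli.
#' @return A list of class `"macula6_grid"`.
#' @export
macula6_grid <- function(central_radius_mm = 0.5, inner_radius_mm = 1.5,
                         middle_radius_mm = 3) {
  stopifnot(central_radius_mm > 0, inner_radius_mm > central_radius_mm,
            middle_radius_mm > inner_radius_mm)
  structure(
    list(central_radius_mm = central_radius_mm,
         inner_radius_mm = inner_radius_mm,
         middle_radius_mm = middle_radius_mm),
    class = "macula6_grid"
  )
}

#' Region membership of every raster point of a thickness map
#'
#' @param map A `thickness_map`.
#' @param grid A [macula6_grid()].
#' @return Character matrix with values `"central"`,
#'   `"superior_inner"`, `"superior_middle"`, `"superior_outer"`,
#'   `"inferior_inner"`, `"inferior_middle"`, `"inferior_outer"`.
#' @export
macula6_membership <- function(map, grid = macula6_grid()) {
  stopifnot(inherits(map, "thickness_map"), inherits(grid, "macula6_grid"))
  co <- map_coordinates(map)
  d <- dim(map$thickness_um)
  y <- matrix(co$y_mm, d[1], d[2])
  x <- matrix(co$x_mm, d[1], d[2], byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  zone <- ifelse(r <= grid$central_radius_mm, "central",
          ifelse(r <= grid$inner_radius_mm, "inner",
          ifelse(r <= grid$middle_radius_mm, "middle", "outer")))
  hemi <- ifelse(y >= 0, "superior", "inferior")
  out <- ifelse(zone == "central", "central", paste(hemi, zone, sep = "_"))
  matrix(out, d[1], d[2])
}

#' Macula 6 subfield means and overall mean
#'
#' Subfield means are taken over the valid raster points of each region; the
#' overall mean is the point-weighted mean over all valid points of the six
#' included regions — the central field is excluded from analysis. A subfield
#' with no valid points yields `NA`, which propagates.
#'
#' @param map A `thickness_map`.
#' @param grid A [macula6_grid()].
#' @return Tibble with columns `region`, `mean_um`, `n_points`; the last row
#'   (`region == "overall"`) is the grid mean.
#' @examples
#' map <- simulate_thickness_surface(retina_surface_params(), 32, 32)
#' macula6_mean(map)
#' @export
macula6_mean <- function(map, grid = macula6_grid()) {
  mem <- macula6_membership(map, grid)
  regions <- c("superior_inner", "superior_middle", "superior_outer",
               "inferior_inner", "inferior_middle", "inferior_outer")
  th <- map$thickness_um
  th[!map$valid] <- NA_real_
  rows <- lapply(regions, function(rg) {
    vals <- th[mem == rg]
    tibble(region = rg,
           mean_um = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
           n_points = sum(!is.na(vals)))
  })
  incl <- th[mem != "central"]
  rows <- c(rows, list(tibble(
    region = "overall",
    mean_um = if (all(is.na(incl))) NA_real_ else mean(incl, na.rm = TRUE),
    n_points = sum(!is.na(incl))
  )))
  bind_rows(rows)
}

#' Regress technical covariates out of a per-eye trait
#'
#' Ordinary-least-squares fit of the trait on the per-eye covariates
#' (refractive error and the technical scan indicators); the adjusted value
#' is the residual plus the sample mean, so the scale and mean of the trait
#' are preserved. Collinear covariate columns are dropped with a warning.
#' Rows with missing values get `NA` adjusted values.
#'
#' @param data Per-eye data frame.
#' @param value Name of the trait column.
#' @param covariates Character vector of covariate column names.
#' @return `data` with an added `<value>_adj` column.
#' @export
regress_out_eye_covariates <- function(data, value,
                                       covariates = c(
                                         "refractive_error",
                                         "macula_centre_frame",
                                         "macula_centre_aline",
                                         "ilm_indicator", "valid_count",
                                         "min_motion_correlation",
                                         "max_motion_delta",
                                         "max_motion_factor",
                                         "image_quality")) {
  stopifnot(is.data.frame(data), value %in% names(data))
  covariates <- intersect(covariates, names(data))
  if (length(covariates) == 0) {
    abort("None of the requested covariates are present in `data`.")
  }
  df <- data[, c(value, covariates)]
  names(df)[1] <- ".y"
  fit <- lm(.y ~ ., data = df, na.action = stats::na.exclude)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped)) {
    warn(paste0("Dropped collinear covariate terms: ",
                paste(dropped, collapse = ", ")))
  }
  adj <- resid(fit) + mean(df$.y, na.rm = TRUE)
  data[[paste0(value, "_adj")]] <- as.numeric(adj)
  data
}

#' Average a trait across left and right eyes
#'
#' The participant-level value is the mean of the available eyes: both eyes
#' when both passed, the single available eye otherwise, missing only when
#' both are missing.
#'
#' @param left,right Numeric vectors (per-participant, one eye each).
#' @return Numeric vector of the same length.
#' @examples
#' average_eyes(c(100, 100, NA), c(110, NA, NA))
#' @export
average_eyes <- function(left, right) {
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# Extract a central cross-section (row or column nearest the field centre),
# interpolate invalid points, and fit a cubic smoothing spline.
fit_cross_spline <- function(vals, pos_mm, spar = NULL) {
  ok <- !is.na(vals)
  if (sum(ok) < 4) return(NULL)
  if (!all(ok)) {
    vals <- approx(pos_mm[ok], vals[ok], xout = pos_mm, rule = 2)$y
  }
  if (pop_sd(vals) == 0) {
    # degenerate constant profile: the spline is the constant itself
    return(list(constant = vals[1], x = pos_mm))
  }
  args <- list(x = pos_mm, y = vals)
  if (!is.null(spar)) args$spar <- spar
  do.call(smooth.spline, args)
}

predict_cross_spline <- function(fit, at) {
  if (is.null(fit)) return(NA_real_)
  if (!is.null(fit$constant)) return(fit$constant)
  predict(fit, at)$y
}

#' Smoothed central cross-sections of a thickness map
#'
#' Extracts the central row (fixed B-scan, varying A-scan) and central column
#' of the map — the rows/columns nearest the field centre — fits a cubic
#' smoothing spline to each (smoothing parameter chosen by generalised
#' cross-validation unless `spar` is given), and returns the smoothed vectors
#' sampled at the original positions. Invalid points are linearly
#' interpolated before fitting; an all-invalid cross-section yields `NA`s.
#'
#' @param map A `thickness_map`.
#' @param spar Optional fixed smoothing parameter for [stats::smooth.spline()].
#' @return List with tibbles `along_ascan` and `along_bscan` (columns
#'   `pos_mm`, `raw_um`, `smooth_um`) and the fitted spline objects.
#' @export
cross_section_splines <- function(map, spar = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  co <- map_coordinates(map)
  th <- map$thickness_um
  th[!map$valid] <- NA_real_
  b_mid <- which.min(abs(co$y_mm))
  a_mid <- which.min(abs(co$x_mm))
  row_vals <- th[b_mid, ]
  col_vals <- th[, a_mid]
  f_row <- fit_cross_spline(row_vals, co$x_mm, spar)
  f_col <- fit_cross_spline(col_vals, co$y_mm, spar)
  sm_row <- if (is.null(f_row)) rep(NA_real_, length(row_vals)) else
    predict_cross_spline(f_row, co$x_mm)
  sm_col <- if (is.null(f_col)) rep(NA_real_, length(col_vals)) else
    predict_cross_spline(f_col, co$y_mm)
  list(
    along_ascan = tibble(pos_mm = co$x_mm, raw_um = row_vals,
                         smooth_um = sm_row),
    along_bscan = tibble(pos_mm = co$y_mm, raw_um = col_vals,
                         smooth_um = sm_col),
    spline_ascan = f_row,
    spline_bscan = f_col
  )
}

#' Central foveal thickness of a map
#'
#' The overall retinal thickness at the midpoint of the two smoothed
#' cross-sectional vectors (one across A-scans, one across B-scans): each
#' spline is evaluated at the centre of the field (0 mm) and the two values
#' averaged.
#'
#' @param map A `thickness_map`.
#' @param spar Optional fixed smoothing parameter.
#' @return Thickness in micrometres (`NA` if both cross-sections are
#'   unusable).
#' @examples
#' map <- simulate_thickness_surface(retina_surface_params(), 32, 32)
#' central_foveal_thickness(map)
#' @export
central_foveal_thickness <- function(map, spar = NULL) {
  cs <- cross_section_splines(map, spar)
  v <- c(predict_cross_spline(cs$spline_ascan, 0),
         predict_cross_spline(cs$spline_bscan, 0))
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Central foveal thickness for every participant map of a cohort
#'
#' @param cohort An `oct_cohort` simulated with `keep_maps = TRUE`.
#' @param spar Optional fixed smoothing parameter.
#' @return Tibble with `participant_id`, `eye`, `cft_um`.
#' @export
cohort_foveal_thickness <- function(cohort, spar = NULL) {
  stopifnot(inherits(cohort, "oct_cohort"))
  if (is.null(cohort$maps)) {
    abort("Cohort was simulated without maps; rerun with `keep_maps = TRUE`.")
  }
  n <- dim(cohort$maps)[3]
  cft <- vapply(seq_len(n), function(i) {
    central_foveal_thickness(new_thickness_map(cohort$maps[, , i]), spar)
  }, numeric(1))
  tibble(participant_id = dimnames(cohort$maps)[[3]],
         eye = cohort$map_eye, cft_um = cft)
}

#' Genotype-stratified mean thickness maps and difference maps
#'
#' Stratifies the per-participant thickness maps by dosage of the alternative
#' allele (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternative), averages pointwise within each group, and forms the
#' difference maps heterozygous − reference and alternative − reference.
#' An empty dosage group yields `NULL` for its outputs, with a warning.
#'
#' @param maps 3-D array `(b_scan, a_scan, participant)` of thickness maps,
#'   or an `oct_cohort` with stored maps.
#' @param dosage Integer vector of dosages, one per participant (or, for a
#'   cohort, a variant id or dosage vector).
#' @param extent_mm Lateral field extent (metadata for plotting/peak
#'   localisation).
#' @return A list of class `"stratified_maps"`: `mean_maps` (named list
#'   `"0"`, `"1"`, `"2"`), `diff_het` (het − ref), `diff_alt` (alt − ref),
#'   `n` (group sizes), `extent_mm`.
#' @export
genotype_stratified_maps <- function(maps, dosage, extent_mm = 6) {
  if (inherits(maps, "oct_cohort")) {
    cohort <- maps
    if (is.null(cohort$maps)) abort("Cohort has no stored maps.")
    if (is.character(dosage) && length(dosage) == 1) {
      dosage <- cohort$dosages[, dosage]
    }
    maps <- cohort$maps
  }
  stopifnot(is.array(maps), length(dim(maps)) == 3,
            length(dosage) == dim(maps)[3])
  groups <- c("0", "1", "2")
  mean_maps <- setNames(vector("list", 3), groups)
  n <- setNames(integer(3), groups)
  for (g in 0:2) {
    idx <- which(dosage == g)
    n[as.character(g)] <- length(idx)
    if (length(idx) == 0) {
      warn(paste0("Dosage group ", g, " is empty; its outputs are missing."))
      next
    }
    mean_maps[[as.character(g)]] <-
      apply(maps[, , idx, drop = FALSE], c(1, 2), mean)
  }
  d_het <- if (!is.null(mean_maps[["1"]]) && !is.null(mean_maps[["0"]])) {
    mean_maps[["1"]] - mean_maps[["0"]]
  }
  d_alt <- if (!is.null(mean_maps[["2"]]) && !is.null(mean_maps[["0"]])) {
    mean_maps[["2"]] - mean_maps[["0"]]
  }
  structure(
    list(mean_maps = mean_maps, diff_het = d_het, diff_alt = d_alt, n = n,
         extent_mm = extent_mm),
    class = "stratified_maps"
  )
}

#' Location of the absolute maximum of a difference map
#'
#' @param diff_map Numeric matrix (e.g. `diff_alt` from
#'   [genotype_stratified_maps()]).
#' @param extent_mm Lateral field extent.
#' @return One-row tibble with `y_mm`, `x_mm`, `value_um` and `r_mm`
#'   (distance of the peak from the field centre).
#' @export
diff_map_peak <- function(diff_map, extent_mm = 6) {
  stopifnot(is.matrix(diff_map))
  idx <- which(abs(diff_map) == max(abs(diff_map)), arr.ind = TRUE)[1, ]
  half <- extent_mm / 2
  y <- seq(-half, half, length.out = nrow(diff_map))[idx[1]]
  x <- seq(-half, half, length.out = ncol(diff_map))[idx[2]]
  tibble(y_mm = y, x_mm = x, value_um = diff_map[idx[1], idx[2]],
         r_mm = sqrt(x^2 + y^2))
}

#' @export
print.stratified_maps <- function(x, ...) {
  cat(sprintf("<stratified_maps> group sizes: 0=%d, 1=%d, 2=%d\n",
              x$n["0"], x$n["1"], x$n["2"]))
  invisible(x)
}

#' Plot genotype-stratified difference maps
#'
#' @param object A `stratified_maps` object.
#' @param ... Unused.
#' @return A ggplot object with one panel per available difference map.
#' @export
autoplot.stratified_maps <- function(object, ...) {
  panels <- list(`het - ref` = object$diff_het,
                 `alt - ref` = object$diff_alt)
  panels <- panels[!vapply(panels, is.null, logical(1))]
  half <- object$extent_mm / 2
  df <- purrr::map_dfr(names(panels), function(nm) {
    m <- panels[[nm]]
    tibble(
      contrast = nm,
      y_mm = rep(seq(-half, half, length.out = nrow(m)), times = ncol(m)),
      x_mm = rep(seq(-half, half, length.out = ncol(m)), each = nrow(m)),
      diff_um = as.vector(m)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$diff_um)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_fill_gradient2(name = "Δ thickness (µm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Ganglion cell complex thickness
#'
#' The GCC is the collective name for the two inner retinal layers; its
#' thickness is the sum of the GCIPL and RNFL thicknesses.
#'
#' @param gcipl,rnfl Numeric vectors, micrometres.
#' @return Numeric vector, micrometres.
#' @examples
#' gcc_thickness(50, 30)
#' @export
gcc_thickness <- function(gcipl, rnfl) {
  gcipl + rnfl
}
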