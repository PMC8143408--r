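#' Running median with shrinking symmetric edge windows
#'
#' Smooths an intensity profile with a centred running median of odd width.
#' Near the edges the window shrinks symmetrically (width `2h + 1` with
#' `h = min(half, i - 1, n - i)`), so the output always has the input length
#' and `window = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer, at most `length(x)`.
#' @return Numeric vector of the same length.
#' @examples
#' running_median(c(0, 0, 9, 0, 0), 3)
#' @export
running_median <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 == 0) {
    abort("`window` must be an odd positive integer.")
  }
  if (window > length(x)) {
    abort("`window` must not exceed `length(x)`.")
  }
  cpp_running_median(as.numeric(x), as.integer(window))
}

#' Detect points of interest in a smoothed A-scan
#'
#' Points of interest are depth indices whose smoothed intensity lies strictly
#' outside two standard deviations of the median of the profile:
#' `|x_i - median(x)| > 2 * sd(x)`, with the population standard deviation of
#' the smoothed profile. A zero-variance profile yields an empty set.
#'
#' @param smoothed Numeric vector (length >= 3), typically the output of
#'   [running_median()].
#' @return Integer vector of depth indices (possibly empty).
#' @export
detect_points_of_interest <- function(smoothed) {
  if (length(smoothed) < 3) {
    abort("`smoothed` must have length >= 3.")
  }
  med <- median(smoothed)
  s <- pop_sd(smoothed)
  which(abs(smoothed - med) > 2 * s)
}

#' Segment one A-scan into ILM and BM depths
#'
#' Smooths the axial intensity profile with a running median, detects points
#' of interest, and labels the extreme indices of that set as the two
#' boundaries: with `orientation = "inner_high"` the maximum index (vitreous
#' side) is the ILM and the minimum the BM; `"inner_low"` mirrors this.
#' A-scans with fewer than two points of interest are flagged invalid, never
#' raised as errors.
#'
#' @param ascan Numeric intensity profile.
#' @param window Running-median window (odd).
#' @param orientation `"inner_high"` or `"inner_low"`.
#' @return List with `ilm`, `bm` (1-based depth indices, `NA` when invalid)
#'   and `valid`.
#' @export
segment_ascan <- function(ascan, window = 15,
                          orientation = c("inner_high", "inner_low")) {
  orientation <- match.arg(orientation)
  if (window %% 2 == 0 || window < 1) {
    abort("`window` must be an odd positive integer.")
  }
  res <- cpp_segment_ascan(as.numeric(ascan), as.integer(window),
                           orientation == "inner_high")
  list(ilm = res$ilm, bm = res$bm, valid = res$valid)
}

#' Interpolate outliers along each B-scan row of a boundary surface
#'
#' Within each B-scan row, a position is an outlier when its depth deviates
#' from the sliding-window median of the row by more than
#' `k_mad * max(MAD, mad_floor)`, where MAD is the (consistency-scaled)
#' median absolute deviation of the window's depths from that same sliding
#' median — the Hampel filter rule, whose window-local spread tolerates
#' genuine surface curvature (the foveal dip) while catching isolated
#' spikes. `mad_floor` guards against degenerate spread: boundaries are
#' voxel-quantised, so deviations below half a voxel are never outliers.
#' Outliers and invalid positions are replaced by linear interpolation along
#' the A-scan axis, with nearest-valid extrapolation at the row edges. Rows
#' with fewer than two valid anchors are marked wholly invalid.
#'
#' @param surface Numeric matrix of depths (B-scans in rows).
#' @param valid Logical matrix of the same dimension (default: non-`NA`).
#' @param window Sliding-median window in A-scan positions (odd).
#' @param k_mad Outlier multiplier.
#' @param mad_floor Lower bound on the MAD, in voxels.
#' @return List with `surface` (corrected depths) and `valid`.
#' @export
interpolate_boundary_outliers <- function(surface, valid = NULL, window = 11,
                                          k_mad = 3, mad_floor = 0.5) {
  stopifnot(is.matrix(surface), window %% 2 == 1, window >= 1)
  if (is.null(valid)) valid <- !is.na(surface)
  stopifnot(all(dim(valid) == dim(surface)))
  na_ <- ncol(surface)
  half <- (window - 1) %/% 2
  out <- surface
  out_valid <- valid
  for (b in seq_len(nrow(surface))) {
    d <- surface[b, ]
    v <- valid[b, ] & !is.na(d)
    if (sum(v) < 2) {
      out[b, ] <- NA_real_
      out_valid[b, ] <- FALSE
      next
    }
    stats_j <- vapply(seq_len(na_), function(j) {
      idx <- max(1, j - half):min(na_, j + half)
      vals <- d[idx][v[idx]]
      if (length(vals) == 0) return(c(NA_real_, NA_real_))
      m <- median(vals)
      c(m, 1.4826 * median(abs(vals - m)))
    }, numeric(2))
    med <- stats_j[1, ]
    mad_loc <- stats_j[2, ]
    dev <- abs(d - med)
    thr <- k_mad * pmax(mad_loc, mad_floor)
    good <- v & !is.na(dev) & dev <= thr
    if (sum(good) < 2) {
      out[b, ] <- NA_real_
      out_valid[b, ] <- FALSE
      next
    }
    filled <- approx(x = which(good), y = d[good], xout = seq_len(na_),
                     method = "linear", rule = 2)$y
    out[b, ] <- ifelse(good, d, filled)
    out_valid[b, ] <- TRUE
  }
  list(surface = out, valid = out_valid)
}

#' Segment a whole OCT volume
#'
#' Applies [segment_ascan()] to every A-scan of the volume (via a compiled
#' kernel) and then [interpolate_boundary_outliers()] to each of the two
#' composite boundary surfaces. Per-position validity is carried through; no
#' errors are raised for unsegmentable A-scans.
#'
#' @param volume An [new_oct_volume()] object.
#' @param window Running-median window (odd voxels).
#' @param interpolate Apply outlier interpolation to the composite surfaces?
#' @param outlier_window,k_mad,mad_floor Passed to
#'   [interpolate_boundary_outliers()].
#' @param fill_rows After the row-wise pass, fill B-scan rows that are wholly
#'   invalid (e.g. blink-suppressed) by linear interpolation across the
#'   B-scan axis from neighbouring valid rows, producing a composite surface
#'   over the whole raster. Volumes with no valid rows stay invalid.
#' @return A [new_boundary_surfaces()] object.
#' @examples
#' map <- simulate_thickness_surface(retina_surface_params(), 8, 8)
#' r <- render_oct_volume(map, n_depth = 160)
#' s <- segment_volume(r$volume)
#' @export
segment_volume <- function(volume, window = 15, interpolate = TRUE,
                           outlier_window = 11, k_mad = 3, mad_floor = 0.5,
                           fill_rows = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  res <- cpp_segment_volume(volume$intensities, as.integer(window),
                            volume$orientation == "inner_high")
  ilm <- res$ilm; bm <- res$bm; valid <- res$valid
  if (interpolate) {
    ci <- interpolate_boundary_outliers(ilm, valid, outlier_window, k_mad,
                                        mad_floor)
    cb <- interpolate_boundary_outliers(bm, valid, outlier_window, k_mad,
                                        mad_floor)
    ilm <- ci$surface; bm <- cb$surface
    valid <- ci$valid & cb$valid
    if (fill_rows) {
      filled_i <- fill_invalid_rows(ilm, valid)
      filled_b <- fill_invalid_rows(bm, valid)
      ilm <- filled_i$surface; bm <- filled_b$surface
      valid <- filled_i$valid & filled_b$valid
    }
    ilm[!valid] <- NA_real_
    bm[!valid] <- NA_real_
  }
  new_boundary_surfaces(ilm, bm, valid, dim(volume$intensities)[3],
                        volume$orientation)
}

# Column-wise linear interpolation across the B-scan axis for rows that are
# wholly invalid; requires at least two valid rows, else a no-op.
fill_invalid_rows <- function(surface, valid) {
  row_ok <- rowSums(valid) > 0
  if (all(row_ok) || sum(row_ok) < 2) {
    return(list(surface = surface, valid = valid))
  }
  for (a in seq_len(ncol(surface))) {
    ok <- valid[, a] & !is.na(surface[, a])
    if (sum(ok) < 2) next
    fill <- !ok & !row_ok
    if (!any(fill)) next
    surface[fill, a] <- approx(x = which(ok), y = surface[ok, a],
                               xout = which(fill), rule = 2)$y
    valid[fill, a] <- TRUE
  }
  list(surface = surface, valid = valid)
}

#' Total retinal thickness map from boundary surfaces
#'
#' Thickness is the absolute axial distance between the ILM and BM surfaces,
#' `|ilm - bm| * axial_voxel_um`, so the result is invariant to the depth
#' orientation convention. Validity masks are intersected.
#'
#' @param surfaces A [new_boundary_surfaces()] object.
#' @param axial_voxel_um Axial voxel size, micrometres.
#' @param extent_mm Lateral extent of the scanned field, millimetres.
#' @return A [new_thickness_map()] object.
#' @export
thickness_from_surfaces <- function(surfaces, axial_voxel_um = 3.5,
                                    extent_mm = 6) {
  stopifnot(inherits(surfaces, "boundary_surfaces"), axial_voxel_um > 0)
  th <- abs(surfaces$ilm - surfaces$bm) * axial_voxel_um
  th[!surfaces$valid] <- NA_real_
  new_thickness_map(th, surfaces$valid, extent_mm)
}
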