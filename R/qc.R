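#' ILM indicator: minimum localised edge strength at the ILM boundary
#'
#' Edge strength at a position is the absolute central-difference axial
#' intensity gradient evaluated at the (rounded) ILM depth; one-sided
#' differences are used at the volume borders. The indicator is the minimum
#' edge strength over all valid positions of the scan — blinks, signal fading
#' and segmentation failures drive it towards zero.
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `boundary_surfaces` for the same volume.
#' @return A single non-negative number; 0 when no position is valid.
#' @export
ilm_indicator <- function(volume, surfaces) {
  stopifnot(inherits(volume, "oct_volume"),
            inherits(surfaces, "boundary_surfaces"))
  ok <- which(surfaces$valid & !is.na(surfaces$ilm), arr.ind = TRUE)
  if (nrow(ok) == 0) return(0)
  nd <- dim(volume$intensities)[3]
  d <- round(surfaces$ilm[ok])
  d <- pmin(pmax(d, 1), nd)
  up <- pmin(d + 1, nd)
  dn <- pmax(d - 1, 1)
  i_up <- volume$intensities[cbind(ok, up)]
  i_dn <- volume$intensities[cbind(ok, dn)]
  g <- abs((i_up - i_dn) / (up - dn))
  min(g)
}

#' Valid count: fraction of unclipped, valid A-scans
#'
#' A position counts as valid when both boundaries are valid and lie within
#' `[margin + 1, n_depth - margin]` (i.e. at least `margin_voxels` away from
#' either end of the depth axis); scans with substantial z-axis clipping score
#' low.
#'
#' @param surfaces A `boundary_surfaces`.
#' @param margin_voxels Margin from the depth-range ends, voxels.
#' @return Fraction in `[0, 1]` over all raster positions.
#' @export
valid_count <- function(surfaces, margin_voxels = 5) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  lo <- margin_voxels + 1
  hi <- surfaces$n_depth - margin_voxels
  inside <- surfaces$valid &
    !is.na(surfaces$ilm) & !is.na(surfaces$bm) &
    surfaces$ilm >= lo & surfaces$ilm <= hi &
    surfaces$bm >= lo & surfaces$bm <= hi
  mean(inside)
}

#' Motion indicators from consecutive B-scan thickness profiles
#'
#' For every pair of consecutive B-scans and each of the two layers (nerve
#' fibre layer and full retinal thickness), computes the Pearson correlation
#' and the mean absolute difference of the per-A-scan thickness vectors. The
#' reported indicators are: the minimum correlation over all pairs and layers
#' (`min_motion_correlation`), the maximum mean absolute difference in µm
#' (`max_motion_delta`), and the maximum mean absolute difference divided by
#' the pooled mean thickness of the pair (`max_motion_factor`,
#' dimensionless). A zero-variance vector within a pair makes that pair's
#' correlation 0 and sets a flag.
#'
#' When no nerve-fibre-layer profiles are available the full-thickness
#' profiles are used for both layers and `nfl_from_full` is set.
#'
#' @param full_profiles Numeric matrix of full retinal thickness, B-scans in
#'   rows and A-scans in columns.
#' @param nfl_profiles Optional matrix of nerve fibre layer thickness of the
#'   same dimension.
#' @return One-row tibble with `min_motion_correlation`, `max_motion_delta`,
#'   `max_motion_factor`, `zero_variance` and `nfl_from_full`.
#' @export
motion_indicators <- function(full_profiles, nfl_profiles = NULL) {
  stopifnot(is.matrix(full_profiles), nrow(full_profiles) >= 2)
  nfl_from_full <- is.null(nfl_profiles)
  if (nfl_from_full) nfl_profiles <- full_profiles
  stopifnot(all(dim(nfl_profiles) == dim(full_profiles)))
  nb <- nrow(full_profiles)
  cors <- c(); deltas <- c(); factors <- c()
  zero_var <- FALSE
  for (layer in list(nfl_profiles, full_profiles)) {
    for (b in seq_len(nb - 1)) {
      x <- layer[b, ]; y <- layer[b + 1, ]
      if (pop_sd(x) == 0 || pop_sd(y) == 0) {
        cors <- c(cors, 0)
        zero_var <- TRUE
      } else {
        cors <- c(cors, cor(x, y))
      }
      d <- mean(abs(x - y))
      deltas <- c(deltas, d)
      pooled <- mean(c(x, y))
      factors <- c(factors, if (pooled == 0) NA_real_ else d / pooled)
    }
  }
  tibble(
    min_motion_correlation = min(cors),
    max_motion_delta = max(deltas),
    max_motion_factor = max(factors, na.rm = TRUE),
    zero_variance = zero_var,
    nfl_from_full = nfl_from_full
  )
}

# Mark the poorest floor(fraction * N) entries; entries tied with the cut
# value are retained (strictly-poorer removal). `poor_low` = TRUE when low
# values are poor.
mark_poorest <- function(x, fraction, poor_low) {
  n <- length(x)
  k <- floor(fraction * n)
  if (k <= 0) return(rep(FALSE, n))
  s <- sort(x, decreasing = !poor_low)
  if (k >= n) return(rep(TRUE, n))
  cut <- s[k + 1]
  if (poor_low) x < cut else x > cut
}

#' Apply the image-quality and percentile scan-removal rules
#'
#' Scans with `image_quality` below `quality_threshold` are removed.
#' Independently, for each of the five segmentation indicators, the poorest
#' `poorest_fraction` of the population is marked (poorest = lowest for
#' `ilm_indicator`, `valid_count` and `min_motion_correlation`; highest for
#' `max_motion_delta` and `max_motion_factor`); the removal set is the union
#' and every triggering rule is recorded as a reason. Percentiles are taken
#' over the full input population by default; `percentile_population =
#' "post_quality"` restricts them to scans that passed the quality-score rule.
#' Entries tied with the percentile cut value are retained, so with distinct
#' values each indicator marks exactly `floor(poorest_fraction * N)` scans.
#'
#' @param indicators Tibble with one row per scan: a `scan_id` column (or
#'   `participant_id` + `eye`, from which one is built) plus `image_quality`,
#'   `ilm_indicator`, `valid_count`, `min_motion_correlation`,
#'   `max_motion_delta`, `max_motion_factor`.
#' @param quality_threshold Image-quality score cut (strict `<` removal).
#' @param poorest_fraction Fraction removed per segmentation indicator.
#' @param percentile_population `"all"` or `"post_quality"`.
#' @return Tibble with `scan_id`, `kept` and a list-column `reasons` of rule
#'   labels (empty iff kept).
#' @examples
#' ind <- tibble::tibble(scan_id = paste0("s", 1:10),
#'   image_quality = 50 + 1:10, ilm_indicator = 1:10 * 1.0,
#'   valid_count = seq(0.5, 1, length.out = 10),
#'   min_motion_correlation = seq(0.4, 1, length.out = 10),
#'   max_motion_delta = 10:1 * 1.0, max_motion_factor = 10:1 / 100)
#' apply_image_qc(ind)
#' @export
apply_image_qc <- function(indicators, quality_threshold = 45,
                           poorest_fraction = 0.20,
                           percentile_population = c("all", "post_quality")) {
  percentile_population <- match.arg(percentile_population)
  if (nrow(indicators) == 0) {
    return(tibble(scan_id = character(), kept = logical(),
                  reasons = list()))
  }
  if (!"scan_id" %in% names(indicators)) {
    if (all(c("participant_id", "eye") %in% names(indicators))) {
      indicators$scan_id <- paste(indicators$participant_id, indicators$eye,
                                  sep = "_")
    } else {
      abort("`indicators` needs a `scan_id` column (or `participant_id` + `eye`).")
    }
  }
  needed <- c("image_quality", "ilm_indicator", "valid_count",
              "min_motion_correlation", "max_motion_delta",
              "max_motion_factor")
  missing_cols <- setdiff(needed, names(indicators))
  if (length(missing_cols)) {
    abort(paste0("Missing indicator columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  low_poor <- c("ilm_indicator", "valid_count", "min_motion_correlation")
  high_poor <- c("max_motion_delta", "max_motion_factor")

  quality_fail <- indicators$image_quality < quality_threshold
  pop <- if (percentile_population == "post_quality") !quality_fail else
    rep(TRUE, nrow(indicators))

  reasons <- vector("list", nrow(indicators))
  for (i in which(quality_fail)) {
    reasons[[i]] <- c(reasons[[i]], "image_quality")
  }
  for (col in c(low_poor, high_poor)) {
    marked <- rep(FALSE, nrow(indicators))
    marked[pop] <- mark_poorest(indicators[[col]][pop], poorest_fraction,
                                poor_low = col %in% low_poor)
    for (i in which(marked)) {
      reasons[[i]] <- c(reasons[[i]], paste0("poorest_", col))
    }
  }
  tibble(
    scan_id = indicators$scan_id,
    kept = lengths(reasons) == 0,
    reasons = lapply(reasons, function(r) r %||% character())
  )
}

#' Refractive error (spherical equivalent)
#'
#' `refractive error = spherical power + 0.5 * cylindrical power`, dioptres.
#'
#' @param spherical_power,cylindrical_power Numeric vectors, dioptres.
#' @return Numeric vector, dioptres.
#' @examples
#' refractive_error(-2, -1)
#' @export
refractive_error <- function(spherical_power, cylindrical_power) {
  spherical_power + 0.5 * cylindrical_power
}

#' Flag refractive-error outliers
#'
#' Default rule: a value is an outlier when it lies more than
#' `k * IQR + sd_slack * sd` from the median. The canonical configuration
#' (`k = 1.5`, `sd_slack = 0`) flags values outside 1.5 inter-quartile ranges
#' of the median; both constants are exposed because published phrasings of
#' this rule vary.
#'
#' @param values Numeric vector (dioptres).
#' @param k IQR multiplier.
#' @param sd_slack Additional slack in standard deviations.
#' @return Logical vector, `TRUE` = outlier (`NA` for missing input).
#' @export
refractive_outlier_mask <- function(values, k = 1.5, sd_slack = 0) {
  ok <- !is.na(values)
  med <- median(values[ok])
  iqr <- diff(quantile(values[ok], c(0.25, 0.75), names = FALSE))
  slack <- if (sd_slack > 0) sd_slack * sd(values[ok]) else 0
  out <- abs(values - med) > k * iqr + slack
  out[!ok] <- NA
  out
}

#' Keep participants near the genetic-PC centroid
#'
#' Retains participants whose Euclidean distance from the centroid of the
#' (PC1, PC2) cloud is at most `radius` (boundary inclusive). The radius can
#' alternatively be given as a quantile of the observed distances.
#'
#' @param pc1,pc2 Numeric vectors.
#' @param radius Absolute distance threshold (default `Inf` keeps everyone).
#' @param radius_quantile If non-`NULL`, overrides `radius` with this
#'   quantile of the distance distribution.
#' @return Logical vector, `TRUE` = kept.
#' @export
pc_distance_filter <- function(pc1, pc2, radius = Inf,
                               radius_quantile = NULL) {
  stopifnot(length(pc1) == length(pc2))
  d <- sqrt((pc1 - mean(pc1))^2 + (pc2 - mean(pc2))^2)
  if (!is.null(radius_quantile)) {
    radius <- quantile(d, radius_quantile, names = FALSE)
  }
  d <= radius
}

#' Remove related participants by greedy vertex deletion
#'
#' Builds a relatedness graph over pairs related to at most `max_degree`
#' (e.g. third degree or closer) and greedily deletes the node with the most
#' remaining relationships until no edge remains; among equally connected
#' nodes the lexicographically smallest id is deleted, making the result
#' deterministic. The retained set therefore induces an edge-free subgraph.
#'
#' @param pairs Data frame with columns `id1`, `id2`, `degree`.
#' @param ids Universe of participant ids (default: ids appearing in
#'   `pairs`); unrelated ids are always retained.
#' @param max_degree Only pairs with `degree <= max_degree` count as related.
#' @return Character vector of retained ids (sorted).
#' @examples
#' kinship_filter(tibble::tibble(id1 = "A", id2 = "B", degree = 2))
#' @export
kinship_filter <- function(pairs, ids = NULL, max_degree = 3) {
  stopifnot(is.data.frame(pairs),
            all(c("id1", "id2", "degree") %in% names(pairs)))
  ids <- ids %||% sort(unique(c(pairs$id1, pairs$id2)))
  pairs <- pairs[pairs$degree <= max_degree, , drop = FALSE]
  removed <- character()
  edges <- pairs[, c("id1", "id2")]
  edges <- edges[edges$id1 != edges$id2, , drop = FALSE]
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    worst <- names(deg)[deg == max(deg)]
    victim <- sort(worst)[1]
    removed <- c(removed, victim)
    edges <- edges[edges$id1 != victim & edges$id2 != victim, , drop = FALSE]
  }
  sort(setdiff(ids, removed))
}
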