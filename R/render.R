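#' Construct an OCT volume object
#'
#' A volume is a 3-D intensity array indexed `(b_scan, a_scan, depth)` plus
#' the physical metadata needed to interpret it: the axial voxel size, lateral
#' spacing, eye laterality and the depth orientation convention
#' (`"inner_high"`: the inner retina / vitreous lies at high depth index).
#'
#' @param intensities 3-D numeric array `(b_scan, a_scan, depth)`.
#' @param axial_voxel_um Axial voxel size in micrometres (positive).
#' @param extent_mm Lateral side length of the scanned field, millimetres.
#' @param eye `"left"` or `"right"`.
#' @param orientation `"inner_high"` or `"inner_low"`.
#' @return An object of class `"oct_volume"`.
#' @export
new_oct_volume <- function(intensities, axial_voxel_um = 3.5, extent_mm = 6,
                           eye = "left", orientation = "inner_high") {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3,
            axial_voxel_um > 0)
  eye <- match.arg(eye, c("left", "right"))
  orientation <- match.arg(orientation, c("inner_high", "inner_low"))
  if (any(!is.finite(intensities))) {
    abort("Volume intensities must be finite.")
  }
  structure(
    list(intensities = intensities, axial_voxel_um = axial_voxel_um,
         extent_mm = extent_mm, eye = eye, orientation = orientation),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<oct_volume> %d B-scans x %d A-scans x %d depth voxels (%s eye, %s, %.2f um axial)\n",
    d[1], d[2], d[3], x$eye, x$orientation, x$axial_voxel_um))
  invisible(x)
}

#' Construct a boundary-surfaces object
#'
#' Per-(B-scan, A-scan) depth voxel indices of the inner limiting membrane
#' (ILM) and Bruch's membrane (BM), with a validity mask.
#'
#' @param ilm,bm Numeric matrices of depth indices (1-based; may be fractional
#'   after interpolation).
#' @param valid Logical matrix; positions where both boundaries are usable.
#' @param n_depth Depth extent of the source volume in voxels.
#' @param orientation Depth orientation convention of the source volume.
#' @return An object of class `"boundary_surfaces"`.
#' @export
new_boundary_surfaces <- function(ilm, bm, valid, n_depth,
                                  orientation = "inner_high") {
  stopifnot(is.matrix(ilm), all(dim(bm) == dim(ilm)),
            all(dim(valid) == dim(ilm)))
  structure(
    list(ilm = ilm, bm = bm, valid = valid, n_depth = n_depth,
         orientation = match.arg(orientation, c("inner_high", "inner_low"))),
    class = "boundary_surfaces"
  )
}

#' @export
print.boundary_surfaces <- function(x, ...) {
  cat(sprintf("<boundary_surfaces> %d x %d positions, %.1f%% valid (%s)\n",
              nrow(x$ilm), ncol(x$ilm), 100 * mean(x$valid), x$orientation))
  invisible(x)
}

#' Render a synthetic OCT volume from a thickness surface
#'
#' Produces an intensity volume with a bright reflective band at the ILM and
#' at the BM of every A-scan, so that the segmentation pipeline can be
#' exercised against known truth. Bands are `band_width` voxels wide with a
#' linearly decaying intensity profile peaked exactly at the truth boundary
#' voxel (the ILM band extends outward from the inner boundary, the BM band
#' inward from the outer boundary). With the default `inner_high` orientation
#' BM sits at a fixed base depth and the ILM at
#' `base + round(thickness / axial_voxel_um)`.
#'
#' Optional artifacts emulate the common scan failures:
#' * `blink_bscans`: bands suppressed (background only) in those B-scans;
#' * `motion_bscans`: whole B-scans shifted axially by a random integer shift
#'   up to `motion_max_shift` voxels (truth surfaces shift with them);
#' * `clip_ascans`: those A-scan columns are pushed outside the depth range
#'   (bands not rendered, truth marked invalid), emulating z-clipping.
#'
#' @param map A [new_thickness_map()] object (truth thickness in micrometres).
#' @param axial_voxel_um Axial voxel size, micrometres.
#' @param n_depth Number of depth voxels.
#' @param bm_base_voxel Depth index of the BM surface (all A-scans).
#' @param band_intensity Peak band intensity.
#' @param background Background intensity.
#' @param band_width Band width in voxels. Matching the segmentation's
#'   running-median window makes noiseless recovery exact.
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param blink_bscans,motion_bscans,clip_ascans Integer index vectors
#'   selecting artifact-affected B-scans / A-scan columns (see Details).
#' @param motion_max_shift Maximum axial shift (voxels) for motion artifacts.
#' @param eye,orientation Metadata passed to [new_oct_volume()].
#' @param seed Integer seed; the render is a pure function of (inputs, seed).
#' @return A list of class `"rendered_oct"` with elements `volume`
#'   (`oct_volume`) and `truth` (`boundary_surfaces`).
#' @examples
#' map <- simulate_thickness_surface(retina_surface_params(), 16, 16)
#' r <- render_oct_volume(map, seed = 1)
#' @export
render_oct_volume <- function(map,
                              axial_voxel_um = 3.5,
                              n_depth = 256,
                              bm_base_voxel = 30,
                              band_intensity = 200,
                              background = 10,
                              band_width = 15,
                              noise_sd = 0,
                              blink_bscans = integer(),
                              motion_bscans = integer(),
                              clip_ascans = integer(),
                              motion_max_shift = 8,
                              eye = "left",
                              orientation = "inner_high",
                              seed = NULL) {
  stopifnot(inherits(map, "thickness_map"), band_intensity > background,
            band_width >= 1, bm_base_voxel > band_width)
  orientation <- match.arg(orientation, c("inner_high", "inner_low"))
  d <- dim(map$thickness_um)
  nb <- d[1]; na_ <- d[2]
  thick_vox <- round(map$thickness_um / axial_voxel_um)
  bm <- matrix(bm_base_voxel, nb, na_)
  ilm <- bm + thick_vox
  clip_ascans <- intersect(as.integer(clip_ascans), seq_len(na_))
  clipped <- matrix(FALSE, nb, na_)
  if (length(clip_ascans)) clipped[, clip_ascans] <- TRUE
  if (any(ilm[!clipped] + motion_max_shift * (length(motion_bscans) > 0) >
            n_depth)) {
    abort(paste0("Thickness exceeds the depth range: increase `n_depth` or ",
                 "flag the affected A-scans as clipped."))
  }

  with_seed(seed, {
    contrast <- band_intensity - background
    vol <- array(background, dim = c(nb, na_, n_depth))
    bseq <- rep(seq_len(nb), times = na_)
    aseq <- rep(seq_len(na_), each = nb)
    keep <- !as.vector(clipped)
    # decaying band profiles, peak value at the truth boundary voxel
    for (off in 0:(band_width - 1)) {
      val <- background + contrast * (band_width - off) / band_width
      di <- as.vector(ilm) - off      # ILM band extends inward (lower index)
      db <- as.vector(bm) + off       # BM band extends inward (higher index)
      oki <- keep & di >= 1 & di <= n_depth
      okb <- keep & db >= 1 & db <= n_depth
      vol[cbind(bseq[oki], aseq[oki], di[oki])] <- val
      vol[cbind(bseq[okb], aseq[okb], db[okb])] <- val
    }

    valid <- map$valid & !clipped
    ilm_t <- ifelse(valid, ilm, NA_real_)
    bm_t <- ifelse(valid, bm, NA_real_)

    motion_bscans <- intersect(as.integer(motion_bscans), seq_len(nb))
    shifts <- setNames(integer(length(motion_bscans)),
                       as.character(motion_bscans))
    for (b in motion_bscans) {
      s <- sample(c(-motion_max_shift:-1, 1:motion_max_shift), 1)
      shifts[as.character(b)] <- s
      slice <- matrix(background, na_, n_depth)
      src <- seq_len(n_depth) - s
      ok <- src >= 1 & src <= n_depth
      slice[, which(ok)] <- vol[b, , src[ok]]
      vol[b, , ] <- slice
      ilm_t[b, ] <- ilm_t[b, ] + s
      bm_t[b, ] <- bm_t[b, ] + s
      out <- !is.na(ilm_t[b, ]) & (ilm_t[b, ] > n_depth | bm_t[b, ] < 1)
      valid[b, out] <- FALSE
      ilm_t[b, out] <- NA_real_
      bm_t[b, out] <- NA_real_
    }

    blink_bscans <- intersect(as.integer(blink_bscans), seq_len(nb))
    for (b in blink_bscans) vol[b, , ] <- background

    if (noise_sd > 0) {
      vol <- vol + array(rnorm(length(vol), 0, noise_sd), dim = dim(vol))
    }

    if (orientation == "inner_low") {
      vol <- vol[, , n_depth:1, drop = FALSE]
      ilm_t <- n_depth + 1 - ilm_t
      bm_t <- n_depth + 1 - bm_t
    }

    structure(
      list(
        volume = new_oct_volume(vol, axial_voxel_um, map$extent_mm, eye,
                                orientation),
        truth = new_boundary_surfaces(ilm_t, bm_t, valid, n_depth,
                                      orientation),
        motion_shifts = shifts,
        blink_bscans = blink_bscans,
        clip_ascans = clip_ascans
      ),
      class = "rendered_oct"
    )
  })
}
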