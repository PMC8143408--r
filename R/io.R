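#' Write a thickness map as a TSV matrix with a metadata sidecar
#'
#' The matrix is written as a headerless TSV (B-scans in rows); invalid
#' positions are written as `NA`. A YAML sidecar (`<path>.meta.yaml`) records
#' the field extent.
#'
#' @param map A `thickness_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_thickness_tsv <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  th <- map$thickness_um
  th[!map$valid] <- NA_real_
  utils::write.table(th, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(extent_mm = map$extent_mm,
                        n_bscan = nrow(th), n_ascan = ncol(th)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a thickness map written by [write_thickness_tsv()]
#'
#' @param path TSV path.
#' @return A `thickness_map`.
#' @export
read_thickness_tsv <- function(path) {
  th <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(th) <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  extent <- if (file.exists(meta_path)) {
    yaml::read_yaml(meta_path)$extent_mm
  } else 6
  new_thickness_map(th, extent_mm = extent)
}

#' Write an OCT volume as a multi-page TIFF with a metadata sidecar
#'
#' One 32-bit float page per B-scan (A-scans in rows, depth in columns),
#' intensities rescaled to `[0, 1]`; the scaling and acquisition metadata go
#' to a YAML sidecar so the volume round-trips through
#' [read_oct_volume_tiff()].
#'
#' @param volume An `oct_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_oct_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  v <- volume$intensities
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[1]), function(b) {
    (v[b, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  yaml::write_yaml(
    list(intensity_min = lo, intensity_scale = scale,
         axial_voxel_um = volume$axial_voxel_um,
         extent_mm = volume$extent_mm, eye = volume$eye,
         orientation = volume$orientation),
    paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an OCT volume written by [write_oct_volume_tiff()]
#'
#' @param path TIFF path (its `.meta.yaml` sidecar must sit alongside).
#' @return An `oct_volume`.
#' @export
read_oct_volume_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nb <- length(pages)
  na_ <- nrow(pages[[1]]); nd <- ncol(pages[[1]])
  v <- array(NA_real_, c(nb, na_, nd))
  for (b in seq_len(nb)) {
    v[b, , ] <- pages[[b]] * meta$intensity_scale + meta$intensity_min
  }
  new_oct_volume(v, axial_voxel_um = meta$axial_voxel_um,
                 extent_mm = meta$extent_mm, eye = meta$eye,
                 orientation = meta$orientation)
}

#' Build a cohort configuration from a YAML file
#'
#' The file may contain any of the [cohort_config()] arguments (scalars or
#' named mappings) plus a `variants` list whose entries hold
#' [variant_spec()] fields and a `surface` mapping with
#' [retina_surface_params()] fields.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("n_participants", "noise_sd_um", "map_noise_sd_um",
                          "eye_correlation", "glaucoma_fraction",
                          "gcc_deficit_um", "n_bscan", "n_ascan", "seed"))]
  if (!is.null(cfg$covariate_effects)) {
    args$covariate_effects <- unlist(cfg$covariate_effects)
  }
  if (!is.null(cfg$artifact_rates)) {
    args$artifact_rates <- unlist(cfg$artifact_rates)
  }
  if (!is.null(cfg$surface)) {
    args$surface <- do.call(retina_surface_params, cfg$surface)
  }
  if (!is.null(cfg$variants)) {
    args$variants <- bind_rows(lapply(cfg$variants, function(v) {
      do.call(variant_spec, v)
    }))
  }
  do.call(cohort_config, args)
}
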