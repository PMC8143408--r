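#' Configuration for a simulated OCT cohort
#'
#' Bundles everything that defines a synthetic study population: sample size,
#' the variant table, covariate effects on overall retinal thickness, noise
#' levels, the between-eye correlation of thickness noise, artifact rates and
#' the base surface parameters.
#'
#' @param n_participants Number of participants (>= 2).
#' @param variants Variant table from [variant_spec()] rows.
#' @param covariate_effects Named numeric vector mapping participant
#'   covariates (`age`, `weight`, `height`, `sex`) to a slope in micrometres
#'   of plateau thickness per covariate unit.
#' @param noise_sd_um SD of per-eye plateau-thickness noise (µm).
#' @param map_noise_sd_um SD of per-raster-point measurement noise on
#'   thickness maps (µm).
#' @param eye_correlation Correlation in `[0, 1]` of the thickness noise
#'   between a participant's two eyes.
#' @param artifact_rates Named probabilities for `blink`, `motion`, `clip`
#'   scan artifacts (per eye).
#' @param glaucoma_fraction Fraction of participants labelled glaucomatous.
#' @param gcc_deficit_um Mean ganglion cell complex deficit (µm) applied to
#'   glaucomatous participants' inner-layer thicknesses.
#' @param surface Base [retina_surface_params()].
#' @param n_bscan,n_ascan Raster dimensions of simulated thickness maps.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants,
                          variants = variant_spec("rs_null"),
                          covariate_effects = c(age = -0.15),
                          noise_sd_um = 5,
                          map_noise_sd_um = 2,
                          eye_correlation = 0.8,
                          artifact_rates = c(blink = 0.01, motion = 0.02,
                                             clip = 0.01),
                          glaucoma_fraction = 0.08,
                          gcc_deficit_um = 10,
                          surface = retina_surface_params(),
                          n_bscan = 64,
                          n_ascan = 64,
                          seed = 1) {
  stopifnot(is.numeric(n_participants), n_participants >= 2,
            is.data.frame(variants))
  if (eye_correlation < 0 || eye_correlation > 1) {
    abort("`eye_correlation` must lie in [0, 1].")
  }
  rates <- artifact_rates[c("blink", "motion", "clip")]
  rates[is.na(rates)] <- 0
  names(rates) <- c("blink", "motion", "clip")
  if (any(rates < 0 | rates > 1) || glaucoma_fraction < 0 ||
      glaucoma_fraction > 1) {
    abort("Artifact rates and `glaucoma_fraction` must be probabilities.")
  }
  stopifnot(noise_sd_um >= 0, map_noise_sd_um >= 0)
  structure(
    list(n_participants = as.integer(n_participants), variants = variants,
         covariate_effects = covariate_effects, noise_sd_um = noise_sd_um,
         map_noise_sd_um = map_noise_sd_um, eye_correlation = eye_correlation,
         artifact_rates = rates, glaucoma_fraction = glaucoma_fraction,
         gcc_deficit_um = gcc_deficit_um, surface = surface,
         n_bscan = n_bscan, n_ascan = n_ascan, seed = seed),
    class = "cohort_config"
  )
}

#' Simulate a ground-truthed OCT cohort
#'
#' Draws participants with covariates, Hardy-Weinberg genotypes, per-eye
#' surface parameters perturbed by genotype and covariate effects, per-eye
#' inner-layer thickness phenotypes, visual acuity, ordinal hair colour,
#' glaucoma labels, scan-quality indicators with injected artifacts, and
#' (optionally) per-participant truth thickness maps for one eye.
#'
#' Effect injection follows the variant table: foveal variants subtract
#' `beta_um_per_allele * dosage` from the pit depth (shallower pit, thicker
#' central fovea), diffuse variants add it to the plateau thickness. Per-eye
#' plateau noise is `noise_sd_um * (sqrt(rho) z_participant +
#' sqrt(1 - rho) z_eye)` so eyes correlate at `rho = eye_correlation`.
#'
#' @param config A [cohort_config()].
#' @param keep_maps Store truth thickness maps (array `n_bscan x n_ascan x n`)
#'   for `map_eye`? Needed for genotype-stratified mapping.
#' @param map_eye Which eye's maps to store (`"left"`, following the central
#'   foveal thickness convention).
#' @return A list of class `"oct_cohort"`: `participants` (tibble, one row per
#'   participant), `eyes` (tibble, one row per eye with truth values, traits
#'   and QC indicators), `dosages` (matrix), `variants`, `maps`, `map_eye`,
#'   `config`.
#' @examples
#' cfg <- cohort_config(50, seed = 7)
#' coh <- simulate_cohort(cfg, keep_maps = FALSE)
#' @export
simulate_cohort <- function(config, keep_maps = TRUE, map_eye = "left") {
  stopifnot(inherits(config, "cohort_config"))
  map_eye <- match.arg(map_eye, c("left", "right"))
  n <- config$n_participants
  v <- config$variants
  surf <- config$surface

  with_seed(config$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    participants <- tibble(
      participant_id = ids,
      age = rnorm(n, 57, 8),
      sex = rbinom(n, 1, 0.5),
      weight = rnorm(n, 78, 14),
      height = rnorm(n, 170, 9),
      machine_id = sample(c("machine_A", "machine_B"), n, replace = TRUE),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
      pc5 = rnorm(n),
      spherical_power = rnorm(n, -0.25, 1.5),
      cylindrical_power = rnorm(n, -0.3, 0.5)
    )

    dosages <- vapply(v$maf, function(p) rbinom(n, 2L, p), integer(n))
    dosages <- matrix(dosages, nrow = n, dimnames = list(ids, v$id))

    fov <- v$effect_mode == "foveal"
    dif <- v$effect_mode == "diffuse"
    pit_shift <- if (any(fov)) {
      drop(dosages[, fov, drop = FALSE] %*% v$beta_um_per_allele[fov])
    } else rep(0, n)
    plateau_shift <- if (any(dif)) {
      drop(dosages[, dif, drop = FALSE] %*% v$beta_um_per_allele[dif])
    } else rep(0, n)

    ce <- config$covariate_effects
    for (nm in names(ce)) {
      if (!nm %in% names(participants)) {
        abort(paste0("Unknown covariate in `covariate_effects`: ", nm))
      }
      plateau_shift <- plateau_shift + ce[[nm]] * participants[[nm]]
    }

    pit_i <- pmax(surf$pit_depth_um - pit_shift, 0)

    rho <- config$eye_correlation
    z_shared <- rnorm(n)
    glaucoma <- runif(n) < config$glaucoma_fraction

    acuity_shift <- drop(dosages %*% v$beta_acuity_per_allele)
    latent_pigment <- drop(dosages %*% v$beta_pigment_per_allele) + rnorm(n)
    hair_colour <- as.integer(cut(latent_pigment,
                                  breaks = quantile(latent_pigment,
                                                    c(0, .25, .5, .75, 1)),
                                  include.lowest = TRUE, labels = FALSE))
    participants$hair_colour <- hair_colour
    participants$red_hair <- runif(n) < 0.04
    participants$glaucoma <- glaucoma
    participants$latent_pigment <- latent_pigment

    rates <- config$artifact_rates
    dome0 <- surf$dome_amplitude_um * exp(-2)  # dome term at r = 0
    eye_tbl <- lapply(c("left", "right"), function(eye) {
      z_eye <- rnorm(n)
      noise <- config$noise_sd_um *
        (sqrt(rho) * z_shared + sqrt(1 - rho) * z_eye)
      plateau_ie <- surf$plateau_thickness_um + plateau_shift + noise
      cft_true <- plateau_ie + dome0 - pit_i
      rnfl <- 29 + 0.30 * (plateau_ie - surf$plateau_thickness_um) +
        rnorm(n, 0, 1.5) - ifelse(glaucoma, 0.4 * config$gcc_deficit_um, 0)
      gcipl <- 75 + 0.40 * (plateau_ie - surf$plateau_thickness_um) +
        rnorm(n, 0, 1.5) - ifelse(glaucoma, 0.6 * config$gcc_deficit_um, 0)
      blink <- runif(n) < rates["blink"]
      motion <- runif(n) < rates["motion"]
      clip <- runif(n) < rates["clip"]
      tibble(
        participant_id = ids, eye = eye,
        plateau_um = plateau_ie, pit_depth_um = pit_i,
        cft_true_um = cft_true,
        rnfl_um = rnfl, gcipl_um = gcipl,
        logmar = 0.0 + acuity_shift + rnorm(n, 0, 0.12),
        image_quality = rnorm(n, 60, 8) - ifelse(blink, 20, 0),
        ilm_indicator = pmax(rnorm(n, 80, 10), 0) * ifelse(blink, 0.02, 1),
        valid_count = pmin(1, 1 - abs(rnorm(n, 0, 0.01)) -
                             ifelse(clip, runif(n, 0.1, 0.4), 0)),
        min_motion_correlation = pmin(1, 1 - abs(rnorm(n, 0, 0.02)) -
                                        ifelse(motion, runif(n, 0.2, 0.6), 0)),
        max_motion_delta = abs(rnorm(n, 2, 1)) +
          ifelse(motion, runif(n, 10, 30), 0),
        macula_centre_frame = rnorm(n, 64, 3),
        macula_centre_aline = rnorm(n, 256, 10),
        blink = blink, motion = motion, clip = clip
      )
    })
    eyes <- bind_rows(eye_tbl)
    eyes$max_motion_factor <- eyes$max_motion_delta / eyes$plateau_um

    maps <- NULL
    if (keep_maps) {
      half <- 3
      yb <- seq(-half, half, length.out = config$n_bscan)
      xa <- seq(-half, half, length.out = config$n_ascan)
      r <- sqrt(outer(yb^2, xa^2, `+`))
      dome_sd <- surf$dome_radius_mm / 2
      dome_m <- surf$dome_amplitude_um *
        exp(-(r - surf$dome_radius_mm)^2 / (2 * dome_sd^2))
      pit_g <- exp(-r^2 / (2 * surf$pit_width_mm^2))
      plate_eye <- eyes$plateau_um[eyes$eye == map_eye]
      maps <- array(NA_real_,
                    dim = c(config$n_bscan, config$n_ascan, n),
                    dimnames = list(NULL, NULL, ids))
      npt <- config$n_bscan * config$n_ascan
      for (i in seq_len(n)) {
        maps[, , i] <- plate_eye[i] + dome_m - pit_i[i] * pit_g +
          if (config$map_noise_sd_um > 0) {
            rnorm(npt, 0, config$map_noise_sd_um)
          } else 0
      }
    }

    structure(
      list(participants = participants, eyes = eyes, dosages = dosages,
           variants = v, maps = maps, map_eye = map_eye, config = config),
      class = "oct_cohort"
    )
  })
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("<oct_cohort> %d participants, %d variants%s\n",
              nrow(x$participants), nrow(x$variants),
              if (!is.null(x$maps)) {
                sprintf(", %s-eye maps %dx%d", x$map_eye,
                        dim(x$maps)[1], dim(x$maps)[2])
              } else ""))
  invisible(x)
}

#' Write cohort tables to a directory of TSV files
#'
#' Writes `participants.tsv`, `eyes.tsv`, `variants.tsv` and `dosages.tsv`.
#'
#' @param cohort An `oct_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oct_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  readr::write_tsv(cohort$eyes, file.path(dir, "eyes.tsv"))
  readr::write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_dosage_tsv(cohort$dosages, file.path(dir, "dosages.tsv"),
                   ids = cohort$participants$participant_id)
  invisible(dir)
}
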