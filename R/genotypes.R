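#' Describe a simulated genetic variant
#'
#' Each variant is a biallelic SNP with a minor-allele frequency and an
#' effect mode on retinal morphology:
#' * `"foveal"`: each alternative allele shallows the foveal pit by
#'   `beta_um_per_allele` micrometres (a foveal-hypoplasia-like, localised
#'   effect raising central thickness);
#' * `"diffuse"`: each alternative allele shifts the plateau thickness by
#'   `beta_um_per_allele` micrometres across the whole field;
#' * `"null"`: no effect (all betas must be 0).
#'
#' Variants can additionally carry effects on LogMAR visual acuity and on a
#' latent pigmentation score (binned into ordinal hair colour downstream).
#'
#' @param id Variant label (e.g. an rsid-like string).
#' @param chrom Chromosome label.
#' @param bp Base-pair position (integer).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param effect_mode One of `"foveal"`, `"diffuse"`, `"null"`.
#' @param beta_um_per_allele Morphology effect per alternative allele (µm).
#' @param beta_acuity_per_allele LogMAR units per alternative allele.
#' @param beta_pigment_per_allele Latent pigmentation score units per allele.
#' @return A one-row tibble; rows from several calls can be `rbind`-ed into a
#'   variant table.
#' @examples
#' variant_spec("rs_fov", 1, 1e6, maf = 0.3, effect_mode = "foveal",
#'              beta_um_per_allele = 10)
#' @export
variant_spec <- function(id, chrom = 1, bp = 1L, maf = 0.25,
                         effect_mode = c("null", "foveal", "diffuse"),
                         beta_um_per_allele = 0,
                         beta_acuity_per_allele = 0,
                         beta_pigment_per_allele = 0) {
  effect_mode <- match.arg(effect_mode)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    abort("`maf` must lie in (0, 0.5].")
  }
  if (effect_mode == "null" &&
      any(c(beta_um_per_allele, beta_acuity_per_allele,
            beta_pigment_per_allele) != 0)) {
    abort("A null variant must have all betas equal to 0.")
  }
  tibble(
    id = as.character(id), chrom = as.character(chrom), bp = as.integer(bp),
    maf = maf, effect_mode = effect_mode,
    beta_um_per_allele = beta_um_per_allele,
    beta_acuity_per_allele = beta_acuity_per_allele,
    beta_pigment_per_allele = beta_pigment_per_allele
  )
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosage counts the alternative allele: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternative. Each variant is drawn
#' independently as Binomial(2, maf).
#'
#' @param n Number of participants (>= 1).
#' @param variants Variant table as built from [variant_spec()] rows (needs
#'   `id` and `maf` columns).
#' @param seed Integer seed.
#' @return Integer matrix `n x n_variants` with values in `{0, 1, 2}`,
#'   variant ids as column names.
#' @examples
#' v <- variant_spec("rs1", maf = 0.5)
#' g <- simulate_genotypes(100, v, seed = 1)
#' table(g)
#' @export
simulate_genotypes <- function(n, variants, seed = NULL) {
  stopifnot(is.numeric(n), n >= 1, is.data.frame(variants),
            all(c("id", "maf") %in% names(variants)))
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    abort("All `maf` values must lie in (0, 0.5].")
  }
  with_seed(seed, {
    g <- vapply(variants$maf, function(p) rbinom(n, 2L, p), integer(n))
    g <- matrix(g, nrow = n)
    colnames(g) <- variants$id
    g
  })
}

#' Write genotype dosages as a TSV table
#'
#' @param dosages Matrix from [simulate_genotypes()] (participants in rows).
#' @param ids Participant identifiers (defaults to `sample_1 ... sample_n`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(dosages, path, ids = NULL) {
  ids <- ids %||% paste0("sample_", seq_len(nrow(dosages)))
  df <- as_tibble(as.data.frame(dosages))
  df <- dplyr::bind_cols(tibble(participant_id = ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Emits a VCFv4.2 file with one line per variant and hard-called unphased
#' genotypes (`0/0`, `0/1`, `1/1`) derived from the dosage of the alternative
#' allele. Reference/alternative alleles are taken from the variant table if
#' present (`ref`, `alt` columns), else default to A/G.
#'
#' @param dosages Matrix from [simulate_genotypes()].
#' @param variants Variant table with `id`, `chrom`, `bp` (and optionally
#'   `ref`, `alt`).
#' @param path Output file path.
#' @param ids Participant identifiers.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(dosages, variants, path, ids = NULL) {
  stopifnot(ncol(dosages) == nrow(variants))
  ids <- ids %||% paste0("sample_", seq_len(nrow(dosages)))
  ref <- if ("ref" %in% names(variants)) variants$ref else
    rep("A", nrow(variants))
  alt <- if ("alt" %in% names(variants)) variants$alt else
    rep("G", nrow(variants))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=octmorph",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(j) {
    paste(c(variants$chrom[j], variants$bp[j], variants$id[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gt_code[as.character(dosages[, j])]),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
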