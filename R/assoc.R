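# Treatment-code a categorical covariate with the most frequent level as
# reference; numeric columns pass through.
prep_covariates <- function(data, covariates) {
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- sort(table(x), decreasing = TRUE)
      data[[cv]] <- factor(x, levels = names(tab))
    }
  }
  data
}

assoc_row <- function(fit, term, variant, trait, n) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    return(tibble(variant = variant, trait = trait, beta = NA_real_,
                  se = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  n = n))
  }
  tibble(
    variant = variant, trait = trait,
    beta = sm[term, "Estimate"], se = sm[term, "Std. Error"],
    statistic = sm[term, "t value"], p_value = sm[term, "Pr(>|t|)"],
    n = n
  )
}

#' Additive linear SNP association
#'
#' Ordinary least squares of a quantitative trait on the dosage of the
#' alternative allele plus covariates, the standard additive genetic model.
#' Dosages may be hard calls in `{0, 1, 2}` or fractional (imputed); the
#' model is agnostic. Two-sided p-values come from the t distribution with
#' residual degrees of freedom. Categorical covariates (e.g. OCT machine id)
#' are treatment-coded with the most frequent level as reference.
#'
#' @param data Data frame with one row per participant.
#' @param trait Name of the outcome column.
#' @param dosage Name of the dosage column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param variant_id Label recorded in the result (defaults to the dosage
#'   column name).
#' @return One-row tibble: `variant`, `trait`, `beta` (trait units per
#'   alternative allele), `se`, `statistic`, `p_value`, `n`. A monomorphic
#'   dosage yields an all-`NA` result with a warning, never an error.
#' @examples
#' d <- data.frame(y = rnorm(50), g = rbinom(50, 2, 0.3))
#' additive_linear_assoc(d, "y", "g")
#' @export
additive_linear_assoc <- function(data, trait, dosage,
                                  covariates = character(),
                                  variant_id = dosage) {
  stopifnot(is.data.frame(data), trait %in% names(data),
            dosage %in% names(data), all(covariates %in% names(data)))
  df <- data[, c(trait, dosage, covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= length(covariates) + 2) {
    abort("Too few complete observations for the design.")
  }
  if (var(df[[dosage]]) == 0) {
    warn(paste0("Monomorphic dosage for ", variant_id, "; no result."))
    return(tibble(variant = variant_id, trait = trait, beta = NA_real_,
                  se = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  n = n))
  }
  df <- prep_covariates(df, covariates)
  fml <- stats::reformulate(c(dosage, covariates), response = trait)
  fit <- lm(fml, data = df)
  assoc_row(fit, dosage, variant_id, trait, n)
}

#' Association scan over a dosage matrix
#'
#' Runs the additive model of [additive_linear_assoc()] for every variant
#' column of a dosage matrix. Covariates are projected out of the trait and
#' of each dosage once (the Frisch–Waugh–Lovell decomposition), so each
#' per-variant fit reduces to a simple regression on residuals — numerically
#' identical to the full model, at a fraction of the cost for large scans.
#'
#' @param data Participant data frame (must align row-wise with `dosages`).
#' @param trait Outcome column name.
#' @param dosages Numeric matrix, participants in rows, variants in columns
#'   (column names are the variant ids).
#' @param covariates Character vector of covariate column names.
#' @return Tibble with one row per variant (same contract as
#'   [additive_linear_assoc()]); monomorphic variants get `NA` rows.
#' @export
assoc_scan <- function(data, trait, dosages, covariates = character()) {
  stopifnot(is.data.frame(data), is.matrix(dosages),
            nrow(dosages) == nrow(data))
  df <- prep_covariates(data[, c(trait, covariates), drop = FALSE],
                        covariates)
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  dosages <- dosages[keep, , drop = FALSE]
  n <- nrow(df)
  x_cov <- if (length(covariates)) {
    model.matrix(stats::reformulate(covariates), data = df)
  } else {
    matrix(1, n, 1)
  }
  qr_cov <- qr(x_cov)
  p_cov <- qr_cov$rank
  ry <- qr.resid(qr_cov, df[[trait]])
  ids <- colnames(dosages) %||% paste0("v", seq_len(ncol(dosages)))
  out <- vector("list", ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    g <- dosages[, j]
    if (var(g) == 0) {
      out[[j]] <- tibble(variant = ids[j], trait = trait, beta = NA_real_,
                         se = NA_real_, statistic = NA_real_,
                         p_value = NA_real_, n = n)
      next
    }
    rg <- qr.resid(qr_cov, g)
    sxx <- sum(rg^2)
    beta <- sum(rg * ry) / sxx
    dfree <- n - p_cov - 1
    sigma2 <- sum((ry - beta * rg)^2) / dfree
    se <- sqrt(sigma2 / sxx)
    tval <- beta / se
    out[[j]] <- tibble(variant = ids[j], trait = trait, beta = beta, se = se,
                       statistic = tval,
                       p_value = 2 * pt(-abs(tval), dfree), n = n)
  }
  bind_rows(out)
}

#' Sex-interaction SNP association
#'
#' The additive model with main effects plus a dosage-by-sex interaction
#' term; the reported coefficient is the interaction, testing whether the
#' genetic effect differs between the sexes.
#'
#' @inheritParams additive_linear_assoc
#' @param sex Name of the (binary) sex column.
#' @return One-row tibble for the interaction coefficient.
#' @export
sex_interaction_assoc <- function(data, trait, dosage, sex = "sex",
                                  covariates = character(),
                                  variant_id = dosage) {
  stopifnot(sex %in% names(data))
  df <- data[, c(trait, dosage, sex, covariates)]
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df[[sex]])) < 2) {
    abort("`sex` is constant in the sample; the interaction is inestimable.")
  }
  if (var(df[[dosage]]) == 0) {
    abort("Monomorphic dosage; the interaction is inestimable.")
  }
  df <- prep_covariates(df, c(sex, covariates))
  inter <- paste0(dosage, ":", sex)
  fml <- stats::reformulate(c(dosage, sex, inter, covariates),
                            response = trait)
  fit <- lm(fml, data = df)
  term <- grep(paste0("^", dosage, ":"), names(coef(fit)), value = TRUE)[1]
  assoc_row(fit, term, variant_id, paste0(trait, ":sex-interaction"),
            nrow(df))
}

#' Minimum-p meta combination across two traits
#'
#' For each variant the lower of the two per-trait p-values is selected as
#' the meta p-value — the selection step used to build a combined ranking
#' across two layer phenotypes. No recalibration is applied: the value is a
#' ranking/plotting device, not a calibrated test, and trait-covariance
#' weighting (as in multi-trait meta-analysis software) is deliberately not
#' implemented.
#'
#' @param p_trait_a,p_trait_b Numeric vectors of per-variant p-values.
#' @return Elementwise minimum.
#' @examples
#' min_p_meta(c(0.01, 0.8), c(0.5, 0.2))
#' @export
min_p_meta <- function(p_trait_a, p_trait_b) {
  stopifnot(length(p_trait_a) == length(p_trait_b))
  pmin(p_trait_a, p_trait_b)
}

#' Group variants into loci by genomic distance
#'
#' Single-linkage chaining per chromosome: variants are sorted by position
#' and a new locus starts whenever the gap to the previous variant exceeds
#' `window_bp` (default 1.5 Mb). Variants on different chromosomes are never
#' grouped; the result is invariant to input order.
#'
#' @param variants Data frame with `id`, `chrom`, `bp`.
#' @param window_bp Maximum within-locus gap, base pairs.
#' @return The input rows (sorted by chromosome and position) with an added
#'   `locus` label, plus attribute `"loci"`: a tibble of locus spans.
#' @examples
#' v <- tibble::tibble(id = c("a", "b", "c"), chrom = "1",
#'                     bp = c(1e6, 2.4e6, 5e6))
#' cluster_loci(v)
#' @export
cluster_loci <- function(variants, window_bp = 1.5e6) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "bp") %in% names(variants)))
  v <- arrange(as_tibble(variants), .data$chrom, .data$bp)
  v$locus <- NA_character_
  loci <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    gap_new <- c(TRUE, diff(v$bp[idx]) > window_bp)
    grp <- cumsum(gap_new)
    v$locus[idx] <- sprintf("chr%s_L%d", ch, grp)
  }
  spans <- v |>
    group_by(.data$locus) |>
    summarise(chrom = .data$chrom[1], min_bp = min(.data$bp),
              max_bp = max(.data$bp), n_variants = n(), .groups = "drop")
  attr(v, "loci") <- spans
  v
}

#' Bonferroni significance mask
#'
#' Flags p-values below `alpha / m`, `m` the number of tests (defaults to
#' the length of the vector).
#'
#' @param p_values Numeric vector.
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return Logical vector.
#' @export
bonferroni_mask <- function(p_values, alpha = 0.05, m = length(p_values)) {
  p_values < alpha / m
}

#' Genome-wide significance mask
#'
#' @param p_values Numeric vector.
#' @param threshold Significance level (default the conventional 5e-8).
#' @return Logical vector.
#' @export
genomewide_significant <- function(p_values, threshold = 5e-8) {
  p_values < threshold
}

#' Association of dosage with an ordinal trait
#'
#' OLS of an ordinal code (e.g. hair colour in ascending order from light to
#' dark) on dosage, after dropping rows matched by the exclusion filter
#' (e.g. red-haired participants, whose colour does not fit the
#' light-to-dark axis).
#'
#' @param data Data frame.
#' @param trait Ordinal outcome column (integer codes).
#' @param dosage Dosage column.
#' @param exclude Optional name of a logical column; `TRUE` rows are dropped
#'   before fitting.
#' @param covariates Covariate column names.
#' @param variant_id Label for the result.
#' @return One-row tibble (same contract as [additive_linear_assoc()]).
#' @export
ordinal_trait_assoc <- function(data, trait, dosage, exclude = NULL,
                                covariates = character(),
                                variant_id = dosage) {
  if (!is.null(exclude)) {
    stopifnot(exclude %in% names(data))
    data <- data[!data[[exclude]], , drop = FALSE]
  }
  if (var(data[[trait]], na.rm = TRUE) == 0) {
    abort("Zero-variance ordinal outcome after exclusion.")
  }
  additive_linear_assoc(data, trait, dosage, covariates, variant_id)
}

#' Better-seeing-eye LogMAR
#'
#' LogMAR is lower for better acuity, so the better eye is the elementwise
#' minimum of the two eyes; a single available eye is used as-is.
#'
#' @param logmar_left,logmar_right Numeric vectors.
#' @return Numeric vector.
#' @examples
#' better_eye_logmar(0.2, 0.0)
#' @export
better_eye_logmar <- function(logmar_left, logmar_right) {
  out <- pmin(logmar_left, logmar_right, na.rm = TRUE)
  out[is.na(logmar_left) & is.na(logmar_right)] <- NA_real_
  out
}

#' Association of dosage with visual acuity
#'
#' OLS of better-seeing-eye LogMAR on dosage, adjusted for age, sex and
#' genetic principal components.
#'
#' @param data Data frame containing per-eye LogMAR columns.
#' @param dosage Dosage column name.
#' @param logmar_left,logmar_right Per-eye LogMAR column names.
#' @param covariates Covariate column names (default age, sex; add PCs as
#'   available).
#' @param variant_id Label for the result.
#' @return One-row tibble (same contract as [additive_linear_assoc()]).
#' @export
acuity_assoc <- function(data, dosage, logmar_left = "logmar_left",
                         logmar_right = "logmar_right",
                         covariates = c("age", "sex"),
                         variant_id = dosage) {
  stopifnot(all(c(logmar_left, logmar_right) %in% names(data)))
  data$logmar_better <- better_eye_logmar(data[[logmar_left]],
                                          data[[logmar_right]])
  additive_linear_assoc(data, "logmar_better", dosage, covariates,
                        variant_id)
}

#' Wilcoxon rank-sum contrast of GCC thickness between groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with continuity
#' and tie correction) comparing ganglion cell complex thickness between,
#' e.g., glaucomatous and non-glaucomatous participants.
#'
#' @param data Data frame.
#' @param gcc Name of the GCC thickness column.
#' @param status Name of a logical (or two-level) group column; `TRUE` /
#'   the second level is the case group.
#' @return One-row tibble with `statistic` (rank-sum W), `p_value`,
#'   `n_case`, `n_control`.
#' @export
gcc_group_contrast <- function(data, gcc, status) {
  stopifnot(gcc %in% names(data), status %in% names(data))
  x <- data[[gcc]]
  g <- as.logical(data[[status]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (sum(g) == 0 || sum(!g) == 0) {
    abort("Both groups must be non-empty.")
  }
  wt <- wilcox.test(x[g], x[!g], exact = FALSE, correct = TRUE)
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_case = sum(g), n_control = sum(!g))
}
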