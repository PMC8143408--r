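#' Select independent genome-wide-significant instruments
#'
#' Keeps variants with `p < p_threshold` and then, within each chromosome,
#' greedily retains the lowest-p variant and drops all others within
#' `prune_window_bp` of it, repeating until none remain. Distance-window
#' pruning is a stand-in for reference-panel LD clumping (no LD panel is
#' shipped); both constants are explicit and configurable.
#'
#' @param stats GWAS summary tibble with `id`, `chrom`, `bp`, `p` columns.
#' @param p_threshold Significance threshold (default genome-wide 5e-8).
#' @param prune_window_bp Independence window in base pairs (default 10 Mb).
#' @return The retained subset of `stats`, sorted by chromosome and position.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8,
                               prune_window_bp = 1e7) {
  stopifnot(is.data.frame(stats),
            all(c("id", "chrom", "bp", "p") %in% names(stats)))
  s <- filter(as_tibble(stats), .data$p < p_threshold)
  keep <- s[0, ]
  for (ch in unique(s$chrom)) {
    pool <- filter(s, .data$chrom == ch)
    while (nrow(pool) > 0) {
      best <- pool[which.min(pool$p), ]
      keep <- bind_rows(keep, best)
      pool <- filter(pool, abs(.data$bp - best$bp) > prune_window_bp)
    }
  }
  arrange(keep, .data$chrom, .data$bp)
}

is_palindromic <- function(a1, a2) {
  paste0(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2))) %in%
    c("AT", "CG")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Intersects the two studies on variant id and aligns the outcome effects to
#' the exposure's effect allele: where the outcome's effect allele is the
#' exposure's other allele, the outcome beta sign is flipped and its alleles
#' swapped (flag `sign_flipped`). Palindromic (A/T or C/G) variants are
#' strand-ambiguous and dropped by default; rows whose allele pairs cannot be
#' reconciled are dropped with a reason. Dropped counts are reported in the
#' `"dropped"` attribute.
#'
#' @param exposure,outcome Summary tibbles with `id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`.
#' @param drop_palindromic Drop strand-ambiguous variants?
#' @return Tibble of class `"instrument_set"`: `id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `effect_allele`,
#'   `other_allele`, `sign_flipped`.
#' @examples
#' sim <- simulate_mr_summary(10, 0.5, flip_fraction = 0.5, seed = 1)
#' harmonise_instruments(sim$exposure, sim$outcome)
#' @export
harmonise_instruments <- function(exposure, outcome,
                                  drop_palindromic = TRUE) {
  need <- c("id", "effect_allele", "other_allele", "beta", "se")
  stopifnot(all(need %in% names(exposure)), all(need %in% names(outcome)))
  m <- dplyr::inner_join(
    select(as_tibble(exposure), "id", "effect_allele", "other_allele",
           beta_exposure = "beta", se_exposure = "se"),
    select(as_tibble(outcome), "id", out_ea = "effect_allele",
           out_oa = "other_allele", beta_outcome = "beta",
           se_outcome = "se"),
    by = "id"
  )
  aligned <- m$out_ea == m$effect_allele & m$out_oa == m$other_allele
  swapped <- m$out_ea == m$other_allele & m$out_oa == m$effect_allele
  pal <- is_palindromic(m$effect_allele, m$other_allele)
  dropped <- c(
    palindromic = if (drop_palindromic) sum(pal & (aligned | swapped)) else 0L,
    incompatible = sum(!aligned & !swapped)
  )
  keep <- (aligned | swapped) & !(drop_palindromic & pal)
  m <- m[keep, , drop = FALSE]
  flip <- swapped[keep]
  m$beta_outcome[flip] <- -m$beta_outcome[flip]
  out <- tibble(
    id = m$id,
    beta_exposure = m$beta_exposure, se_exposure = m$se_exposure,
    beta_outcome = m$beta_outcome, se_outcome = m$se_outcome,
    effect_allele = m$effect_allele, other_allele = m$other_allele,
    sign_flipped = flip
  )
  class(out) <- c("instrument_set", class(out))
  attr(out, "dropped") <- dropped
  out
}

new_mr_estimate <- function(method, slope, slope_se, slope_p, n_instruments,
                            instruments, intercept = NA_real_,
                            intercept_se = NA_real_, intercept_p = NA_real_,
                            q_stat = NA_real_, overdispersion = NA_real_) {
  structure(
    list(method = method, slope = slope, slope_se = slope_se,
         slope_p = slope_p, intercept = intercept,
         intercept_se = intercept_se, intercept_p = intercept_p,
         n_instruments = n_instruments, q_stat = q_stat,
         overdispersion = overdispersion, instruments = instruments),
    class = "mr_estimate"
  )
}

#' Inverse-variance-weighted MR estimate
#'
#' The fixed-effect IVW causal estimate is the weighted regression of
#' outcome on exposure effects through the origin with weights
#' `w_j = 1 / se_outcome_j^2`:
#' `slope = sum(w b_X b_Y) / sum(w b_X^2)`, with
#' `se = sqrt(1 / sum(w b_X^2))`. Two-sided p-values come from the normal
#' distribution. With `overdispersion = TRUE`, a multiplicative
#' random-effects scaling `sqrt(Q / (k - 1))` inflates the standard error
#' when the heterogeneity statistic exceeds its degrees of freedom.
#'
#' @param instruments An `instrument_set` (or any tibble with
#'   `beta_exposure`, `beta_outcome`, `se_outcome`).
#' @param overdispersion Apply multiplicative random-effects scaling when
#'   heterogeneity warrants it?
#' @param allow_single Permit a single instrument (the estimate then reduces
#'   to the Wald ratio `b_Y / b_X`)?
#' @return An object of class `"mr_estimate"`; see [tidy.mr_estimate()].
#' @examples
#' sim <- simulate_mr_summary(20, 0.5, seed = 1)
#' ivw_estimate(harmonise_instruments(sim$exposure, sim$outcome))
#' @export
ivw_estimate <- function(instruments, overdispersion = FALSE,
                         allow_single = FALSE) {
  k <- nrow(instruments)
  if (k < 2 && !allow_single) {
    abort("IVW needs at least 2 instruments (set `allow_single = TRUE` for a Wald ratio).")
  }
  if (k < 1) abort("No instruments.")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  sxx <- sum(w * bx^2)
  if (sxx == 0) abort("All exposure effects are zero; IVW undefined.")
  slope <- sum(w * bx * by) / sxx
  se <- sqrt(1 / sxx)
  q <- sum(w * (by - slope * bx)^2)
  scale <- 1
  if (overdispersion && k > 1) {
    scale <- max(1, sqrt(q / (k - 1)))
  }
  se <- se * scale
  new_mr_estimate("IVW", slope, se, 2 * pnorm(-abs(slope / se)), k,
                  as_tibble(instruments), q_stat = q,
                  overdispersion = scale)
}

#' MR-Egger estimate
#'
#' Weighted least squares of outcome effects on exposure effects *with an
#' intercept*, weights `1 / se_outcome^2`; exposure effects are oriented
#' positive first (the standard Egger orientation, flipping the sign of both
#' betas for instruments with negative exposure effect). The slope is the
#' causal estimate and the intercept estimates directional pleiotropy; an
#' intercept near zero supports the IVW assumptions. P-values come from the
#' t distribution with `k - 2` degrees of freedom.
#'
#' @param instruments An `instrument_set` (>= 3 instruments).
#' @return An object of class `"mr_estimate"` with intercept fields.
#' @examples
#' sim <- simulate_mr_summary(20, 0.5, seed = 1)
#' egger_estimate(harmonise_instruments(sim$exposure, sim$outcome))
#' @export
egger_estimate <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) abort("MR-Egger needs at least 3 instruments.")
  sgn <- ifelse(instruments$beta_exposure < 0, -1, 1)
  bx <- instruments$beta_exposure * sgn
  by <- instruments$beta_outcome * sgn
  w <- 1 / instruments$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  new_mr_estimate(
    "Egger",
    slope = sm["bx", "Estimate"], slope_se = sm["bx", "Std. Error"],
    slope_p = sm["bx", "Pr(>|t|)"], n_instruments = k,
    instruments = as_tibble(instruments),
    intercept = sm["(Intercept)", "Estimate"],
    intercept_se = sm["(Intercept)", "Std. Error"],
    intercept_p = sm["(Intercept)", "Pr(>|t|)"]
  )
}

#' Two-sample MR between two summary-statistic tables
#'
#' Convenience wrapper: selects instruments from the exposure study,
#' harmonises them against the outcome study, and fits the requested
#' estimators. Swapping the `exposure` and `outcome` arguments runs the
#' reverse-direction analysis with no other changes.
#'
#' @param exposure,outcome Summary tibbles (`id`, `chrom`, `bp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`).
#' @param method `"ivw"`, `"egger"` or `"both"`.
#' @param p_threshold,prune_window_bp Passed to [select_instruments()].
#' @param drop_palindromic Passed to [harmonise_instruments()].
#' @param overdispersion Passed to [ivw_estimate()].
#' @return A list of `mr_estimate` objects (named `ivw`, `egger`), with the
#'   harmonised `instrument_set` as attribute `"instruments"`.
#' @export
mr_analysis <- function(exposure, outcome, method = c("both", "ivw", "egger"),
                        p_threshold = 5e-8, prune_window_bp = 1e7,
                        drop_palindromic = TRUE, overdispersion = FALSE) {
  method <- match.arg(method)
  sel <- select_instruments(exposure, p_threshold, prune_window_bp)
  inst <- harmonise_instruments(sel, outcome, drop_palindromic)
  out <- list()
  if (method %in% c("both", "ivw")) {
    out$ivw <- ivw_estimate(inst, overdispersion = overdispersion)
  }
  if (method %in% c("both", "egger")) {
    out$egger <- egger_estimate(inst)
  }
  attr(out, "instruments") <- inst
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: slope %.4f (se %.4f, p %.3g), k = %d\n",
              x$method, x$slope, x$slope_se, x$slope_p, x$n_instruments))
  if (x$method == "Egger") {
    cat(sprintf("  intercept %.4f (se %.4f, p %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`slope`, and `intercept` for
#'   Egger): `method`, `term`, `estimate`, `std.error`, `p.value`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  rows <- tibble(method = x$method, term = "slope", estimate = x$slope,
                 std.error = x$slope_se, p.value = x$slope_p)
  if (!is.na(x$intercept)) {
    rows <- bind_rows(rows, tibble(
      method = x$method, term = "intercept", estimate = x$intercept,
      std.error = x$intercept_se, p.value = x$intercept_p))
  }
  rows
}

#' One-row summary of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `estimate`, `std.error`, `p.value`,
#'   `n_instruments`, `q_stat`.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, estimate = x$slope, std.error = x$slope_se,
         p.value = x$slope_p, n_instruments = x$n_instruments,
         q_stat = x$q_stat)
}

#' Scatter plot of an MR fit
#'
#' Per-instrument exposure vs outcome effects with the fitted causal slope
#' (through the origin for IVW, with intercept for Egger).
#'
#' @param object An `mr_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_estimate <- function(object, ...) {
  inst <- object$instruments
  icept <- if (is.na(object$intercept)) 0 else object$intercept
  ggplot2::ggplot(inst, ggplot2::aes(.data$beta_exposure,
                                     .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
                   ymax = .data$beta_outcome + 1.96 * .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = icept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Effect on exposure", y = "Effect on outcome",
                  title = sprintf("%s estimate: %.3f (se %.3f)",
                                  object$method, object$slope,
                                  object$slope_se)) +
    ggplot2::theme_minimal()
}
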