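#' Simulate two-sample MR summary statistics
#'
#' Generates per-instrument exposure and outcome GWAS summary tables under a
#' linear causal model: for instrument j,
#' `beta_Y_j = causal_effect * beta_X_j + pleiotropy_j + noise`,
#' where `pleiotropy_j ~ N(pleiotropy_mean, pleiotropy_sd)` and the outcome
#' noise has the stated standard error. Exposure effects are treated as
#' measured without error (the no-measurement-error assumption under which
#' IVW and MR-Egger are derived); `se_exposure` is emitted as the reported
#' uncertainty column. A configurable fraction of
#' outcome rows is emitted with effect/other alleles swapped (and beta
#' negated) so that harmonisation is exercised.
#'
#' @param n_instruments Number of instruments (>= 3).
#' @param causal_effect True causal slope of outcome on exposure.
#' @param beta_x_mean,beta_x_sd Distribution of true exposure effects
#'   (drawn positive at the defaults, the standard orientation).
#' @param se_exposure,se_outcome Standard errors of the exposure and outcome
#'   effect estimates.
#' @param pleiotropy_mean,pleiotropy_sd Directional pleiotropy mean and
#'   spread added to outcome effects (both default 0).
#' @param flip_fraction Fraction of outcome rows emitted on the opposite
#'   effect allele.
#' @param palindromic_fraction Fraction of instruments given strand-ambiguous
#'   (A/T or C/G) alleles.
#' @param seed Integer seed.
#' @return List with tibbles `exposure` and `outcome`, each with columns
#'   `id`, `chrom`, `bp`, `effect_allele`, `other_allele`, `beta`, `se`, `p`.
#' @examples
#' sim <- simulate_mr_summary(10, causal_effect = 0.5, seed = 1)
#' head(sim$outcome)
#' @export
simulate_mr_summary <- function(n_instruments,
                                causal_effect,
                                beta_x_mean = 0.2,
                                beta_x_sd = 0.05,
                                se_exposure = 0.02,
                                se_outcome = 0.05,
                                pleiotropy_mean = 0,
                                pleiotropy_sd = 0,
                                flip_fraction = 0,
                                palindromic_fraction = 0,
                                seed = NULL) {
  stopifnot(n_instruments >= 3, se_outcome >= 0, se_exposure >= 0,
            flip_fraction >= 0, flip_fraction <= 1)
  with_seed(seed, {
    k <- n_instruments
    ids <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    # successive instruments on a chromosome sit 20 Mb apart, beyond any
    # default pruning window; stored as double to avoid integer overflow
    bp <- 1e5 + ((seq_len(k) - 1) %/% 22) * 2e7
    bx_true <- rnorm(k, beta_x_mean, beta_x_sd)
    bx_obs <- bx_true
    pleio <- rnorm(k, pleiotropy_mean, pleiotropy_sd)
    by_obs <- causal_effect * bx_true + pleio + rnorm(k, 0, se_outcome)

    pal <- runif(k) < palindromic_fraction
    a1 <- sample(c("A", "C"), k, replace = TRUE)
    # palindromic pairs are A/T or C/G; non-palindromic default A/G or C/T
    a2 <- ifelse(pal, ifelse(a1 == "A", "T", "G"),
                 ifelse(a1 == "A", "G", "T"))

    p_of <- function(b, s) {
      if (s == 0) ifelse(b == 0, 1, 0) else 2 * pnorm(-abs(b / s))
    }
    exposure <- tibble(
      id = ids, chrom = chrom, bp = bp,
      effect_allele = a1, other_allele = a2,
      beta = bx_obs, se = rep(max(se_exposure, 1e-12), k),
      p = p_of(bx_obs, se_exposure)
    )
    outcome <- tibble(
      id = ids, chrom = chrom, bp = bp,
      effect_allele = a1, other_allele = a2,
      beta = by_obs, se = rep(max(se_outcome, 1e-12), k),
      p = p_of(by_obs, se_outcome)
    )
    flip <- runif(k) < flip_fraction
    outcome$effect_allele[flip] <- a2[flip]
    outcome$other_allele[flip] <- a1[flip]
    outcome$beta[flip] <- -outcome$beta[flip]

    list(exposure = exposure, outcome = outcome,
         truth = tibble(id = ids, beta_x_true = bx_true, pleiotropy = pleio,
                        flipped = flip, palindromic = pal))
  })
}
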