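#' Scale marginal effects to the standardized-genotype scale
#'
#' The sampler operates on effects of mean-zero unit-variance genotypes for a
#' unit-variance phenotype. On that scale the marginal effect of variant `j`
#' is its Z-score divided by the square root of its sample size:
#' `beta_hat_j = gamma_hat_j / (se_j * sqrt(n_j))`. The back-scaling factor
#' `scale_j = se_j * sqrt(n_j)` restores allele-scale effects exactly, and is
#' what posterior means are multiplied by on output. Per-variant sample sizes
#' are carried through so meta-analyses with varying coverage are handled.
#'
#' @param ss Summary-statistics tibble (for binary traits, `n` must already
#'   hold the effective sample size).
#' @return The input tibble with columns `beta_hat` and `scale` appended.
#' @export
scale_to_std <- function(ss) {
  ss <- as_tibble(ss)
  ss$scale <- ss$se_gamma * sqrt(ss$n)
  ss$beta_hat <- ss$gamma_hat / ss$scale
  ss
}

#' Genotype standard deviations implied by summary statistics
#'
#' From the standard-error identity of simple regression,
#' `sd(G_j) ~ sd(y) / (se_j * sqrt(n_j))` for a linear-regression GWAS, and
#' `sd(G_j) ~ 2 / (se_j * sqrt(neff_j))` for a logistic GWAS on the effective
#' sample-size scale. Comparing these implied SDs with SDs observed in a
#' validation panel exposes mismatched summary statistics (wrong n, mixed
#' genomic builds, meta-analysis artefacts) before they destabilize the
#' sampler.
#'
#' For linear traits with unknown `sd_y`, the phenotype SD is estimated by
#' the median of `sd_val_j * se_j * sqrt(n_j)` when validation SDs are
#' supplied (robust to a minority of bad variants), or else by
#' `min_j(0.5 * se_j * sqrt(n_j))`, which uses the fact that a binary-coded
#' genotype SD cannot exceed 0.5.
#'
#' @param ss Summary-statistics tibble.
#' @param trait `"linear"` or `"binary"`.
#' @param sd_y Known phenotype SD (linear traits); overrides estimation.
#' @param sd_val Optional per-variant validation-panel genotype SDs (used to
#'   estimate `sd_y` by the median rule).
#' @param sd_y_method `"median"` (default) or `"min"`; only consulted when
#'   `sd_y` is absent.
#' @return The input tibble with an `sd_ss` column appended; the `sd_y`
#'   estimate used (linear traits) is attached as attribute `"sd_y_est"`.
#' @export
sd_from_sumstats <- function(ss, trait = c("linear", "binary"), sd_y = NULL,
                             sd_val = NULL, sd_y_method = c("median", "min")) {
  trait <- match.arg(trait)
  sd_y_method <- match.arg(sd_y_method)
  ss <- as_tibble(ss)
  sen <- ss$se_gamma * sqrt(ss$n)
  if (trait == "binary") {
    ss$sd_ss <- 2 / sen
    return(ss)
  }
  if (is.null(sd_y)) {
    if (!is.null(sd_val)) {
      sd_y <- median(sd_val * sen)
    } else if (sd_y_method == "min") {
      sd_y <- min(0.5 * sen)
    } else {
      abort("linear trait: supply `sd_y`, or `sd_val` for the median rule, or set sd_y_method = \"min\"")
    }
  }
  ss$sd_ss <- sd_y / sen
  attr(ss, "sd_y_est") <- sd_y
  ss
}

#' Quality-control filter on summary statistics
#'
#' A variant is kept iff none of four rules fires (all strict inequalities):
#' `sd_ss < 0.5 * sd_val` (implied SD much too small, e.g. wrong sample
#' size), `sd_ss > sd_val + 0.1` (implied SD too large), `sd_ss < 0.1`
#' (near-degenerate), `sd_val < 0.05` (validation panel monomorphic-ish).
#'
#' @param sd_ss Per-variant SD implied by summary statistics.
#' @param sd_val Per-variant SD observed in the validation panel.
#' @return A `qc_report` tibble: `sd_ss`, `sd_val`, one logical column per
#'   rule (`rule_low_ratio`, `rule_high_diff`, `rule_ss_floor`,
#'   `rule_val_floor`) and `keep`. Per-rule removal counts are in attribute
#'   `"rule_counts"`.
#' @export
qc_filter <- function(sd_ss, sd_val) {
  if (length(sd_ss) != length(sd_val)) {
    abort("`sd_ss` and `sd_val` must have the same length")
  }
  out <- tibble(
    sd_ss = as.numeric(sd_ss),
    sd_val = as.numeric(sd_val),
    rule_low_ratio = sd_ss < 0.5 * sd_val,
    rule_high_diff = sd_ss > sd_val + 0.1,
    rule_ss_floor = sd_ss < 0.1,
    rule_val_floor = sd_val < 0.05
  )
  out$keep <- !(out$rule_low_ratio | out$rule_high_diff |
                  out$rule_ss_floor | out$rule_val_floor)
  attr(out, "rule_counts") <- c(
    low_ratio = sum(out$rule_low_ratio),
    high_diff = sum(out$rule_high_diff),
    ss_floor = sum(out$rule_ss_floor),
    val_floor = sum(out$rule_val_floor)
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' SNP heritability by constrained LD score regression
#'
#' Fits `chi2_j = 1 + n_j * h2 * ell_j / M` with the intercept fixed at 1,
#' by weighted least squares through the origin on `chi2_j - 1`. Weights are
#' iterated twice: the first pass uses `1/ell_j` (down-weighting variants
#' that tag many others), the second adds the standard heteroscedasticity
#' factor `1/(1 + n_j * h2 * ell_j / M)^2` using the first-pass estimate.
#' The estimate is clamped to `[1e-4, 1]`: liability-scale SNP heritability
#' cannot exceed 1, and downstream grid multipliers need a positive value.
#'
#' @param chi2 Per-variant chi-squared association statistics (`z^2`).
#' @param ell Per-variant LD scores from [ld_scores()].
#' @param n Per-variant GWAS sample sizes.
#' @param M Total number of variants in the model.
#' @return The h2 point estimate (scalar).
#' @export
ldsc_h2_constrained <- function(chi2, ell, n, M = length(chi2)) {
  if (any(chi2 < 0)) abort("`chi2` must be non-negative")
  n <- rep_len(n, length(chi2))
  if (all(ell == 0)) abort("all LD scores are zero; cannot regress")
  x <- n * ell / M
  y <- chi2 - 1
  w <- 1 / pmax(ell, 1e-12)
  h2 <- sum(w * x * y) / sum(w * x * x)
  w <- w / (1 + pmax(h2, 0) * x)^2
  h2 <- sum(w * x * y) / sum(w * x * x)
  min(max(h2, 1e-4), 1)
}
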