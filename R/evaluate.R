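#' Compute polygenic scores
#'
#' `score_i = sum_j dosage_ij * effect_j` after aligning the effects table to
#' the panel on `(chr, pos)` with allele reconciliation (swapped-allele
#' effects are negated). Missing dosages are imputed to the per-variant mean.
#'
#' @param panel A `geno_panel`.
#' @param effects Tibble with `chr`, `pos`, `a0`, `a1` and an `effect`
#'   column (e.g. a `pgs_result`), a `pgs_auto` fit, or a bare numeric
#'   vector already aligned with the panel columns.
#' @return Numeric vector of per-individual scores.
#' @export
compute_pgs <- function(panel, effects) {
  X <- panel$X
  if (inherits(effects, "pgs_auto")) {
    effects <- .chain_effect_table(list(effect = effects$effect),
                                   effects$scaled)
  }
  if (is.numeric(effects) && is.null(dim(effects))) {
    if (length(effects) != ncol(X)) abort("effects vector must match panel columns")
    eff <- effects
    cols <- seq_len(ncol(X))
  } else {
    eff_tb <- as_tibble(effects)
    if (!("effect" %in% names(eff_tb))) abort("`effects` must have an `effect` column")
    eff_tb$gamma_hat <- eff_tb$effect
    eff_tb$se_gamma <- 1
    eff_tb$n <- 1
    matched <- suppressMessages(
      match_variants(eff_tb, panel$map, remove_ambiguous = FALSE)
    )
    cols <- matched$panel_index
    eff <- matched$gamma_hat
  }
  Xs <- X[, cols, drop = FALSE]
  if (anyNA(Xs)) {
    mu <- colMeans(Xs, na.rm = TRUE)
    idx <- which(is.na(Xs), arr.ind = TRUE)
    Xs[idx] <- mu[idx[, 2]]
  }
  as.numeric(Xs %*% eff)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a random case outscores a
#' random control, with ties counted one half (computed from midranks).
#'
#' @param scores Numeric predictor.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap AUC summary
#'
#' Resamples individuals with replacement `n_boot` times, computes the AUC
#' of each replicate, and reports the mean with the 2.5% and 97.5% quantiles
#' as a 95% interval. Replicates that draw a single class are redrawn (and
#' counted), keeping `n_boot` fixed.
#'
#' @param scores Numeric predictor.
#' @param labels Binary labels.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the summary is deterministic given it.
#' @return An `auc_summary` list: `estimate` (full-sample AUC), `mean`,
#'   `lower`, `upper`, `n_boot`, `n_redrawn`, `seed`.
#' @export
auc_boot <- function(scores, labels, n_boot = 10000, seed = NULL) {
  labels <- as.integer(labels)
  point <- auc(scores, labels)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  vals <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    vals[b] <- auc(scores[idx], labels[idx])
  }
  qs <- unname(quantile(vals, c(0.025, 0.975)))
  structure(list(estimate = point, mean = mean(vals), lower = qs[1],
                 upper = qs[2], n_boot = n_boot, n_redrawn = n_redrawn,
                 seed = seed),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf("AUC %.4f [bootstrap mean %.4f, 95%% CI %.4f-%.4f, %d replicates]\n",
              x$estimate, x$mean, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Select the best candidate score by regression Z-score
#'
#' For each candidate, the phenotype is regressed on the score (simple
#' linear regression) and the slope Z-statistic recorded; the candidate with
#' the largest Z wins (ties broken toward the lowest index). This criterion
#' is more robust than per-model AUC when candidates are near-collinear.
#' Constant columns score Z = 0.
#'
#' @param y Phenotype vector (binary or quantitative).
#' @param scores Matrix of candidate scores (individuals x candidates) or a
#'   single vector.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return Index of the selected candidate; per-candidate Z-scores in
#'   attribute `"z"`.
#' @export
zscore_select <- function(y, scores, family = c("linear", "logistic")) {
  family <- match.arg(family)
  scores <- as.matrix(scores)
  n <- length(y)
  z <- vapply(seq_len(ncol(scores)), function(k) {
    s <- scores[, k]
    if (sd(s) == 0) return(0)
    if (family == "logistic") {
      fit <- suppressWarnings(glm(y ~ s, family = binomial()))
      cf <- summary(fit)$coefficients
      if (nrow(cf) < 2) return(0)
      return(cf[2, 1] / cf[2, 2])
    }
    r <- cor(y, s)
    r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  }, numeric(1))
  best <- which.max(z)
  attr(best, "z") <- z
  best
}

#' Maximum attainable AUC under the liability threshold model
#'
#' The AUC of a predictor equal to the true genetic liability, in closed
#' form under normal theory. With threshold `T = qnorm(1 - K)`, density
#' `z = dnorm(T)`, and mean liabilities of cases `i = z/K` and controls
#' `i2 = -z/(1-K)`:
#' `AUC = pnorm((i - i2) * h2 / sqrt(h2 * ((1 - h2*i*(i - T)) +
#' (1 - h2*i2*(i2 - T)))))`.
#' No polygenic score can beat this bound in expectation, which makes it the
#' natural yardstick for simulation results.
#'
#' @param h2 Liability-scale heritability in (0, 1].
#' @param K Prevalence in (0, 1).
#' @return The maximum AUC (scalar in `[0.5, 1]`).
#' @export
#' @examples
#' max_theoretical_auc(0.4, 0.15)  # ~0.825
max_theoretical_auc <- function(h2, K) {
  stopifnot(h2 >= 0, h2 <= 1, K > 0, K < 1)
  if (h2 == 0) return(0.5)
  T <- qnorm(1 - K)
  z <- dnorm(T)
  i <- z / K
  i2 <- -z / (1 - K)
  v <- h2 * ((1 - h2 * i * (i - T)) + (1 - h2 * i2 * (i2 - T)))
  pnorm((i - i2) * h2 / sqrt(v))
}
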