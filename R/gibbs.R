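.as_dgc <- function(R) as(as(R, "generalMatrix"), "CsparseMatrix")

.check_aligned <- function(scaled, ld) {
  if (!all(c("beta_hat", "scale", "n") %in% names(scaled))) {
    abort("`scaled` must carry `beta_hat`, `scale` and `n`; run scale_to_std() first")
  }
  if (nrow(scaled) != nrow(ld$R)) {
    abort("variant count mismatch between summary statistics and LD matrix")
  }
}

.new_pgs_result <- function(scaled, omega_std, params, diverged = FALSE,
                            method = "gibbs") {
  effect <- omega_std * scaled$scale
  out <- tibble(beta_std = omega_std, effect = effect)
  meta <- intersect(c("chr", "pos", "a0", "a1"), names(scaled))
  out <- dplyr::bind_cols(scaled[, meta, drop = FALSE], out)
  structure(out,
            class = c("pgs_result", class(out)),
            params = params, method = method, diverged = diverged,
            sparsity = if (diverged) NA_real_ else mean(effect == 0))
}

#' @export
print.pgs_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<pgs_result> %s, %d variants%s, sparsity %.3f\n",
              attr(x, "method"), nrow(x),
              if (attr(x, "diverged")) " [DIVERGED]" else "",
              attr(x, "sparsity")))
  if (!is.null(p)) {
    cat(sprintf("  p = %s, h2 = %s, sparse = %s\n",
                format(p$p), format(p$h2), format(p$sparse %||% FALSE)))
  }
  NextMethod()
}

#' Analytic infinitesimal polygenic-score solver
#'
#' Under the infinitesimal prior (every variant causal with effect variance
#' `h2/M`), the posterior mean of the standardized effects has the closed
#' form `(R + M/(n*h2) I)^{-1} beta_hat`, solved here with a sparse direct
#' factorization per chromosome block. `M` is the total variant count and
#' `n` the mean per-variant sample size.
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix` aligned with `scaled`.
#' @param h2 SNP heritability (> 0), typically from [ldsc_h2_constrained()].
#' @return A `pgs_result` tibble with standardized (`beta_std`) and
#'   allele-scale (`effect`) posterior means.
#' @export
solve_inf <- function(scaled, ld, h2) {
  .check_aligned(scaled, ld)
  if (h2 <= 0) abort("`h2` must be positive")
  M <- nrow(scaled)
  n_mean <- mean(scaled$n)
  A <- ld$R + Matrix::Diagonal(M, M / (n_mean * h2))
  x <- as.numeric(Matrix::solve(A, scaled$beta_hat))
  resid <- sqrt(sum((as.numeric(A %*% x) - scaled$beta_hat)^2))
  denom <- sqrt(sum(scaled$beta_hat^2))
  if (denom > 0 && resid / denom > 1e-10) {
    abort(sprintf("infinitesimal solve did not converge (relative residual %.3g)",
                  resid / denom))
  }
  .new_pgs_result(scaled, x, list(p = 1, h2 = h2, sparse = FALSE),
                  method = "inf")
}

#' Residualized marginal effect
#'
#' The marginal effect of variant `j` with the LD-mediated contribution of
#' all other current effects removed:
#' `btilde_j = beta_hat_j - sum_{k != j} R[k, j] * beta_k`.
#'
#' @param j Variant index (1-based).
#' @param beta_hat Standardized marginal effects.
#' @param beta Current effect vector.
#' @param ld An `ld_matrix`.
#' @return Scalar residualized effect.
#' @export
residualized_effect <- function(j, beta_hat, beta, ld) {
  col <- ld$R[, j]
  beta_hat[j] - sum(col * beta) + beta[j] * ld$R[j, j]
}

#' Posterior probability that a variant is causal
#'
#' Under the spike-and-slab prior, the posterior odds of the slab given the
#' residualized effect have a closed form; this evaluates it in the
#' numerically stable arrangement
#' `1 / (1 + ((1-p)/p) * sqrt(1 + n*h2/(M*p)) * exp(-n*btilde^2 / 2 /
#' (1 + M*p/(n*h2))))`, which cannot overflow however large `n * btilde^2`
#' becomes (the naive two-density ratio does).
#'
#' @param btilde Residualized marginal effect(s) on the standardized scale.
#' @param p Prior proportion of causal variants, in (0, 1].
#' @param h2 SNP heritability (> 0).
#' @param n Per-variant sample size(s).
#' @param M Total variant count.
#' @return Posterior probabilities in `[0, 1]`, vectorized over `btilde`/`n`.
#' @export
causal_posterior_prob <- function(btilde, p, h2, n, M) {
  stopifnot(p > 0, p <= 1, h2 > 0)
  ratio <- pmin(M * p / (n * h2), 1e12)
  log_odds_null <- log((1 - p) / p) + 0.5 * log1p(n * h2 / (M * p)) -
    0.5 * n * btilde^2 / (1 + ratio)
  1 / (1 + exp(log_odds_null))
}

#' Run one Gibbs chain at fixed hyper-parameters
#'
#' Algorithm: per sweep, each variant in ascending genomic order gets its
#' residualized marginal effect, its causal posterior probability, a sampled
#' effect (slab draw with that probability, else zero), and its per-sweep
#' posterior mean; posterior means are averaged over the post-burn-in
#' sweeps and scaled back to the allele scale. With the sparse rule active,
#' variants whose causal probability falls below `p` have both the sample
#' and the posterior mean set to exactly zero, yielding truly sparse output.
#'
#' The product `R * beta` is cached and updated incrementally as effects
#' change, with a full recomputation every `refresh_every` sweeps to bound
#' floating-point drift; `cache = "direct"` recomputes every dot product
#' from scratch instead (slower, used as a cross-check).
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix` aligned with `scaled`.
#' @param p Proportion of causal variants, in (0, 1].
#' @param h2 SNP heritability (> 0).
#' @param sparse Apply the sparse rule (default `FALSE`).
#' @param burn_in,num_iter Burn-in and retained sweep counts.
#' @param seed Integer seed; the chain is bit-reproducible given it.
#' @param cache `"incremental"` (default) or `"direct"`.
#' @param refresh_every Full cache refresh period in sweeps.
#' @return A `pgs_result` tibble. A diverged chain returns `NA` effects and
#'   carries `diverged = TRUE` (inspect with [glance()]); a warning is
#'   raised.
#' @export
run_gibbs <- function(scaled, ld, p, h2, sparse = FALSE, burn_in = 100,
                      num_iter = 500, seed = NULL, cache = "incremental",
                      refresh_every = 100) {
  .check_aligned(scaled, ld)
  stopifnot(p > 0, p <= 1, h2 > 0, burn_in >= 0, num_iter >= 1)
  R <- .as_dgc(ld$R)
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_chain_cpp(R, scaled$beta_hat, scaled$n, nrow(scaled),
                          p, h2, sparse, FALSE, as.integer(burn_in),
                          as.integer(num_iter), cache,
                          as.integer(refresh_every))
  if (res$diverged) warn("Gibbs chain diverged; effects are NA")
  .new_pgs_result(scaled, res$omega, list(p = p, h2 = h2, sparse = sparse),
                  diverged = res$diverged)
}

#' Default hyper-parameter grid
#'
#' 21 values of `p` log-spaced on `[1e-5, 1]` (endpoints exact), three
#' heritability values `{0.7, 1, 1.4}` times the LD-score-regression
#' estimate, and the sparse rule off/on: 126 settings in total.
#'
#' @param h2_ldsc Heritability estimate from [ldsc_h2_constrained()].
#' @return A tibble with columns `p`, `h2`, `sparse` (126 rows).
#' @export
default_grid <- function(h2_ldsc) {
  if (h2_ldsc <= 0) abort("`h2_ldsc` must be positive")
  p_seq <- exp(seq(log(1e-5), log(1), length.out = 21))
  p_seq[1] <- 1e-5
  p_seq[21] <- 1
  tidyr::expand_grid(p = p_seq, h2 = c(0.7, 1, 1.4) * h2_ldsc,
                     sparse = c(FALSE, TRUE))
}

#' Run the Gibbs sampler over a hyper-parameter grid
#'
#' One independent chain per `(p, h2, sparse)` setting. Per-model seeds are
#' derived deterministically from `(seed, model index)`, so the result does
#' not depend on execution order or on `threads` (execution is serial; the
#' argument is accepted for interface compatibility and results are
#' identical for any value).
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix`.
#' @param grid Tibble with columns `p`, `h2`, `sparse` (see
#'   [default_grid()]).
#' @param burn_in,num_iter Sweep counts per model.
#' @param seed Master seed.
#' @param threads Accepted, ignored (results are thread-count independent).
#' @return A `pgs_grid` object: allele-scale effects matrix (variants x
#'   models), standardized effects, and a `manifest` tibble (`model`, `p`,
#'   `h2`, `sparse`, `seed`, `diverged`, `sparsity`).
#' @export
run_grid <- function(scaled, ld, grid, burn_in = 100, num_iter = 500,
                     seed = 1, threads = 1) {
  if (!nrow(grid)) abort("`grid` must be nonempty")
  .check_aligned(scaled, ld)
  set.seed(seed)
  model_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  R <- .as_dgc(ld$R)
  fits <- purrr::pmap(
    list(grid$p, grid$h2, grid$sparse, model_seeds),
    function(p, h2, sparse, s) {
      set.seed(s)
      .gibbs_chain_cpp(R, scaled$beta_hat, scaled$n, nrow(scaled),
                       p, h2, sparse, FALSE, as.integer(burn_in),
                       as.integer(num_iter), "incremental", 100L)
    })
  std <- vapply(fits, function(f) f$omega, numeric(nrow(scaled)))
  std <- matrix(std, nrow = nrow(scaled))
  eff <- std * scaled$scale
  manifest <- tibble(
    model = seq_len(nrow(grid)), p = grid$p, h2 = grid$h2,
    sparse = grid$sparse, seed = model_seeds,
    diverged = vapply(fits, function(f) f$diverged, logical(1)),
    sparsity = apply(eff, 2, function(v) mean(v == 0))
  )
  if (any(manifest$diverged)) {
    warn(paste0(sum(manifest$diverged), " grid model(s) diverged"))
  }
  structure(list(effects = eff, std_effects = std, manifest = manifest,
                 scaled = scaled),
            class = "pgs_grid")
}

#' @export
print.pgs_grid <- function(x, ...) {
  cat(sprintf("<pgs_grid> %d variants x %d models (%d diverged)\n",
              nrow(x$effects), ncol(x$effects), sum(x$manifest$diverged)))
  invisible(x)
}
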