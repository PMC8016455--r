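#' Sample the proportion of causal variants from its posterior
#'
#' With `Mc` of `M` sampled effects nonzero and a uniform Beta(1, 1) prior,
#' the conjugate posterior of `p` is `Beta(1 + Mc, 1 + M - Mc)`.
#'
#' @param Mc Number of currently nonzero effects.
#' @param M Total variant count.
#' @return One draw from the posterior.
#' @export
sample_p_posterior <- function(Mc, M) {
  if (Mc < 0 || Mc > M) abort("`Mc` must lie in [0, M]")
  rbeta(1, 1 + Mc, 1 + M - Mc)
}

#' Heritability implied by a standardized effect vector
#'
#' `h2 = beta' R beta` over the stored nonzeros of the sparse LD matrix. A
#' windowed correlation matrix can be indefinite, so a negative quadratic
#' form is floored at `1e-4` and flagged via attribute `"floored"`.
#'
#' @param beta Standardized effect vector.
#' @param ld An `ld_matrix`.
#' @return The h2 value (scalar), attribute `"floored"` TRUE if the floor
#'   was applied.
#' @export
estimate_h2_from_beta <- function(beta, ld) {
  q <- sum(beta * as.numeric(ld$R %*% beta))
  floored <- q < 1e-4
  structure(max(q, 1e-4), floored = floored)
}

#' Run one self-tuning Gibbs chain
#'
#' A Gibbs chain in which the hyper-parameters are learned alongside the
#' effects: after every sweep, `p` is redrawn from its
#' `Beta(1 + Mc, 1 + M - Mc)` posterior (with `Mc` the count of exactly
#' nonzero sampled effects) and `h2` is re-estimated as `beta' R beta`.
#' Point estimates `p_hat` and `h2_hat` are the means of the post-burn-in
#' trajectories. Chains whose `h2` exceeds 1.5 for 10 consecutive updates,
#' or whose state becomes non-finite or extreme, are flagged diverged rather
#' than raising an error, so multi-chain runs can filter them.
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix`.
#' @param init_p Initial proportion of causal variants, in (0, 1).
#' @param init_h2 Initial heritability (> 0), e.g. the LDSC estimate.
#' @param burn_in,num_iter Sweep counts.
#' @param seed Integer seed.
#' @param update_hyper Update `p` and `h2` between sweeps (default `TRUE`);
#'   with `FALSE` the chain is the fixed-hyper-parameter sampler of
#'   [run_gibbs()].
#' @return An `auto_chain` list: `omega` (standardized posterior means),
#'   `effect` (allele scale), `p_hat`, `h2_hat`, trajectories `p_traj` /
#'   `h2_traj`, inits, and `diverged`.
#' @export
run_auto_chain <- function(scaled, ld, init_p, init_h2, burn_in = 500,
                           num_iter = 500, seed = NULL, update_hyper = TRUE) {
  .check_aligned(scaled, ld)
  stopifnot(init_p > 0, init_p < 1, init_h2 > 0)
  R <- .as_dgc(ld$R)
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_chain_cpp(R, scaled$beta_hat, scaled$n, nrow(scaled),
                          init_p, init_h2, FALSE, update_hyper,
                          as.integer(burn_in), as.integer(num_iter),
                          "incremental", 100L)
  keep <- seq.int(burn_in + 1L, burn_in + num_iter)
  diverged <- res$diverged
  structure(list(
    omega = res$omega,
    effect = res$omega * scaled$scale,
    init_p = init_p, init_h2 = init_h2,
    p_traj = res$p_traj, h2_traj = res$h2_traj,
    p_hat = if (diverged || !update_hyper) NA_real_ else mean(res$p_traj[keep]),
    h2_hat = if (diverged || !update_hyper) NA_real_ else mean(res$h2_traj[keep]),
    diverged = diverged
  ), class = "auto_chain")
}

#' Default initial values for multi-chain auto runs
#'
#' `n_chains` initial `p` values equally spaced on a log scale between
#' `1e-4` and `0.9` (endpoints exact).
#'
#' @param n_chains Number of chains (default 30).
#' @return Numeric vector of initial `p` values.
#' @export
auto_init_p <- function(n_chains = 30) {
  out <- exp(seq(log(1e-4), log(0.9), length.out = n_chains))
  out[1] <- 1e-4
  out[n_chains] <- 0.9
  out
}

#' Combine auto chains with MAD-based divergence filtering
#'
#' Each chain yields a candidate effect vector; chains that drifted produce
#' predictors with aberrant spread. The per-chain predictor standard
#' deviation is computed on a reference genotype panel when one is supplied
#' (the SD of the polygenic score across individuals), else by the proxy
#' `sqrt(omega' R omega)`. Chains farther than three median absolute
#' deviations from the median SD, and chains flagged diverged, are dropped;
#' the survivors' allele-scale effects are averaged elementwise.
#'
#' @param chains List of `auto_chain` objects.
#' @param ld An `ld_matrix` (for the proxy SD).
#' @param ref_panel Optional `geno_panel` for predictor SDs.
#' @param scaled The scaled summary statistics the chains were run on.
#' @return A list: `effect` (averaged allele-scale effects), `omega`
#'   (averaged standardized effects), `kept` (indices of retained chains),
#'   `sd_pred` (per-chain predictor SDs), `sd_source`.
#' @export
combine_chains <- function(chains, ld, scaled, ref_panel = NULL) {
  ok <- which(!vapply(chains, function(ch) isTRUE(ch$diverged), logical(1)))
  if (!length(ok)) {
    abort("all auto chains diverged; check summary-statistics QC before rerunning")
  }
  sd_source <- if (is.null(ref_panel)) "ld_proxy" else "ref_panel"
  sd_pred <- rep(NA_real_, length(chains))
  for (i in ok) {
    if (is.null(ref_panel)) {
      q <- sum(chains[[i]]$omega * as.numeric(ld$R %*% chains[[i]]$omega))
      sd_pred[i] <- sqrt(max(q, 0))
    } else {
      sd_pred[i] <- sd(compute_pgs(ref_panel, .chain_effect_table(chains[[i]], scaled)))
    }
  }
  med <- median(sd_pred[ok])
  madv <- mad(sd_pred[ok])
  kept <- ok[abs(sd_pred[ok] - med) <= 3 * madv]
  omega <- rowMeans(vapply(chains[kept], function(ch) ch$omega,
                           numeric(length(chains[[kept[1]]]$omega))))
  list(effect = omega * scaled$scale, omega = omega, kept = kept,
       sd_pred = sd_pred, sd_source = sd_source)
}

.chain_effect_table <- function(chain, scaled) {
  meta <- intersect(c("chr", "pos", "a0", "a1"), names(scaled))
  out <- scaled[, meta, drop = FALSE]
  out$effect <- chain$effect
  out
}

#' Self-tuning polygenic-score model (multi-chain)
#'
#' Runs `n_chains` self-tuning Gibbs chains from dispersed initial values of
#' `p` (log-spaced on `[1e-4, 0.9]`), filters aberrant chains by the
#' three-MAD rule on predictor standard deviations, and averages the
#' survivors. Needs no validation data: `p` and `h2` are learned inside the
#' sampler.
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix`.
#' @param init_h2 Initial heritability for every chain (e.g. the LDSC
#'   estimate).
#' @param n_chains Number of chains (default 30).
#' @param burn_in,num_iter Sweep counts per chain.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param ref_panel Optional `geno_panel` for the chain filter's predictor
#'   SDs.
#' @param threads Accepted, ignored (results are thread-count independent).
#' @return A `pgs_auto` object: `effect`/`omega` consensus vectors, a
#'   `chains` tibble (`chain`, `init_p`, `p_hat`, `h2_hat`, `sd_pred`,
#'   `kept`, `diverged`), consensus `p_hat`/`h2_hat` (means over kept
#'   chains), the chain list, and `sd_source`.
#' @export
run_auto <- function(scaled, ld, init_h2, n_chains = 30, burn_in = 500,
                     num_iter = 500, seed = 1, ref_panel = NULL, threads = 1) {
  .check_aligned(scaled, ld)
  inits <- auto_init_p(n_chains)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  chains <- purrr::map2(inits, chain_seeds, function(p0, s) {
    run_auto_chain(scaled, ld, init_p = p0, init_h2 = init_h2,
                   burn_in = burn_in, num_iter = num_iter, seed = s)
  })
  comb <- combine_chains(chains, ld, scaled, ref_panel)
  chains_tb <- tibble(
    chain = seq_len(n_chains),
    init_p = inits,
    seed = chain_seeds,
    p_hat = vapply(chains, function(ch) ch$p_hat, numeric(1)),
    h2_hat = vapply(chains, function(ch) ch$h2_hat, numeric(1)),
    sd_pred = comb$sd_pred,
    kept = seq_len(n_chains) %in% comb$kept,
    diverged = vapply(chains, function(ch) ch$diverged, logical(1))
  )
  structure(list(
    effect = comb$effect, omega = comb$omega,
    chains = chains_tb, chain_fits = chains,
    p_hat = mean(chains_tb$p_hat[chains_tb$kept]),
    h2_hat = mean(chains_tb$h2_hat[chains_tb$kept]),
    kept = comb$kept, sd_source = comb$sd_source, scaled = scaled
  ), class = "pgs_auto")
}

#' @export
print.pgs_auto <- function(x, ...) {
  cat(sprintf("<pgs_auto> %d chains, %d kept; p_hat = %.4g, h2_hat = %.4g\n",
              nrow(x$chains), sum(x$chains$kept), x$p_hat, x$h2_hat))
  invisible(x)
}

#' Sparse variant of the self-tuning model
#'
#' One fixed-hyper-parameter Gibbs run with the sparse rule enabled, at the
#' `(p_hat, h2_hat)` learned by [run_auto()].
#'
#' @param scaled Summary statistics after [scale_to_std()].
#' @param ld An `ld_matrix`.
#' @param auto_fit A `pgs_auto` fit (or supply `p_hat`/`h2_hat` directly).
#' @param p_hat,h2_hat Hyper-parameter values; default from `auto_fit`.
#' @param ... Passed to [run_gibbs()] (`burn_in`, `num_iter`, `seed`, ...).
#' @return A `pgs_result` with exact zeros and a reported sparsity fraction.
#' @export
auto_sparse <- function(scaled, ld, auto_fit = NULL, p_hat = auto_fit$p_hat,
                        h2_hat = auto_fit$h2_hat, ...) {
  run_gibbs(scaled, ld, p = min(p_hat, 1), h2 = h2_hat, sparse = TRUE, ...)
}
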