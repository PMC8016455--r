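---
title: "Polygenic scores from summary statistics: models and methods in ldpgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores from summary statistics: models and methods in ldpgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A polygenic score (PGS) predicts a trait as a weighted sum of allele dosages
across many variants. When individual-level training data are unavailable,
the weights must be derived from genome-wide association study (GWAS)
*summary statistics* — per-variant marginal effects $\hat\gamma_j$, their
standard errors, and sample sizes — together with a linkage-disequilibrium
(LD) reference: a matrix $R$ of correlations between variant dosages
estimated in a panel from the same population.

`ldpgs` implements a family of such methods built around a spike-and-slab
Gibbs sampler on the standardized-effect scale: an analytic infinitesimal
solver, a grid of models over the prior parameters with an optional truly
sparse mode, and a self-tuning ("auto") mode that learns the prior from the
data, plus everything needed to exercise the pipeline end to end on
synthetic data.

## From marginal to joint effects

Write $S$ for the diagonal matrix of genotype standard deviations. For a
phenotype with unit variance, the marginal and joint (all-variants-at-once)
effects are related through the LD matrix by
$\hat\gamma_{joint} = S^{-1} R^{-1} S \hat\gamma_{marg}$. On the
standardized scale the marginal effect reduces to a Z-score over the square
root of the sample size:

$$\hat\beta_j = \frac{\hat\gamma_j}{\mathrm{se}(\hat\gamma_j)\sqrt{n_j}},$$

which is the input to all samplers (`scale_to_std()`), and output effects
are mapped back to the allele scale by the inverse factor
$\mathrm{se}(\hat\gamma_j)\sqrt{n_j}$. Per-variant sample sizes $n_j$ are
carried everywhere, so meta-analyses with varying variant coverage are
handled without assuming a common $n$. For case-control GWAS, $n_j$ must be
the *effective* sample size $n_{\mathrm{eff}} = 4/(1/n_{case} +
1/n_{control})$ (`effective_sample_size()`).

A useful by-product of the same identity is a quality-control signal: the
genotype standard deviation implied by the summary statistics,
$\mathrm{sd}(G_j) \approx \mathrm{sd}(y)/(\mathrm{se}(\hat\gamma_j)\sqrt{n_j})$
for linear GWAS and $\approx 2/(\mathrm{se}(\hat\gamma_j)\sqrt{n_{\mathrm{eff},j}})$
for logistic GWAS. Comparing it with the SD observed in the validation
panel (`sd_from_sumstats()`, `qc_filter()`) exposes wrong sample sizes,
scale mismatches and meta-analysis artefacts before they destabilize the
sampler. A variant is removed when any of four strict rules fires:
$SD_{ss} < 0.5\,SD_{val}$, $SD_{ss} > SD_{val} + 0.1$, $SD_{ss} < 0.1$, or
$SD_{val} < 0.05$. All four inequalities are strict so that boundary cases
are kept; this is a fixed, testable convention. When $\mathrm{sd}(y)$ is
unknown for a linear trait it is estimated by the median of
$SD_{val,j}\cdot\mathrm{se}(\hat\gamma_j)\sqrt{n_j}$ (robust to a minority
of bad variants); a fallback uses the fact that a binary-coded genotype SD
cannot exceed 0.5. The median rule is the default because it degrades
gracefully when a few variants are corrupted.

## The spike-and-slab model and the Gibbs sampler

Standardized effects are modeled as
$$\beta_j \sim \begin{cases} N\!\left(0, \frac{h^2}{Mp}\right) & \text{with probability } p\\ 0 & \text{otherwise,}\end{cases}$$
with $p$ the proportion of causal variants, $h^2$ the SNP heritability and
$M$ the number of variants. One Gibbs sweep visits every variant in
ascending genomic order (a fixed order keeps runs bit-reproducible; the
update order is not identifiable from output) and computes:

1. the *residualized* marginal effect
   $\tilde\beta_j = \hat\beta_j - \sum_{k\neq j} R_{kj}\beta_k$, i.e. the
   marginal signal with the LD-mediated contribution of all other current
   effects removed;
2. the posterior probability that the variant is causal,
   $$\bar p_j = \frac{1}{1 + \frac{1-p}{p}\sqrt{1 + \frac{n_j h^2}{Mp}}\,
   \exp\!\left(-\tfrac{1}{2}\,\frac{n_j\tilde\beta_j^2}{1 + Mp/(n_j h^2)}\right)};$$
3. a sample $\beta_j \sim N\!\left(\frac{\tilde\beta_j}{1 + Mp/(n_j h^2)},
   \frac{1}{(1 + Mp/(n_j h^2))\,n_j}\right)$ with probability $\bar p_j$,
   else $\beta_j = 0$;
4. the per-sweep posterior mean
   $\omega_j = \bar p_j\,\tilde\beta_j/(1 + Mp/(n_j h^2))$.

Posterior means are averaged over the post-burn-in sweeps and scaled back
to the allele scale. The arrangement of $\bar p_j$ above is evaluated in
log space and cannot overflow however large $n_j\tilde\beta_j^2$ gets; the
naive ratio of two Gaussian densities does overflow, and the package keeps
a battery of frozen extended-precision oracle values to pin the stable form
down to $10^{-12}$.

**Sparse rule.** With the sparse option, whenever $\bar p_j < p$ both the
sample and the posterior mean are set to exactly zero. The output then
contains true zeros (the reported sparsity fraction), while correlating
almost perfectly with its non-sparse twin.

**Infinitesimal solver.** At $p = 1$ the posterior mean has the closed form
$(R + \frac{M}{n h^2} I)^{-1}\hat\beta$, solved sparsely and exactly
(`solve_inf()`); the $p=1$ sampler agrees with it to Monte-Carlo precision,
which is one of the package's cross-checks.

**Implementation.** The sweep is C++ (Rcpp) with the product $R\beta$
cached and updated incrementally as effects change; the cache is fully
recomputed every 100 sweeps to bound floating-point drift, and a
`cache = "direct"` mode recomputes every dot product from scratch as an
in-test oracle. R's own RNG drives the chain, so `set.seed()` makes any run
bit-reproducible. Degenerate corners ($p \to 0$ or $h^2 \to 0$) cap the
shrinkage ratio $Mp/(n_j h^2)$ at $10^{12}$ to avoid `0 * Inf`. A chain is
flagged diverged — not an error — when a residualized effect becomes
non-finite or a sampled standardized effect exceeds 10.

## Heritability from LD score regression

The grid and auto modes need an initial $h^2$. Under the model, the
expected association chi-squared of variant $j$ grows linearly in its LD
score $\ell_j = \sum_k R_{jk}^2$:
$E[\chi^2_j] = 1 + n_j h^2 \ell_j/M$. `ldsc_h2_constrained()` fits this
with the intercept fixed at 1 by weighted least squares, iterating the
weights twice ($1/\ell_j$ on the first pass, then the standard
heteroscedasticity factor $1/(1 + n_j h^2 \ell_j/M)^2$). Only the point
estimate is produced — no standard errors — because it is consumed solely
as a scale anchor. The estimate is clamped to $[10^{-4}, 1]$: liability
heritability cannot exceed 1, and grid multipliers need a positive value.

## The grid and its defaults

`default_grid()` builds the Cartesian product of 21 values of $p$
log-spaced on $[10^{-5}, 1]$, $h^2 \in \{0.7, 1, 1.4\}\cdot
h^2_{\mathrm{LDSC}}$, and the sparse flag: 126 models. Each grid model runs
an independent chain (defaults: 100 burn-in + 500 retained sweeps) with a
seed derived deterministically from the master seed and the model index, so
results never depend on scheduling; the `threads` argument is accepted for
interface compatibility but execution is serial, which makes thread-count
invariance hold by construction. The best model is then chosen on a
validation set, preferably by the Z-score of the regression of phenotype on
score (`zscore_select()`), which is more robust than per-model AUC when
candidates are near-collinear; linear regression is the default even for
binary traits, with logistic available behind a flag.

## The auto mode

`run_auto()` removes the need for a validation set by learning $p$ and
$h^2$ inside the sampler. After each sweep, $p$ is redrawn from its
conjugate posterior $\mathrm{Beta}(1 + M_c,\, 1 + M - M_c)$, where $M_c$
counts the exactly nonzero sampled effects, and $h^2$ is re-estimated as
the quadratic form $\beta^\top R \beta$ over the stored nonzeros. A
windowed $R$ can be indefinite, so a negative quadratic form is floored at
$10^{-4}$ and flagged; a chain whose $h^2$ exceeds 1.5 for 10 consecutive
updates is marked diverged. Point estimates are the means of the
post-burn-in trajectories. The sparse rule is never active inside auto
chains; sparse auto output comes from one subsequent fixed-parameter run at
the learned $(\hat p, \hat h^2)$ with sparsity on (`auto_sparse()`).

Thirty chains (default) start from initial $p$ values log-spaced on
$[10^{-4}, 0.9]$, all from the LDSC $h^2$. Chains are then filtered by the
spread of their predictors: the per-chain predictor SD is computed on a
reference panel when one is supplied, else by the proxy
$\sqrt{\omega^\top R\,\omega}$ (the choice is recorded in the result), and
chains farther than three median absolute deviations from the median SD
are dropped before the survivors are averaged. `stats::mad()` with its
default consistency constant (1.4826) is used; the filter is
scale-equivariant, so the constant only shifts how aggressive "three MADs"
is, and the aberrant-chain tests do not depend on it. Auto defaults to 500
burn-in + 500 retained sweeps — self-tuning chains need longer burn-in than
fixed-parameter ones because the hyper-parameters themselves must
equilibrate.

## Windowed LD on the genetic-distance scale

`windowed_correlation()` computes Pearson correlations between dosage
columns, kept only for same-chromosome pairs closer than `window_cM`
(default 3 cM) in *genetic* distance; everything else is structurally zero.
Genetic distance, not physical distance, is the right ruler because
recombination coldspots — HLA spans 8 Mb but only about 3 cM — carry LD far
beyond any fixed base-pair window; on the cM scale one globally small
window suffices. Physical positions are interpolated to cM by
piecewise-linear interpolation on a genetic map, extrapolating linearly
beyond the terminal knots (`interpolate_genetic_pos()`). The window test
uses strict inequality (`< window_cM`): the boundary convention is not
determined by theory, so the package fixes one and asserts it in tests.
Missing dosages are handled pairwise-complete by default with per-column
mean imputation behind a flag. Correlations use the unbiased $(n-1)$
denominator. Monomorphic columns get a unit diagonal, zero off-diagonals
and a flag. No positive-semidefinite projection is applied to the windowed
matrix; downstream code tolerates small negative quadratic forms instead
(the $h^2$ floor above), because projecting would silently change the
matrix every consumer sees. Per-chromosome blocks concatenate
block-diagonally (`assemble_genomewide()`), and `save_ld()`/`load_ld()`
round-trip the container losslessly behind a format-version tag.

## The synthetic-data harness

`simu_genotypes()` draws each haplotype from a latent AR(1) Gaussian
series (correlation $\rho^{|j-k|}$) thresholded at the per-variant
allele-frequency quantile; dosages are sums of two haplotypes. This is not
a coalescent model: it produces realistic-looking local LD with one tunable
knob, which is what the method's tests need, but it has no population
structure, no relatedness, no allele-frequency/LD coupling, and its LD
decays geometrically. Passing tests therefore demonstrate correctness of
the machinery under a controlled LD process, not robustness to every
pattern in real cohorts. The emitted genetic map runs at about 1 cM per Mb
with an optional compressed interval (rate multiplied by 3/8) emulating an
HLA-like recombination coldspot.

`simu_pheno_ltm()` implements the liability threshold model: causal
variants drawn uniformly (optionally within a region), standardized-dosage
weights $w_j \sim N(0, h^2/|S|)$, and the two liability components rescaled
so the in-sample genetic variance is *exactly* $h^2$ and the total
liability variance *exactly* 1 — the noise is first orthogonalized to the
genetic component so the variances add exactly. Cases are liabilities above
the standard-normal quantile at $1-K$; there is no ascertainment or
case-enrichment sampling. Defaults ($h^2 = 0.4$, $K = 0.15$) mirror the
main simulation conditions the package's evaluation targets.

`run_gwas()` produces the per-variant summary statistics: closed-form OLS
for linear traits (vectorized when there is no missingness), per-variant
logistic ML for binary traits, without covariates; a linear fallback for
binary traits exists purely for speed at large $n$. Per-variant $n_j$ is
the non-missing count; binary output carries the effective sample size.

Some package tests generate summary statistics directly in model space —
$\hat\beta \sim N(R\beta,\, R/n)$ with a fixed causal count and $\beta$
rescaled so $\beta^\top R \beta$ is exactly $h^2$, mirroring the exact-
variance convention of the phenotype simulator — because that isolates the
sampler from GWAS estimation noise and makes hyper-parameter recovery a
well-posed question.

## Evaluation

`auc()` is the Mann-Whitney estimator with ties counted one half;
`auc_boot()` resamples individuals with replacement (default 10 000
replicates), reporting the mean and the 2.5%/97.5% quantiles; replicates
that draw a single class are redrawn rather than skipped so the replicate
count stays fixed. The yardstick for simulations is the closed-form
maximum attainable AUC of the true genetic liability under the liability
threshold model (`max_theoretical_auc()`): with $T = \Phi^{-1}(1-K)$,
$z = \phi(T)$, $i = z/K$, $i_2 = -z/(1-K)$,
$$\mathrm{AUC}_{max} = \Phi\!\left(\frac{(i - i_2)\,h^2}{\sqrt{h^2\left[(1 - h^2 i (i - T)) + (1 - h^2 i_2 (i_2 - T))\right]}}\right),$$
which evaluates to 82.5% at $h^2 = 0.4$, $K = 0.15$. The package verifies
this expression against a $10^7$-draw Monte-Carlo simulation of the
bivariate liability model at a second parameter point.

## Problem sizes used by the test suite

Tests run at sizes chosen to exercise every code path while keeping the
suite fast enough to run habitually: oracle comparisons at 1–50 variants;
LD, QC and LDSC properties at 200–5000 variants; hyper-parameter recovery
at $M = 2000$, $n = 20\,000$ with 10 chains over 10 seeds; the end-to-end
simulation study at $m = 400$–$500$, $n = 3000$–$8000$ over several seeds;
and the liability-model contracts at $n = 50\,000$ individuals. These sizes
are the package's own trade-off between statistical resolution and
turnaround; all thresholds asserted in tests were fixed from the method's
stated tolerances and from pre-computed oracle values, not fitted to runs.

## Known limitations

* The LD container is an R-serialized versioned payload, not a
  memory-mapped format; genome-scale matrices (~10^6 variants) would need
  out-of-core storage.
* Execution is serial; the `threads` arguments exist for interface
  stability only.
* Multi-allelic variants, indels and dosage (non-integer) genotypes are out
  of scope; strand-ambiguous variants are dropped by default rather than
  frequency-resolved.
* The auto mode's $h^2$ update is a plug-in quadratic form, not a draw from
  a posterior; its uncertainty is assessed only across chains.
* No formal convergence diagnostics (e.g. split-$\hat R$) are computed; the
  MAD filter on predictor SDs is the only cross-chain check.
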