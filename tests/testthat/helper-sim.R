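# Shared fixtures, all built in code.

# Banded AR(1) correlation matrix as an ld_matrix; with the default spacing
# the 3 cM window spans 60 neighbors, where rho^60 is far below double
# precision, so the banded matrix is numerically the exact AR(1) matrix
# (hence positive definite and Cholesky-factorizable).
helper_ar1_ld <- function(m, rho = 0.6, spacing_cM = 0.05, window_cM = 3) {
  genpos <- (seq_len(m) - 1) * spacing_cM
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  R[abs(outer(genpos, genpos, "-")) >= window_cM] <- 0
  info <- tibble::tibble(chr = "1", pos = 100000L + (seq_len(m) - 1L) * 1000L,
                         a0 = "A", a1 = "C")
  new_ld_matrix(R, genpos, info, window_cM)
}

# Summary statistics drawn from the model the sampler assumes: a fixed
# count round(p * m) of causal variants with Gaussian standardized effects,
# rescaled so the realized heritability beta' R beta is exactly h2 (the
# same convention the phenotype simulator uses), and
# beta_hat ~ N(R beta, R / n) with the same correlation matrix R. se is
# chosen as 1/sqrt(n) so the standardized and allele scales coincide
# (scale = 1).
helper_model_sumstats <- function(ld, n, p, h2, seed) {
  set.seed(seed)
  m <- nrow(ld$R)
  Rd <- as.matrix(ld$R)
  n_causal <- max(1L, round(p * m))
  causal <- sort(sample.int(m, n_causal))
  beta <- numeric(m)
  beta[causal] <- stats::rnorm(n_causal, 0, sqrt(h2 / n_causal))
  beta <- beta * sqrt(h2 / sum(beta * as.numeric(Rd %*% beta)))
  L <- t(chol(Rd))
  beta_hat <- as.numeric(Rd %*% beta) + as.numeric(L %*% stats::rnorm(m)) / sqrt(n)
  scaled <- tibble::tibble(
    chr = "1", pos = ld$info$pos, a0 = "A", a1 = "C",
    gamma_hat = beta_hat, se_gamma = 1 / sqrt(n), n = n,
    scale = 1, beta_hat = beta_hat
  )
  list(scaled = scaled, beta = beta, causal = causal)
}

# Small dosage panel with no missing data (exact linear-algebra tests).
helper_panel <- function(n, m, rho = 0.5, seed = 1, missing_rate = 0) {
  simu_genotypes(n = n, m = m, rho = rho, missing_rate = missing_rate,
                 seed = seed)
}

# ld_matrix straight from a dense correlation matrix (window Inf).
helper_ld_from_dense <- function(R, chr = "1") {
  m <- nrow(R)
  info <- tibble::tibble(chr = chr, pos = 100000L + (seq_len(m) - 1L) * 1000L,
                         a0 = "A", a1 = "C")
  new_ld_matrix(R, seq_len(m) * 0.01, info, Inf)
}

# Minimal scaled-sumstats tibble on the standardized scale.
helper_scaled <- function(beta_hat, n, se = 1 / sqrt(n)) {
  tibble::tibble(
    chr = "1", pos = 100000L + seq_along(beta_hat) * 1000L,
    a0 = "A", a1 = "C",
    gamma_hat = beta_hat * se * sqrt(n), se_gamma = se, n = n,
    scale = se * sqrt(n), beta_hat = beta_hat
  )
}
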