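test_that("genotype simulator controls local LD through rho", {
  # rho = 0: adjacent variants essentially uncorrelated
  sim0 <- simu_genotypes(n = 5000, m = 50, rho = 0, seed = 101)
  r2 <- vapply(1:49, function(j) {
    cor(sim0$panel$X[, j], sim0$panel$X[, j + 1])^2
  }, numeric(1))
  expect_lt(mean(r2), 0.01)

  # rho = 0.9: dosage correlation decays with distance, monotone on average
  sim9 <- simu_genotypes(n = 5000, m = 50, rho = 0.9, seed = 103)
  mean_abs_r <- function(lag) {
    mean(vapply(seq_len(50 - lag), function(j) {
      abs(cor(sim9$panel$X[, j], sim9$panel$X[, j + lag]))
    }, numeric(1)))
  }
  lags <- c(1, 3, 10)
  vals <- vapply(lags, mean_abs_r, numeric(1))
  expect_gt(vals[1], vals[2])
  expect_gt(vals[2], vals[3])
  expect_gt(vals[1], 0.5)

  # determinism
  sim9b <- simu_genotypes(n = 5000, m = 50, rho = 0.9, seed = 103)
  expect_identical(sim9$panel$X, sim9b$panel$X)
})

test_that("the synthetic genetic map compresses the designated region", {
  sim <- simu_genotypes(n = 10, m = 100, rho = 0.2, seed = 105,
                        compressed_region = c(40, 60))
  g <- sim$map$pos_cM
  rate_out <- (g[20] - g[10]) / (sim$map$pos_bp[20] - sim$map$pos_bp[10])
  rate_in <- (g[55] - g[45]) / (sim$map$pos_bp[55] - sim$map$pos_bp[45])
  expect_equal(rate_in / rate_out, 3 / 8, tolerance = 1e-9)
  expect_true(all(diff(sim$map$pos_bp) > 0))
  expect_true(all(diff(g) >= 0))
})

test_that("liability threshold phenotypes have the exact stated variances", {
  sim <- helper_panel(n = 2000, m = 100, rho = 0.4, seed = 107)
  ph <- simu_pheno_ltm(sim$panel, h2 = 0.4, K = 0.15, n_causal = 20, seed = 109)
  # reconstruct the genetic component from the stored causal set and weights
  Xs <- scale(sim$panel$X[, ph$causal$index])
  gcomp <- as.numeric(Xs %*% ph$causal$weight)
  gcomp <- gcomp - mean(gcomp)
  gcomp <- gcomp * sqrt(0.4 / var(gcomp))
  expect_equal(var(gcomp), 0.4, tolerance = 1e-12)
  # and the simulator's own liability obeys both variance contracts
  expect_equal(var(ph$liability), 1, tolerance = 1e-12)
  noise <- ph$liability - gcomp
  expect_equal(var(noise), 0.6, tolerance = 1e-10)
  expect_equal(cor(ph$liability, gcomp)^2, 0.4, tolerance = 1e-10)

  # binary phenotype thresholds the liability at the prevalence quantile
  expect_identical(ph$y, as.integer(ph$liability > qnorm(0.85)))
})

test_that("null heritability makes genotypes uninformative", {
  sim <- helper_panel(n = 3000, m = 50, rho = 0.3, seed = 111)
  ph <- simu_pheno_ltm(sim$panel, h2 = 0, K = 0.15, n_causal = 10, seed = 113)
  set.seed(115)
  score <- as.numeric(sim$panel$X %*% rnorm(50))
  a <- auc(score, ph$y)
  expect_lt(abs(a - 0.5), 0.05)
})

test_that("causal variants avoid monomorphic columns", {
  sim <- helper_panel(n = 50, m = 20, rho = 0.2, seed = 117)
  sim$panel$X[, 5] <- 2L
  panel <- new_geno_panel(sim$panel$X, sim$panel$map)
  ph <- simu_pheno_ltm(panel, h2 = 0.3, K = 0.2, n_causal = 15, seed = 119)
  expect_false(5L %in% ph$causal$index)
})

test_that("per-variant GWAS matches closed-form simple regression", {
  X <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), ncol = 1)
  map <- tibble::tibble(chr = "1", pos = 100L, a0 = "A", a1 = "C")
  y <- c(0.1, 0.9, 2.2, -0.3, 1.1, 1.8)
  gw <- run_gwas(new_geno_panel(X, map), y, trait = "linear")
  x <- X[, 1]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  expect_equal(gw$gamma_hat, slope, tolerance = 1e-12)
  expect_equal(gw$se_gamma, sqrt(rss / (4 * sxx)), tolerance = 1e-12)
  expect_equal(gw$n, 6L)
  # and against lm as an independent oracle
  fit <- summary(lm(y ~ x))$coefficients
  expect_equal(gw$gamma_hat, fit[2, 1], tolerance = 1e-10)
  expect_equal(gw$se_gamma, fit[2, 2], tolerance = 1e-10)
})

test_that("GWAS p-values are calibrated under the null", {
  sim <- simu_genotypes(n = 300, m = 2000, rho = 0, seed = 121)
  set.seed(123)
  y <- rnorm(300)
  gw <- suppressMessages(run_gwas(sim$panel, y, trait = "linear"))
  tstat <- gw$gamma_hat / gw$se_gamma
  pvals <- 2 * pt(-abs(tstat), df = gw$n - 2)
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(gw))
  expect_lt(abs(frac - 0.05), 2.5 * se)
})

test_that("implied genotype SDs from a linear GWAS track the truth", {
  sim <- helper_panel(n = 2000, m = 200, rho = 0.4, seed = 125)
  ph <- simu_pheno_ltm(sim$panel, h2 = 0.3, K = 0.15, n_causal = 40,
                       trait = "linear", seed = 127)
  gw <- suppressMessages(run_gwas(sim$panel, ph$y, trait = "linear"))
  implied <- sd(ph$y) / (gw$se_gamma * sqrt(gw$n))
  true_sd <- apply(sim$panel$X, 2, sd)
  expect_lt(median(abs(implied - true_sd) / true_sd), 0.02)
})

test_that("logistic GWAS returns finite effects and the effective sample size", {
  sim <- helper_panel(n = 800, m = 30, rho = 0.3, seed = 129)
  ph <- simu_pheno_ltm(sim$panel, h2 = 0.5, K = 0.3, n_causal = 10, seed = 131)
  gw <- suppressMessages(run_gwas(sim$panel, ph$y, trait = "binary"))
  expect_true(all(is.finite(gw$gamma_hat)))
  expect_true(all(gw$se_gamma > 0))
  expect_equal(gw$n[1],
               effective_sample_size(sum(ph$y == 1), sum(ph$y == 0)))
  # the fast linear approximation ranks variants the same way
  gwl <- suppressMessages(run_gwas(sim$panel, ph$y, trait = "binary",
                                   method = "linear"))
  shared <- intersect(gw$pos, gwl$pos)
  expect_gt(cor(gw$gamma_hat[match(shared, gw$pos)] / gw$se_gamma[match(shared, gw$pos)],
                gwl$gamma_hat[match(shared, gwl$pos)] / gwl$se_gamma[match(shared, gwl$pos)]),
            0.98)
})

test_that("marginal standardized effects are unbiased without LD", {
  sim <- simu_genotypes(n = 4000, m = 300, rho = 0, seed = 133)
  ph <- simu_pheno_ltm(sim$panel, h2 = 0.4, K = 0.15, n_causal = 100,
                       trait = "linear", seed = 135)
  gw <- suppressMessages(run_gwas(sim$panel, ph$y, trait = "linear"))
  sc <- scale_to_std(gw)
  # true standardized effects of the causal set (post-rescaling)
  Xs <- scale(sim$panel$X[, ph$causal$index])
  gcomp <- as.numeric(Xs %*% ph$causal$weight)
  w_scaled <- ph$causal$weight * sqrt(0.4 / var(gcomp - mean(gcomp)))
  diffs <- sc$beta_hat[ph$causal$index] - w_scaled
  se_mean <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se_mean)
})

test_that("grid model beats infinitesimal and marginal scores out of sample", {
  wins_grid <- 0L
  wins_inf <- 0L
  n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    sim <- simu_genotypes(n = 3000, m = 400, rho = 0.6, seed = 200 + s)
    ph <- simu_pheno_ltm(sim$panel, h2 = 0.4, K = 0.15, n_causal = 10,
                         trait = "linear", seed = 300 + s)
    train <- 1:2400
    test <- 2401:3000
    train_panel <- new_geno_panel(sim$panel$X[train, ], sim$panel$map)
    gw <- suppressMessages(run_gwas(train_panel, ph$y[train], trait = "linear"))
    gen <- interpolate_genetic_pos(sim$panel$map$chr, sim$panel$map$pos, sim$map)
    ld <- windowed_correlation(train_panel, gen, window_cM = 3)
    sc <- scale_to_std(gw)
    h2l <- ldsc_h2_constrained((gw$gamma_hat / gw$se_gamma)^2, ld_scores(ld),
                               gw$n)
    grid <- tidyr::expand_grid(p = c(0.003, 0.01, 0.03, 0.1),
                               h2 = h2l * c(0.7, 1, 1.4), sparse = FALSE)
    gfit <- run_grid(sc, ld, grid, burn_in = 60, num_iter = 200, seed = s)
    inf <- solve_inf(sc, ld, h2l)
    test_panel <- new_geno_panel(sim$panel$X[test, ], sim$panel$map)
    cor_of <- function(eff) cor(compute_pgs(test_panel, eff), ph$y[test])
    best_grid <- max(apply(gfit$effects, 2, function(e) {
      cor(compute_pgs(test_panel, e), ph$y[test])
    }))
    c_inf <- cor_of(inf$effect)
    c_marg <- cor_of(gw$gamma_hat)
    if (best_grid > c_inf) wins_grid <- wins_grid + 1L
    if (c_inf > c_marg) wins_inf <- wins_inf + 1L
  }
  expect_gte(wins_grid, n_seeds - 1L)
  expect_gte(wins_inf, n_seeds - 2L)
})
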