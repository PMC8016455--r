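test_that("infinitesimal solver matches diagonal, dense and limit oracles", {
  # identity LD, M = 2, n = 100, h2 = 0.5: ridge is 0.04, so x = beta_hat/1.04
  sc <- helper_scaled(c(0.3, -0.2), n = 100)
  ld <- helper_ld_from_dense(diag(2))
  expect_equal(solve_inf(sc, ld, 0.5)$beta_std, c(0.3, -0.2) / 1.04,
               tolerance = 1e-12)

  # 20-variant PD system vs dense direct solve
  ld20 <- helper_ar1_ld(20, rho = 0.7)
  set.seed(5)
  sc20 <- helper_scaled(rnorm(20, 0, 0.02), n = 40000)
  x <- solve_inf(sc20, ld20, 0.4)$beta_std
  A <- as.matrix(ld20$R) + diag(20) * 20 / (40000 * 0.4)
  expect_equal(x, solve(A, sc20$beta_hat), tolerance = 1e-8)

  # h2 -> infinity limit recovers the joint effects R^-1 beta_hat
  ld5 <- helper_ar1_ld(5, rho = 0.3)
  sc5 <- helper_scaled(c(0.1, 0.05, -0.02, 0, 0.08), n = 1000)
  xinf <- solve_inf(sc5, ld5, 1e9)$beta_std
  expect_equal(xinf, solve(as.matrix(ld5$R), sc5$beta_hat), tolerance = 1e-5)

  expect_error(solve_inf(sc5, ld5, 0), "positive")
})

test_that("residualized effects subtract LD-mediated contributions", {
  ld <- helper_ld_from_dense(diag(3))
  bh <- c(0.1, 0.2, 0.3)
  # identity LD: residualization changes nothing
  for (j in 1:3) {
    expect_equal(residualized_effect(j, bh, c(0.5, -0.1, 0.2), ld), bh[j])
  }
  # zero current effects: btilde is the marginal effect
  ld2 <- helper_ld_from_dense(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(residualized_effect(1, c(0.1, 0.2), c(0, 0), ld2), 0.1)
  # two variants, r = 0.5: btilde_1 = 0.1 - 0.5*0.1 = 0.05
  expect_equal(residualized_effect(1, c(0.1, 0.2), c(0.05, 0.1), ld2), 0.05)
})

test_that("causal posterior probability matches extended-precision oracles", {
  # frozen 80-digit evaluations of the naive two-density form
  cases <- list(
    list(p = 0.5,  h2 = 0.3, n = 1e4, M = 1e3,  bt = 0,
         want = 0.27429188517743177),
    list(p = 0.01, h2 = 0.4, n = 2e4, M = 2e3,  bt = 0.005,
         want = 0.00064686620308692805),
    list(p = 0.001, h2 = 0.2, n = 5e4, M = 1e5, bt = 0.002,
         want = 0.00010995766830907233),
    list(p = 0.3,  h2 = 0.5, n = 5e3, M = 500,  bt = 0.02,
         want = 0.20755258081772422),
    list(p = 1e-5, h2 = 0.3, n = 1e6, M = 1e6,  bt = 0.001,
         want = 9.5186736919318593e-08),
    list(p = 0.1,  h2 = 0.01, n = 1e4, M = 1e6, bt = 1e-4,
         want = 0.099955035968865801)
  )
  for (cs in cases) {
    expect_equal(causal_posterior_prob(cs$bt, cs$p, cs$h2, cs$n, cs$M),
                 cs$want, tolerance = 1e-12)
  }
  # bt = 0 with n h2/(M p) = 3: exactly 1/(1 + sqrt(4)) = 1/3
  expect_equal(causal_posterior_prob(0, 0.5, 0.3, 1000, 200), 1 / 3,
               tolerance = 1e-12)
  # p = 1: always causal
  expect_equal(causal_posterior_prob(c(0, 0.5, -2), 1, 0.3, 1e4, 1e3),
               rep(1, 3))
  # n * btilde^2 = 1e6: finite, within 1e-15 of 1, no overflow
  v <- causal_posterior_prob(0.1, 1e-5, 0.3, 1e8, 1e6)
  expect_true(is.finite(v))
  expect_equal(v, 1, tolerance = 1e-15)
})

test_that("stable form equals the naive two-density form where it is finite", {
  set.seed(17)
  for (i in 1:200) {
    p <- 10^runif(1, -5, 0)
    h2 <- runif(1, 0.01, 0.9)
    n <- 10^runif(1, 2, 6)
    M <- 10^runif(1, 2, 6)
    bt <- rnorm(1, 0, 0.05)
    s1 <- h2 / (M * p) + 1 / n
    s0 <- 1 / n
    n1 <- p / sqrt(s1) * exp(-bt^2 / (2 * s1))
    n0 <- (1 - p) / sqrt(s0) * exp(-bt^2 / (2 * s0))
    naive <- n1 / (n1 + n0)
    if (is.finite(naive) && (n1 + n0) > 0) {
      expect_equal(causal_posterior_prob(bt, p, h2, n, M), naive,
                   tolerance = 1e-12)
    }
  }
})

test_that("posterior-mean shrinkage is monotone in p at fixed btilde", {
  bt <- 0.01; h2 <- 0.3; n <- 5e4; M <- 1e4
  ps <- 10^seq(-5, 0, length.out = 30)
  omega <- vapply(ps, function(p) {
    causal_posterior_prob(bt, p, h2, n, M) * bt / (1 + M * p / (n * h2))
  }, numeric(1))
  expect_true(all(diff(abs(omega)) > 0))
})

test_that("single-variant chain is the closed form, exactly and repeatably", {
  sc <- helper_scaled(0.04, n = 10000)
  ld <- helper_ld_from_dense(matrix(1, 1, 1))
  p <- 0.2; h2 <- 0.15
  fit <- run_gibbs(sc, ld, p, h2, burn_in = 10, num_iter = 50, seed = 3)
  C <- 1 + p / (10000 * h2)
  pbar <- causal_posterior_prob(0.04, p, h2, 10000, 1)
  expect_equal(fit$beta_std, pbar * 0.04 / C, tolerance = 1e-14)
  fit2 <- run_gibbs(sc, ld, p, h2, burn_in = 10, num_iter = 50, seed = 3)
  expect_identical(fit$beta_std, fit2$beta_std)
})

test_that("zero marginal effects under the sparse rule give exact zeros", {
  sc <- helper_scaled(rep(0, 20), n = 1e4)
  ld <- helper_ar1_ld(20, rho = 0.4)
  fit <- run_gibbs(sc, ld, p = 0.01, h2 = 0.2, sparse = TRUE,
                   burn_in = 10, num_iter = 50, seed = 9)
  expect_true(all(fit$effect == 0))
  expect_equal(attr(fit, "sparsity"), 1)
})

test_that("incremental cache and direct recomputation agree", {
  ld <- helper_ar1_ld(50, rho = 0.6)
  dat <- helper_model_sumstats(ld, n = 2e4, p = 0.1, h2 = 0.3, seed = 23)
  inc <- run_gibbs(dat$scaled, ld, p = 0.1, h2 = 0.3, burn_in = 20,
                   num_iter = 100, seed = 5, cache = "incremental")
  dir <- run_gibbs(dat$scaled, ld, p = 0.1, h2 = 0.3, burn_in = 20,
                   num_iter = 100, seed = 5, cache = "direct")
  expect_equal(inc$beta_std, dir$beta_std, tolerance = 1e-10)
})

test_that("p = 1 chain agrees with the analytic infinitesimal solution", {
  ld <- helper_ar1_ld(10, rho = 0.5)
  dat <- helper_model_sumstats(ld, n = 5e4, p = 1, h2 = 0.4, seed = 29)
  inf <- solve_inf(dat$scaled, ld, 0.4)
  # Monte Carlo standard error from twelve independent chains
  fits <- lapply(1:12, function(s) {
    run_gibbs(dat$scaled, ld, p = 1, h2 = 0.4, burn_in = 200,
              num_iter = 2000, seed = 100 + s)$beta_std
  })
  est <- Reduce(`+`, fits) / 12
  mcse <- apply(do.call(cbind, fits), 1, sd) / sqrt(12)
  expect_true(all(abs(est - inf$beta_std) <= 3 * pmax(mcse, 1e-6)))
})

test_that("non-sparse chains have no exact zeros, sparse chains do", {
  ld <- helper_ar1_ld(100, rho = 0.5)
  dat <- helper_model_sumstats(ld, n = 2e4, p = 0.05, h2 = 0.3, seed = 37)
  ns <- run_gibbs(dat$scaled, ld, p = 0.05, h2 = 0.3, burn_in = 50,
                  num_iter = 300, seed = 7)
  sp <- run_gibbs(dat$scaled, ld, p = 0.05, h2 = 0.3, sparse = TRUE,
                  burn_in = 50, num_iter = 300, seed = 7)
  expect_false(any(ns$effect == 0))
  expect_gt(attr(sp, "sparsity"), 0)
  expect_equal(glance(sp)$sparse, TRUE)
})

test_that("default grid has the documented structure", {
  g <- default_grid(0.2)
  expect_equal(nrow(g), 126L)
  p_vals <- sort(unique(g$p))
  expect_length(p_vals, 21L)
  expect_identical(p_vals[1], 1e-5)
  expect_identical(p_vals[21], 1)
  # log-spacing: consecutive ratios constant to 1e-12
  ratios <- p_vals[-1] / p_vals[-21]
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_equal(sort(unique(g$h2)), c(0.7, 1, 1.4) * 0.2)
  expect_equal(sort(unique(g$sparse)), c(FALSE, TRUE))
  expect_error(default_grid(0), "positive")
})

test_that("grid runner reduces to single chains and is reproducible", {
  ld <- helper_ar1_ld(30, rho = 0.5)
  dat <- helper_model_sumstats(ld, n = 1e4, p = 0.2, h2 = 0.3, seed = 43)
  grid1 <- tibble::tibble(p = 0.2, h2 = 0.3, sparse = FALSE)
  gfit <- run_grid(dat$scaled, ld, grid1, burn_in = 20, num_iter = 100,
                   seed = 11)
  # a size-1 grid is one run_gibbs chain at the derived per-model seed
  single <- run_gibbs(dat$scaled, ld, p = 0.2, h2 = 0.3, burn_in = 20,
                      num_iter = 100, seed = gfit$manifest$seed[1])
  expect_identical(as.numeric(gfit$std_effects), single$beta_std)

  # thread count does not enter the result
  g2 <- tidyr::expand_grid(p = c(0.01, 0.3), h2 = c(0.2, 0.4),
                           sparse = c(FALSE, TRUE))
  f1 <- run_grid(dat$scaled, ld, g2, burn_in = 10, num_iter = 50, seed = 13,
                 threads = 1)
  f4 <- run_grid(dat$scaled, ld, g2, burn_in = 10, num_iter = 50, seed = 13,
                 threads = 4)
  expect_identical(f1$effects, f4$effects)
  expect_equal(nrow(glance(f1)), 8L)
})

test_that("sparse and non-sparse twins at matched (p, h2) nearly coincide", {
  ld <- helper_ar1_ld(300, rho = 0.5)
  dat <- helper_model_sumstats(ld, n = 5e4, p = 0.05, h2 = 0.4, seed = 51)
  twins <- run_grid(dat$scaled, ld,
                    tibble::tibble(p = 0.05, h2 = 0.4, sparse = c(FALSE, TRUE)),
                    burn_in = 100, num_iter = 400, seed = 15)
  expect_gt(cor(twins$effects[, 1], twins$effects[, 2]), 0.99)
  expect_gt(twins$manifest$sparsity[2], 0)
  expect_equal(twins$manifest$sparsity[1], 0)
})
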