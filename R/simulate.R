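#' Simulate a genotype panel with local LD
#'
#' Latent-Gaussian threshold scheme: each haplotype is a first-order
#' autoregressive latent series (correlation `rho^|j-k|` between variant
#' latents) thresholded at the per-variant allele-frequency quantile; the
#' dosage is the sum of two independent haplotypes, so it takes values 0/1/2
#' with tunable local LD. A synthetic genetic map is emitted at roughly
#' 1 cM per Mb, optionally with a recombination-suppressed interval in
#' which the map runs at a reduced rate, emulating long-range-LD regions
#' such as HLA (8 Mb but only 3 cM).
#'
#' @param n Number of individuals.
#' @param m Number of variants.
#' @param maf_range Per-variant minor-allele frequencies are drawn uniformly
#'   from this range.
#' @param rho Latent AR(1) correlation between adjacent variants (0 = free
#'   recombination).
#' @param chr Chromosome label.
#' @param spacing_bp Physical distance between adjacent variants.
#' @param cm_per_mb Baseline genetic-map rate.
#' @param compressed_region Optional integer vector `c(first, last)` of
#'   variant indices over which the map rate is multiplied by
#'   `compressed_factor`.
#' @param compressed_factor Map-rate multiplier inside the compressed
#'   region (default 3/8, i.e. 3 cM over what would physically be 8).
#' @param missing_rate Fraction of dosages set missing at random.
#' @param seed Integer seed.
#' @return A list: `panel` (a `geno_panel`) and `map` (genetic-map tibble
#'   `chr`, `pos_bp`, `pos_cM` with one knot per variant).
#' @export
simu_genotypes <- function(n, m, maf_range = c(0.05, 0.5), rho = 0.9,
                           chr = "1", spacing_bp = 5000, cm_per_mb = 1,
                           compressed_region = NULL, compressed_factor = 3 / 8,
                           missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  thr <- qnorm(maf)
  X <- matrix(0L, nrow = n, ncol = m)
  for (h in 1:2) {
    Z <- matrix(0, nrow = n, ncol = m)
    Z[, 1] <- rnorm(n)
    if (m > 1) {
      noise_sd <- sqrt(1 - rho^2)
      for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + noise_sd * rnorm(n)
    }
    X <- X + (Z < rep(thr, each = n))
  }
  storage.mode(X) <- "integer"
  if (missing_rate > 0) {
    X[stats::runif(length(X)) < missing_rate] <- NA_integer_
  }
  pos <- as.integer(1e5 + (seq_len(m) - 1L) * spacing_bp)
  rate <- rep(cm_per_mb, m)
  if (!is.null(compressed_region)) {
    inside <- seq_len(m) >= compressed_region[1] & seq_len(m) <= compressed_region[2]
    rate[inside] <- cm_per_mb * compressed_factor
  }
  # integrate the local rate along physical position
  seg_cm <- c(0, diff(pos) / 1e6 * rate[-1])
  pos_cM <- cumsum(seg_cm)
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4, m, replace = TRUE)
  map <- tibble(chr = as.character(chr), pos = pos,
                a0 = pairs[pick, 1], a1 = pairs[pick, 2],
                id = paste0("v", seq_len(m)), maf = maf)
  genmap <- tibble(chr = as.character(chr), pos_bp = pos, pos_cM = pos_cM)
  list(panel = new_geno_panel(X, map), map = genmap)
}

#' Simulate a phenotype under the liability threshold model
#'
#' A latent liability is built as a weighted sum of standardized causal
#' dosages plus Gaussian noise; weights are drawn `N(0, h2 / n_causal)`.
#' Both parts are rescaled so the in-sample variance of the genetic
#' component is exactly `h2` and the in-sample variance of the total
#' liability is exactly 1 (the noise is orthogonalized to the genetic
#' component first, so the two variances add). Cases are individuals whose
#' liability exceeds the standard-normal quantile at `1 - K`.
#'
#' @param panel A `geno_panel`.
#' @param h2 Liability-scale heritability in (0, 1].
#' @param K Prevalence in (0, 1) (binary trait).
#' @param n_causal Number of causal variants.
#' @param causal_region Optional integer vector `c(first, last)`: causal
#'   variants are drawn uniformly from this index interval (emulating a
#'   single-region architecture); default is the whole panel.
#' @param trait `"binary"` (default) thresholds the liability;
#'   `"linear"` returns the liability itself as the phenotype.
#' @param seed Integer seed.
#' @return A list: `liability`, `genetic` (the rescaled genetic component,
#'   with in-sample variance exactly `h2`), `y` (0/1 for binary, the
#'   liability for linear), `causal` tibble (`index`, `weight`), `h2`, `K`,
#'   `trait`.
#' @export
simu_pheno_ltm <- function(panel, h2 = 0.4, K = 0.15, n_causal = 300,
                           causal_region = NULL, trait = c("binary", "linear"),
                           seed = NULL) {
  trait <- match.arg(trait)
  stopifnot(h2 >= 0, h2 <= 1, K > 0, K < 1)
  if (!is.null(seed)) set.seed(seed)
  X <- panel$X
  n <- nrow(X)
  m <- ncol(X)
  if (n_causal > m) abort("`n_causal` exceeds the number of variants")
  pool <- if (is.null(causal_region)) seq_len(m) else
    seq.int(causal_region[1], causal_region[2])
  pool <- setdiff(pool, panel$monomorphic)
  if (length(pool) < n_causal) abort("not enough polymorphic variants in the causal region")
  causal <- sort(sample(pool, n_causal))

  g <- numeric(n)
  w <- rnorm(n_causal, 0, sqrt(h2 / max(n_causal, 1)))
  if (h2 > 0) {
    Xs <- X[, causal, drop = FALSE]
    mu <- colMeans(Xs, na.rm = TRUE)
    sds <- apply(Xs, 2, sd, na.rm = TRUE)
    Xs <- sweep(Xs, 2, mu)
    Xs[is.na(Xs)] <- 0  # mean imputation after centering
    Xs <- sweep(Xs, 2, sds, "/")
    g <- as.numeric(Xs %*% w)
    g <- g - mean(g)
    g <- g * sqrt(h2 / var(g))
  }
  e <- rnorm(n)
  if (h2 > 0) e <- e - g * (stats::cov(e, g) / var(g))
  e <- e - mean(e)
  ve <- var(e)
  e <- if (1 - h2 > 0) e * sqrt((1 - h2) / ve) else numeric(n)
  liab <- g + e
  y <- if (trait == "binary") as.integer(liab > qnorm(1 - K)) else liab
  list(liability = liab, genetic = g, y = y,
       causal = tibble(index = causal, weight = w),
       h2 = h2, K = K, trait = trait)
}

#' Per-variant GWAS on a genotype panel
#'
#' Simple (single-variant) regression with an intercept for every variant:
#' ordinary least squares for linear traits, logistic maximum likelihood for
#' binary traits (with `method = "linear"` available as a fast large-n
#' approximation). Missing dosages are excluded per variant, and the
#' per-variant sample size is the non-missing count; for binary traits the
#' reported `n` is the effective sample size from the case/control counts.
#' Monomorphic and non-converged variants are dropped with a logged count.
#'
#' @param panel A `geno_panel`.
#' @param y Phenotype vector aligned to the panel rows.
#' @param trait `"linear"` or `"binary"`.
#' @param method For binary traits: `"logistic"` (default) or `"linear"`.
#' @return A summary-statistics tibble (`chr`, `pos`, `a0`, `a1`,
#'   `gamma_hat`, `se_gamma`, `n`, `freq`, and for binary traits `ncase`,
#'   `ncontrol`).
#' @export
run_gwas <- function(panel, y, trait = c("linear", "binary"),
                     method = c("logistic", "linear")) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  X <- panel$X
  if (length(y) != nrow(X)) abort("`y` must have one entry per individual")
  m <- ncol(X)
  gamma_hat <- se <- rep(NA_real_, m)
  nn <- integer(m)
  freq <- rep(NA_real_, m)
  use_logistic <- trait == "binary" && method == "logistic"

  any_na <- anyNA(X)
  if (!use_logistic && !any_na) {
    # vectorized OLS across all variants at once
    n <- nrow(X)
    yc <- y - mean(y)
    mu <- colMeans(X)
    Sxy <- as.numeric(crossprod(X, yc))          # centering y suffices
    Sxx <- (colMeans(X^2) - mu^2) * n
    Syy <- sum(yc^2)
    slope <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
    rss <- pmax(Syy - slope^2 * Sxx, 0)
    gamma_hat <- slope
    se <- sqrt(rss / ((n - 2) * Sxx))
    nn <- rep(n, m)
    freq <- mu / 2
  } else {
    for (j in seq_len(m)) {
      x <- X[, j]
      okr <- !is.na(x) & !is.na(y)
      xj <- x[okr]
      yj <- y[okr]
      nj <- length(xj)
      nn[j] <- nj
      freq[j] <- mean(xj) / 2
      if (nj < 3 || sd(xj) == 0) next
      if (use_logistic) {
        fit <- suppressWarnings(
          glm(yj ~ xj, family = binomial())
        )
        if (!fit$converged) next
        cf <- summary(fit)$coefficients
        if (nrow(cf) < 2) next
        gamma_hat[j] <- cf[2, 1]
        se[j] <- cf[2, 2]
      } else {
        xc <- xj - mean(xj)
        yc <- yj - mean(yj)
        Sxx <- sum(xc^2)
        slope <- sum(xc * yc) / Sxx
        rss <- max(sum(yc^2) - slope^2 * Sxx, 0)
        gamma_hat[j] <- slope
        se[j] <- sqrt(rss / ((nj - 2) * Sxx))
      }
    }
  }

  out <- panel$map[, intersect(c("chr", "pos", "a0", "a1"), names(panel$map))]
  out$gamma_hat <- gamma_hat
  out$se_gamma <- se
  out$freq <- freq
  if (trait == "binary") {
    ncase <- sum(y == 1, na.rm = TRUE)
    ncontrol <- sum(y == 0, na.rm = TRUE)
    out$ncase <- ncase
    out$ncontrol <- ncontrol
    out$n <- effective_sample_size(ncase, ncontrol)
  } else {
    out$n <- nn
  }
  bad <- !is.finite(out$gamma_hat) | !is.finite(out$se_gamma) | out$se_gamma <= 0
  if (any(bad)) {
    inform(paste0("dropped ", sum(bad),
                  " variant(s) from GWAS output (monomorphic or non-converged)"))
  }
  as_tibble(out[!bad, , drop = FALSE])
}
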