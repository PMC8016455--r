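#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted polygenic-score objects
#'
#' `tidy()` returns one row per variant (effects) or per chain/model;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `pgs_result`, `pgs_grid`, `pgs_auto`, `qc_report` or
#'   `auc_summary`.
#' @param ... Unused.
#' @name ldpgs-tidiers
NULL

#' @rdname ldpgs-tidiers
#' @export
tidy.pgs_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pgs_result")
  out
}

#' @rdname ldpgs-tidiers
#' @export
glance.pgs_result <- function(x, ...) {
  prm <- attr(x, "params")
  tibble(method = attr(x, "method"), p = prm$p, h2 = prm$h2,
         sparse = isTRUE(prm$sparse), diverged = attr(x, "diverged"),
         sparsity = attr(x, "sparsity"), n_variants = nrow(x))
}

#' @rdname ldpgs-tidiers
#' @export
tidy.pgs_grid <- function(x, ...) {
  eff <- as_tibble(x$effects, .name_repair = ~ paste0("model", seq_along(.x)))
  dplyr::bind_cols(
    x$scaled[, intersect(c("chr", "pos", "a0", "a1"), names(x$scaled))], eff
  ) |>
    tidyr::pivot_longer(dplyr::starts_with("model"), names_to = "model",
                        names_prefix = "model", names_transform = as.integer,
                        values_to = "effect")
}

#' @rdname ldpgs-tidiers
#' @export
glance.pgs_grid <- function(x, ...) x$manifest

#' @rdname ldpgs-tidiers
#' @export
tidy.pgs_auto <- function(x, ...) x$chains

#' @rdname ldpgs-tidiers
#' @export
glance.pgs_auto <- function(x, ...) {
  tibble(p_hat = x$p_hat, h2_hat = x$h2_hat,
         n_chains = nrow(x$chains), n_kept = sum(x$chains$kept),
         sd_source = x$sd_source)
}

#' @rdname ldpgs-tidiers
#' @export
glance.qc_report <- function(x, ...) {
  cnt <- attr(x, "rule_counts")
  tibble(n_variants = nrow(x), n_kept = sum(x$keep),
         n_low_ratio = cnt[["low_ratio"]], n_high_diff = cnt[["high_diff"]],
         n_ss_floor = cnt[["ss_floor"]], n_val_floor = cnt[["val_floor"]])
}

#' @rdname ldpgs-tidiers
#' @export
tidy.auc_summary <- function(x, ...) {
  tibble(estimate = x$estimate, boot_mean = x$mean, conf_low = x$lower,
         conf_high = x$upper, n_boot = x$n_boot)
}

#' Plot methods
#'
#' `autoplot()` on a `qc_report` draws implied vs observed genotype SDs
#' colored by QC decision; on a `pgs_auto` it draws the per-chain `p` and
#' `h2` trajectories; on a `pgs_grid` it draws sparsity by `p`.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name ldpgs-autoplot
NULL

#' @rdname ldpgs-autoplot
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sd_val, y = .data$sd_ss,
                                       colour = .data$keep)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "SD observed in validation panel",
                  y = "SD implied by summary statistics",
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' @rdname ldpgs-autoplot
#' @export
autoplot.pgs_auto <- function(object, ...) {
  traj <- purrr::imap_dfr(object$chain_fits, function(ch, i) {
    tibble(chain = i, sweep = seq_along(ch$p_traj),
           p = ch$p_traj, h2 = ch$h2_traj, kept = i %in% object$kept)
  })
  traj <- tidyr::pivot_longer(traj, c("p", "h2"), names_to = "parameter")
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$sweep, y = .data$value,
                                     group = .data$chain,
                                     colour = .data$kept)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = NULL, colour = "kept") +
    ggplot2::theme_minimal()
}

#' @rdname ldpgs-autoplot
#' @export
autoplot.pgs_grid <- function(object, ...) {
  ggplot2::ggplot(object$manifest,
                  ggplot2::aes(x = .data$p, y = .data$sparsity,
                               colour = factor(.data$h2),
                               linetype = .data$sparse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prior proportion of causal variants p",
                  y = "fraction of exactly-zero effects",
                  colour = "h2", linetype = "sparse") +
    ggplot2::theme_minimal()
}
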