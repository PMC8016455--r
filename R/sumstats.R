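#' Read GWAS summary statistics
#'
#' Parses a delimited text file of per-variant marginal GWAS results into the
#' canonical summary-statistics tibble used throughout the package. Rows
#' violating basic invariants (non-positive standard error or sample size,
#' identical alleles, duplicated `(chr, pos, a0, a1)` keys) are dropped and
#' counted. When `ncase`/`ncontrol` are mapped but `n` is not, the per-variant
#' effective sample size `4 / (1/ncase + 1/ncontrol)` is filled in, which is
#' the scale on which binary-trait summary statistics must enter the model.
#'
#' @param path Path to a whitespace- or tab-delimited file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`chr`, `pos`, `a0`, `a1`, `gamma_hat`, `se_gamma`, and optionally `n`,
#'   `ncase`, `ncontrol`, `freq`) to column names in the file. Canonical names
#'   already present in the file need not be mapped.
#'
#' @return A tibble with columns `chr`, `pos`, `a0`, `a1`, `gamma_hat`,
#'   `se_gamma`, `n` (plus any optional columns present), one row per retained
#'   variant. The number of dropped rows is attached as attribute
#'   `"n_dropped"`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) abort(paste0("empty summary-statistics file: ", path))
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols)) {
      abort(paste0("mapped column(s) absent from file: ",
                   paste(missing_cols, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_req <- setdiff(.ss_required, names(raw))
  if (length(missing_req)) {
    abort(paste0("required column(s) missing: ",
                 paste(missing_req, collapse = ", ")))
  }
  ss <- as_tibble(raw[, intersect(c(.ss_required, .ss_optional), names(raw))])
  validate_sumstats(ss)
}

#' Enforce summary-statistics invariants
#'
#' Normalizes chromosome labels (stripping any `"chr"` prefix), upper-cases
#' alleles, fills `n` from case/control counts where needed, and drops rows
#' with non-positive `se_gamma` or `n`, identical alleles, or duplicated
#' variant keys.
#'
#' @param ss A summary-statistics data frame.
#' @return A validated tibble; dropped-row count in attribute `"n_dropped"`.
#' @export
validate_sumstats <- function(ss) {
  ss <- as_tibble(ss)
  ss$chr <- .norm_chr(ss$chr)
  ss$a0 <- toupper(as.character(ss$a0))
  ss$a1 <- toupper(as.character(ss$a1))
  if (!("n" %in% names(ss)) || all(is.na(ss$n))) {
    if (all(c("ncase", "ncontrol") %in% names(ss))) {
      ss$n <- effective_sample_size(ss$ncase, ss$ncontrol)
    } else {
      abort("summary statistics need either `n` or both `ncase` and `ncontrol`")
    }
  }
  ok <- is.finite(ss$gamma_hat) & is.finite(ss$se_gamma) & is.finite(ss$n) &
    ss$se_gamma > 0 & ss$n > 0 & ss$a0 != ss$a1
  key <- paste(ss$chr, ss$pos, ss$a0, ss$a1, sep = ":")
  ok <- ok & !duplicated(key)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0("dropped ", n_dropped,
                  " summary-statistics row(s) violating invariants"))
  }
  out <- ss[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics
#'
#' Tab-delimited output that round-trips through [read_sumstats()].
#'
#' @param ss Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Effective sample size of a case-control GWAS
#'
#' The sample size of a balanced design with the same power:
#' `neff = 4 / (1/ncase + 1/ncontrol)`. For a balanced study this equals the
#' total sample size; as one arm grows unboundedly it saturates at four times
#' the smaller arm. Binary-trait summary statistics are placed on this scale
#' before modeling.
#'
#' @param ncase,ncontrol Case and control counts (vectorized).
#' @return Numeric vector of effective sample sizes.
#' @export
#' @examples
#' effective_sample_size(5000, 5000)  # 10000
effective_sample_size <- function(ncase, ncontrol) {
  if (any(ncase <= 0) || any(ncontrol <= 0)) {
    abort("`ncase` and `ncontrol` must be positive")
  }
  4 / (1 / ncase + 1 / ncontrol)
}

#' Match summary statistics to a genotype panel
#'
#' Joins variants on `(chr, pos)` and reconciles alleles against the panel's
#' variant metadata. Exact-orientation matches are kept as-is; matches with
#' `a0`/`a1` swapped are kept with `gamma_hat` negated (and `freq` reflected)
#' so that effects always count copies of the panel's first-listed allele.
#' Strand-ambiguous variants (A/T and C/G pairs) are removed under the default
#' policy since their orientation cannot be resolved without frequencies.
#'
#' @param ss Summary-statistics tibble.
#' @param panel_meta Variant metadata with columns `chr`, `pos`, `a0`, `a1`
#'   (e.g. the `map` element of a genotype panel).
#' @param remove_ambiguous Drop strand-ambiguous variants (default `TRUE`).
#' @return The matched summary-statistics tibble, in panel order, with an
#'   extra integer column `panel_index` giving each variant's column in the
#'   panel. Per-category counts (`n_exact`, `n_swapped`, `n_ambiguous_removed`,
#'   `n_unmatched`) are attached as attribute `"match_counts"`.
#' @export
match_variants <- function(ss, panel_meta, remove_ambiguous = TRUE) {
  pm <- as_tibble(panel_meta)
  pm$chr <- .norm_chr(pm$chr)
  pm$a0 <- toupper(as.character(pm$a0))
  pm$a1 <- toupper(as.character(pm$a1))
  ss <- as_tibble(ss)
  ss$chr <- .norm_chr(ss$chr)

  pm$panel_index <- seq_len(nrow(pm))
  joined <- dplyr::inner_join(
    ss, pm[, c("chr", "pos", "a0", "a1", "panel_index")],
    by = c("chr", "pos"), suffix = c("", "_panel"), relationship = "many-to-many"
  )
  exact <- joined$a0 == joined$a0_panel & joined$a1 == joined$a1_panel
  swapped <- joined$a0 == joined$a1_panel & joined$a1 == joined$a0_panel
  keep <- exact | swapped
  joined <- joined[keep, , drop = FALSE]
  is_sw <- swapped[keep]

  # reorient swapped rows onto the panel's allele pair
  joined$gamma_hat[is_sw] <- -joined$gamma_hat[is_sw]
  if ("freq" %in% names(joined)) joined$freq[is_sw] <- 1 - joined$freq[is_sw]
  tmp <- joined$a0[is_sw]
  joined$a0[is_sw] <- joined$a1[is_sw]
  joined$a1[is_sw] <- tmp

  amb <- .is_ambiguous(joined$a0, joined$a1)
  n_amb <- 0L
  if (remove_ambiguous) {
    n_amb <- sum(amb)
    joined <- joined[!amb, , drop = FALSE]
    is_sw <- is_sw[!amb]
  }
  if (nrow(joined) == 0L) abort("no variants matched between summary statistics and panel")

  joined <- joined[order(joined$panel_index), , drop = FALSE]
  joined$a0_panel <- NULL
  joined$a1_panel <- NULL
  counts <- c(n_exact = sum(!is_sw), n_swapped = sum(is_sw),
              n_ambiguous_removed = n_amb,
              n_unmatched = nrow(ss) - sum(keep))
  inform(paste0(nrow(joined), " variant(s) matched (", counts[["n_swapped"]],
                " swapped, ", n_amb, " ambiguous removed, ",
                counts[["n_unmatched"]], " unmatched)"))
  attr(joined, "match_counts") <- counts
  joined
}
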