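#' Construct an LD matrix container
#'
#' Internal constructor. The correlation matrix is stored as a
#' column-compressed symmetric (upper-triangle) sparse matrix at full double
#' precision, together with the genetic positions and the window size that
#' defined its sparsity pattern.
#'
#' @param R A symmetric sparse correlation matrix (coercible to `dsCMatrix`).
#' @param genpos Per-variant genetic positions (cM).
#' @param info Variant metadata tibble aligned with `R`.
#' @param window_cM Window size (cM) used to build `R` (may be `Inf`).
#' @param monomorphic Integer indices of monomorphic variants.
#' @return An `ld_matrix` object.
#' @export
new_ld_matrix <- function(R, genpos, info, window_cM, monomorphic = integer()) {
  R <- as(Matrix::forceSymmetric(Matrix::Matrix(R, sparse = TRUE)),
          "CsparseMatrix")
  if (nrow(R) != length(genpos)) abort("`genpos` length must match `R`")
  structure(list(R = R, genpos = as.numeric(genpos), info = as_tibble(info),
                 window_cM = window_cM, monomorphic = as.integer(monomorphic)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants, window %s cM, %d stored nonzeros\n",
              nrow(x$R), format(x$window_cM), Matrix::nnzero(x$R)))
  invisible(x)
}

#' @export
dim.ld_matrix <- function(x) dim(x$R)

#' Windowed LD correlation matrix
#'
#' Pearson correlations between dosage columns, kept only for pairs on the
#' same chromosome whose genetic distance is strictly below `window_cM`;
#' all other entries are structurally zero. Genetic distance (rather than
#' physical distance or a variant count) is used so that recombination
#' coldspots with far-reaching LD, such as the HLA region, fit inside a
#' globally small window. Monomorphic columns receive a unit diagonal and
#' zero off-diagonals and are flagged.
#'
#' @param panel A `geno_panel`.
#' @param genpos Per-variant genetic positions in cM, aligned with the
#'   panel's columns (e.g. from [interpolate_genetic_pos()]).
#' @param window_cM Window size in cM (default 3). `Inf` gives the dense
#'   per-chromosome correlation matrix.
#' @param impute `"pairwise"` (default) computes each correlation over
#'   pairwise-complete individuals; `"mean"` mean-imputes missing dosages
#'   per column first.
#' @return An `ld_matrix`.
#' @export
windowed_correlation <- function(panel, genpos, window_cM = 3,
                                 impute = c("pairwise", "mean")) {
  impute <- match.arg(impute)
  X <- panel$X
  if (nrow(X) < 2L) abort("at least 2 individuals are required to estimate LD")
  m <- ncol(X)
  if (length(genpos) != m) abort("`genpos` must have one entry per variant")
  chr <- .norm_chr(panel$map$chr)

  if (impute == "mean") {
    X <- apply(X, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      col
    })
  }

  blocks <- list()
  mono_all <- integer()
  offset <- 0L
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    Xi <- X[, idx, drop = FALSE]
    Ci <- suppressWarnings(cor(Xi, use = "pairwise.complete.obs"))
    mono <- which(apply(Xi, 2, function(v) {
      v <- v[!is.na(v)]
      length(v) < 2L || sd(v) == 0
    }))
    Ci[!is.finite(Ci)] <- 0
    if (length(mono)) {
      Ci[mono, ] <- 0
      Ci[, mono] <- 0
    }
    diag(Ci) <- 1
    g <- genpos[idx]
    if (is.finite(window_cM)) {
      D <- abs(outer(g, g, "-"))
      Ci[D >= window_cM] <- 0
    }
    blocks[[length(blocks) + 1L]] <- Matrix::drop0(Matrix::Matrix(Ci, sparse = TRUE))
    mono_all <- c(mono_all, mono + offset)
    offset <- offset + length(idx)
  }
  # variants are processed chromosome by chromosome in input order
  ord <- unlist(lapply(unique(chr), function(cc) which(chr == cc)))
  R <- Matrix::bdiag(blocks)
  # restore original column order if input interleaved chromosomes
  inv <- order(ord)
  R <- R[inv, inv, drop = FALSE]
  mono_all <- sort(ord[mono_all])
  new_ld_matrix(R, genpos, panel$map, window_cM, mono_all)
}

#' Per-variant LD scores
#'
#' `ell_j = sum_k R[j,k]^2` over the stored nonzeros (diagonal included);
#' the regressor of LD score regression.
#'
#' @param ld An `ld_matrix`.
#' @return Numeric vector of LD scores, one per variant.
#' @export
ld_scores <- function(ld) {
  A <- as(ld$R, "generalMatrix")
  as.numeric(Matrix::rowSums(A * A))
}

#' Assemble per-chromosome LD blocks genome-wide
#'
#' Block-diagonal concatenation of per-chromosome `ld_matrix` objects;
#' cross-chromosome entries are structurally zero and the variant order is
#' the concatenation order.
#'
#' @param blocks List of `ld_matrix` objects with disjoint chromosomes.
#' @return A single genome-wide `ld_matrix`.
#' @export
assemble_genomewide <- function(blocks) {
  if (!length(blocks)) abort("`blocks` must be a nonempty list")
  if (length(blocks) == 1L) return(blocks[[1L]])
  chrs <- lapply(blocks, function(b) unique(.norm_chr(b$info$chr)))
  all_chr <- unlist(chrs)
  if (anyDuplicated(all_chr)) {
    abort(paste0("duplicated chromosome(s) across blocks: ",
                 paste(unique(all_chr[duplicated(all_chr)]), collapse = ", ")))
  }
  R <- Matrix::bdiag(lapply(blocks, function(b) b$R))
  genpos <- unlist(lapply(blocks, function(b) b$genpos))
  info <- dplyr::bind_rows(lapply(blocks, function(b) b$info))
  offs <- cumsum(c(0L, vapply(blocks, function(b) nrow(b$R), integer(1))))
  mono <- unlist(lapply(seq_along(blocks),
                        function(i) blocks[[i]]$monomorphic + offs[i]))
  new_ld_matrix(R, genpos, info, blocks[[1L]]$window_cM, mono)
}

.ld_format_version <- 1L

#' Save / load an LD matrix
#'
#' Lossless on-disk round trip of the sparse values, sparsity pattern,
#' variant metadata, genetic positions and the window size used, behind an
#' explicit format-version tag.
#'
#' @param ld An `ld_matrix`.
#' @param path File path (conventionally `.ldx`).
#' @return `save_ld()` returns `path` invisibly; `load_ld()` returns the
#'   `ld_matrix`.
#' @export
save_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  payload <- list(format = "ldpgs_ld", version = .ld_format_version,
                  R = ld$R, genpos = ld$genpos, info = ld$info,
                  window_cM = ld$window_cM, monomorphic = ld$monomorphic)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_ld
#' @export
load_ld <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "ldpgs_ld") ||
      !identical(payload$version, .ld_format_version)) {
    abort(paste0("unrecognized LD container format/version in ", path))
  }
  new_ld_matrix(payload$R, payload$genpos, payload$info, payload$window_cM,
                payload$monomorphic)
}
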