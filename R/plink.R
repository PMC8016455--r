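#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes the variant-major 2-bit PLINK encoding. Per the package convention,
#' a dosage counts copies of the bim file's first-listed allele (`a0` here),
#' so the code `00` decodes to dosage 2, `10` (heterozygote) to 1, `11` to 0,
#' and `01` to missing (`NA`). Columns with zero variance among non-missing
#' entries are flagged monomorphic.
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return A `geno_panel` object: list with `X` (individuals x variants
#'   integer dosage matrix, `NA` = missing), `map` (tibble: `chr`, `pos`,
#'   `a0`, `a1`, `id`), `fam` (tibble of sample identifiers) and
#'   `monomorphic` (integer indices of zero-variance columns).
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) abort(paste0("file not found: ", f))

  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  m <- nrow(bim_df)
  n <- nrow(fam_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B) ||
      raw[3] != as.raw(0x01)) {
    abort("not a variant-major PLINK bed file (bad magic bytes)")
  }
  bpv <- ceiling(n / 4)
  if (length(raw) != 3L + bpv * m) {
    abort(sprintf("bed size %d inconsistent with %d samples x %d variants",
                  length(raw), n, m))
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample 1 in the lowest-order bits of each byte
  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)
  shifted <- matrix(body, nrow = bpv, ncol = m)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bpv), ] <-
      bitwAnd(shifted %/% (4L^k), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # codes 00, 01, 10, 11
  X <- matrix(lut[codes + 1L], nrow = n, ncol = m)

  map <- tibble(chr = .norm_chr(bim_df[[1]]), id = as.character(bim_df[[2]]),
                genpos = as.numeric(bim_df[[3]]), pos = as.integer(bim_df[[4]]),
                a0 = toupper(as.character(bim_df[[5]])),
                a1 = toupper(as.character(bim_df[[6]])))
  fam_tb <- tibble(fid = as.character(fam_df[[1]]), iid = as.character(fam_df[[2]]))
  new_geno_panel(X, map[, c("chr", "pos", "a0", "a1", "id", "genpos")], fam_tb)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink_bed()] under the same dosage convention.
#'
#' @param panel A `geno_panel`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(panel, prefix) {
  X <- panel$X
  n <- nrow(X)
  m <- ncol(X)
  code <- matrix(1L, nrow = n, ncol = m)         # default: missing (01)
  code[!is.na(X) & X == 2L] <- 0L
  code[!is.na(X) & X == 1L] <- 2L
  code[!is.na(X) & X == 0L] <- 3L
  bpv <- ceiling(n / 4)
  padded <- matrix(0L, nrow = 4L * bpv, ncol = m)
  padded[seq_len(n), ] <- code
  bytes <- matrix(0L, nrow = bpv, ncol = m)
  for (k in 0:3) {
    bytes <- bytes + padded[seq.int(k + 1L, by = 4L, length.out = bpv), ,
                            drop = FALSE] * 4L^k
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)

  map <- panel$map
  id <- if ("id" %in% names(map)) map$id else paste0("v", seq_len(m))
  genpos <- if ("genpos" %in% names(map)) map$genpos else 0
  utils::write.table(
    data.frame(map$chr, id, genpos, map$pos, map$a0, map$a1),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  fam <- panel$fam
  utils::write.table(
    data.frame(fam$fid, fam$iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Construct a genotype panel
#'
#' @param X Integer dosage matrix (individuals x variants), `NA` = missing.
#' @param map Variant metadata tibble with at least `chr`, `pos`, `a0`, `a1`.
#' @param fam Sample metadata tibble with `fid`, `iid` (built from row count
#'   when omitted).
#' @return A `geno_panel` object.
#' @export
new_geno_panel <- function(X, map, fam = NULL) {
  map <- as_tibble(map)
  if (ncol(X) != nrow(map)) abort("column count of `X` must equal rows of `map`")
  if (is.null(fam)) {
    fam <- tibble(fid = paste0("F", seq_len(nrow(X))),
                  iid = paste0("I", seq_len(nrow(X))))
  }
  sds <- apply(X, 2, sd, na.rm = TRUE)
  mono <- which(is.na(sds) | sds == 0)
  structure(list(X = X, map = map, fam = as_tibble(fam), monomorphic = mono),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d individuals x %d variants (%d monomorphic, %.2f%% missing)\n",
              nrow(x$X), ncol(x$X), length(x$monomorphic),
              100 * mean(is.na(x$X))))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$X)
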