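#' Read a genetic map
#'
#' Three-column delimited text (`chr`, `pos_bp`, `pos_cM`) with a header row.
#' Knots are sorted by physical position per chromosome; physical positions
#' must be strictly increasing and genetic positions non-decreasing.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `chr`, `pos_bp`, `pos_cM`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chr", "pos_bp", "pos_cM")
  df$chr <- .norm_chr(df$chr)
  df <- df[order(df$chr, df$pos_bp), , drop = FALSE]
  validate_genetic_map(as_tibble(df))
}

validate_genetic_map <- function(map) {
  by_chr <- split(map, map$chr)
  for (b in by_chr) {
    if (is.unsorted(b$pos_bp, strictly = TRUE)) {
      abort("genetic map: pos_bp must be strictly increasing within chromosome")
    }
    if (is.unsorted(b$pos_cM)) {
      abort("genetic map: pos_cM must be non-decreasing within chromosome")
    }
  }
  map
}

#' Interpolate physical to genetic positions
#'
#' Piecewise-linear interpolation of base-pair positions onto the genetic
#' (centimorgan) scale, per chromosome. Queries beyond the map's ends are
#' extrapolated linearly from the two terminal knots, so long arms are never
#' silently clamped.
#'
#' @param chr Chromosome label per query (recycled if length 1).
#' @param pos_bp Physical positions to interpolate.
#' @param map Genetic map tibble (`chr`, `pos_bp`, `pos_cM`).
#' @return Numeric vector of genetic positions in cM.
#' @export
interpolate_genetic_pos <- function(chr, pos_bp, map) {
  chr <- rep_len(.norm_chr(chr), length(pos_bp))
  map$chr <- .norm_chr(map$chr)
  missing_chr <- setdiff(unique(chr), unique(map$chr))
  if (length(missing_chr)) {
    abort(paste0("chromosome(s) absent from genetic map: ",
                 paste(missing_chr, collapse = ", ")))
  }
  out <- numeric(length(pos_bp))
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    knots <- map[map$chr == cc, , drop = FALSE]
    knots <- knots[order(knots$pos_bp), , drop = FALSE]
    x <- knots$pos_bp
    y <- knots$pos_cM
    if (length(x) == 1L) {
      out[idx] <- y
      next
    }
    q <- pos_bp[idx]
    v <- approx(x, y, xout = q, rule = 1)$y
    lo <- q < x[1]
    hi <- q > x[length(x)]
    if (any(lo)) {
      s <- (y[2] - y[1]) / (x[2] - x[1])
      v[lo] <- y[1] + s * (q[lo] - x[1])
    }
    if (any(hi)) {
      k <- length(x)
      s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
      v[hi] <- y[k] + s * (q[hi] - x[k])
    }
    out[idx] <- v
  }
  out
}
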