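# Sequence-logo statistics: per-column information content and letter heights.

#' Compute sequence-logo statistics for an aligned domain set
#'
#' Per-column information content in bits,
#' `IC = log2(20) - H(column) - correction`, with per-residue letter heights
#' `frequency x IC`. Columns whose gap fraction exceeds the threshold are
#' excluded (rare insertion/deletion columns are not represented in the
#' logo). The optional small-sample correction subtracts the expected
#' entropy bias `(20 - 1) / (2 ln 2 n)`; IC is clamped at 0.
#'
#' @param aligned Character vector of >= 2 aligned sequences (`-` gaps).
#' @param gap_column_threshold Gap fraction above which a column is dropped
#'   (default 0.5).
#' @param small_sample_correction Apply the finite-sample bias correction
#'   (default FALSE).
#' @return A list with `positions` (retained original column indices),
#'   `ic_bits` (numeric per column) and `heights` (20 x L matrix of letter
#'   heights, rows [AA_STANDARD]).
#' @export
compute_logo <- function(aligned, gap_column_threshold = 0.5,
                         small_sample_correction = FALSE) {
  if (length(aligned) < 2L) {
    stop("need at least 2 aligned sequences", call. = FALSE)
  }
  if (length(unique(nchar(aligned))) != 1L) {
    stop("ragged alignment", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-" | chars == ".")
  keep <- which(gap_frac <= gap_column_threshold)
  if (!length(keep)) stop("all columns are gap-dominated", call. = FALSE)

  max_ic <- log2(20)
  ic <- numeric(length(keep))
  heights <- matrix(0, nrow = 20, ncol = length(keep),
                    dimnames = list(AA_STANDARD, keep))
  for (j in seq_along(keep)) {
    col <- chars[, keep[j]]
    col <- col[col %in% AA_STANDARD]
    n <- length(col)
    freq <- as.numeric(table(factor(col, levels = AA_STANDARD))) / n
    h <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
    corr <- if (small_sample_correction) (20 - 1) / (2 * log(2) * n) else 0
    ic[j] <- max(0, max_ic - h - corr)
    heights[, j] <- freq * ic[j]
  }
  list(positions = keep, ic_bits = ic, heights = heights)
}
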