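# Position-profile construction and windowed log-odds repeat scanning.

#' Build a position profile from aligned sequences
#'
#' Estimates per-position residue frequencies from an alignment, with
#' background-weighted pseudocounts. Columns with more than 50% gaps are
#' dropped before frequency estimation; remaining gaps are ignored in the
#' per-column counts.
#'
#' @param aligned Character vector of >= 2 aligned sequences (equal length,
#'   `-` for gaps).
#' @param pseudocount Pseudocount mass added per column, spread over the
#'   background (default 1).
#' @param background Named background probabilities over [AA_STANDARD]
#'   (default uniform).
#' @param gap_column_threshold Gap fraction above which a column is dropped
#'   (default 0.5).
#' @return An object of class `repeat_profile`: list with `length`, `freq`
#'   (20 x L matrix, rows [AA_STANDARD]), `background`, `pseudocount`,
#'   `columns` (retained original column indices).
#' @export
build_profile <- function(aligned, pseudocount = 1,
                          background = uniform_background(),
                          gap_column_threshold = 0.5) {
  if (length(aligned) < 2L) {
    stop("need at least 2 aligned sequences", call. = FALSE)
  }
  if (length(unique(nchar(aligned))) != 1L) {
    stop("ragged alignment: sequences differ in aligned length",
         call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  background <- background[AA_STANDARD]
  stopifnot(!anyNA(background), abs(sum(background) - 1) < 1e-9)

  chars <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-" | chars == ".")
  keep <- which(gap_frac <= gap_column_threshold)
  if (!length(keep)) stop("all columns are gap-dominated", call. = FALSE)

  freq <- vapply(keep, function(j) {
    col <- chars[, j]
    col <- col[col %in% AA_STANDARD]
    counts <- table(factor(col, levels = AA_STANDARD))
    as.numeric(counts + pseudocount * background) /
      (length(col) + pseudocount)
  }, numeric(20))
  rownames(freq) <- AA_STANDARD

  if (ncol(freq) < 10L) {
    stop("profile length must be >= 10 positions", call. = FALSE)
  }
  structure(list(length = ncol(freq), freq = freq, background = background,
                 pseudocount = pseudocount, columns = keep),
            class = "repeat_profile")
}

#' Single-repeat profile from a template domain sequence
#'
#' Convenience constructor: builds a repeat-level profile from the two repeat
#' instances of a template domain (the R2 segment and the first
#' repeat-length positions of R3), so that one profile detects both repeats
#' of an embedded domain.
#'
#' @param template_seq 105-residue template sequence from [make_template()].
#' @param tpl The [canonical_template()] describing its coordinates.
#' @param pseudocount Passed to [build_profile()].
#' @return A `repeat_profile` of the R2 repeat length (52).
#' @export
repeat_profile <- function(template_seq, tpl = canonical_template(),
                           pseudocount = 1) {
  w <- tpl$r2_span[2] - tpl$r2_span[1] + 1L
  segs <- c(substr(template_seq, tpl$r2_span[1], tpl$r2_span[2]),
            substr(template_seq, tpl$r3_span[1], tpl$r3_span[1] + w - 1L))
  build_profile(segs, pseudocount = pseudocount)
}

#' Scan a protein for MYB repeats by windowed log-odds
#'
#' Scores every length-L window as the sum of per-position
#' `log2(freq / background)` and selects non-overlapping hits greedily in
#' decreasing score order (ties broken by smaller start), keeping windows
#' above the bit-score threshold. Retained hits are re-sorted by start and
#' grouped: a spacing between consecutive hits outside `[min_gap, max_gap]`
#' starts a new repeat group.
#'
#' @param sequence Protein sequence (single string).
#' @param profile A `repeat_profile`.
#' @param score_threshold_bits Minimum window score in bits (default 50,
#'   calibrated so random sequences of matched composition essentially never
#'   produce a hit; see the package vignette).
#' @param min_gap,max_gap Allowed residue spacing between consecutive hits of
#'   one repeat group (defaults 0 and 20).
#' @return data.frame with columns `repeat_index`, `start`, `end`, `score`,
#'   `group` (1-based inclusive coordinates). Zero rows (with a warning) if
#'   the sequence is shorter than the profile.
#' @export
scan_repeats <- function(sequence, profile, score_threshold_bits = 50,
                         min_gap = 0L, max_gap = 20L) {
  stopifnot(inherits(profile, "repeat_profile"))
  empty <- data.frame(repeat_index = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      group = integer(0))
  L <- profile$length
  n <- nchar(sequence)
  if (n < L) {
    warning("sequence shorter than profile; no hits", call. = FALSE)
    return(empty)
  }

  lo <- log2(sweep(profile$freq, 1, profile$background, "/"))
  chars <- str_chars(sequence)
  idx <- match(chars, AA_STANDARD)
  if (anyNA(idx)) {
    stop("sequence contains non-standard residues: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  # contrib[i, p] = log-odds of residue i under profile position p
  contrib <- lo[idx, , drop = FALSE]
  n_win <- n - L + 1L
  scores <- vapply(seq_len(n_win), function(s) {
    sum(contrib[cbind(s:(s + L - 1L), seq_len(L))])
  }, numeric(1))

  cand <- which(scores >= score_threshold_bits)
  if (!length(cand)) return(empty)
  cand <- cand[order(-scores[cand], cand)]
  taken <- rep(FALSE, n)
  starts <- integer(0)
  for (s in cand) {
    span <- s:(s + L - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      starts <- c(starts, s)
    }
  }
  starts <- sort(starts)
  hits <- data.frame(repeat_index = seq_along(starts), start = starts,
                     end = starts + L - 1L, score = scores[starts])
  gaps <- if (nrow(hits) > 1L) {
    hits$start[-1] - hits$end[-nrow(hits)] - 1L
  } else integer(0)
  hits$group <- cumsum(c(1L, as.integer(gaps < min_gap | gaps > max_gap)))
  hits
}
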