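# PWM motif scanning, motif comparison, Poaceae clade rules.

#' Construct a protein motif matrix
#'
#' @param probs Numeric matrix, width x 20 (columns named by [AA_STANDARD]
#'   in any order); each row must sum to 1.
#' @param motif_id Motif identifier (`"PS1"`..`"PS5"`, `"motif12"`, or any
#'   user label).
#' @param background Named background probabilities (default uniform).
#' @param width_range Allowed width band; default `c(6, 53)`, the width band
#'   used for auxiliary-motif discovery in protein MYB analyses.
#' @return Object of class `motif_matrix`: list with `id`, `mat`
#'   (width x 20, columns in [AA_STANDARD] order), `background`.
#' @export
motif_matrix <- function(probs, motif_id,
                         background = uniform_background(),
                         width_range = c(6L, 53L)) {
  stopifnot(is.matrix(probs), ncol(probs) == 20L,
            !is.null(colnames(probs)),
            setequal(colnames(probs), AA_STANDARD))
  probs <- probs[, AA_STANDARD, drop = FALSE]
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("motif rows must each sum to 1", call. = FALSE)
  }
  w <- nrow(probs)
  if (w < width_range[1] || w > width_range[2]) {
    stop("motif width ", w, " outside [", width_range[1], ", ",
         width_range[2], "]", call. = FALSE)
  }
  structure(list(id = motif_id, mat = probs,
                 background = background[AA_STANDARD]),
            class = "motif_matrix")
}

#' Motif from a consensus string
#'
#' Convenience constructor: probability `p_consensus` on the consensus
#' residue per position, the remainder spread over the other residues.
#'
#' @param consensus Residue string (width 6-53).
#' @param motif_id Motif identifier.
#' @param p_consensus Consensus probability per position (default 0.9).
#' @return A `motif_matrix`.
#' @export
motif_from_consensus <- function(consensus, motif_id, p_consensus = 0.9) {
  chars <- str_chars(consensus)
  stopifnot(all(chars %in% AA_STANDARD))
  mat <- matrix((1 - p_consensus) / 19, nrow = length(chars), ncol = 20,
                dimnames = list(NULL, AA_STANDARD))
  mat[cbind(seq_along(chars), match(chars, AA_STANDARD))] <- p_consensus
  motif_matrix(mat, motif_id)
}

#' Consensus string of a motif
#' @param motif A `motif_matrix`.
#' @return Character string of per-position argmax residues.
#' @export
motif_consensus <- function(motif) {
  paste(colnames(motif$mat)[max.col(motif$mat, ties.method = "first")],
        collapse = "")
}

#' Scan a sequence for a motif
#'
#' Log-odds PWM scan: the score at an offset is
#' `sum log2(p(residue) / background)` over the motif width; the best offset
#' is reported and the motif is called present when the best score reaches
#' `threshold_fraction` of the way from the minimum to the maximum
#' attainable score (0 accepts any sequence, 1 demands the perfect
#' consensus; log-odds scores can be negative, so the threshold is taken on
#' the attainable range rather than as a bare multiple of the maximum).
#'
#' @param sequence Protein sequence.
#' @param motif A `motif_matrix`.
#' @param threshold_fraction Presence threshold as a fraction of the
#'   attainable score range (default 0.8; calibrated so random sequences
#'   are called present in well under 5% of draws).
#' @return list with `present`, `score`, `max_score`, `offset` (1-based
#'   start of the best occurrence). If the sequence is shorter than the
#'   motif, `present = FALSE` with a warning and NA score/offset.
#' @export
scan_motif <- function(sequence, motif, threshold_fraction = 0.8) {
  stopifnot(inherits(motif, "motif_matrix"))
  w <- nrow(motif$mat)
  n <- nchar(sequence)
  if (n < w) {
    warning("sequence shorter than motif ", motif$id, "; called absent",
            call. = FALSE)
    return(list(present = FALSE, score = NA_real_, max_score = NA_real_,
                offset = NA_integer_))
  }
  lo <- log2(sweep(motif$mat, 2, motif$background, "/"))
  idx <- match(str_chars(sequence), AA_STANDARD)
  if (anyNA(idx)) stop("non-standard residues in sequence", call. = FALSE)
  scores <- vapply(seq_len(n - w + 1L), function(s) {
    sum(lo[cbind(seq_len(w), idx[s:(s + w - 1L)])])
  }, numeric(1))
  best <- which.max(scores)
  max_score <- sum(apply(lo, 1, max))
  min_score <- sum(apply(lo, 1, min))
  cutoff <- min_score + threshold_fraction * (max_score - min_score)
  list(present = scores[best] >= cutoff,
       score = scores[best], max_score = max_score,
       offset = as.integer(best))
}

#' Motif presence table for a sequence set
#'
#' @param sequences Named character vector of protein sequences.
#' @param motifs Named list of `motif_matrix` objects.
#' @param threshold_fraction Passed to [scan_motif()].
#' @return list with `present` (logical sequences x motifs matrix), `score`
#'   and `offset` matrices.
#' @export
scan_motif_set <- function(sequences, motifs, threshold_fraction = 0.8) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)),
            length(motifs) >= 1L, !is.null(names(motifs)))
  pres <- matrix(FALSE, length(sequences), length(motifs),
                 dimnames = list(names(sequences), names(motifs)))
  score <- offset <- matrix(NA_real_, length(sequences), length(motifs),
                            dimnames = dimnames(pres))
  for (i in seq_along(sequences)) {
    for (j in seq_along(motifs)) {
      hit <- scan_motif(sequences[[i]], motifs[[j]], threshold_fraction)
      pres[i, j] <- hit$present
      score[i, j] <- hit$score
      offset[i, j] <- hit$offset
    }
  }
  list(present = pres, score = score, offset = offset)
}

#' Classify a sequence into the Poaceae motif clades
#'
#' Applies the presence/absence rules, in priority order: PS1 with motif
#' 12-Jiang but not PS2 is Poaceae-specific group A; PS1 with PS2 but not
#' motif 12-Jiang is group B; PS3 marks the Poaceae-unique clade; PS4 and
#' PS5 together mark the Poaceae-basal clade; anything else is
#' unclassified. The rule sets are disjoint on real data, so the priority
#' only guards degenerate inputs.
#'
#' @param presence Named logical vector covering `PS1`, `PS2`, `PS3`, `PS4`,
#'   `PS5`, `motif12`.
#' @return One of `"poaceae_specific_A"`, `"poaceae_specific_B"`,
#'   `"poaceae_unique"`, `"poaceae_basal"`, `"unclassified"`.
#' @export
classify_poaceae_clade <- function(presence) {
  need <- c("PS1", "PS2", "PS3", "PS4", "PS5", "motif12")
  if (!all(need %in% names(presence))) {
    stop("presence row must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- as.logical(presence[need])
  names(p) <- need
  if (p["PS1"] && p["motif12"] && !p["PS2"]) return("poaceae_specific_A")
  if (p["PS1"] && p["PS2"] && !p["motif12"]) return("poaceae_specific_B")
  if (p["PS3"]) return("poaceae_unique")
  if (p["PS4"] && p["PS5"]) return("poaceae_basal")
  "unclassified"
}

#' Compare two motif matrices
#'
#' Mean column-wise Pearson correlation of the per-position probability
#' vectors over the best-scoring ungapped offset alignment: the shorter
#' motif is slid along the longer one, alignments with fewer overlapping
#' columns than `min_overlap` are skipped, and the offset maximizing the
#' mean correlation is reported. Symmetric by construction.
#'
#' @param m1,m2 `motif_matrix` objects.
#' @param min_overlap Minimum overlapping columns (default half the shorter
#'   motif's width).
#' @return Similarity in \[-1, 1\].
#' @export
compare_motifs <- function(m1, m2, min_overlap = NULL) {
  stopifnot(inherits(m1, "motif_matrix"), inherits(m2, "motif_matrix"))
  # canonical order: shorter motif slides along the longer
  if (nrow(m1$mat) > nrow(m2$mat)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  ws <- nrow(m1$mat); wl <- nrow(m2$mat)
  if (is.null(min_overlap)) min_overlap <- floor(ws / 2)
  if (min_overlap > ws) {
    stop("minimum overlap exceeds the shorter motif's width", call. = FALSE)
  }
  best <- -Inf
  for (d in seq(-(ws - min_overlap), wl - min_overlap)) {
    # shorter column i aligns with longer column i + d
    i <- seq_len(ws)
    j <- i + d
    keep <- j >= 1L & j <= wl
    if (sum(keep) < min_overlap) next
    cors <- vapply(which(keep), function(k) {
      a <- m1$mat[k, ]; b <- m2$mat[j[k], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    val <- mean(cors, na.rm = TRUE)
    if (!is.nan(val) && val > best) best <- val
  }
  if (!is.finite(best)) {
    stop("no alignment with sufficient overlap", call. = FALSE)
  }
  best
}

#' Presence/absence correlation between motifs
#'
#' Pearson (phi) correlation of the 0/1 presence columns of a presence
#' table; the diagonal is 1 and constant columns give NA.
#'
#' @param present Logical sequences x motifs matrix (e.g.
#'   `scan_motif_set()$present`), >= 2 sequences.
#' @return Motifs x motifs correlation matrix.
#' @export
presence_correlation <- function(present) {
  stopifnot(is.matrix(present), nrow(present) >= 2L)
  x <- present * 1
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  out <- suppressWarnings(stats::cor(x))
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out) <- 1
  out
}

#' Synthetic PS motif set
#'
#' Six synthetic stand-in motif matrices named `PS1`..`PS5` and `motif12`,
#' built from seeded random consensus strings (PS2 is a perturbed copy of
#' PS1, mirroring the fact that the two Poaceae-specific motifs are related
#' variants). These are demonstration/testing stand-ins, not the published
#' motif models.
#'
#' @param seed Integer seed.
#' @param width Consensus width (default 12).
#' @param p_consensus Consensus probability (default 0.9).
#' @return Named list of `motif_matrix` objects.
#' @export
synthetic_ps_motifs <- function(seed = 1L, width = 12L, p_consensus = 0.9) {
  with_seed(seed, {
    ids <- c("PS1", "PS3", "PS4", "PS5", "motif12")
    cons <- vapply(ids, function(i) random_residues(width), character(1))
    # PS2: PS1 consensus with a third of its positions substituted
    ps1 <- str_chars(cons[["PS1"]])
    swap <- sample_safe(seq_along(ps1), ceiling(width / 3))
    for (i in swap) ps1[i] <- sample_safe(setdiff(AA_STANDARD, ps1[i]), 1L)
    cons <- c(cons, PS2 = paste(ps1, collapse = ""))
    out <- lapply(names(cons), function(id) {
      motif_from_consensus(cons[[id]], id, p_consensus)
    })
    stats::setNames(out, names(cons))[c("PS1", "PS2", "PS3", "PS4", "PS5",
                                        "motif12")]
  })
}

#' Simulate motif-bearing sequences
#'
#' Embeds motif consensus strings into random background sequences according
#' to a presence plan, at seeded non-overlapping offsets.
#'
#' @param motifs Named list of `motif_matrix` objects.
#' @param plan Logical matrix (sequences x motifs; column names must match
#'   `names(motifs)`).
#' @param length Background sequence length (default 200).
#' @param seed Integer seed.
#' @return list with `sequences` (named character) and `truth` (the plan).
#' @export
simulate_motif_sequences <- function(motifs, plan, length = 200L, seed = 1L) {
  stopifnot(is.matrix(plan), setequal(colnames(plan), names(motifs)))
  total_w <- sum(vapply(motifs, function(m) nrow(m$mat), integer(1)))
  if (length < 2L * total_w) {
    stop("`length` too short to embed all motifs without overlap",
         call. = FALSE)
  }
  with_seed(seed, {
    ids <- rownames(plan)
    if (is.null(ids)) ids <- sprintf("seq_%03d", seq_len(nrow(plan)))
    seqs <- vapply(seq_len(nrow(plan)), function(i) {
      s <- str_chars(random_residues(length))
      pos <- 1L
      for (m in names(motifs)) {
        if (plan[i, m]) {
          cons <- str_chars(motif_consensus(motifs[[m]]))
          gap <- sample(3:10, 1L)
          s[(pos + gap):(pos + gap + length(cons) - 1L)] <- cons
          pos <- pos + gap + length(cons)
        }
      }
      paste(s, collapse = "")
    }, character(1))
    list(sequences = stats::setNames(seqs, ids), truth = plan)
  })
}
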