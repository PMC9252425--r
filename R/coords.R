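# Protein-span -> CDS -> genomic coordinate mapping across exon structures.

#' Map a protein span to genomic intervals
#'
#' Protein positions `[a, b]` map to CDS nucleotides `[3a - 2, 3b]`, which
#' are then projected onto the genome through the exon structure of the
#' representative transcript, splitting at exon boundaries. On the minus
#' strand the CDS walks the exons from the highest genomic coordinate
#' downward (reverse-complement orientation). Output intervals are 1-based
#' inclusive and sorted by genomic start; their lengths always sum to
#' `3 * (b - a + 1)`.
#'
#' @param span Integer vector `c(a, b)`, 1-based inclusive protein
#'   coordinates (`a <= b`).
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic, non-overlapping, sorted ascending).
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `start`, `end`, sorted by `start`.
#' @export
map_domain_to_genome <- function(span, exons, strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(length(span) == 2L, span[1] >= 1L, span[2] >= span[1],
            all(c("start", "end") %in% names(exons)), nrow(exons) >= 1L)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exon intervals overlap", call. = FALSE)
  }
  exon_len <- exons$end - exons$start + 1L
  cds_len <- sum(exon_len)
  q1 <- 3L * span[1] - 2L
  q2 <- 3L * span[2]
  if (q2 > cds_len) {
    stop("protein span extends beyond the CDS (", q2, " > ", cds_len, " nt)",
         call. = FALSE)
  }

  # exon order in transcription direction
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  out <- list()
  cum <- 0L
  for (i in ord) {
    lo <- cum + 1L
    hi <- cum + exon_len[i]
    ov1 <- max(q1, lo)
    ov2 <- min(q2, hi)
    if (ov1 <= ov2) {
      if (strand == "+") {
        g1 <- exons$start[i] + (ov1 - lo)
        g2 <- exons$start[i] + (ov2 - lo)
      } else {
        g1 <- exons$end[i] - (ov2 - lo)
        g2 <- exons$end[i] - (ov1 - lo)
      }
      out[[length(out) + 1L]] <- c(g1, g2)
    }
    cum <- hi
  }
  res <- do.call(rbind, out)
  res <- data.frame(start = res[, 1], end = res[, 2])
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
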