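# Expression-matrix filters, display summaries, stand-in differential test.

#' Filter a TPM matrix to expressed genes
#'
#' Keeps a gene iff its TPM strictly exceeds the threshold in at least one
#' sample. Idempotent.
#'
#' @param matrix Numeric genes x samples TPM matrix.
#' @param tpm_threshold Threshold (default 5; strict `>`).
#' @return The row-subset matrix.
#' @export
filter_expressed <- function(matrix, tpm_threshold = 5) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  keep <- apply(matrix, 1, max) > tpm_threshold
  matrix[keep, , drop = FALSE]
}

#' Retain study condition groups with enough biological replicates
#'
#' The replicate rule is per (study, condition) group: a group is retained
#' iff it has at least `min_reps` replicates; a study can contribute one arm
#' and lose another.
#'
#' @param metadata data.frame with columns `sample`, `study`, `condition`.
#' @param min_reps Minimum biological replicates (default 3).
#' @return The retained metadata rows.
#' @export
filter_studies_by_replicates <- function(metadata, min_reps = 3L) {
  stopifnot(all(c("sample", "study", "condition") %in% names(metadata)))
  key <- paste(metadata$study, metadata$condition, sep = "\r")
  counts <- table(key)
  metadata[counts[key] >= min_reps, , drop = FALSE]
}

#' Per-condition display summary: log2(TPM + 1) of replicate means
#'
#' Replicate TPMs are averaged first, then log-transformed — the order
#' matters and matches the standard heat-map convention
#' `log2(mean(TPM) + 1)`.
#'
#' @param matrix Genes x samples TPM matrix.
#' @param conditions Character/factor of length `ncol(matrix)` assigning
#'   samples to condition groups.
#' @return Genes x conditions matrix of `log2(mean TPM + 1)`.
#' @export
summarize_for_display <- function(matrix, conditions) {
  stopifnot(is.matrix(matrix), length(conditions) == ncol(matrix))
  groups <- unique(as.character(conditions))
  out <- vapply(groups, function(g) {
    log2(rowMeans(matrix[, conditions == g, drop = FALSE]) + 1)
  }, numeric(nrow(matrix)))
  dimnames(out) <- list(rownames(matrix), groups)
  out
}

#' Stand-in differential expression test
#'
#' A deliberately simple two-group test (documented stand-in, not a
#' dispersion-shrinkage method; a DESeq2 result table can be swapped in
#' wherever this output is consumed): median-of-ratios library-size
#' normalization, Welch t test on `log2(normalized count + 1)`,
#' Benjamini-Hochberg adjustment. A gene is flagged differentially
#' expressed iff `|log2FC| > log2(fc_threshold)` (strict) and adjusted
#' p < alpha.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor/character of length `ncol(counts)` with exactly two
#'   levels; log2FC is second level vs first.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha FDR cut-off (default 0.05).
#' @param normalize Apply median-of-ratios size-factor normalization
#'   (default TRUE).
#' @return data.frame `gene`, `log2fc`, `p_value`, `padj`, `de`.
#' @export
differential_expression <- function(counts, groups, fc_threshold = 2,
                                    alpha = 0.05, normalize = TRUE) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(tapply(colSums(counts), groups, sum) == 0)) {
    stop("a group has zero total counts", call. = FALSE)
  }
  if (min(table(groups)) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }

  norm <- if (normalize) {
    sweep(counts, 2, size_factors(counts), "/")
  } else counts

  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  logn <- log2(norm + 1)
  stats_g <- function(gene_row) {
    a <- logn[gene_row, g1]; b <- logn[gene_row, g2]
    if (stats::var(a) < 1e-12 && stats::var(b) < 1e-12) {
      return(if (abs(mean(b) - mean(a)) < 1e-12) 1 else 0)
    }
    stats::t.test(b, a)$p.value
  }
  p <- vapply(seq_len(nrow(counts)), stats_g, numeric(1))
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  log2fc <- ifelse(m1 == 0 & m2 == 0, 0, log2(m2 / m1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = if (is.null(rownames(counts))) {
               sprintf("g%04d", seq_len(nrow(counts)))
             } else rownames(counts),
             log2fc = log2fc, p_value = p, padj = padj,
             de = abs(log2fc) > log2(fc_threshold) & padj < alpha,
             stringsAsFactors = FALSE)
}

# DESeq-style median-of-ratios size factors; falls back to library-size
# ratios when no gene is positive in all samples
size_factors <- function(counts) {
  geo <- exp(rowMeans(log(counts)))
  usable <- is.finite(geo) & geo > 0
  if (!any(usable)) {
    libs <- colSums(counts)
    return(libs / exp(mean(log(libs))))
  }
  apply(counts[usable, , drop = FALSE], 2, function(col) {
    stats::median(col / geo[usable])
  })
}
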