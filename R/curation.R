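# Representative-isoform selection, curation filters, chromosome-ordered naming.

#' Select a gene's representative isoform
#'
#' Retains the longest-CDS isoform if its domain annotation passes the
#' integrity filter; otherwise falls through to the next-longest passing
#' isoform. If no isoform passes, the gene keeps its longest isoform and
#' inherits that isoform's MYB class (possibly MYB-related or none).
#' Equal-length isoforms are ordered by mRNA id.
#'
#' @param isoforms data.frame with columns `mrna_id`, `cds_length`.
#' @param annotations data.frame with columns `mrna_id`, `integrity_pass`
#'   (logical), `myb_class`.
#' @return list with `mrna_id`, `myb_class`, `integrity_pass`,
#'   `fallback_rank` (1 = longest, 2 = second longest, ...).
#' @export
select_representative <- function(isoforms, annotations) {
  stopifnot(nrow(isoforms) >= 1L,
            all(c("mrna_id", "cds_length") %in% names(isoforms)),
            all(c("mrna_id", "integrity_pass", "myb_class") %in%
                  names(annotations)))
  ord <- order(-isoforms$cds_length, isoforms$mrna_id)
  ranked <- isoforms$mrna_id[ord]
  ann <- annotations[match(ranked, annotations$mrna_id), ]
  if (anyNA(ann$mrna_id)) {
    stop("missing domain annotation for isoform(s): ",
         paste(ranked[is.na(ann$mrna_id)], collapse = ", "), call. = FALSE)
  }
  pass_idx <- which(ann$integrity_pass)
  pick <- if (length(pass_idx)) pass_idx[1] else 1L
  list(mrna_id = ranked[pick],
       myb_class = ann$myb_class[pick],
       integrity_pass = isTRUE(ann$integrity_pass[pick]),
       fallback_rank = as.integer(pick))
}

#' Ambiguous-base / low-expression removal rule
#'
#' A gene is dropped only when its CDS contains ambiguous bases (N) *and*
#' its expression never reaches the TPM floor in any sample — both
#' conditions are required; either one alone keeps the gene.
#'
#' @param cds_sequence CDS nucleotide sequence over `A`, `C`, `G`, `T`, `N`.
#' @param max_tpm_across_samples Maximum TPM over all samples.
#' @param tpm_floor Expression floor (default 1 TPM).
#' @return `"keep"` or `"drop"`.
#' @export
ambiguity_expression_filter <- function(cds_sequence, max_tpm_across_samples,
                                        tpm_floor = 1) {
  chars <- unique(str_chars(toupper(cds_sequence)))
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("CDS contains non-nucleotide symbols: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  has_n <- grepl("N", toupper(cds_sequence), fixed = TRUE)
  if (has_n && max_tpm_across_samples < tpm_floor) "drop" else "keep"
}

#' Assign chromosome-ordered family names
#'
#' Names genes `prefix + chromosome label + zero-padded global ordinal`
#' (e.g. `TdMYB1A001` ... `TdMYBU233`): genomes ordered A, then B, then the
#' unanchored set U; chromosomes 1-7 within a genome; genes ordered by start
#' coordinate within a chromosome (U genes, whose coordinates are not
#' assumed reliable, are ordered by gene id). The ordinal is global and the
#' assignment is invariant to the input row order.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`
#'   (`1A`..`7A`, `1B`..`7B` or `U`) and `start`.
#' @param prefix Name prefix (default `"TdMYB"`).
#' @return data.frame `gene_id`, `chromosome`, `name`, sorted in naming
#'   order.
#' @export
assign_names <- function(genes, prefix = "TdMYB") {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(genes)))
  chrom <- as.character(genes$chromosome)
  if (!all(chrom %in% TD_CHROMOSOMES)) {
    stop("unknown chromosome label(s): ",
         paste(setdiff(chrom, TD_CHROMOSOMES), collapse = ", "),
         call. = FALSE)
  }
  letter <- substr(chrom, nchar(chrom), nchar(chrom))
  digit <- suppressWarnings(as.integer(substr(chrom, 1L, 1L)))
  digit[letter == "U"] <- 99L
  start_key <- ifelse(letter == "U", 0L, genes$start)
  ord <- order(match(letter, c("A", "B", "U")), digit, start_key,
               genes$gene_id)
  out <- data.frame(gene_id = genes$gene_id[ord],
                    chromosome = chrom[ord],
                    stringsAsFactors = FALSE)
  pad <- max(3L, nchar(nrow(out)))
  out$name <- sprintf("%s%s%0*d", prefix,
                      ifelse(out$chromosome == "U", "U", out$chromosome),
                      pad, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Assemble a curated gene-family table
#'
#' Joins representative-isoform selection, naming, intron counts and protein
#' properties into one per-gene table (the shape of a curated family
#' supplement: one row per gene with its representative transcript, class,
#' assigned name, structure and physico-chemical properties).
#'
#' @param genes data.frame `gene_id`, `chromosome`, `strand`, `start`.
#' @param isoforms data.frame `gene_id`, `mrna_id`, `cds_length`,
#'   `exon_count` (optional).
#' @param annotations data.frame `mrna_id`, `integrity_pass`, `myb_class`.
#' @param proteins Named character vector of representative protein
#'   sequences (names = `mrna_id`); optional, enables pI/Mw columns.
#' @param prefix Passed to [assign_names()].
#' @return data.frame, one row per gene, naming order: `gene_id`, `name`,
#'   `chromosome`, `strand`, `representative_mrna`, `myb_class`,
#'   `intron_count`, `pi`, `mw_da`.
#' @export
curate_family <- function(genes, isoforms, annotations, proteins = NULL,
                          prefix = "TdMYB") {
  named <- assign_names(genes, prefix = prefix)
  rows <- lapply(named$gene_id, function(g) {
    iso <- isoforms[isoforms$gene_id == g, , drop = FALSE]
    rep_sel <- select_representative(iso, annotations)
    exon_count <- if ("exon_count" %in% names(iso)) {
      iso$exon_count[iso$mrna_id == rep_sel$mrna_id]
    } else NA_integer_
    gi <- genes[genes$gene_id == g, ]
    pimw <- if (!is.null(proteins) && rep_sel$mrna_id %in% names(proteins)) {
      compute_pi_mw(proteins[[rep_sel$mrna_id]])
    } else list(pi = NA_real_, mw_da = NA_real_)
    data.frame(gene_id = g,
               name = named$name[named$gene_id == g],
               chromosome = gi$chromosome, strand = gi$strand,
               representative_mrna = rep_sel$mrna_id,
               myb_class = rep_sel$myb_class,
               intron_count = if (is.na(exon_count)) NA_integer_
                              else as.integer(exon_count) - 1L,
               pi = pimw$pi, mw_da = pimw$mw_da,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
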