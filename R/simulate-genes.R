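# Synthetic multi-isoform gene models on named wheat-style chromosomes.

TD_CHROMOSOMES <- c(paste0(1:7, "A"), paste0(1:7, "B"), "U")

#' Simulate multi-isoform gene models
#'
#' Generates gene/mRNA/exon/CDS features on named chromosomes (tetraploid
#' wheat style: 1A..7A, 1B..7B plus the unanchored scaffold set "U"), with a
#' truth table marking, for each gene, the representative isoform expected
#' under the longest / second-longest selection rule. For a seeded fraction
#' of multi-isoform genes the longest isoform is flagged as carrying an
#' incomplete MYB domain, so the second-longest passing isoform is the
#' correct representative.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chromosomes Chromosome label pool; default the 14 + U wheat labels.
#' @param isoforms_per_gene Maximum isoforms per gene (per-gene count drawn
#'   uniformly from 1..max), default 3.
#' @param frac_incomplete_longest Fraction of multi-isoform genes whose
#'   longest isoform lacks a complete domain, default 0.2.
#' @param seed Integer seed.
#' @return A list with `gff` (data.frame of gene/mRNA/exon/CDS rows with
#'   1-based inclusive coordinates: `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`), `genes` (truth: `gene_id`, `chromosome`,
#'   `strand`, `start`, `representative_mrna`, `expected_name`) sorted in
#'   naming order, and `isoforms` (truth: `gene_id`, `mrna_id`,
#'   `cds_length`, `domain_complete`).
#' @export
simulate_gene_models <- function(n_genes,
                                 chromosomes = TD_CHROMOSOMES,
                                 isoforms_per_gene = 3L,
                                 frac_incomplete_longest = 0.2,
                                 seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  isoforms_per_gene <- check_count(isoforms_per_gene, "isoforms_per_gene",
                                   min = 1L)
  check_probability(frac_incomplete_longest, "frac_incomplete_longest")
  stopifnot(all(chromosomes %in% TD_CHROMOSOMES))

  with_seed(seed, {
    chrom <- sample_safe(chromosomes, n_genes, replace = TRUE)
    start <- sample.int(5e7, n_genes)
    strand <- sample_safe(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("TRITD_G%04d", seq_len(n_genes))

    gff_rows <- list()
    iso_rows <- list()
    rep_mrna <- character(n_genes)

    for (g in seq_len(n_genes)) {
      n_iso <- sample.int(isoforms_per_gene, 1L)
      # distinct CDS lengths (multiples of 3) so the length order is strict
      cds_len <- 3L * sample(seq(100L, 400L), n_iso)
      ord <- order(-cds_len)
      longest_incomplete <- n_iso > 1L &&
        stats::runif(1) < frac_incomplete_longest
      complete <- rep(TRUE, n_iso)
      if (longest_incomplete) complete[ord[1]] <- FALSE
      # expected representative: longest complete isoform, else longest
      passing <- ord[complete[ord]]
      rep_idx <- if (length(passing)) passing[1] else ord[1]

      gene_end <- 0L
      for (k in seq_len(n_iso)) {
        mrna_id <- sprintf("%s.%d", gene_id[g], k)
        n_exons <- sample.int(5L, 1L)
        # split the CDS length over exons in multiples of 3
        cuts <- sort(sample_safe(seq_len(cds_len[k] / 3L - 1L),
                                 n_exons - 1L))
        exon_len <- diff(c(0L, cuts, cds_len[k] / 3L)) * 3L
        intron_len <- if (n_exons > 1L) {
          sample(50:500, n_exons - 1L, replace = TRUE)
        } else integer(0)
        ex_start <- start[g] + cumsum(c(0L, exon_len[-n_exons] +
                                          intron_len))
        ex_end <- ex_start + exon_len - 1L
        gene_end <- max(gene_end, ex_end[n_exons])

        gff_rows[[length(gff_rows) + 1L]] <- data.frame(
          seqid = chrom[g],
          type = c("mRNA", rep(c("exon", "CDS"), each = n_exons)),
          start = c(ex_start[1], ex_start, ex_start),
          end = c(ex_end[n_exons], ex_end, ex_end),
          strand = strand[g],
          ID = c(mrna_id,
                 sprintf("%s.exon%d", mrna_id, seq_len(n_exons)),
                 sprintf("%s.cds%d", mrna_id, seq_len(n_exons))),
          Parent = c(gene_id[g], rep(mrna_id, 2L * n_exons)),
          stringsAsFactors = FALSE)
        iso_rows[[length(iso_rows) + 1L]] <- data.frame(
          gene_id = gene_id[g], mrna_id = mrna_id,
          cds_length = cds_len[k], domain_complete = complete[k],
          stringsAsFactors = FALSE)
      }
      rep_mrna[g] <- sprintf("%s.%d", gene_id[g], rep_idx)
      gff_rows[[length(gff_rows) + 1L]] <- data.frame(
        seqid = chrom[g], type = "gene", start = start[g], end = gene_end,
        strand = strand[g], ID = gene_id[g], Parent = NA_character_,
        stringsAsFactors = FALSE)
    }

    genes <- data.frame(gene_id = gene_id, chromosome = chrom,
                        strand = strand, start = start,
                        representative_mrna = rep_mrna,
                        stringsAsFactors = FALSE)
    # generator's own naming order (independent of assign_names): genome
    # letter A < B < U, chromosome digit 1..7, start coordinate, gene id
    letter <- substr(chrom, nchar(chrom), nchar(chrom))
    digit <- suppressWarnings(as.integer(substr(chrom, 1L, 1L)))
    digit[letter == "U"] <- 99L
    ord <- order(match(letter, c("A", "B", "U")), digit, start, gene_id)
    genes <- genes[ord, ]
    chrom_part <- ifelse(genes$chromosome == "U", "U", genes$chromosome)
    genes$expected_name <- sprintf("TdMYB%s%03d", chrom_part,
                                   seq_len(nrow(genes)))
    rownames(genes) <- NULL

    gff <- do.call(rbind, gff_rows)
    gff <- gff[order(gff$seqid, gff$start,
                     match(gff$type, c("gene", "mRNA", "exon", "CDS"))), ]
    rownames(gff) <- NULL
    isoforms <- do.call(rbind, iso_rows)
    rownames(isoforms) <- NULL
    list(gff = gff, genes = genes, isoforms = isoforms)
  })
}
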