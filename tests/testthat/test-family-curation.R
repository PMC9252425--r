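# Representative selection, curation filters, naming, pI/Mw, coordinates.

test_that("representative selection follows the longest/second-longest rule", {
  iso <- data.frame(mrna_id = c("m1", "m2"), cds_length = c(900, 600))
  ann_pass <- data.frame(mrna_id = c("m1", "m2"),
                         integrity_pass = c(TRUE, TRUE),
                         myb_class = "R2R3")
  expect_equal(select_representative(iso, ann_pass)$mrna_id, "m1")

  ann_fail1 <- data.frame(mrna_id = c("m1", "m2"),
                          integrity_pass = c(FALSE, TRUE),
                          myb_class = c("MYB_related", "R2R3"))
  sel <- select_representative(iso, ann_fail1)
  expect_equal(sel$mrna_id, "m2")
  expect_equal(sel$fallback_rank, 2L)

  # no isoform passes: the longest stays, class inherited from it
  ann_none <- data.frame(mrna_id = c("m1", "m2"),
                         integrity_pass = c(FALSE, FALSE),
                         myb_class = c("MYB_related", "none"))
  sel_none <- select_representative(iso, ann_none)
  expect_equal(sel_none$mrna_id, "m1")
  expect_equal(sel_none$myb_class, "MYB_related")
  expect_false(sel_none$integrity_pass)

  # equal lengths: lexicographically smaller mRNA id wins
  iso_tie <- data.frame(mrna_id = c("mB", "mA"), cds_length = c(600, 600))
  ann_tie <- data.frame(mrna_id = c("mA", "mB"),
                        integrity_pass = TRUE, myb_class = "R2R3")
  expect_equal(select_representative(iso_tie, ann_tie)$mrna_id, "mA")
})

test_that("selection matches the planted representative on simulated models", {
  gm <- simulate_gene_models(80, isoforms_per_gene = 3,
                             frac_incomplete_longest = 0.3, seed = 21)
  ann <- data.frame(mrna_id = gm$isoforms$mrna_id,
                    integrity_pass = gm$isoforms$domain_complete,
                    myb_class = ifelse(gm$isoforms$domain_complete,
                                       "R2R3", "MYB_related"))
  for (g in gm$genes$gene_id) {
    iso <- gm$isoforms[gm$isoforms$gene_id == g, ]
    expect_equal(select_representative(iso, ann)$mrna_id,
                 gm$genes$representative_mrna[gm$genes$gene_id == g])
  }
})

test_that("the N/low-TPM removal rule is a strict conjunction", {
  expect_equal(ambiguity_expression_filter("ATGNNA", 0.4), "drop")
  expect_equal(ambiguity_expression_filter("ATGNNA", 7), "keep")
  expect_equal(ambiguity_expression_filter("ATGGCA", 0), "keep")
  expect_error(ambiguity_expression_filter("ATGX", 1), "X")
})

test_that("naming starts at 1A001, ends with U, and is order-invariant", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    chromosome = c("1A", "3B", "1A", "U", "7A"),
    start = c(500, 100, 100, 10, 999))
  named <- assign_names(genes)
  expect_equal(named$name[named$gene_id == "g3"], "TdMYB1A001")
  expect_equal(named$name[named$gene_id == "g1"], "TdMYB1A002")
  expect_equal(named$name[named$gene_id == "g5"], "TdMYB7A003")
  expect_equal(named$name[named$gene_id == "g2"], "TdMYB3B004")
  expect_equal(named$name[named$gene_id == "g4"], "TdMYBU005")

  # permuting input rows changes nothing; names are a bijection
  for (perm_seed in 1:3) {
    shuffled <- withr::with_seed(perm_seed, genes[sample(nrow(genes)), ])
    renamed <- assign_names(shuffled)
    expect_identical(renamed, named)
    expect_equal(anyDuplicated(renamed$name), 0)
  }
})

test_that("233 simulated genes are named through to the last U gene", {
  gm <- simulate_gene_models(233, seed = 31)
  named <- assign_names(gm$genes)
  expect_identical(named$name, gm$genes$expected_name)
  expect_equal(named$name[1], paste0("TdMYB", named$chromosome[1], "001"))
  expect_equal(substr(named$name[233], nchar(named$name[233]) - 2, 999), "233")
})

test_that("molecular weight matches the hand-summed mass table", {
  expect_equal(compute_pi_mw("G")$mw_da, 57.0519 + 18.0153, tolerance = 1e-9)
  expect_equal(compute_pi_mw("GG")$mw_da, 2 * 57.0519 + 18.0153,
               tolerance = 1e-9)
  expect_error(compute_pi_mw("GZ"), "Z")
})

test_that("appending an acidic residue strictly lowers the pI", {
  base <- "MKKLLRG"
  expect_lt(compute_pi_mw(paste0(base, "D"))$pi, compute_pi_mw(base)$pi)
})

test_that("pI agrees with a brute-force fine-grid charge scan", {
  grid <- seq(0, 14, by = 1e-4)
  seqs <- withr::with_seed(77, vapply(1:100, function(i) {
    paste(sample(AA_STANDARD, sample(30:120, 1), replace = TRUE),
          collapse = "")
  }, character(1)))
  for (s in seqs) {
    q <- protein_net_charge(s, grid)
    oracle <- grid[which.min(abs(q))]
    expect_lt(abs(compute_pi_mw(s)$pi - oracle), 1e-3)
  }
})

test_that("single-exon plus-strand spans map to one contiguous interval", {
  exons <- data.frame(start = 1001, end = 2000)
  got <- map_domain_to_genome(c(1, 105), exons, "+")
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 1001)
  expect_equal(got$end, 1315)
})

test_that("a span straddling one intron splits into length-conserving pieces", {
  exons <- data.frame(start = c(1001, 2001), end = c(1150, 2300))
  got <- map_domain_to_genome(c(40, 80), exons, "+")
  expect_equal(nrow(got), 2)
  expect_equal(sum(got$end - got$start + 1), 3 * (80 - 40 + 1))
})

test_that("interval lengths always sum to 3x the protein span", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n_ex <- sample(1:5, 1)
      len <- sample(30:300, n_ex) * 3
      gaps <- sample(50:500, n_ex, replace = TRUE)
      starts <- 1000 + cumsum(gaps) + cumsum(c(0, head(len, -1)))
      exons <- data.frame(start = starts, end = starts + len - 1)
      aa_total <- sum(len) / 3
      a <- sample(seq_len(aa_total - 1), 1)
      b <- sample(a:aa_total, 1)
      strand <- sample(c("+", "-"), 1)
      got <- map_domain_to_genome(c(a, b), exons, strand)
      expect_equal(sum(got$end - got$start + 1), 3 * (b - a + 1))
      expect_true(all(diff(got$start) > 0))
    }
  })
})

test_that("minus-strand mapping round-trips through translation", {
  # synthetic two-exon minus-strand gene with a known protein
  protein <- "MKWVD"
  cds <- as.character(Biostrings::DNAString(
    "ATGAAATGGGTTGAT"))  # encodes MKWVD
  # genome layout: exon2 (first in transcription) at 2001..2008,
  # exon1 at 1001..1007; minus strand, so genomic = revcomp of CDS pieces
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  genome <- list(`1001` = rc(substr(cds, 9, 15)),
                 `2001` = rc(substr(cds, 1, 8)))
  exons <- data.frame(start = c(1001, 2001), end = c(1007, 2008))
  got <- map_domain_to_genome(c(1, 5), exons, "-")
  # stitch extracted genomic pieces in descending genomic order, revcomp
  extract <- function(iv) {
    block_start <- if (iv[1] >= 2001) 2001 else 1001
    s <- genome[[as.character(block_start)]]
    substr(s, iv[1] - block_start + 1, iv[2] - block_start + 1)
  }
  pieces <- apply(got[order(-got$start), ], 1,
                  function(r) extract(c(r[["start"]], r[["end"]])))
  recovered <- paste(vapply(pieces, rc, character(1)), collapse = "")
  expect_equal(recovered, as.character(cds))
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(recovered))), protein)
})

test_that("spans beyond the CDS are coordinate errors", {
  exons <- data.frame(start = 1, end = 30)
  expect_error(map_domain_to_genome(c(1, 11), exons, "+"), "beyond")
})

test_that("curate_family assembles one named row per gene", {
  gm <- simulate_gene_models(20, seed = 41)
  gm$isoforms$exon_count <- 3L
  ann <- data.frame(mrna_id = gm$isoforms$mrna_id,
                    integrity_pass = gm$isoforms$domain_complete,
                    myb_class = ifelse(gm$isoforms$domain_complete,
                                       "R2R3", "MYB_related"))
  fam <- curate_family(gm$genes, gm$isoforms, ann)
  expect_equal(nrow(fam), 20)
  expect_equal(anyDuplicated(fam$name), 0)
  expect_equal(fam$representative_mrna,
               gm$genes$representative_mrna[match(fam$gene_id,
                                                  gm$genes$gene_id)])
  expect_true(all(fam$intron_count == 2))
})
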