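# qPCR quantification, expression filters, display summary, stand-in DE.

make_ct <- function(gene_ct_ctrl, gene_ct_str, ref_ct = 20, gene = "g1",
                    tissue = "root", time_h = 6) {
  stopifnot(length(gene_ct_ctrl) == length(gene_ct_str))
  n <- length(gene_ct_ctrl)
  rbind(
    data.frame(gene = gene, tissue = tissue, condition = "control",
               time_h = time_h, bio_rep = seq_len(n), tech_rep = 1,
               ct = gene_ct_ctrl),
    data.frame(gene = gene, tissue = tissue, condition = "stressed",
               time_h = time_h, bio_rep = seq_len(n), tech_rep = 1,
               ct = gene_ct_str),
    data.frame(gene = "ref", tissue = tissue,
               condition = rep(c("control", "stressed"), each = n),
               time_h = time_h, bio_rep = seq_len(n), tech_rep = 1,
               ct = ref_ct))
}

test_that("2^-ddCt closed forms: null gives 1, one cycle gives 2", {
  tab_null <- make_ct(c(26, 26.2, 25.8), c(26, 26.2, 25.8))
  res <- delta_delta_ct(tab_null, "g1", "ref")
  expect_equal(res$rel, 1, tolerance = 1e-12)

  tab_one <- make_ct(c(26, 26, 26) + c(-.1, 0, .1),
                     c(25, 25, 25) + c(-.1, 0, .1))
  expect_equal(delta_delta_ct(tab_one, "g1", "ref")$rel, 2,
               tolerance = 1e-12)
})

test_that("technical replicates are averaged within biological replicates", {
  tab <- rbind(
    data.frame(gene = "g1", tissue = "root", condition = "control",
               time_h = 2, bio_rep = rep(1:2, each = 3), tech_rep = 1:3,
               ct = c(26.1, 26.0, 25.9, 26.3, 26.2, 26.1)),
    data.frame(gene = "g1", tissue = "root", condition = "stressed",
               time_h = 2, bio_rep = rep(1:2, each = 3), tech_rep = 1:3,
               ct = c(24.1, 24.0, 23.9, 24.3, 24.2, 24.1)),
    data.frame(gene = "ref", tissue = "root",
               condition = rep(c("control", "stressed"), each = 6),
               time_h = 2, bio_rep = rep(rep(1:2, each = 3), 2),
               tech_rep = 1:3, ct = 20))
  expect_equal(delta_delta_ct(tab, "g1", "ref")$rel, 4, tolerance = 1e-12)
})

test_that("planted folds are recovered within 10% under realistic Ct noise", {
  rels <- vapply(1:20, function(seed) {
    qp <- simulate_qpcr(
      data.frame(gene = "g", tissue = "root", time_h = 6, fold = 7.8),
      ct_noise_sd = 0.1, seed = seed)
    delta_delta_ct(qp$ct, "g", "RLIa")$rel
  }, numeric(1))
  expect_true(all(abs(rels - 7.8) / 7.8 < 0.10))
})

test_that("ddCt is invariant to a constant shift of every Ct in a block", {
  tab <- make_ct(c(26.3, 26.1, 25.9), c(24.8, 25.0, 24.6))
  shifted <- tab
  shifted$ct <- shifted$ct + 3.7
  expect_equal(delta_delta_ct(tab, "g1", "ref")[c("rel", "p_value")],
               delta_delta_ct(shifted, "g1", "ref")[c("rel", "p_value")],
               tolerance = 1e-12)
})

test_that("undetected conditions set the quantification status", {
  tab <- make_ct(c(NA, NA, NA), c(24, 24.2, 23.8))
  res <- delta_delta_ct(tab, "g1", "ref")
  expect_equal(res$status, "not_quantifiable")
  expect_true(is.na(res$rel))

  tab2 <- make_ct(c(NA, NA, NA), c(NA, NA, NA))
  expect_equal(delta_delta_ct(tab2, "g1", "ref")$status, "not_expressed")
})

test_that("single biological replicates warn and give no p-value", {
  tab <- make_ct(26, 24)
  expect_warning(res <- delta_delta_ct(tab, "g1", "ref"), "replicates")
  expect_true(is.na(res$p_value))
  expect_equal(res$tier, "ns")
  expect_equal(res$rel, 4, tolerance = 1e-12)
})

test_that("null qPCR tables trip the 0.05 tier at the nominal rate", {
  hits <- vapply(1:1000, function(seed) {
    qp <- simulate_qpcr(
      data.frame(gene = "g", tissue = "root", time_h = 2, fold = 1),
      ct_noise_sd = 0.2, seed = seed)
    delta_delta_ct(qp$ct, "g", "RLIa")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("TPM filter is strict at the boundary and idempotent", {
  m <- rbind(at5 = c(5, 5), above = c(0, 5.01), low = c(1, 2))
  got <- filter_expressed(m, 5)
  expect_equal(rownames(got), "above")
  expect_identical(filter_expressed(got, 5), got)
})

test_that("replicate filtering works per study arm", {
  md <- data.frame(sample = sprintf("s%d", 1:8),
                   study = c(rep("A", 5), rep("B", 3)),
                   condition = c(rep("ctrl", 3), rep("drought", 2),
                                 rep("ctrl", 3)))
  kept <- filter_studies_by_replicates(md, 3)
  expect_setequal(kept$sample, c("s1", "s2", "s3", "s6", "s7", "s8"))
})

test_that("display summary averages before the log transform", {
  m <- matrix(c(3, 5, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  got <- summarize_for_display(m, c("cond", "cond"))
  expect_equal(got["g1", "cond"], log2(5), tolerance = 1e-12)
  expect_equal(got["g2", "cond"], 0)
  # replicate order irrelevant
  expect_equal(summarize_for_display(m[, 2:1, drop = FALSE],
                                     c("cond", "cond")), got)
})

test_that("identical groups yield no differential calls", {
  withr::with_seed(12, {
    counts <- matrix(rpois(600, 100), nrow = 100)
    counts <- cbind(counts, counts)  # second group duplicates the first
    groups <- rep(c("a", "b"), each = 6)
    res <- differential_expression(counts, groups)
    expect_false(any(res$de))
    expect_true(all(res$padj >= res$p_value - 1e-12))
  })
})

test_that("a planted 8-fold gene is flagged", {
  withr::with_seed(13, {
    counts <- matrix(rpois(100 * 10, 100), nrow = 100)
    counts[1, 6:10] <- rpois(5, 800)
    res <- differential_expression(counts, rep(c("a", "b"), each = 5))
    expect_true(res$de[1])
    expect_equal(sum(res$de), 1)
    expect_gt(res$log2fc[1], 1)
  })
})

test_that("the 2-fold boundary is strict", {
  base <- matrix(rep(c(9, 10, 11), 40), nrow = 20, byrow = TRUE)
  counts <- cbind(base, base * 2)  # exact 2-fold, nonzero variance
  res <- differential_expression(counts, rep(c("a", "b"), each = 6),
                                 normalize = FALSE)
  expect_equal(res$log2fc, rep(1, 20), tolerance = 1e-12)
  expect_false(any(res$de))
  # a 2.5-fold gene with the same variance structure is called
  counts25 <- cbind(base, base * 2.5)
  res25 <- differential_expression(counts25, rep(c("a", "b"), each = 6),
                                   normalize = FALSE)
  expect_true(all(res25$de))
})

test_that("the DE set shrinks monotonically with the fold threshold", {
  withr::with_seed(14, {
    counts <- matrix(rpois(200 * 10, 50), nrow = 200)
    counts[1:30, 6:10] <- matrix(rpois(150, 50 * 2^runif(150, 0.5, 3)),
                                 nrow = 30)
    groups <- rep(c("a", "b"), each = 5)
    sets <- lapply(c(2, 4, 8), function(fc) {
      res <- differential_expression(counts, groups, fc_threshold = fc)
      which(res$de)
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  })
})

test_that("degenerate count groups are rejected", {
  counts <- matrix(0, nrow = 5, ncol = 4)
  counts[, 3:4] <- 5
  expect_error(differential_expression(counts, c("a", "a", "b", "b")),
               "zero total")
  expect_error(differential_expression(matrix(1, 2, 3), c("a", "a", "b")),
               "replicates")
})
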