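# Profile construction, repeat scanning, landmark validation, logo stats.

test_that("profiles from identical sequences are deterministic one-hot", {
  seqs <- rep("ACDEFGHIKLMNPQRSTVWY", 10)
  prof <- build_profile(seqs, pseudocount = 0)
  expect_equal(prof$length, 20)
  expect_true(all(apply(prof$freq, 2, max) == 1))
  expect_equal(colnames(prof$freq), NULL)
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-9))
})

test_that("huge pseudocounts pull frequencies to the background", {
  seqs <- rep("ACDEFGHIKLMNPQRSTVWY", 5)
  prof <- build_profile(seqs, pseudocount = 1e9)
  expect_true(all(abs(prof$freq - 1 / 20) < 1e-6))
})

test_that("profile consensus of a zero-mutation family equals the template", {
  fam <- simulate_family(50, 0, mutation_rate = 0, seed = 2)
  doms <- unname(family_domains(fam))
  prof <- build_profile(doms, pseudocount = 0.1)
  consensus <- paste(rownames(prof$freq)[apply(prof$freq, 2, which.max)],
                     collapse = "")
  expect_equal(consensus, fam$template_seq)
})

test_that("ragged alignments are rejected", {
  expect_error(build_profile(c("ACD", "AC")), "ragged")
})

test_that("scan recovers both planted repeats at the truth offsets", {
  fam <- fixture_family(n_true = 6, n_decoys = 0)
  prof <- fixture_profile(fam)
  for (i in seq_len(nrow(fam$truth))) {
    tr <- fam$truth[i, ]
    hits <- scan_repeats(fam$sequences[[tr$seq_id]], prof)
    expect_equal(nrow(hits), 2)
    expect_equal(hits$start, c(tr$r2_start, tr$r3_start))
    expect_equal(hits$group, c(1, 1))
  }
})

test_that("single-repeat decoys yield exactly one hit", {
  fam <- fixture_family(n_true = 1, n_decoys = 3)
  prof <- fixture_profile(fam)
  sr <- fam$truth[fam$truth$class == "single_repeat", ]
  for (id in sr$seq_id) {
    expect_equal(nrow(scan_repeats(fam$sequences[[id]], prof)), 1)
  }
})

test_that("random sequences essentially never score above threshold", {
  fam <- fixture_family(n_true = 2, n_decoys = 0)
  prof <- fixture_profile(fam)
  n_fp <- withr::with_seed(123, {
    sum(vapply(1:200, function(i) {
      s <- paste(sample(AA_STANDARD, 150, replace = TRUE), collapse = "")
      nrow(scan_repeats(s, prof)) > 0
    }, logical(1)))
  })
  expect_lt(n_fp / 200, 0.05)
})

test_that("hit coordinates shift with, and counts are invariant to, flanks", {
  fam <- fixture_family(n_true = 3, n_decoys = 0)
  prof <- fixture_profile(fam)
  s <- fam$sequences[[1]]
  base <- scan_repeats(s, prof)
  pad <- withr::with_seed(5, paste(sample(AA_STANDARD, 30, replace = TRUE),
                                   collapse = ""))
  shifted <- scan_repeats(paste0(pad, s, pad), prof)
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(shifted$start, base$start + 30)
})

test_that("sequences shorter than the profile warn and return no hits", {
  fam <- fixture_family(n_true = 1, n_decoys = 0)
  prof <- fixture_profile(fam)
  expect_warning(h <- scan_repeats("ACDEF", prof), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("landmark validation reads the planted domain correctly", {
  fam <- fixture_family(n_true = 1, n_decoys = 0)
  prof <- fixture_profile(fam)
  tr <- fam$truth[1, ]
  h <- scan_repeats(fam$sequences[[tr$seq_id]], prof)
  rep <- validate_landmarks(fam$sequences[[tr$seq_id]], h[1, ], h[2, ])
  expect_equal(rep$w_match_count, 5)
  expect_true(rep$l35_present)
  expect_true(rep$linker_has_LRPD)
  expect_true(rep$r3_first_compliant)
  expect_equal(rep$conserved_matches, 13)
  expect_equal(as.integer(names(rep$landmark_states)), c(6, 26, 46, 78, 97))
})

test_that("substituted R3 tryptophans lower the match count as observed in planta", {
  # W78 -> F and W97 -> Y, the substitution pattern seen in rare family members
  tpl_seq <- make_template(seed = 1)
  chars <- strsplit(tpl_seq, "")[[1]]
  chars[78] <- "F"; chars[97] <- "Y"
  mutated <- paste(chars, collapse = "")
  rep <- validate_landmarks(mutated,
                            list(start = 1, end = 52),
                            list(start = 53, end = 104))
  expect_equal(rep$w_match_count, 3)
  expect_equal(unname(rep$landmark_states[c("78", "97")]), c("F", "Y"))
})

test_that("overlapping hits are a coordinate error", {
  s <- make_template(seed = 1)
  expect_error(validate_landmarks(s, list(start = 1, end = 52),
                                  list(start = 40, end = 91)),
               "overlap")
})

test_that("integrity filter sits at the 3-of-5 tryptophan boundary", {
  mk <- function(n_repeats, w) {
    list(n_repeats = n_repeats, landmark_report = list(w_match_count = w))
  }
  expect_true(integrity_filter(mk(2, 3))$pass)
  expect_true(integrity_filter(mk(2, 5))$pass)
  v2 <- integrity_filter(mk(2, 2))
  expect_false(v2$pass)
  expect_equal(v2$reason, "tryptophan_deficient")
  v1 <- integrity_filter(mk(1, 5))
  expect_false(v1$pass)
  expect_equal(v1$reason, "incomplete_repeat")
  # monotone: destroying one more landmark never rescues a failure
  for (w in 0:4) {
    if (!integrity_filter(mk(2, w + 1))$pass) {
      expect_false(integrity_filter(mk(2, w))$pass)
    }
  }
})

test_that("truncated-repeat decoys fail with reason incomplete_repeat", {
  fam <- fixture_family(n_true = 1, n_decoys = 3)
  prof <- fixture_profile(fam)
  tr <- fam$truth[fam$truth$class == "truncated_repeat", ]
  for (id in tr$seq_id) {
    ann <- annotate_domain(fam$sequences[[id]], prof)
    expect_false(ann$integrity_pass)
    expect_equal(ann$integrity_reason, "incomplete_repeat")
  }
})

test_that("logo information content matches closed forms", {
  all_w <- rep("WW", 4)
  logo <- compute_logo(all_w)
  expect_equal(logo$ic_bits, rep(log2(20), 2), tolerance = 1e-12)
  expect_equal(unname(logo$heights["W", ]), logo$ic_bits)

  uniform <- vapply(AA_STANDARD, function(a) paste0(a, a), character(1))
  logo_u <- compute_logo(unname(uniform))
  expect_equal(logo_u$ic_bits, c(0, 0), tolerance = 1e-12)
})

test_that("logo IC stays within bounds and correction only lowers it", {
  fam <- simulate_family(30, 0, mutation_rate = 0.1, seed = 6)
  doms <- unname(family_domains(fam))
  raw <- compute_logo(doms)
  corr <- compute_logo(doms, small_sample_correction = TRUE)
  expect_true(all(raw$ic_bits >= 0 & raw$ic_bits <= log2(20) + 1e-12))
  expect_true(all(corr$ic_bits <= raw$ic_bits + 1e-12))
})

test_that("gap-dominated columns are excluded from the logo", {
  aligned <- c("AW-", "AW-", "AWC", "AW-")
  logo <- compute_logo(aligned, gap_column_threshold = 0.5)
  expect_equal(logo$positions, c(1, 2))
})

test_that("landmark columns attain the maximal IC of the family logo", {
  fam <- simulate_family(200, 0, mutation_rate = 0.05, seed = 10)
  logo <- compute_logo(unname(family_domains(fam)))
  landmark_ic <- logo$ic_bits[match(c(6, 26, 46, 78, 97), logo$positions)]
  expect_equal(landmark_ic, rep(max(logo$ic_bits), 5), tolerance = 1e-12)
})

test_that("end-to-end classification recovers truth on a mutated family", {
  fam <- simulate_family(100, 10, mutation_rate = 0.05, seed = 13,
                         decoy_kinds = c("single_repeat", "truncated_repeat",
                                         "w_deficient", "triple_repeat"))
  prof <- fixture_profile(fam)
  check <- fam$truth[fam$truth$class %in% c("R2R3", "single_repeat"), ]
  got <- vapply(check$seq_id, function(id) {
    annotate_domain(fam$sequences[[id]], prof)$myb_class
  }, character(1))
  expect_equal(unname(got), check$expected_myb_class)
})
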