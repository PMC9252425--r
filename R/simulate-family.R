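# Synthetic protein families with embedded R2R3 domains and decoy classes.

#' Simulate a protein family with embedded R2R3 domains and decoys
#'
#' Generates true R2R3-MYB members (the template domain embedded in random
#' flanking sequence, with seeded point substitutions that never touch
#' constrained positions) plus decoy classes mirroring the sequence classes a
#' family curation discards: `single_repeat` keeps only the R2 repeat,
#' `truncated_repeat` deletes a block of >= 10 positions from one repeat,
#' `w_deficient` mutates three landmark tryptophans to alanine, and
#' `triple_repeat` prepends an extra R2-like copy.
#'
#' @param n_true_r2r3 Number of true R2R3 members.
#' @param n_decoys_per_kind Number of decoys of each kind.
#' @param mutation_rate Per-position substitution probability at
#'   unconstrained domain positions, in \[0, 1\].
#' @param seed Integer seed; identical spec + seed reproduces the output
#'   byte-for-byte.
#' @param decoy_kinds Subset of
#'   `c("single_repeat", "truncated_repeat", "w_deficient", "triple_repeat")`.
#' @param template A [canonical_template()].
#' @param flank_range Flank length range per side (uniform draw), default
#'   `c(10, 80)`.
#' @return A list with `sequences` (named character vector), `truth` (a
#'   data.frame with one row per sequence: `seq_id`, `class` (decoy kind or
#'   `"R2R3"`), `expected_myb_class`, `domain_start`, `domain_end`,
#'   `r2_start`, `r3_start`, `n_mutations`, `w_landmarks_intact`), the
#'   `template` object and the realized `template_seq`.
#' @export
simulate_family <- function(n_true_r2r3,
                            n_decoys_per_kind = 0L,
                            mutation_rate = 0,
                            seed = 1L,
                            decoy_kinds = c("single_repeat", "truncated_repeat",
                                            "w_deficient", "triple_repeat"),
                            template = canonical_template(),
                            flank_range = c(10L, 80L)) {
  n_true_r2r3 <- check_count(n_true_r2r3, "n_true_r2r3")
  n_decoys_per_kind <- check_count(n_decoys_per_kind, "n_decoys_per_kind")
  check_probability(mutation_rate, "mutation_rate")
  decoy_kinds <- match.arg(decoy_kinds, several.ok = TRUE)
  validate_template(template)

  constraints <- as.integer(names(constrained_positions(template)))
  template_seq <- make_template(template, seed = seed)
  r2_len <- template$r2_span[2] - template$r2_span[1] + 1L

  with_seed(seed + 1L, {
    rows <- list()
    seqs <- character(0)

    mutate_domain <- function(domain, local_constraints) {
      chars <- str_chars(domain)
      free <- setdiff(seq_along(chars), local_constraints)
      hit <- free[stats::runif(length(free)) < mutation_rate]
      for (i in hit) {
        chars[i] <- sample_safe(setdiff(AA_STANDARD, chars[i]), 1L)
      }
      list(seq = paste(chars, collapse = ""), n_mut = length(hit))
    }

    embed <- function(core) {
      lf <- sample(flank_range[1]:flank_range[2], 1L)
      rf <- sample(flank_range[1]:flank_range[2], 1L)
      list(seq = paste0(random_residues(lf), core, random_residues(rf)),
           offset = lf)
    }

    add_record <- function(id, core, n_mut, class, expected, r2_rel, r3_rel,
                           w_intact) {
      emb <- embed(core)
      seqs[[id]] <<- emb$seq
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = id, class = class, expected_myb_class = expected,
        domain_start = emb$offset + 1L,
        domain_end = emb$offset + nchar(core),
        r2_start = if (is.na(r2_rel)) NA_integer_ else emb$offset + r2_rel,
        r3_start = if (is.na(r3_rel)) NA_integer_ else emb$offset + r3_rel,
        n_mutations = n_mut, w_landmarks_intact = w_intact,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_true_r2r3)) {
      m <- mutate_domain(template_seq, constraints)
      add_record(sprintf("true_r2r3_%03d", i), m$seq, m$n_mut,
                 "R2R3", "R2R3", 1L, r2_len + 1L, 5L)
    }

    for (kind in decoy_kinds) {
      for (i in seq_len(n_decoys_per_kind)) {
        id <- sprintf("%s_%03d", kind, i)
        if (kind == "single_repeat") {
          core <- substr(template_seq, template$r2_span[1], template$r2_span[2])
          m <- mutate_domain(core, constraints[constraints <= r2_len])
          add_record(id, m$seq, m$n_mut, kind, "MYB_related", 1L, NA, 3L)
        } else if (kind == "truncated_repeat") {
          # delete a central block of 10-20 positions from one repeat, so
          # neither remaining intact run can carry a full-window hit
          del_len <- sample(10:20, 1L)
          in_r2 <- stats::runif(1) < 0.5
          span <- if (in_r2) template$r2_span else template$r3_span
          span_len <- span[2] - span[1] + 1L
          lo_start <- span[1] + max(0L, span_len - del_len - 26L)
          hi_start <- min(span[1] + 26L, span[2] - del_len + 1L)
          del_start <- sample(lo_start:hi_start, 1L)
          chars <- str_chars(template_seq)
          core <- paste(chars[-(del_start:(del_start + del_len - 1L))],
                        collapse = "")
          add_record(id, core, 0L, kind, NA_character_, NA, NA, NA_integer_)
        } else if (kind == "w_deficient") {
          chars <- str_chars(template_seq)
          dead <- sample_safe(template$landmarks, 3L)
          chars[dead] <- "A"
          m <- mutate_domain(paste(chars, collapse = ""),
                             union(constraints, dead))
          add_record(id, m$seq, m$n_mut, kind, NA_character_,
                     1L, r2_len + 1L, 2L)
        } else if (kind == "triple_repeat") {
          extra <- substr(template_seq, template$r2_span[1], template$r2_span[2])
          m <- mutate_domain(paste0(extra, template_seq),
                             c(constraints[constraints <= r2_len],
                               r2_len + constraints))
          add_record(id, m$seq, m$n_mut, kind, "R3MYB_3R",
                     1L, r2_len + 1L, 5L)
        }
      }
    }

    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(sequences = unlist(seqs), truth = truth,
         template = template, template_seq = template_seq)
  })
}

#' Extract the planted domain sequences of a simulated family
#'
#' Convenience accessor returning, for each sequence whose truth row carries a
#' domain span, the domain substring — the alignment-free "aligned" domain set
#' for logo and profile computation (all true domains share the template
#' coordinate system, so no alignment step is needed).
#'
#' @param fam Result of [simulate_family()].
#' @param classes Truth classes to keep (default `"R2R3"`).
#' @return Named character vector of domain sequences.
#' @export
family_domains <- function(fam, classes = "R2R3") {
  tr <- fam$truth[fam$truth$class %in% classes, , drop = FALSE]
  stats::setNames(
    substr(fam$sequences[tr$seq_id], tr$domain_start, tr$domain_end),
    tr$seq_id)
}
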