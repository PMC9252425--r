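# Landmark-tryptophan validation, MYB class assignment, integrity filtering.

MYB_CLASSES <- c("none", "MYB_related", "R2R3", "R3MYB_3R", "MYB_4R")

myb_class_from_repeats <- function(n_repeats) {
  if (n_repeats <= 0L) "none"
  else if (n_repeats == 1L) "MYB_related"
  else if (n_repeats == 2L) "R2R3"
  else if (n_repeats == 3L) "R3MYB_3R"
  else "MYB_4R"
}

#' Validate the landmark residues of a detected R2R3 domain
#'
#' Anchors the template coordinate system at the R2 hit start and reads the
#' residues at the five landmark tryptophan positions (6, 26, 46, 78, 97),
#' the R3 first-helix W/F/I slot, the L35 insertion site, the LRPD linker
#' window, and the thirteen additional conserved residues. The F/I slot does
#' not count toward the tryptophan match count: the five-landmark census is
#' the positions 6/26/46/78/97 only.
#'
#' @param sequence Protein sequence containing the domain.
#' @param r2_hit,r3_hit Single rows of the [scan_repeats()] result (or any
#'   list with `start`/`end`) for the R2 and R3 repeats.
#' @param template The [canonical_template()] defining the coordinates.
#' @return An object of class `landmark_report`: list with
#'   `landmark_states` (named residue vector over the 5 landmark positions),
#'   `w_match_count` (0-5), `r3_first_residue`, `r3_first_compliant`
#'   (W, F or I at the slot), `l35_present`, `linker_has_LRPD`,
#'   `conserved_matches` (0-13), `anchor` (sequence coordinate of template
#'   position 1).
#' @export
validate_landmarks <- function(sequence, r2_hit, r3_hit,
                               template = canonical_template()) {
  validate_template(template)
  if (r3_hit$start <= r2_hit$end) {
    stop("R2 and R3 hits overlap: invalid domain coordinates",
         call. = FALSE)
  }
  anchor <- r2_hit$start
  at <- function(p) substr(sequence, anchor + p - 1L, anchor + p - 1L)

  landmark_states <- vapply(template$landmarks, at, character(1))
  names(landmark_states) <- template$landmarks
  w_match_count <- sum(landmark_states == "W")

  r3_first_residue <- at(template$r3_first_slot)
  cons_pos <- as.integer(names(template$conserved))
  conserved_matches <- sum(vapply(cons_pos, at, character(1)) ==
                             unname(template$conserved))
  linker <- substr(sequence, anchor + template$linker_start - 1L,
                   anchor + template$linker_start +
                     nchar(template$linker_motif) - 2L)

  structure(list(
    landmark_states = landmark_states,
    w_match_count = as.integer(w_match_count),
    r3_first_residue = r3_first_residue,
    r3_first_compliant = r3_first_residue %in% template$r3_first_allowed,
    l35_present = at(template$l35_site) == "L",
    linker_has_LRPD = linker == template$linker_motif,
    conserved_matches = as.integer(conserved_matches),
    anchor = as.integer(anchor)
  ), class = "landmark_report")
}

#' Annotate the MYB domain architecture of one protein
#'
#' Runs the repeat scan, determines the repeat count of the primary repeat
#' group (the group with most hits; earliest on ties), assigns the MYB class
#' (1 repeat = MYB-related, 2 = R2R3, 3 = 3R, 4+ = 4R), and for >= 2 repeats
#' validates the landmark residues of the R2/R3 pair (the last two repeats
#' of the group, so an extra N-terminal repeat copy does not shift the
#' anchor away from the canonical R2).
#'
#' @param sequence Protein sequence.
#' @param profile A `repeat_profile` (see [repeat_profile()]).
#' @param template The [canonical_template()].
#' @param ... Passed to [scan_repeats()].
#' @return An object of class `domain_annotation`: list with `hits`,
#'   `n_repeats`, `myb_class`, `r2`, `r3` (hit rows or NULL),
#'   `landmark_report` (or NULL), `integrity_pass`, `integrity_reason`.
#' @export
annotate_domain <- function(sequence, profile,
                            template = canonical_template(), ...) {
  hits <- scan_repeats(sequence, profile, ...)
  if (nrow(hits) == 0L) {
    ann <- structure(list(hits = hits, n_repeats = 0L, myb_class = "none",
                          r2 = NULL, r3 = NULL, landmark_report = NULL,
                          integrity_pass = NA, integrity_reason = NA_character_),
                     class = "domain_annotation")
    return(apply_integrity(ann))
  }
  grp_sizes <- table(hits$group)
  primary <- as.integer(names(grp_sizes)[which.max(grp_sizes)])
  grp <- hits[hits$group == primary, , drop = FALSE]
  n_rep <- nrow(grp)
  ann <- list(hits = hits, n_repeats = n_rep,
              myb_class = myb_class_from_repeats(n_rep),
              r2 = NULL, r3 = NULL, landmark_report = NULL,
              integrity_pass = NA, integrity_reason = NA_character_)
  if (n_rep >= 2L) {
    ann$r2 <- grp[n_rep - 1L, ]
    ann$r3 <- grp[n_rep, ]
    ann$landmark_report <- validate_landmarks(sequence, ann$r2, ann$r3,
                                              template)
  }
  apply_integrity(structure(ann, class = "domain_annotation"))
}

apply_integrity <- function(ann) {
  v <- integrity_filter(ann)
  ann$integrity_pass <- v$pass
  ann$integrity_reason <- v$reason
  ann
}

#' Integrity filter for a domain annotation
#'
#' Implements the curation rule that discards sequences with incomplete MYB
#' repeats or lacking more than two of the five highly conserved landmark
#' tryptophans: fail when fewer than two full-length repeats were found
#' (`incomplete_repeat`) or when fewer than three landmark positions carry W
#' (`tryptophan_deficient`); a domain missing exactly two landmarks still
#' passes.
#'
#' @param annotation A `domain_annotation` from [annotate_domain()] (or any
#'   list with `n_repeats` and `landmark_report$w_match_count`).
#' @return list with `pass` (logical) and `reason`
#'   (`"ok"`, `"incomplete_repeat"` or `"tryptophan_deficient"`).
#' @export
integrity_filter <- function(annotation) {
  if (annotation$n_repeats < 2L) {
    return(list(pass = FALSE, reason = "incomplete_repeat"))
  }
  w <- annotation$landmark_report$w_match_count
  if (is.null(w) || w < 3L) {
    return(list(pass = FALSE, reason = "tryptophan_deficient"))
  }
  list(pass = TRUE, reason = "ok")
}
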