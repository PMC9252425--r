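# Canonical R2R3 domain coordinate system and template sequence generation.

#' Canonical R2R3-MYB domain template
#'
#' Defines the 105-position coordinate system of the plant R2R3-MYB
#' DNA-binding domain together with its conserved-residue constraints: the
#' five landmark tryptophans at positions 6, 26 and 46 (R2 repeat) and 78 and
#' 97 (R3 repeat), the thirteen additional highly conserved residues, the
#' leucine insertion at position 35, the LRPD linker between the repeats, and
#' the R3 first-helix slot that in plants typically carries F or I in place of
#' the ancestral tryptophan.
#'
#' @param r3_first_slot Position of the R3 first-helix W/F/I slot. The slot
#'   sits in R3 helix 1, between the linker and the landmark at 78; default 58.
#' @param r3_first_residue Residue placed at that slot when generating a
#'   template sequence; must be one of `"F"`, `"I"`, `"W"`.
#' @param linker_start Start position of the 4-residue LRPD linker
#'   (default 50, immediately after the last R2 landmark).
#' @return An object of class `myb_template`: a list with elements `length`,
#'   `landmarks`, `conserved` (named residue vector), `l35_site`,
#'   `linker_motif`, `linker_start`, `r3_first_slot`, `r3_first_residue`,
#'   `r3_first_allowed`, `r2_span`, `r3_span`.
#' @examples
#' tpl <- canonical_template()
#' tpl$landmarks
#' @export
canonical_template <- function(r3_first_slot = 58,
                               r3_first_residue = "F",
                               linker_start = 50) {
  if (!r3_first_residue %in% c("F", "I", "W")) {
    stop("`r3_first_residue` must be one of F, I, W", call. = FALSE)
  }
  tpl <- structure(list(
    length           = 105L,
    landmarks        = c(6L, 26L, 46L, 78L, 97L),
    conserved        = c(`10` = "E", `11` = "D", `14` = "L", `22` = "G",
                         `42` = "C", `43` = "R", `45` = "R", `63` = "E",
                         `75` = "G", `82` = "A", `88` = "R", `94` = "K",
                         `95` = "N"),
    l35_site         = 35L,
    linker_motif     = "LRPD",
    linker_start     = as.integer(linker_start),
    r3_first_slot    = as.integer(r3_first_slot),
    r3_first_residue = r3_first_residue,
    r3_first_allowed = c("F", "I", "W"),
    r2_span          = c(1L, 52L),
    r3_span          = c(53L, 105L)
  ), class = "myb_template")
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  stopifnot(inherits(tpl, "myb_template"))
  pos <- c(tpl$landmarks, as.integer(names(tpl$conserved)), tpl$l35_site,
           tpl$linker_start:(tpl$linker_start + nchar(tpl$linker_motif) - 1L),
           tpl$r3_first_slot)
  if (any(pos < 1L | pos > tpl$length)) {
    stop("template constraint positions must lie within [1, ",
         tpl$length, "]", call. = FALSE)
  }
  if (any(diff(tpl$landmarks) <= 0L)) {
    stop("landmark positions must be strictly increasing", call. = FALSE)
  }
  if (!(tpl$r2_span[1] == 1L && tpl$r3_span[2] == tpl$length &&
        tpl$r2_span[2] + 1L == tpl$r3_span[1])) {
    stop("r2_span and r3_span must partition [1, ", tpl$length, "]",
         call. = FALSE)
  }
  # building the constraint map errors on conflicting constraints
  constrained_positions(tpl)
  invisible(tpl)
}

#' Constrained positions of a domain template
#'
#' Flattens a [canonical_template()] into a named residue vector
#' (position -> mandated residue). Conflicting constraints at one position
#' raise an error.
#'
#' @param tpl A `myb_template`.
#' @return Named character vector; names are 1-based positions.
#' @export
constrained_positions <- function(tpl) {
  linker <- str_chars(tpl$linker_motif)
  pos <- c(tpl$landmarks,
           as.integer(names(tpl$conserved)),
           tpl$l35_site,
           tpl$linker_start + seq_along(linker) - 1L,
           tpl$r3_first_slot)
  res <- c(rep("W", length(tpl$landmarks)),
           unname(tpl$conserved),
           "L",
           linker,
           tpl$r3_first_residue)
  ord <- order(pos)
  pos <- pos[ord]; res <- res[ord]
  dup <- duplicated(pos)
  if (any(dup)) {
    for (p in unique(pos[dup])) {
      if (length(unique(res[pos == p])) > 1L) {
        stop("conflicting constraints at template position ", p,
             call. = FALSE)
      }
    }
    res <- res[!dup]; pos <- pos[!dup]
  }
  stats::setNames(res, pos)
}

#' Generate a template domain sequence
#'
#' Produces a 105-residue amino-acid sequence obeying every constraint of the
#' template. Unconstrained positions are drawn uniformly from the 19
#' non-tryptophan residues, so that tryptophan remains the distinctive rare
#' landmark residue of the domain (as in real MYB alignments, where W outside
#' the landmark columns is exceptional).
#'
#' @param tpl A `myb_template`; default [canonical_template()].
#' @param seed Integer seed; identical `(tpl, seed)` gives identical output.
#' @return A single character string of length `tpl$length`.
#' @examples
#' s <- make_template(seed = 1)
#' substr(s, 6, 6)    # "W"
#' substr(s, 50, 53)  # "LRPD"
#' @export
make_template <- function(tpl = canonical_template(), seed = 1L) {
  validate_template(tpl)
  constraints <- constrained_positions(tpl)
  free_alphabet <- setdiff(AA_STANDARD, "W")
  with_seed(seed, {
    res <- sample_safe(free_alphabet, tpl$length, replace = TRUE)
    res[as.integer(names(constraints))] <- constraints
    paste(res, collapse = "")
  })
}
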