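# Shared constants and small internal helpers.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order, the residue alphabet used by every
#' profile, motif matrix and generator in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# uniform background over the 20 residues
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_STANDARD)
}

# run code under a temporary RNG state; never clobbers the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# split a string into single residues
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# random residue string of length n over an alphabet
random_residues <- function(n, alphabet = AA_STANDARD) {
  paste(sample_safe(alphabet, n, replace = TRUE), collapse = "")
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
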