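# Shared fixtures built in code at test time.

fixture_family <- function(n_true = 5, n_decoys = 2, mutation_rate = 0,
                           seed = 7) {
  simulate_family(n_true, n_decoys, mutation_rate = mutation_rate,
                  seed = seed)
}

fixture_profile <- function(fam) {
  repeat_profile(fam$template_seq, fam$template)
}

# one-hot motif matrix on a consensus string (probability 1 per position)
onehot_motif <- function(consensus, id) {
  chars <- strsplit(consensus, "")[[1]]
  mat <- matrix(0, nrow = length(chars), ncol = 20,
                dimnames = list(NULL, AA_STANDARD))
  mat[cbind(seq_along(chars), match(chars, AA_STANDARD))] <- 1
  motif_matrix(mat, id)
}

# brute-force hypergeometric upper tail by enumeration over a tiny universe
enum_hyper_p <- function(overlap, category_size, universe_size, query_size) {
  draws <- utils::combn(universe_size, query_size)
  in_cat <- colSums(draws <= category_size)  # wlog category = first K genes
  mean(in_cat >= overlap)
}
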