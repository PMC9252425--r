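# Expression matrices generated from a known regulator -> target network,
# and GO annotation maps with one planted enriched category.

#' Simulate expression data from a known regulatory network
#'
#' Transcription-factor abundances are drawn i.i.d. log-normal across
#' samples; each non-TF gene's abundance is a link function (linear or
#' hinge) of its true regulators' abundances plus additive Gaussian noise
#' scaled to a fraction of the signal's spread. Counts are Poisson draws
#' around the abundances, and TPM columns are normalized to sum to 10^6.
#'
#' @param n_genes Total genes (TFs included).
#' @param n_tfs Number of regulators (`n_tfs < n_genes`).
#' @param edges_per_target Regulators per non-TF gene (default 2).
#' @param n_samples Number of samples (>= 2; default 100).
#' @param noise_sd Additive noise standard deviation, as a fraction of each
#'   target's signal standard deviation (default 0.3; 0 = deterministic
#'   targets).
#' @param link_function `"linear"` (weighted sum of regulator abundances) or
#'   `"hinge"` (weighted sum thresholded at its median, a saturating
#'   activation).
#' @param seed Integer seed.
#' @return A list with `tpm` and `counts` (gene x sample matrices),
#'   `abundance` (the latent noiseless-normalization matrix actually
#'   generated), `regulators` (TF ids), and `true_edges`
#'   (data.frame `regulator`, `target`, `weight`).
#' @export
simulate_grn_expression <- function(n_genes,
                                    n_tfs,
                                    edges_per_target = 2L,
                                    n_samples = 100L,
                                    noise_sd = 0.3,
                                    link_function = c("linear", "hinge"),
                                    seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_tfs <- check_count(n_tfs, "n_tfs", min = 1L)
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  edges_per_target <- check_count(edges_per_target, "edges_per_target",
                                  min = 1L)
  if (n_tfs >= n_genes) stop("`n_tfs` must be < `n_genes`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (edges_per_target > n_tfs) {
    stop("`edges_per_target` cannot exceed `n_tfs`", call. = FALSE)
  }
  link_function <- match.arg(link_function)

  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  targets <- sprintf("G%04d", seq_len(n_genes - n_tfs))
  genes <- c(tfs, targets)

  with_seed(seed, {
    tf_expr <- matrix(exp(stats::rnorm(n_tfs * n_samples)), nrow = n_tfs,
                      dimnames = list(tfs, NULL))
    edge_rows <- list()
    tgt_expr <- matrix(0, nrow = length(targets), ncol = n_samples,
                       dimnames = list(targets, NULL))
    for (i in seq_along(targets)) {
      regs <- sample_safe(tfs, edges_per_target)
      w <- stats::runif(edges_per_target, 0.5, 1.5)
      signal <- as.numeric(w %*% tf_expr[regs, , drop = FALSE])
      if (link_function == "hinge") {
        signal <- pmax(signal - stats::median(signal), 0)
      }
      noise <- if (noise_sd > 0) {
        stats::rnorm(n_samples, sd = noise_sd * stats::sd(signal))
      } else 0
      tgt_expr[i, ] <- pmax(signal + noise, 0)
      edge_rows[[i]] <- data.frame(regulator = regs, target = targets[i],
                                   weight = w, stringsAsFactors = FALSE)
    }
    abundance <- rbind(tf_expr, tgt_expr)
    colnames(abundance) <- sprintf("S%03d", seq_len(n_samples))
    tpm <- sweep(abundance, 2, colSums(abundance), "/") * 1e6
    counts <- matrix(stats::rpois(length(abundance), abundance * 20),
                     nrow = nrow(abundance), dimnames = dimnames(abundance))
    true_edges <- do.call(rbind, edge_rows)
    rownames(true_edges) <- NULL
    list(tpm = tpm, counts = counts, abundance = abundance,
         regulators = tfs, true_edges = true_edges)
  })
}

#' Simulate a GO annotation map with one planted enriched category
#'
#' Annotates genes to categories at random, then plants a single category
#' that overlaps a designated target gene set by a chosen fraction; at 100%
#' overlap the planted category is maximally enriched by construction, while
#' at the random-expectation overlap the map carries no signal.
#'
#' @param n_genes Universe size.
#' @param n_categories Number of categories (planted one included).
#' @param planted_category_size Size of the planted category; must lie in
#'   the 10..1000 band used for enrichment testing.
#' @param target_set_overlap Fraction of the target set drawn from the
#'   planted category, in \[0, 1\]. The target set has the same size as the
#'   planted category.
#' @param seed Integer seed.
#' @param category_size_range Size range for the background categories
#'   (default 10..100).
#' @return A list with `annotation` (data.frame `gene`, `category`),
#'   `universe`, `target_set`, and `planted_category`.
#' @export
simulate_go_annotation <- function(n_genes,
                                   n_categories,
                                   planted_category_size,
                                   target_set_overlap = 1,
                                   seed = 1L,
                                   category_size_range = c(10L, 100L)) {
  n_genes <- check_count(n_genes, "n_genes", min = 20L)
  n_categories <- check_count(n_categories, "n_categories", min = 2L)
  check_probability(target_set_overlap, "target_set_overlap")
  if (planted_category_size < 10 || planted_category_size > 1000) {
    stop("`planted_category_size` must lie in [10, 1000]", call. = FALSE)
  }
  if (planted_category_size > n_genes) {
    stop("`planted_category_size` cannot exceed `n_genes`", call. = FALSE)
  }

  universe <- sprintf("G%05d", seq_len(n_genes))
  cats <- sprintf("GO:%07d", seq_len(n_categories))
  planted <- cats[1]

  with_seed(seed, {
    rows <- list()
    planted_genes <- sample_safe(universe, planted_category_size)
    rows[[1]] <- data.frame(gene = planted_genes, category = planted,
                            stringsAsFactors = FALSE)
    for (k in 2:n_categories) {
      size <- sample(category_size_range[1]:category_size_range[2], 1L)
      rows[[k]] <- data.frame(gene = sample_safe(universe, size),
                              category = cats[k], stringsAsFactors = FALSE)
    }
    n_in <- round(target_set_overlap * planted_category_size)
    target_set <- c(sample_safe(planted_genes, n_in),
                    sample_safe(setdiff(universe, planted_genes),
                                planted_category_size - n_in))
    annotation <- do.call(rbind, rows)
    rownames(annotation) <- NULL
    list(annotation = annotation, universe = universe,
         target_set = target_set, planted_category = planted)
  })
}
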