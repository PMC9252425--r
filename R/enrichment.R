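# Hypergeometric GO enrichment with permutation FWER control.

#' GO category enrichment of a gene set
#'
#' Hypergeometric upper-tail test per category, restricted to categories
#' with between `min_size` and `max_size` annotated genes in the universe
#' (excluding very general and very specific terms). Family-wise error is
#' controlled by permutation: random query sets of equal size drawn from
#' the universe define the null distribution of the minimum p-value, and
#' each category's adjusted p is the permutation fraction
#' `(1 + #{min-p_perm <= p_obs}) / (1 + n_permutations)` (the +1 convention
#' keeps the permutation p-value valid). `method = "bonferroni"` is a fast
#' deterministic fallback.
#'
#' @param query Character vector of query genes (non-empty, subset of
#'   `universe`).
#' @param annotation data.frame with columns `gene`, `category`.
#' @param universe Character vector of background genes (default: all genes
#'   in the annotation).
#' @param min_size,max_size Category size band (defaults 10 and 1000).
#' @param n_permutations Permutations for FWER control (default 1000).
#' @param seed Integer seed for the permutations.
#' @param alpha FWER level for the `significant` flag (default 0.05).
#' @param method `"permutation"` (default) or `"bonferroni"`.
#' @return data.frame per retained category: `category`, `size`, `overlap`,
#'   `p_value`, `p_adjusted`, `significant`, sorted by `p_value`.
#' @export
go_enrichment <- function(query, annotation,
                          universe = unique(annotation$gene),
                          min_size = 10L, max_size = 1000L,
                          n_permutations = 1000L, seed = 1L,
                          alpha = 0.05,
                          method = c("permutation", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "category") %in% names(annotation)))
  if (!length(query)) stop("empty query set", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  query <- unique(query)
  ann <- annotation[annotation$gene %in% universe, ]
  N <- length(universe)
  n <- length(query)

  # category membership as an indicator matrix over the universe
  cats <- split(ann$gene, ann$category)
  cats <- lapply(cats, unique)
  sizes <- lengths(cats)
  keep <- sizes >= min_size & sizes <= max_size
  cats <- cats[keep]; sizes <- sizes[keep]
  if (!length(cats)) {
    stop("no category within the size band [", min_size, ", ", max_size,
         "]", call. = FALSE)
  }
  memb <- vapply(cats, function(g) universe %in% g,
                 logical(N))  # N x n_cats

  hyper_p <- function(qset) {
    ov <- colSums(memb[match(qset, universe), , drop = FALSE])
    stats::phyper(ov - 1, sizes, N - sizes, length(qset),
                  lower.tail = FALSE)
  }
  p_obs <- hyper_p(query)
  overlap <- colSums(memb[match(query, universe), , drop = FALSE])

  p_adj <- if (method == "bonferroni") {
    pmin(1, p_obs * length(p_obs))
  } else {
    minp <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
      min(hyper_p(sample_safe(universe, n)))
    }, numeric(1)))
    vapply(p_obs, function(p) (1 + sum(minp <= p)) / (1 + n_permutations),
           numeric(1))
  }

  out <- data.frame(category = names(cats), size = as.integer(sizes),
                    overlap = as.integer(overlap), p_value = p_obs,
                    p_adjusted = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  out
}
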