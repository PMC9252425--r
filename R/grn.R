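# Tree-ensemble (GENIE3-style) regulatory-network inference and edge handling.

#' Infer a gene regulatory network with regression-tree ensembles
#'
#' GENIE3 scheme: for each target gene, its expression (standardized to
#' unit variance across samples) is predicted from the regulator
#' expressions by a random forest (bootstrap resampling; a random candidate
#' subset of regulators at each split; splits maximize variance
#' reduction). A regulator's edge weight is its total variance-reduction
#' importance. Self-edges are excluded. Deterministic given `seed`.
#'
#' @param expr Numeric genes x samples matrix (TPM or any abundance scale;
#'   tree splits are rank-based, so monotone per-gene transforms do not
#'   change the result).
#' @param regulators Character vector of regulator (TF) gene ids; must be
#'   rows of `expr`.
#' @param targets Target gene ids (default all rows of `expr`).
#' @param n_trees Trees per target (default 100).
#' @param candidate_fraction Fraction of candidate regulators tried at each
#'   split; `NULL` (default) uses the square-root rule
#'   `mtry = floor(sqrt(p))`, 1 considers every regulator.
#' @param seed Integer seed.
#' @return data.frame of directed edges: `regulator`, `target`, `weight`,
#'   `rank`, sorted by decreasing weight (ties by regulator then target
#'   id).
#' @export
infer_network <- function(expr, regulators, targets = rownames(expr),
                          n_trees = 100L, candidate_fraction = NULL,
                          seed = 1L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (length(regulators) < 2L) stop("need >= 2 regulators", call. = FALSE)
  missing <- setdiff(c(regulators, targets), rownames(expr))
  if (length(missing)) {
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  # canonical sample order (by per-gene expression ranks) so edge weights
  # do not depend on the column order of the input matrix, and are
  # untouched by strictly increasing per-gene transforms
  rank_keys <- lapply(seq_len(nrow(expr)), function(i) rank(expr[i, ]))
  expr <- expr[, do.call(order, rank_keys), drop = FALSE]

  edge_rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    preds <- setdiff(regulators, tgt)
    y <- expr[tgt, ]
    x <- t(expr[preds, , drop = FALSE])
    if (stats::sd(y) == 0) {
      warning("constant expression for target ", tgt,
              "; zero-weight edges", call. = FALSE)
      imp <- stats::setNames(rep(0, length(preds)), preds)
    } else {
      y <- as.numeric(scale(y))
      mtry <- if (is.null(candidate_fraction)) {
        max(1L, floor(sqrt(length(preds))))
      } else {
        max(1L, ceiling(candidate_fraction * length(preds)))
      }
      # neutral column names: gene ids need no syntactic mangling
      dat <- as.data.frame(x)
      names(dat) <- sprintf("p%d", seq_along(preds))
      fit <- ranger::ranger(
        y = y, x = dat, num.trees = n_trees, mtry = mtry,
        importance = "impurity", replace = TRUE,
        num.threads = 1L, seed = seed + i)
      imp <- stats::setNames(pmax(fit$variable.importance, 0)[names(dat)],
                             preds)
    }
    edge_rows[[i]] <- data.frame(regulator = preds, target = tgt,
                                 weight = unname(imp),
                                 stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edge_rows)
  edges <- edges[order(-edges$weight, edges$regulator, edges$target), ]
  edges$rank <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  edges
}

#' Keep the top-k edges by weight
#'
#' Boundary ties are broken deterministically by (regulator, target)
#' lexicographic order, so the retained set is stable across runs and
#' nested in k.
#'
#' @param edges Edge data.frame (`regulator`, `target`, `weight`).
#' @param k Number of edges to keep (default 16000).
#' @return The pruned, re-ranked edge data.frame.
#' @export
prune_top_edges <- function(edges, k = 16000L) {
  k <- check_count(k, "k", min = 1L)
  ord <- order(-edges$weight, edges$regulator, edges$target)
  out <- edges[ord[seq_len(min(k, nrow(edges)))], ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Extract the sub-network of a set of query regulators
#'
#' Restricts an edge list to edges whose regulator is in the query set and
#' reports per-regulator out-degrees (zero for query TFs absent from the
#' list — after top-k pruning, a queried TF may retain no edges at all).
#'
#' @param edges Edge data.frame.
#' @param query Character vector of regulator ids.
#' @return list with `edges` (the combined sub-network), `targets` (named
#'   list of per-regulator target vectors) and `out_degree` (named integer,
#'   including zeros).
#' @export
extract_subnetwork <- function(edges, query) {
  sub <- edges[edges$regulator %in% query, , drop = FALSE]
  rownames(sub) <- NULL
  targets <- lapply(stats::setNames(query, query), function(q) {
    sub$target[sub$regulator == q]
  })
  list(edges = sub, targets = targets,
       out_degree = vapply(targets, length, integer(1)))
}

#' Area under the precision-recall curve for a ranked edge list
#'
#' Average-precision form: the mean, over true edges, of the precision at
#' each true edge's rank; planted edges missing from the ranked list
#' contribute zero recall.
#'
#' @param edges Ranked edge data.frame (`regulator`, `target`, in rank
#'   order; if a `rank` column exists it is used).
#' @param true_edges data.frame of planted edges (`regulator`, `target`).
#' @return AUPR in \[0, 1\].
#' @export
edge_aupr <- function(edges, true_edges) {
  if ("rank" %in% names(edges)) edges <- edges[order(edges$rank), ]
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  truth <- unique(key(true_edges))
  hit <- key(edges) %in% truth
  precision_at_hit <- cumsum(hit)[hit] / which(hit)
  sum(precision_at_hit) / length(truth)
}
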