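# Tree-anchored subfamily assignment from reference-annotated leaves.

#' Assign subfamilies to query leaves from annotated references
#'
#' For each unannotated (query) leaf, walks from the leaf toward the root to
#' the smallest enclosing clade containing at least one reference leaf and
#' assigns the majority subgroup among that clade's references; ties give
#' `"ambiguous"`. Functional subgroup labels are typically the Arabidopsis
#' S1..S25 scheme, but any labels work.
#'
#' @param tree An `ape::phylo` object, a Newick string, or a path to a
#'   Newick file. Leaf labels must be unique.
#' @param reference_labels Named character vector: reference leaf label ->
#'   subgroup.
#' @return Named character vector: query leaf -> assigned subgroup (or
#'   `"ambiguous"`).
#' @export
assign_subfamily <- function(tree, reference_labels) {
  phy <- as_phylo(tree)
  if (anyDuplicated(phy$tip.label)) {
    stop("tree leaves must be unique", call. = FALSE)
  }
  refs <- names(reference_labels)
  missing_refs <- setdiff(refs, phy$tip.label)
  if (length(missing_refs)) {
    stop("reference leaves absent from tree: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  if (!length(refs)) stop("need at least one reference leaf", call. = FALSE)

  n_tip <- length(phy$tip.label)
  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]

  # tip sets per internal node, one postorder pass
  tipsets <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) tipsets[[i]] <- i
  edges <- phy$edge[ape::postorder(phy), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }

  ref_idx <- match(refs, phy$tip.label)
  queries <- setdiff(phy$tip.label, refs)
  out <- stats::setNames(character(length(queries)), queries)
  for (q in queries) {
    node <- match(q, phy$tip.label)
    label <- "ambiguous"
    repeat {
      node <- parent[node]
      hit <- intersect(tipsets[[node]], ref_idx)
      if (length(hit)) {
        groups <- reference_labels[phy$tip.label[hit]]
        tab <- sort(table(groups), decreasing = TRUE)
        label <- if (length(tab) > 1L && tab[1] == tab[2]) "ambiguous"
                 else names(tab)[1]
        break
      }
      if (node == root) break
    }
    out[q] <- label
  }
  out
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    text <- if (file.exists(tree)) {
      paste(readLines(tree, warn = FALSE), collapse = "")
    } else tree
    # shelter single-quoted labels (which may hold spaces or punctuation)
    quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
    labels <- substr(quoted, 2L, nchar(quoted) - 1L)
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], sprintf("QUOTEDLABEL%dX", i), text,
                  fixed = TRUE)
    }
    phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
    if (is.null(phy) || !inherits(phy, "phylo")) {
      stop("malformed Newick tree", call. = FALSE)
    }
    restore <- function(labs) {
      for (i in seq_along(labels)) {
        labs[labs == sprintf("QUOTEDLABEL%dX", i)] <- labels[i]
      }
      labs
    }
    phy$tip.label <- restore(phy$tip.label)
    if (!is.null(phy$node.label)) phy$node.label <- restore(phy$node.label)
    return(phy)
  }
  stop("`tree` must be a phylo object, Newick string or file path",
       call. = FALSE)
}
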