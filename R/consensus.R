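new_consensus_tree <- function(tree, freq_tbl, kind) {
  structure(list(tree = tree, frequencies = freq_tbl, kind = kind),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("%s consensus: %d leaves, %d clusters\n",
              x$kind, length(x$tree$tip.label), nrow(x$frequencies)))
  invisible(x)
}

#' @method tidy consensus_tree
#' @export
tidy.consensus_tree <- function(x, ...) x$frequencies

# tally cluster occurrence frequencies across a tree set
cluster_frequencies <- function(trees) {
  leaves <- trees[[1]]$tip.label
  for (t in trees[-1]) {
    if (!setequal(t$tip.label, leaves))
      stop("consensus requires identical leaf sets across trees")
  }
  keys <- unlist(lapply(trees, cluster_key_set))
  tab <- table(keys)
  tibble::tibble(
    clade = lapply(names(tab), key_to_labels),
    key = names(tab),
    count = as.integer(tab),
    frequency = as.integer(tab) / length(trees)
  )
}

#' Strict consensus of a tree set
#'
#' The tree containing exactly the clusters present in every input tree.
#' Always well-defined for trees drawn from a common search (clusters of
#' a common tree set are mutually compatible).
#'
#' @param trees list of `ape::phylo` trees on identical leaf sets (a
#'   `search_result` is also accepted).
#' @return a `consensus_tree` (all recorded frequencies are 1).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "search_result")) trees <- trees$trees
  stopifnot(length(trees) >= 1L)
  freqs <- cluster_frequencies(trees)
  keep <- freqs[freqs$count == length(trees), , drop = FALSE]
  tree <- tree_from_clusters(keep$clade, trees[[1]]$tip.label)
  new_consensus_tree(tree, keep, "strict")
}

#' Majority-rule consensus of a tree set
#'
#' The tree assembled from clusters occurring in strictly more than
#' `threshold` of the input trees (the standard 50% majority rule at the
#' default).  Such clusters are mutually compatible for any threshold of
#' at least 0.5.  Compatible minority clusters are never added (no
#' majority-rule-extended variant).
#'
#' @param trees list of `ape::phylo` trees on identical leaf sets (a
#'   `search_result` is also accepted).
#' @param threshold occurrence fraction that must be exceeded
#'   (default 0.5); values below 0.5 are rejected since compatibility is
#'   no longer guaranteed.
#' @return a `consensus_tree` with per-cluster frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "search_result")) trees <- trees$trees
  stopifnot(length(trees) >= 1L)
  if (threshold < 0.5)
    stop("majority threshold below 0.5 does not guarantee cluster compatibility")
  freqs <- cluster_frequencies(trees)
  keep <- freqs[freqs$frequency > threshold, , drop = FALSE]
  tree <- tree_from_clusters(keep$clade, trees[[1]]$tip.label)
  new_consensus_tree(tree, keep, "majority")
}

#' Write a consensus tree with frequency annotations
#'
#' Emits Newick with cluster frequencies (as percentages) as internal
#' node labels when `annotate = TRUE`.
#'
#' @param x a `consensus_tree`.
#' @param file output path (or `NULL` to return the string).
#' @param annotate add frequency labels to internal nodes.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_consensus <- function(x, file = NULL, annotate = FALSE) {
  tree <- x$tree
  if (annotate && nrow(x$frequencies) > 0) {
    n <- length(tree$tip.label)
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    node_keys <- vapply(pp, function(idx) cluster_key(labs[idx]), "")
    pct <- rep("", length(node_keys))
    hit <- match(node_keys, x$frequencies$key)
    pct[!is.na(hit)] <- sprintf("%.0f", 100 * x$frequencies$frequency[hit[!is.na(hit)]])
    tree$node.label <- pct
  }
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
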