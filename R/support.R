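#' Classify an input tree's relation to a supertree clade
#'
#' Restricting attention to the input tree's taxa, the clade's members
#' form `In` and the remaining supertree taxa form `Out`.  The tree is
#' irrelevant when it samples fewer than 2 members or no outside taxon;
#' it supports the clade when `In` is a clade of the input tree pruned
#' to `In + Out`; it conflicts when some cluster of the pruned tree
#' properly overlaps `In`; otherwise it permits the clade (for example
#' when the relevant region is an unresolved polytomy).
#'
#' @param input_tree an `ape::phylo` tree.
#' @param clade character vector of taxon labels (a supertree cluster).
#' @param supertree_leaves character vector: the supertree's full leaf
#'   set.
#' @return one of `"supports"`, `"conflicts"`, `"permits"`,
#'   `"irrelevant"`.
#' @export
classify_input_tree <- function(input_tree, clade, supertree_leaves) {
  leaves <- input_tree$tip.label
  In <- intersect(clade, leaves)
  Out <- intersect(setdiff(supertree_leaves, clade), leaves)
  if (length(In) < 2L || length(Out) < 1L) return("irrelevant")
  pruned <- prune_to(input_tree, c(In, Out))
  keys <- cluster_key_set(pruned)
  if (cluster_key(In) %in% keys) return("supports")
  for (k in keys) {
    X <- key_to_labels(k)
    inter <- length(intersect(X, In))
    if (inter > 0L && inter < length(X) && inter < length(In))
      return("conflicts")
  }
  "permits"
}

#' V and V+ support for one clade
#'
#' Counts input trees supporting (s), conflicting with (q) and
#' permitting (p) the clade, and computes the support indices
#' `V = (s - q) / (s + q)` and `V+ = (s + p - q) / (s + p + q)`.
#' Both run from -1 (the input-tree set offers no support: a novel
#' relationship) to +1 (full support).  `V` is undefined (NA) when
#' `s + q = 0`, `V+` when `s + p + q = 0`.  A clade is flagged novel
#' when both indices equal -1.  Each retained input tree counts once;
#' curation weights do not enter the counts unless `weighted = TRUE`.
#'
#' @param clade character vector of taxon labels.
#' @param trees an `input_tree_set` tibble or list of `ape::phylo`.
#' @param supertree_leaves the supertree's leaf set.
#' @param weighted count each tree by its curation weight instead
#'   of once.
#' @return one-row tibble: clade (list), s, q, p, irrelevant, V,
#'   V_plus, novel.
#' @export
v_index <- function(clade, trees, supertree_leaves, weighted = FALSE) {
  if (inherits(trees, "input_tree_set")) {
    w <- if (weighted) tree_weights(trees) else rep(1, nrow(trees))
    tr <- trees$tree
  } else {
    tr <- trees
    w <- rep(1, length(tr))
  }
  cls <- vapply(tr, classify_input_tree, "", clade = clade,
                supertree_leaves = supertree_leaves)
  s <- sum(w[cls == "supports"])
  q <- sum(w[cls == "conflicts"])
  p <- sum(w[cls == "permits"])
  r <- sum(w[cls == "irrelevant"])
  V <- if (s + q > 0) (s - q) / (s + q) else NA_real_
  Vp <- if (s + p + q > 0) (s + p - q) / (s + p + q) else NA_real_
  tibble::tibble(clade = list(sort(clade)), s = s, q = q, p = p,
                 irrelevant = r, V = V, V_plus = Vp,
                 novel = !is.na(V) && !is.na(Vp) && V == -1 && Vp == -1)
}

#' Score every clade of a supertree against the input trees
#'
#' One [v_index()] row per non-root internal cluster of the supertree;
#' the S4-file-like support table of a supertree analysis.
#'
#' @param supertree an `ape::phylo` tree (or `consensus_tree`).
#' @param trees an `input_tree_set` tibble or list of `ape::phylo`.
#' @param weighted see [v_index()].
#' @return tibble of class `clade_support`: clade (list column),
#'   clade_label, s, q, p, irrelevant, V, V_plus, novel.
#' @export
score_supertree <- function(supertree, trees, weighted = FALSE) {
  if (inherits(supertree, "consensus_tree")) supertree <- supertree$tree
  leaves <- supertree$tip.label
  rows <- lapply(tree_clusters(supertree), v_index, trees = trees,
                 supertree_leaves = leaves, weighted = weighted)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(clade = list(), s = numeric(), q = numeric(),
                          p = numeric(), irrelevant = numeric(),
                          V = numeric(), V_plus = numeric(),
                          novel = logical())
  out <- dplyr::mutate(out,
    clade_label = vapply(clade, paste, "", collapse = "+"), .after = "clade")
  class(out) <- c("clade_support", class(out))
  out
}

#' Collapse novel clades of a supertree into polytomies
#'
#' Clades supported by no input tree (`V = V+ = -1`) are spurious
#' artefacts of matrix interaction and should not be read as
#' phylogenetic results; this removes each one by reattaching its
#' children to the parent.
#'
#' @param supertree an `ape::phylo` tree (or `consensus_tree`).
#' @param scores a `clade_support` table computed for this supertree.
#' @return an `ape::phylo` tree with every novel clade collapsed.
#' @export
collapse_novel <- function(supertree, scores) {
  if (inherits(supertree, "consensus_tree")) supertree <- supertree$tree
  novel <- scores$clade[scores$novel]
  collapse_clusters(supertree, novel)
}

#' Write a clade-support table as CSV
#'
#' @param scores a `clade_support` tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_support_csv <- function(scores, file) {
  df <- dplyr::select(as.data.frame(scores), -"clade")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Plot clade support
#'
#' Bar chart of V (and V+) per supertree clade, novel clades
#' highlighted.
#'
#' @param object a `clade_support` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot clade_support
#' @export
autoplot.clade_support <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[!is.na(df$V), , drop = FALSE]
  df$clade_label <- stats::reorder(df$clade_label, df$V)
  long <- rbind(
    data.frame(clade_label = df$clade_label, index = "V", value = df$V,
               novel = df$novel),
    data.frame(clade_label = df$clade_label, index = "V+", value = df$V_plus,
               novel = df$novel)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$clade_label, y = .data$value,
                                     fill = .data$novel)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~index) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "support index", fill = "novel clade") +
    ggplot2::theme_minimal()
}
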