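#' Normalize taxon labels
#'
#' Trims surrounding whitespace and quotes and converts internal whitespace
#' to underscores so that names match across source studies regardless of
#' Newick quoting style.  Applied on every parse; no fuzzy synonym matching
#' is attempted (cross-study synonymy is the caller's responsibility, see
#' [run_pipeline()]'s rename table).
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_taxon_labels <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", trimws(x))
  gsub("\\s+", "_", x)
}

# Syntax pre-check so malformed input fails with a character offset instead
# of an opaque downstream error.  Quoted labels may contain parentheses.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quote_char <- ""
  semi_at <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quote_char != "") {
      if (ch == quote_char) quote_char <- ""
      next
    }
    if (ch %in% c("'", '"')) { quote_char <- ch; next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at character %d: unbalanced ')'", i))
    }
    if (ch == ";") { semi_at <- i; break }
  }
  if (quote_char != "")
    stop("newick parse error: unterminated quoted label")
  if (is.na(semi_at))
    stop(sprintf("newick parse error at character %d: missing terminating ';'",
                 length(chars)))
  if (depth != 0L)
    stop(sprintf("newick parse error at character %d: %d unclosed '('",
                 semi_at, depth))
  invisible(TRUE)
}

#' Parse a Newick string into a rooted tree
#'
#' Branch lengths and internal node labels are read and discarded: the
#' analyses in this package are purely topological.  Trees are treated as
#' rooted exactly as written (clade-based MRP coding presumes rootedness);
#' no rerooting is performed.  Unary nodes are suppressed and taxon labels
#' are normalized with [normalize_taxon_labels()].
#'
#' @param text a single Newick string, terminated by `;`.
#' @return an `ape::phylo` tree (polytomies preserved).
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tree_clusters(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop(sprintf("newick parse error: %s", conditionMessage(e)))
  )
  if (is.null(phy)) stop("newick parse error: could not read tree")
  validate_tree(phy)
}

# shared validation/normalization applied after any construction
validate_tree <- function(phy) {
  phy$edge.length <- NULL
  phy$node.label <- NULL
  if (length(phy$tip.label) < 2L)
    stop("a tree must have at least 2 leaves")
  phy <- ape::collapse.singles(phy)
  phy$tip.label <- normalize_taxon_labels(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("duplicate leaf labels: %s",
                 paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                       collapse = ", ")))
  if (length(phy$tip.label) < 2L)
    stop("a tree must have at least 2 leaves")
  phy
}

#' Write a tree as a Newick string
#'
#' Topology-only output; round-trips through [parse_newick()] with an
#' identical cluster set.
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional path; when given the string is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read one or more Newick trees from a file
#'
#' One tree per line (blank lines ignored).
#'
#' @param file path to a UTF-8 Newick file.
#' @return a list of `ape::phylo` trees.
#' @export
read_newick <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick)
}

#' Clusters (clades) of a rooted tree
#'
#' One cluster per internal node excluding the root; singleton leaves are
#' not clusters.  A star tree therefore has an empty cluster set.
#'
#' @param tree an `ape::phylo` tree.
#' @return a list of character vectors (sorted taxon labels), possibly empty.
#' @export
tree_clusters <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- list()
  for (cl in pp) {
    if (length(cl) >= 2L && length(cl) < n)
      out[[length(out) + 1L]] <- sort(labs[cl])
  }
  out
}

# keys of tree_clusters(), the working representation for set algebra
cluster_key_set <- function(tree) {
  vapply(tree_clusters(tree), function(cl) paste(cl, collapse = "\r"), "")
}

#' Restrict a tree to a taxon set
#'
#' Prunes the tree to `taxa` intersected with its leaves, suppressing unary
#' nodes.  Returns `NULL` when fewer than 2 leaves remain.
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa character vector of taxon labels to keep.
#' @return an `ape::phylo` tree or `NULL`.
#' @export
prune_to <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) < 2L) return(NULL)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Robinson-Foulds distance between two rooted trees
#'
#' The size of the symmetric difference of the two cluster sets (rooted
#' clades, not unrooted bipartitions).  Both trees must carry the same
#' leaf set.
#'
#' @param t1,t2 `ape::phylo` trees on identical leaf sets.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop(sprintf("leaf sets differ: only in first (%s); only in second (%s)",
                 paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
                 paste(setdiff(t2$tip.label, t1$tip.label), collapse = ",")))
  k1 <- cluster_key_set(t1)
  k2 <- cluster_key_set(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# ---- internal recursive representation for structural surgery ------------
# A "treelist" is either list(label = <chr>) for a leaf or
# list(children = list(...)) for an internal node.

as_treelist <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  build <- function(node) {
    if (node <= n) return(list(label = phy$tip.label[node]))
    list(children = lapply(kids[[as.character(node)]], build))
  }
  build(root)
}

tl_is_leaf <- function(x) !is.null(x$label)

tl_newick <- function(x) {
  if (tl_is_leaf(x)) return(x$label)
  paste0("(", paste(vapply(x$children, tl_newick, ""), collapse = ","), ")")
}

treelist_to_phylo <- function(x) parse_newick(paste0(tl_newick(x), ";"))

tl_leaves <- function(x) {
  if (tl_is_leaf(x)) return(x$label)
  unlist(lapply(x$children, tl_leaves))
}

#' Collapse named clades into polytomies
#'
#' Removes the internal node of every cluster listed, reattaching its
#' children to the parent.  Clusters are matched by their exact leaf set.
#'
#' @param tree an `ape::phylo` tree.
#' @param clusters list of character vectors (leaf sets of clades to
#'   collapse); clusters not present in the tree are ignored.
#' @return an `ape::phylo` tree.
#' @export
collapse_clusters <- function(tree, clusters) {
  if (length(clusters) == 0L) return(tree)
  keys <- vapply(clusters, cluster_key, "")
  tl <- as_treelist(tree)
  walk <- function(node) {
    if (tl_is_leaf(node)) return(list(node))
    kids <- unlist(lapply(node$children, walk), recursive = FALSE)
    node$children <- kids
    if (cluster_key(tl_leaves(node)) %in% keys) return(node$children)
    list(node)
  }
  new_kids <- unlist(lapply(tl$children, walk), recursive = FALSE)
  treelist_to_phylo(list(children = new_kids))
}

#' Assemble a tree from a compatible cluster set
#'
#' Builds the unique rooted tree whose non-trivial clades are exactly
#' `clusters` (which must be pairwise nested or disjoint).
#'
#' @param clusters list of character vectors, each a proper subset of
#'   `leaves` with >= 2 members; may be empty (gives a star tree).
#' @param leaves character vector of all leaf labels (>= 2).
#' @return an `ape::phylo` tree.
#' @export
tree_from_clusters <- function(clusters, leaves) {
  stopifnot(length(leaves) >= 2L)
  clusters <- unique(lapply(clusters, sort))
  for (cl in clusters) {
    if (length(cl) < 2L || length(cl) >= length(leaves) ||
        !all(cl %in% leaves))
      stop("each cluster must be a proper subset of the leaves with >= 2 members")
  }
  sizes <- vapply(clusters, length, 0L)
  ord <- order(sizes)
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  # pairwise compatibility
  if (length(clusters) >= 2L) {
    for (i in seq_along(clusters)[-1]) {
      for (j in seq_len(i - 1L)) {
        inter <- length(intersect(clusters[[i]], clusters[[j]]))
        if (inter > 0L && inter < sizes[j] && inter < sizes[i])
          stop("clusters are not mutually compatible")
      }
    }
  }
  # parent of each item (leaf or cluster) = smallest strictly containing cluster
  n_cl <- length(clusters)
  emit <- function(members, available) {
    # available: indices of clusters that are subsets of members (strict)
    direct_cl <- integer(0)
    covered <- character(0)
    for (i in rev(available)) {      # largest first
      if (!any(clusters[[i]] %in% covered)) {
        direct_cl <- c(direct_cl, i)
        covered <- c(covered, clusters[[i]])
      }
    }
    free_leaves <- setdiff(members, covered)
    parts <- character(0)
    for (i in direct_cl) {
      sub_avail <- available[vapply(available, function(j)
        length(clusters[[j]]) < length(clusters[[i]]) &&
          all(clusters[[j]] %in% clusters[[i]]), TRUE)]
      parts <- c(parts, emit(clusters[[i]], sub_avail))
    }
    parts <- c(parts, free_leaves)
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- emit(sort(leaves), seq_len(n_cl))
  if (!startsWith(txt, "(")) txt <- paste0("(", txt, ")")
  parse_newick(paste0(txt, ";"))
}
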