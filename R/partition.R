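#' Declare nested data partitions
#'
#' Partitioning replaces a named clade by a single placeholder taxon in
#' the trees of every enclosing analysis, so that a sparse matrix can be
#' analysed in well-overlapping pieces (e.g. a family, its superfamily
#' with the family as one taxon, and the remaining taxa with the
#' superfamily as one taxon).  Sets are listed innermost first and must
#' be pairwise nested or disjoint; partition names double as placeholder
#' taxon labels, and the monophyly of each named set is guaranteed in
#' the final supertree by construction (such clades receive no V score).
#'
#' @param ... named character vectors: `name = c(taxa...)`, innermost
#'   first; each set needs at least 3 members.
#' @return a list of class `partition_spec`.
#' @export
partition_spec <- function(...) {
  sets <- list(...)
  if (length(sets) == 0L) stop("at least one partition set is required")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("partition sets must have unique names")
  for (s in sets) {
    if (length(s) < 3L) stop("each partition set needs at least 3 members")
  }
  sizes <- vapply(sets, length, 0L)
  if (is.unsorted(sizes)) {
    # order innermost (smallest) first, preserving ties
    sets <- sets[order(sizes)]
    nm <- names(sets)
  }
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      if (inter > 0L && inter < length(sets[[j]]))
        stop(sprintf("partition sets '%s' and '%s' are neither nested nor disjoint",
                     nm[j], nm[i]))
    }
  }
  structure(sets, class = "partition_spec")
}

#' Replace a clade by a placeholder leaf in one tree
#'
#' All members present in the tree are pruned and a single leaf `name`
#' is attached in their place: on the members' stem edge when they are
#' monophyletic in the tree, otherwise (with a warning, or an error in
#' strict mode) as a child of the parent of their most recent common
#' ancestor.  Trees containing no members are returned unchanged.
#'
#' @param tree an `ape::phylo` tree.
#' @param name placeholder taxon label.
#' @param members character vector of taxon labels.
#' @param strict error instead of warning when the members are not
#'   monophyletic in the tree.
#' @return an `ape::phylo` tree (possibly unchanged), or `NULL` when
#'   fewer than 2 leaves would remain.
#' @export
reduce_tree <- function(tree, name, members, strict = FALSE) {
  present <- intersect(tree$tip.label, members)
  if (length(present) == 0L) return(tree)
  if (length(present) == length(tree$tip.label)) return(NULL)
  if (length(present) == 1L) {
    tree$tip.label[tree$tip.label == present] <- name
    return(tree)
  }
  keys <- cluster_key_set(tree)
  if (cluster_key(present) %in% keys) {
    # placeholder takes the position of the monophyletic group: keep one
    # representative and rename it
    rep_taxon <- present[1]
    pruned <- prune_to(tree, setdiff(tree$tip.label, setdiff(present, rep_taxon)))
    if (is.null(pruned)) return(NULL)
    pruned$tip.label[pruned$tip.label == rep_taxon] <- name
    return(pruned)
  }
  msg <- sprintf("members of '%s' are not monophyletic in tree (%s); placeholder attached at the parent of their MRCA",
                 name, paste(present, collapse = ","))
  if (strict) stop(msg)
  warning(msg)
  # attachment context: the parent of the members' MRCA, identified by
  # its remaining (non-member) leaf content
  tl <- as_treelist(tree)
  mrca_parent_rest <- NULL
  find <- function(node, parent_leaves) {
    if (tl_is_leaf(node)) return(invisible())
    lv <- tl_leaves(node)
    if (all(present %in% lv)) {
      # node contains all members; descend if a child also does
      for (ch in node$children) {
        chl <- if (tl_is_leaf(ch)) ch$label else tl_leaves(ch)
        if (all(present %in% chl)) {
          find(ch, setdiff(lv, chl))
          return(invisible())
        }
      }
      # node is the MRCA; its parent's context is parent_leaves + this node
      mrca_parent_rest <<- setdiff(lv, present)
    }
  }
  find(tl, character(0))
  rest <- setdiff(tree$tip.label, present)
  pruned <- prune_to(tree, rest)
  if (is.null(pruned)) {
    # everything outside the members was within the MRCA; star with placeholder
    if (length(rest) == 0L) return(NULL)
    return(parse_newick(paste0("(", paste(c(rest, name), collapse = ","), ");")))
  }
  attach_placeholder(pruned, name, mrca_parent_rest)
}

# attach a new leaf `name` as a child of the smallest cluster of `tree`
# containing all of `context` (the root if context is empty/oversized)
attach_placeholder <- function(tree, name, context) {
  tl <- as_treelist(tree)
  context <- intersect(context, tree$tip.label)
  ins <- function(node) {
    if (tl_is_leaf(node)) return(NULL)
    for (i in seq_along(node$children)) {
      ch <- node$children[[i]]
      chl <- if (tl_is_leaf(ch)) ch$label else tl_leaves(ch)
      if (length(context) > 0L && all(context %in% chl)) {
        sub <- ins(ch)
        if (!is.null(sub)) {
          node$children[[i]] <- sub
          return(node)
        }
        if (tl_is_leaf(ch)) {
          node$children[[i]] <- list(children = list(ch, list(label = name)))
        } else {
          ch$children <- c(ch$children, list(list(label = name)))
          node$children[[i]] <- ch
        }
        return(node)
      }
    }
    NULL
  }
  res <- ins(tl)
  if (is.null(res)) {
    tl$children <- c(tl$children, list(list(label = name)))
    res <- tl
  }
  treelist_to_phylo(res)
}

#' Graft a sub-supertree onto a backbone placeholder
#'
#' The leaf `name` of the backbone is replaced by the subtree's root, so
#' the grafted taxa form a clade of the result (the constrained
#' monophyly that justified partitioning).
#'
#' @param backbone an `ape::phylo` tree containing leaf `name`.
#' @param name placeholder leaf label.
#' @param subtree an `ape::phylo` tree; leaves must be disjoint from the
#'   backbone's.
#' @return an `ape::phylo` tree with
#'   `|backbone| - 1 + |subtree|` leaves.
#' @export
graft <- function(backbone, name, subtree) {
  if (!(name %in% backbone$tip.label))
    stop(sprintf("backbone has no placeholder leaf '%s'", name))
  if (length(intersect(backbone$tip.label[backbone$tip.label != name],
                       subtree$tip.label)) > 0L)
    stop("subtree leaves must be disjoint from backbone leaves")
  tl <- as_treelist(backbone)
  sub <- as_treelist(subtree)
  swap <- function(node) {
    if (tl_is_leaf(node)) {
      if (identical(node$label, name)) return(sub)
      return(node)
    }
    node$children <- lapply(node$children, swap)
    node
  }
  treelist_to_phylo(swap(tl))
}

#' Run a partitioned supertree analysis
#'
#' Solves each named partition separately -- innermost first, with every
#' directly nested partition reduced to its placeholder -- then a
#' backbone analysis over the remaining taxa with the outermost
#' partitions as placeholders, and grafts the partition supertrees back
#' into the backbone.  Each partition runs the full encode-search-
#' consensus-support chain on its own reduced tree set.
#'
#' @param trees a curated `input_tree_set` tibble.
#' @param spec a [partition_spec()].
#' @param config a [search_config()].
#' @param consensus_threshold majority-rule threshold (default 0.5).
#' @param strict_reduce error on non-monophyletic placeholder members
#'   (default FALSE: warn and attach at the MRCA's parent).
#' @return list with `partitions` (named list of per-partition results:
#'   trees used, search, strict/majority consensus, support table) and
#'   `supertree` (the grafted majority-rule supertree).
#' @export
run_partitioned <- function(trees, spec, config = search_config(),
                            consensus_threshold = 0.5,
                            strict_reduce = FALSE) {
  stopifnot(inherits(spec, "partition_spec"))
  taxa_all <- all_taxa(trees)
  part_names <- names(spec)

  # j is a direct child of i when spec_j is nested in spec_i with no
  # partition strictly in between
  is_nested <- function(j, i) j != i && all(spec[[j]] %in% spec[[i]])
  direct_children <- function(i) {
    cand <- Filter(function(j) is_nested(j, i), seq_along(spec))
    Filter(function(j) !any(vapply(cand, function(k)
      k != j && is_nested(j, k), TRUE)), cand)
  }

  # membership universe of each analysis: own members, with directly
  # nested partitions replaced by their placeholder names
  analyses <- list()
  for (i in seq_along(spec)) {
    inner <- part_names[unlist(direct_children(i))]
    absorbed <- unlist(spec[match(inner, part_names)], use.names = FALSE)
    analyses[[part_names[i]]] <- c(setdiff(spec[[i]], absorbed), inner)
  }
  # backbone: everything outside the outermost partitions; when a
  # partition already covers every taxon the backbone is degenerate and
  # that partition's supertree is the final tree
  outermost <- part_names[vapply(seq_along(spec), function(i) {
    !any(vapply(seq_along(spec), function(j) is_nested(i, j), TRUE))
  }, TRUE)]
  absorbed <- unlist(spec[match(outermost, part_names)], use.names = FALSE)
  backbone_universe <- c(setdiff(taxa_all, absorbed), outermost)
  has_backbone <- length(backbone_universe) >= 4L
  if (has_backbone) analyses[["backbone"]] <- backbone_universe

  results <- list()
  for (an in names(analyses)) {
    universe <- analyses[[an]]
    placeholders <- intersect(universe, part_names)
    red <- trees
    keep <- rep(TRUE, nrow(red))
    for (i in seq_len(nrow(red))) {
      t <- red$tree[[i]]
      for (ph in placeholders)
        if (!is.null(t)) t <- reduce_tree(t, ph, spec[[ph]], strict = strict_reduce)
      t <- if (is.null(t)) NULL else prune_to(t, universe)
      if (is.null(t) || length(t$tip.label) < 3L ||
          length(tree_clusters(t)) == 0L) {
        keep[i] <- FALSE
      } else {
        red$tree[[i]] <- t
        red$n_taxa[i] <- length(t$tip.label)
      }
    }
    red <- red[keep, , drop = FALSE]
    eff_taxa <- all_taxa(red)
    if (length(eff_taxa) < 4L)
      stop(sprintf("partition '%s' has fewer than 4 effective taxa; no informative search possible", an))
    m <- encode_matrix(red)
    sr <- heuristic_search(m, config)
    strict <- strict_consensus(sr)
    maj <- majority_consensus(sr, consensus_threshold)
    supp <- score_supertree(maj, red)
    # constrained placeholder leaves get no V score by construction
    results[[an]] <- list(trees = red, matrix = m, search = sr,
                          strict = strict, majority = maj, support = supp)
  }

  # graft outermost-in until no placeholder leaves remain
  supertree <- if (has_backbone) results[["backbone"]]$majority$tree
    else results[[outermost[1]]]$majority$tree
  repeat {
    todo <- intersect(part_names, supertree$tip.label)
    if (length(todo) == 0L) break
    for (nm in todo)
      supertree <- graft(supertree, nm, results[[nm]]$majority$tree)
  }
  list(partitions = results, supertree = supertree)
}
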