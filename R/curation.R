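#' Taxon-overlap fractions between two trees
#'
#' The fraction of each tree's taxa shared with the other.  The curation
#' protocol treats two trees built from the same data type as
#' pseudoreplicated when either fraction exceeds 0.5, i.e. both trees are
#' retained only when at least half the taxa in each are absent from the
#' other.
#'
#' @param t1,t2 `ape::phylo` trees.
#' @return numeric length-2 vector `(f1, f2)` with
#'   `f_i = |shared| / |taxa of tree i|`.
#' @export
overlap_fractions <- function(t1, t2) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  shared <- length(intersect(l1, l2))
  c(shared / length(l1), shared / length(l2))
}

new_curation_report <- function(trees = NULL, taxa = NULL, n_components = NA_integer_) {
  trees <- trees %||% tibble::tibble(tree_id = character(), study_id = character(),
                                     status = character(), reason = character(),
                                     weight_num = integer(), weight_den = integer())
  taxa <- taxa %||% tibble::tibble(taxon = character(), reason = character())
  structure(list(trees = trees, taxa = taxa, n_components = n_components),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  kept <- sum(x$trees$status == "retained")
  cat(sprintf("Curation report: %d trees retained, %d discarded; %d taxa removed",
              kept, sum(x$trees$status == "discarded"), nrow(x$taxa)))
  if (!is.na(x$n_components))
    cat(sprintf("; overlap graph components: %d", x$n_components))
  cat("\n")
  invisible(x)
}

#' Reduce pseudoreplication among input trees
#'
#' Trees sharing at least one data-type tag whose taxon overlap exceeds 50%
#' in either direction are treated as built from the same underlying data.
#' Violating pairs are closed transitively into conflict sets (so the
#' outcome does not depend on comparison order) and within each set the
#' most comprehensive tree (largest published leaf count) is kept at full
#' weight; when the largest trees tie -- typically alternative trees from
#' one study -- all n tied trees are kept, each at weight 1/n.  Trees in
#' no conflict set keep weight 1.
#'
#' @param trees an `input_tree_set` tibble; every row must carry at least
#'   one data-type tag.
#' @return list with elements `trees` (retained rows, weights updated) and
#'   `report` (a `curation_report`).
#' @export
resolve_pseudoreplication <- function(trees) {
  n <- nrow(trees)
  no_tag <- vapply(trees$data_types, length, 0L) == 0L
  if (any(no_tag))
    stop(sprintf("missing data-type tags for tree(s): %s",
                 paste(trees$tree_id[no_tag], collapse = ", ")))
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (length(intersect(trees$data_types[[i]], trees$data_types[[j]])) == 0L)
          next
        f <- overlap_fractions(trees$tree[[i]], trees$tree[[j]])
        if (f[1] > 0.5 || f[2] > 0.5)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]

  keep <- rep(TRUE, n)
  wnum <- rep(1L, n)
  wden <- rep(1L, n)
  reason <- rep(NA_character_, n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2L) next
    sizes <- trees$n_taxa[idx]
    top <- idx[sizes == max(sizes)]
    drop <- setdiff(idx, top)
    keep[drop] <- FALSE
    reason[drop] <- "pseudoreplicate_dropped"
    if (length(top) > 1L) wden[top] <- length(top)
  }
  report <- new_curation_report(trees = tibble::tibble(
    tree_id = trees$tree_id, study_id = trees$study_id,
    status = ifelse(keep, "retained", "discarded"),
    reason = reason, weight_num = wnum, weight_den = wden
  ))
  out <- trees[keep, , drop = FALSE]
  out$weight_num <- wnum[keep]
  out$weight_den <- wden[keep]
  list(trees = out, report = report)
}

#' Remove taxa occurring in only one input tree
#'
#' A taxon seen in a single tree cannot be placed relative to the other
#' trees and is pruned.  Pruning that leaves a tree with fewer than 3
#' leaves drops the tree (a 2-leaf rooted tree carries no parsimony
#' character), after which the occurrence census is recomputed; the rule
#' is applied to a fixed point.
#'
#' @param trees an `input_tree_set` tibble (after pseudoreplication
#'   resolution, so counts reflect the final tree set).
#' @return list with `trees` (pruned collection) and `report`.
#' @export
remove_singletons <- function(trees) {
  removed_taxa <- tibble::tibble(taxon = character(), reason = character())
  dropped <- tibble::tibble(tree_id = character(), study_id = character(),
                            status = character(), reason = character(),
                            weight_num = integer(), weight_den = integer())
  repeat {
    census <- table(unlist(lapply(trees$tree, function(t) unique(t$tip.label))))
    singletons <- names(census)[census == 1L]
    if (length(singletons) == 0L) break
    removed_taxa <- dplyr::bind_rows(removed_taxa,
      tibble::tibble(taxon = singletons, reason = "singleton"))
    keep_rows <- rep(TRUE, nrow(trees))
    for (i in seq_len(nrow(trees))) {
      t <- trees$tree[[i]]
      if (!any(singletons %in% t$tip.label)) next
      pruned <- prune_to(t, setdiff(t$tip.label, singletons))
      if (is.null(pruned) || length(pruned$tip.label) < 3L) {
        keep_rows[i] <- FALSE
      } else {
        trees$tree[[i]] <- pruned
        trees$n_taxa[i] <- length(pruned$tip.label)
      }
    }
    if (any(!keep_rows)) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        tree_id = trees$tree_id[!keep_rows], study_id = trees$study_id[!keep_rows],
        status = "discarded", reason = "too_few_leaves",
        weight_num = trees$weight_num[!keep_rows],
        weight_den = trees$weight_den[!keep_rows]))
      trees <- trees[keep_rows, , drop = FALSE]
    }
  }
  report <- new_curation_report(trees = dropped, taxa = removed_taxa)
  list(trees = trees, report = report)
}

#' Overlap-graph connectivity of an input-tree collection
#'
#' Two trees are connected when they share at least 2 taxa, the minimum
#' for one tree to carry information about relationships in the other.
#' A supertree over a disconnected collection is necessarily unresolved
#' across components, so more than one component triggers a warning.
#'
#' @param trees an `input_tree_set` tibble.
#' @return list of character vectors of tree ids, one per connected
#'   component.
#' @export
connectivity_check <- function(trees) {
  n <- nrow(trees)
  if (n == 0L) return(list())
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (length(intersect(trees$tree[[i]]$tip.label,
                             trees$tree[[j]]$tip.label)) >= 2L)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(n)]
  comps <- lapply(sort(unique(memb)), function(m) trees$tree_id[memb == m])
  if (length(comps) > 1L)
    warning(sprintf(paste0("input trees form %d disconnected overlap ",
                           "components; the supertree will be unresolved ",
                           "across components"), length(comps)))
  comps
}

#' Identify under-represented taxa from matrix fill statistics
#'
#' Taxa present in fewer than `min_trees` retained trees or with fewer
#' than `min_cells` informative (non-missing) matrix cells carry too
#' little signal to be placed and are flagged for removal.
#'
#' @param fill_stats per-taxon tibble from [matrix_fill_stats()].
#' @param min_trees minimum number of source trees per taxon (default 2).
#' @param min_cells minimum number of non-missing cells per taxon
#'   (default 2).
#' @return character vector of taxa to remove (possibly empty).
#' @export
representation_filter <- function(fill_stats, min_trees = 2, min_cells = 2) {
  tx <- fill_stats$per_taxon
  tx <- tx[tx$taxon != "MRP_OUTGROUP", , drop = FALSE]
  tx$taxon[tx$n_trees < min_trees | tx$n_nonmissing < min_cells]
}

#' Run the full curation protocol
#'
#' Pseudoreplication resolution, then singleton removal to a fixed point,
#' then the connectivity check, with all actions merged into one
#' exhaustive report (every input tree and removed taxon is accounted
#' for exactly once).
#'
#' @param trees an `input_tree_set` tibble.
#' @return list with `trees` (curated collection) and `report`.
#' @export
curate <- function(trees) {
  ps <- resolve_pseudoreplication(trees)
  sg <- remove_singletons(ps$trees)
  comps <- connectivity_check(sg$trees)
  tr_report <- ps$report$trees
  if (nrow(sg$report$trees) > 0) {
    dropped_ids <- sg$report$trees$tree_id
    tr_report$status[tr_report$tree_id %in% dropped_ids] <- "discarded"
    tr_report$reason[tr_report$tree_id %in% dropped_ids] <- "too_few_leaves"
  }
  report <- new_curation_report(trees = tr_report, taxa = sg$report$taxa,
                                n_components = length(comps))
  list(trees = sg$trees, report = report, components = comps)
}
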