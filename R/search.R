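#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Configuration for the heuristic parsimony search
#'
#' @param n_reps random addition-sequence replicates (default 1000).
#' @param swap branch-swapping neighbourhood: `"TBR"` (default), `"SPR"`
#'   or `"NNI"`.
#' @param seed integer seed; if `NULL` one is drawn and reported.
#' @param max_trees cap on the number of most-parsimonious trees
#'   collected (default 10000); hitting it sets a flag on the result.
#' @param constraints list of character vectors: taxon sets to hold
#'   monophyletic.  Sets must be pairwise nested or disjoint.
#' @return a list of class `search_config`.
#' @export
search_config <- function(n_reps = 1000, swap = c("TBR", "SPR", "NNI"),
                          seed = NULL, max_trees = 10000,
                          constraints = list()) {
  swap <- match.arg(swap)
  stopifnot(n_reps >= 1, max_trees >= 1)
  check_constraint_nesting(constraints)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message(sprintf("search_config: no seed supplied, drew seed = %d", seed))
  }
  structure(list(n_reps = as.integer(n_reps), swap = swap,
                 seed = as.integer(seed), max_trees = as.integer(max_trees),
                 constraints = constraints),
            class = "search_config")
}

check_constraint_nesting <- function(constraints) {
  if (length(constraints) < 2L) return(invisible(TRUE))
  for (i in seq_along(constraints)[-1]) {
    for (j in seq_len(i - 1L)) {
      a <- constraints[[i]]; b <- constraints[[j]]
      inter <- length(intersect(a, b))
      if (inter > 0L && inter < length(a) && inter < length(b))
        stop("constraint sets must be pairwise nested or disjoint")
    }
  }
  invisible(TRUE)
}

# state masks for the C++ engine: "0" -> 1, "1" -> 2, "?" -> 3
states_matrix <- function(m) {
  mm <- m$matrix
  st <- matrix(3L, nrow(mm), ncol(mm), dimnames = dimnames(mm))
  st[mm == "0"] <- 1L
  st[mm == "1"] <- 2L
  st
}

# Monophyly constraints are enforced through high-weight indicator
# characters: a set that is monophyletic costs exactly one step on its
# indicator, anything else costs more, so with weight > total data weight
# every optimal tree satisfies all satisfiable constraints.  The penalty
# is subtracted from reported scores.
with_constraint_chars <- function(st, w, taxa, constraints) {
  n_eff <- 0L
  big <- sum(w) + 1
  for (cs in constraints) {
    members <- intersect(taxa, cs)
    if (length(members) < 2L || length(members) >= length(taxa) - 1L) next
    col <- rep(1L, length(taxa))
    col[taxa %in% members] <- 2L
    st <- cbind(st, col)
    w <- c(w, big)
    n_eff <- n_eff + 1L
  }
  list(states = st, weights = w, n_eff = n_eff, big = big)
}

#' Weighted Fitch parsimony score of a tree on an MRP matrix
#'
#' Sums, over characters, the character weight times the minimum number
#' of state changes on the tree, with `?` treated as the full ambiguity
#' set.  Computed by the exact two-state dynamic program, which handles
#' multifurcating trees.
#'
#' @param tree an `ape::phylo` tree whose leaves are exactly the matrix
#'   taxa (including `MRP_OUTGROUP`).
#' @param m an `mrp_matrix`.
#' @param per_character if `TRUE`, also return unweighted step counts.
#' @return the score as a numeric (exactly representable: an integer
#'   divided by the common weight denominator), with attributes `num`
#'   and `den` giving the exact rational.  With `per_character = TRUE`,
#'   a list with `score` and integer `steps`.
#' @export
fitch_score <- function(tree, m, per_character = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "mrp_matrix"))
  taxa <- rownames(m$matrix)
  if (!setequal(tree$tip.label, taxa))
    stop(sprintf("tree/matrix taxa mismatch: only in tree (%s); only in matrix (%s)",
                 paste(setdiff(tree$tip.label, taxa), collapse = ","),
                 paste(setdiff(taxa, tree$tip.label), collapse = ",")))
  sw <- scaled_weights(m)
  st <- states_matrix(m)[tree$tip.label, , drop = FALSE]
  res <- cpp_fitch_rooted(tree$edge, length(tree$tip.label), st, sw$weights)
  score <- res$total / sw$denom
  attr(score, "num") <- res$total
  attr(score, "den") <- sw$denom
  if (per_character) return(list(score = score, steps = res$steps))
  score
}

new_search_result <- function(trees, score_num, score_den, reps_completed,
                              hit_max_trees) {
  score <- score_num / score_den
  structure(list(trees = trees, best_score = score,
                 score_num = score_num, score_den = score_den,
                 reps_completed = reps_completed,
                 hit_max_trees = hit_max_trees),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Parsimony search: %d MPT(s), best score %s%s\n",
              length(x$trees),
              format(x$best_score),
              if (isTRUE(x$hit_max_trees)) " (max_trees hit)" else ""))
  invisible(x)
}

#' @method glance search_result
#' @export
glance.search_result <- function(x, ...) {
  tibble::tibble(n_mpts = length(x$trees), best_score = x$best_score,
                 reps_completed = x$reps_completed,
                 hit_max_trees = x$hit_max_trees)
}

# shared post-processing of the C++ search output
finalize_search <- function(res, m, constraints, cc, reps, hit_extra = FALSE) {
  sw <- scaled_weights(m)
  trees <- lapply(as.character(res$trees), parse_newick)
  ok <- vapply(trees, enforce_constraints, TRUE, constraints = constraints)
  if (!all(ok))
    stop("internal error: search returned a constraint-violating tree")
  score_num <- res$score - cc$n_eff * cc$big
  new_search_result(trees, score_num, sw$denom, reps,
                    isTRUE(res$hit_max_trees) || hit_extra)
}

#' Exhaustive parsimony search (small problems)
#'
#' Enumerates every unrooted binary topology (equivalently, every rooted
#' topology once the outgroup is fixed) by branch-and-bound and returns
#' all optima.  Intended as an exact oracle; limited to 9 taxa including
#' the outgroup.
#'
#' @param m an `mrp_matrix`.
#' @param constraints list of taxon sets to hold monophyletic.
#' @return a `search_result`; trees have the outgroup removed.
#' @export
exhaustive_search <- function(m, constraints = list()) {
  taxa <- rownames(m$matrix)
  if (length(taxa) > 9L)
    stop("too many taxa for exhaustive enumeration (> 9 including outgroup); use heuristic_search()")
  if (length(taxa) < 4L)
    stop("exhaustive search needs at least 3 ingroup taxa")
  check_constraint_nesting(constraints)
  sw <- scaled_weights(m)
  cc <- with_constraint_chars(states_matrix(m), sw$weights, taxa, constraints)
  res <- cpp_exhaustive_search(cc$states, cc$weights, taxa,
                               which(taxa == "MRP_OUTGROUP") - 1L)
  finalize_search(res, m, constraints, cc, reps = NA_integer_)
}

#' Heuristic parsimony search
#'
#' For each replicate, taxa are added in a random order by stepwise
#' addition (each insertion point chosen to minimize the score, ties
#' broken by the replicate's seeded randomness), followed by
#' first-improvement branch swapping in the configured neighbourhood.
#' All distinct topologies at the final best score are collected by
#' closing the best set under equal-score swaps, subject to
#' `max_trees`.  Deterministic given the seed.
#'
#' @param m an `mrp_matrix`.
#' @param config a [search_config()].
#' @return a `search_result`; trees have the outgroup removed.
#' @export
heuristic_search <- function(m, config = search_config()) {
  stopifnot(inherits(m, "mrp_matrix"), inherits(config, "search_config"))
  taxa <- rownames(m$matrix)
  if (length(taxa) < 4L)
    stop("heuristic search needs at least 3 ingroup taxa")
  sw <- scaled_weights(m)
  cc <- with_constraint_chars(states_matrix(m), sw$weights, taxa,
                              config$constraints)
  lower_bound <- sum(cc$weights)
  res <- cpp_heuristic_search(cc$states, cc$weights, taxa,
                              which(taxa == "MRP_OUTGROUP") - 1L,
                              config$n_reps, config$swap, config$max_trees,
                              config$seed %% 2147483647L, lower_bound)
  finalize_search(res, m, config$constraints, cc, reps = res$reps_completed)
}

#' Test whether a tree satisfies monophyly constraints
#'
#' A constrained taxon set (restricted to the tree's leaves) must be a
#' cluster of the tree, a single leaf, empty, or the entire leaf set.
#'
#' @param tree an `ape::phylo` tree.
#' @param constraints list of character vectors.
#' @return `TRUE` or `FALSE`.
#' @export
enforce_constraints <- function(tree, constraints) {
  if (length(constraints) == 0L) return(TRUE)
  keys <- cluster_key_set(tree)
  for (cs in constraints) {
    members <- intersect(tree$tip.label, cs)
    if (length(members) <= 1L || length(members) == length(tree$tip.label))
      next
    if (!(cluster_key(members) %in% keys)) return(FALSE)
  }
  TRUE
}
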