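# shared fixture builders and independent oracles

# input_tree_set from newick strings
its_from_newick <- function(newicks, tags = NULL, ...) {
  trees <- lapply(newicks, parse_newick)
  tags <- tags %||% as.list(paste0("tag", seq_along(trees)))
  input_tree_set(trees, data_types = tags, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mrp_matrix built directly from a character matrix (rows = taxa incl
# MRP_OUTGROUP, entries "0"/"1"/"?") -- for search tests on raw matrices
make_mrp <- function(mat, wnum = rep(1L, ncol(mat)),
                     wden = rep(1L, ncol(mat))) {
  colnames(mat) <- sprintf("c%04d", seq_len(ncol(mat)))
  structure(list(matrix = mat, char_tree_id = rep("fix", ncol(mat)),
                 char_cluster = vector("list", ncol(mat)),
                 weight_num = as.integer(wnum), weight_den = as.integer(wden)),
            class = "mrp_matrix")
}

# Independent minimum-changes oracle: enumerate every assignment of 0/1
# to internal nodes and to ambiguous leaves, count edge changes, take the
# minimum.  Exponential, for tiny trees only; shares no code with the
# package's dynamic program.
oracle_char_steps <- function(tree, states) {
  n <- length(tree$tip.label)
  nodes <- sort(unique(as.vector(tree$edge)))
  internal <- nodes[nodes > n]
  leaf_states <- states[tree$tip.label]
  free_leaves <- which(is.na(leaf_states))
  n_free <- length(internal) + length(free_leaves)
  best <- Inf
  for (code in 0:(2^n_free - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(max(n_free, 1))]
    assign_state <- leaf_states
    if (length(free_leaves) > 0)
      assign_state[free_leaves] <- bits[seq_along(free_leaves)]
    node_state <- integer(max(nodes))
    node_state[seq_len(n)] <- assign_state
    if (length(internal) > 0)
      node_state[internal] <- bits[length(free_leaves) + seq_along(internal)]
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# random MRP instance for oracle-equivalence tests: random binary
# characters with at least two 1s and one 0 among non-missing cells,
# random missingness, mixed rational weights
random_mrp_instance <- function(n_ingroup, n_chars, seed) {
  set.seed(seed)
  taxa <- c(sprintf("t%02d", seq_len(n_ingroup)), "MRP_OUTGROUP")
  repeat {
    mat <- matrix("?", n_ingroup + 1L, n_chars, dimnames = list(taxa, NULL))
    ok <- TRUE
    for (j in seq_len(n_chars)) {
      present <- sample(n_ingroup, sample(3:n_ingroup, 1))
      ones <- sample(present, max(2, rbinom(1, length(present) - 1, 0.5)))
      mat[present, j] <- "0"
      mat[ones, j] <- "1"
      mat[n_ingroup + 1L, j] <- "0"
      if (sum(mat[, j] == "1") < 2 || sum(mat[, j] == "0") < 2) ok <- FALSE
    }
    if (ok) break
  }
  dens <- sample(c(1L, 2L, 4L), n_chars, replace = TRUE)
  make_mrp(mat, wnum = rep(1L, n_chars), wden = dens)
}

# the frozen Apameini-style conflict fixture: two trees with
# incompatible resolutions of one region, plus a background tree; the
# majority-rule MPT consensus contains both a clade with s = q and a
# novel clade found in no input tree
conflict_fixture <- function() {
  its_from_newick(
    c("(((T007,(T006,T008)),(T011,T002)),(T012,(T001,T004)));",
      "((T008,(((T011,T001),T002),T006)),((T007,T012),T004));",
      "((T005,((T009,T001),(T010,T008))),(T003,T011));"),
    tags = list("COI", "morphology", "multilocus"))
}
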