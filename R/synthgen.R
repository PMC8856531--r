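#' Configuration for the synthetic input-tree generator
#'
#' The generator emulates the statistical structure of a published
#' input-tree collection: a known model phylogeny, clade-focused per-study
#' taxon subsampling with low pairwise overlap, topological estimation
#' noise (random NNI moves), soft polytomies (random edge collapse), and
#' groups of near-duplicate trees sharing a data type (pseudoreplicates).
#'
#' @param n_taxa number of taxa in the model tree.
#' @param n_trees number of input trees to sample.
#' @param taxa_per_tree length-2 integer vector, min/max taxa per tree.
#' @param perturb_moves random NNI moves applied to each sampled tree.
#' @param collapse_prob probability that an internal edge is collapsed
#'   into a polytomy, in `[0, 1]`.
#' @param pseudoreplicate_groups number of pseudoreplicate groups.
#' @param group_size trees per pseudoreplicate group.
#' @param seed integer seed; if `NULL` one is drawn and reported.
#' @param year_range length-2 integer vector of publication years.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 32, n_trees = 12, taxa_per_tree = c(10, 14),
                       perturb_moves = 1, collapse_prob = 0.1,
                       pseudoreplicate_groups = 0, group_size = 3,
                       seed = NULL, year_range = c(1990, 2020)) {
  stopifnot(n_taxa >= 3, n_trees >= 1, length(taxa_per_tree) == 2,
            taxa_per_tree[1] >= 3, taxa_per_tree[1] <= taxa_per_tree[2],
            collapse_prob >= 0, collapse_prob <= 1,
            perturb_moves >= 0, pseudoreplicate_groups >= 0, group_size >= 2,
            length(year_range) == 2, year_range[1] <= year_range[2])
  if (taxa_per_tree[2] > n_taxa)
    stop("taxa_per_tree max exceeds n_taxa: infeasible configuration")
  if (pseudoreplicate_groups * group_size > n_trees)
    stop("pseudoreplicate groups require more trees than n_trees")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message(sprintf("sim_config: no seed supplied, drew seed = %d", seed))
  }
  structure(list(n_taxa = as.integer(n_taxa), n_trees = as.integer(n_trees),
                 taxa_per_tree = as.integer(taxa_per_tree),
                 perturb_moves = as.integer(perturb_moves),
                 collapse_prob = collapse_prob,
                 pseudoreplicate_groups = as.integer(pseudoreplicate_groups),
                 group_size = as.integer(group_size),
                 seed = as.integer(seed),
                 year_range = as.integer(year_range)),
            class = "sim_config")
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a model tree under a Yule process
#'
#' Grows a rooted binary tree by uniform random lineage splitting (the
#' Yule-Harding topology distribution), with leaves labeled `T001`,
#' `T002`, ...  Deterministic for a fixed seed.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed integer seed.
#' @return a rooted binary `ape::phylo` tree.
#' @export
generate_model_tree <- function(n_taxa, seed) {
  if (n_taxa < 3) stop("a model tree needs at least 3 taxa")
  with_seed(seed, {
    parts <- sprintf("T%03d", seq_len(n_taxa))
    while (length(parts) > 1) {
      ij <- sample.int(length(parts), 2L)
      parts <- c(parts[-ij], paste0("(", parts[ij[1]], ",", parts[ij[2]], ")"))
    }
    parse_newick(paste0(parts, ";"))
  })
}

# ---- treelist perturbation operators -------------------------------------

tl_modify_at <- function(tl, path, fn) {
  if (length(path) == 0L) return(fn(tl))
  tl$children[[path[1]]] <- tl_modify_at(tl$children[[path[1]]], path[-1], fn)
  tl
}

tl_get_at <- function(tl, path) {
  for (i in path) tl <- tl$children[[i]]
  tl
}

# one random rooted NNI: swap a child of an internal non-root node with one
# of that node's siblings; replaces exactly one cluster
random_nni <- function(tl) {
  cands <- list()
  walk <- function(node, path) {
    if (tl_is_leaf(node)) return(invisible())
    for (i in seq_along(node$children)) {
      ch <- node$children[[i]]
      if (!tl_is_leaf(ch) && length(node$children) >= 2L)
        cands[[length(cands) + 1L]] <<- c(path, i)
      walk(ch, c(path, i))
    }
  }
  walk(tl, integer(0))
  if (length(cands) == 0L) return(tl)
  vpath <- cands[[sample.int(length(cands), 1L)]]
  ppath <- vpath[-length(vpath)]
  vi <- vpath[length(vpath)]
  p <- tl_get_at(tl, ppath)
  sib_idx <- setdiff(seq_along(p$children), vi)
  si <- sib_idx[sample.int(length(sib_idx), 1L)]
  v <- p$children[[vi]]
  ci <- sample.int(length(v$children), 1L)
  tmp <- v$children[[ci]]
  v$children[[ci]] <- p$children[[si]]
  p$children[[si]] <- tmp
  p$children[[vi]] <- v
  tl_modify_at(tl, ppath, function(node) { node$children <- p$children; node })
}

# collapse each internal non-root edge independently with probability prob
collapse_random_edges <- function(tl, prob) {
  walk <- function(node) {
    if (tl_is_leaf(node)) return(list(node))
    kids <- unlist(lapply(node$children, walk), recursive = FALSE)
    node$children <- kids
    if (stats::runif(1) < prob) return(node$children)
    list(node)
  }
  kids <- unlist(lapply(tl$children, walk), recursive = FALSE)
  list(children = kids)
}

#' Apply random NNI perturbation to a tree
#'
#' @param tree an `ape::phylo` tree.
#' @param moves number of random NNI moves.
#' @return the perturbed tree.  Each effective move replaces one cluster
#'   (Robinson-Foulds distance 2 from the previous tree).
#' @export
perturb_nni <- function(tree, moves) {
  if (moves == 0L) return(tree)
  tl <- as_treelist(tree)
  for (i in seq_len(moves)) tl <- random_nni(tl)
  treelist_to_phylo(tl)
}

# data-type vocabulary mirroring the mix of molecular and morphological
# evidence in published moth phylogenies
DATA_TYPE_VOCAB <- c("COI", "multilocus", "mitogenome", "morphology")

# Partition the model's taxa into clade blocks by repeatedly splitting
# the largest block into its child clades until a whole block plus one
# representative of every other block fits inside a study of `hi` taxa.
# Blocks are exact clades of the model; this is what lets a clade-focused
# study pin the position of its taxa relative to the other blocks.
model_blocks <- function(model, hi, max_blocks) {
  blocks <- list(as_treelist(model))
  repeat {
    sz <- vapply(blocks, function(b) length(tl_leaves(b)), 0L)
    if (max(sz) + length(blocks) - 1L <= hi) break
    splittable <- which(!vapply(blocks, tl_is_leaf, TRUE))
    if (length(splittable) == 0L || length(blocks) >= max_blocks) break
    i <- splittable[which.max(sz[splittable])]
    blocks <- c(blocks[-i], blocks[[i]]$children)
  }
  lapply(blocks, tl_leaves)
}

#' Sample a synthetic input-tree collection from a model tree
#'
#' Emulates the structure of a published input-tree collection: most
#' studies are clade-focused "monographs" that sample one block of the
#' model densely and add the flagship representative of every other
#' block for context, while one or two "backbone" studies sample
#' representatives across the whole tree -- mirroring how higher-level
#' molecular phylogenies and clade revisions jointly cover a fauna.
#' Studies of the same block are assigned different data-type tags (the
#' independent-evidence situation the curation protocol is designed to
#' keep); pseudoreplicate groups, which share a tag and a study by
#' construction, are the deliberate exception.  Each sampled tree is the
#' model pruned to the study's taxa, perturbed by `perturb_moves` random
#' NNI moves, with internal edges collapsed at `collapse_prob`.
#'
#' With no noise, this design makes every rooted triplet of retained
#' taxa either directly observed or entailed, so the conflict-free
#' supertree is unique and the pipeline can recover the model exactly.
#'
#' @param model a rooted `ape::phylo` model tree.
#' @param config a [sim_config()].
#' @return an `input_tree_set` tibble with the model attached as
#'   attribute `"model"`.
#' @export
sample_input_trees <- function(model, config) {
  stopifnot(inherits(model, "phylo"), inherits(config, "sim_config"))
  taxa <- model$tip.label
  if (config$taxa_per_tree[2] > length(taxa))
    stop("taxa_per_tree max exceeds the model's taxon count")
  with_seed(config$seed, {
    lo <- config$taxa_per_tree[1]
    hi <- config$taxa_per_tree[2]

    n_groups <- config$pseudoreplicate_groups
    gsize <- config$group_size
    n_indep <- config$n_trees - n_groups * gsize
    n_backbone <- if (n_indep >= 6L) 2L else if (n_indep >= 1L) 1L else 0L
    n_block_studies <- max(0L, n_indep - n_backbone)

    # Clade blocks, packed into study units.  A monograph unit samples
    # its member blocks completely plus one representative of every
    # other block, so any two units share exactly the k representatives:
    # an overlap fraction of at most k/lo <= 0.5, which the curation
    # protocol accepts regardless of data type.
    blocks <- model_blocks(model, hi = hi,
                           max_blocks = max(1L, min(lo %/% 2L,
                                                    n_block_studies)))
    k <- length(blocks)
    reps <- vapply(blocks, function(b) if (length(b) == 1L) b else
      sample(b, 1L), "")

    # first-fit decreasing packing of blocks into units of <= hi taxa
    bsizes <- vapply(blocks, length, 0L)
    units <- list()
    for (bi in order(bsizes, decreasing = TRUE)) {
      placed <- FALSE
      for (ui in seq_along(units)) {
        m <- length(units[[ui]])
        own <- sum(bsizes[units[[ui]]])
        if (own + bsizes[bi] + (k - m - 1L) <= hi) {
          units[[ui]] <- c(units[[ui]], bi)
          placed <- TRUE
          break
        }
      }
      if (!placed) units[[length(units) + 1L]] <- bi
    }
    # merge underfull units while the union still fits
    repeat {
      usz <- vapply(units, function(u)
        sum(bsizes[u]) + (k - length(u)), 0L)
      if (length(units) <= 1L || all(usz >= lo)) break
      ord <- order(usz)
      i <- ord[1]; j <- ord[2]
      if (sum(bsizes[c(units[[i]], units[[j]])]) +
          (k - length(units[[i]]) - length(units[[j]])) > hi) break
      units[[j]] <- c(units[[j]], units[[i]])
      units[[i]] <- NULL
    }
    # A unit's study samples all member-block taxa plus the external
    # representatives.  Units that an unbalanced clade partition leaves
    # oversized are subsampled, keeping the member representatives as
    # anchors; the unsampled taxa then appear in no study at all (they
    # are simply not covered by this literature), rather than drifting
    # in as weakly constrained padding.
    unit_own <- lapply(units, function(u) {
      own <- unique(unlist(blocks[u]))
      room <- hi - (k - length(u))
      if (length(own) > room) {
        anchors <- intersect(reps, own)
        extra <- setdiff(own, anchors)
        own <- c(anchors, sample(extra, max(0L, room - length(anchors))))
      }
      own
    })
    covered <- unique(c(unlist(unit_own), reps))
    unit_sets <- lapply(seq_along(units), function(ui) {
      set <- unique(c(unit_own[[ui]], reps[setdiff(seq_len(k), units[[ui]])]))
      if (length(set) < lo) {
        pool <- setdiff(covered, set)
        set <- c(set, sample(pool, min(lo - length(set), length(pool))))
      }
      set
    })

    taxon_sets <- vector("list", config$n_trees)
    study_of <- integer(config$n_trees)
    tag_of <- character(config$n_trees)
    idx <- 0L
    study <- 0L
    # Backbone studies: alternative trees from one higher-level study
    # (identical taxon sampling, one dedicated data type) -- if they are
    # flagged as pseudoreplicates they tie and stay in at reduced weight.
    if (n_backbone > 0L) {
      study <- study + 1L
      bb <- reps
      pool <- setdiff(covered, bb)
      if (length(bb) < hi && length(pool) > 0L)
        bb <- c(bb, sample(pool, min(hi - length(bb), length(pool))))
      for (i in seq_len(n_backbone)) {
        idx <- idx + 1L
        taxon_sets[[idx]] <- bb
        study_of[idx] <- study
        tag_of[idx] <- DATA_TYPE_VOCAB[1]
      }
    }
    # Monograph studies: visits to the same unit repeat the same taxon
    # set (independent re-studies of one group) under rotating
    # non-backbone data types, so replicate visits either carry distinct
    # data types or tie as equals during curation.
    nu <- length(unit_sets)
    for (i in seq_len(n_block_studies)) {
      idx <- idx + 1L; study <- study + 1L
      ui <- (i - 1L) %% nu + 1L
      visit <- (i - 1L) %/% nu
      taxon_sets[[idx]] <- unit_sets[[ui]]
      study_of[idx] <- study
      tag_of[idx] <- DATA_TYPE_VOCAB[2L + visit %% 3L]
    }
    for (g in seq_len(n_groups)) {
      study <- study + 1L
      size <- sample(lo:hi, 1L)
      base <- sample(taxa, size)
      tag <- sample(DATA_TYPE_VOCAB, 1L)
      for (j in seq_len(gsize)) {
        idx <- idx + 1L
        set <- base
        if (j > 1L) {
          # jitter: swap one taxon in/out, keeping overlap high
          drop <- sample(set, 1L)
          add <- sample(setdiff(taxa, set), 1L)
          set <- c(setdiff(set, drop), add)
        }
        taxon_sets[[idx]] <- set
        study_of[idx] <- study
        tag_of[idx] <- tag
      }
    }

    trees <- lapply(taxon_sets, function(s) {
      t <- prune_to(model, s)
      t <- perturb_nni(t, config$perturb_moves)
      if (config$collapse_prob > 0)
        t <- treelist_to_phylo(collapse_random_edges(as_treelist(t),
                                                     config$collapse_prob))
      t
    })
    years <- sample(config$year_range[1]:config$year_range[2],
                    config$n_trees, replace = TRUE)
    out <- input_tree_set(trees,
                          tree_id = sprintf("tree%02d", seq_len(config$n_trees)),
                          study_id = sprintf("S%03d", study_of),
                          year = years,
                          data_types = as.list(tag_of))
    attr(out, "model") <- model
    out
  })
}
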