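test_that("partition specs validate nesting, names and size", {
  spec <- partition_spec(inner = c("a", "b", "c"),
                         outer = c("a", "b", "c", "d", "e"))
  expect_s3_class(spec, "partition_spec")
  expect_equal(names(spec), c("inner", "outer"))
  expect_error(partition_spec(x = c("a", "b")), "at least 3")
  expect_error(partition_spec(x = c("a", "b", "c"), y = c("b", "c", "d")),
               "nested nor disjoint")
  expect_error(partition_spec(c("a", "b", "c")), "unique names")
})

test_that("reduce_tree places the placeholder correctly", {
  # monophyletic members: placeholder on their stem edge
  t <- parse_newick("((a1,a2),(B,C));")
  expect_equal(write_newick(reduce_tree(t, "N", c("a1", "a2"))), "(N,(B,C));")
  # non-monophyletic members: warn, attach at the MRCA's parent
  t2 <- parse_newick("((a1,B),(a2,C));")
  expect_warning(r2 <- reduce_tree(t2, "N", c("a1", "a2")), "not monophyletic")
  expect_setequal(r2$tip.label, c("B", "C", "N"))
  expect_length(tree_clusters(r2), 0)  # (N,B,C) star after suppression
  # strict mode errors instead
  expect_error(reduce_tree(t2, "N", c("a1", "a2"), strict = TRUE),
               "not monophyletic")
  # no members: unchanged
  t3 <- parse_newick("((X,Y),Z);")
  expect_equal(rf_distance(reduce_tree(t3, "N", c("a1", "a2")), t3), 0)
  # single member: renamed in place
  t4 <- parse_newick("((a1,B),C);")
  expect_equal(write_newick(reduce_tree(t4, "N", "a1")), "((N,B),C);")
  # reduction never increases the leaf count
  set.seed(81)
  for (i in 1:10) {
    tr <- generate_model_tree(12, seed = i)
    mem <- sample(tr$tip.label, 4)
    red <- suppressWarnings(reduce_tree(tr, "N", mem))
    expect_lte(length(red$tip.label), length(tr$tip.label))
  }
})

test_that("graft replaces the placeholder and keeps the clade", {
  backbone <- parse_newick("(N,(B,C));")
  sub <- parse_newick("((x,y),z);")
  g <- graft(backbone, "N", sub)
  expect_equal(write_newick(g), "(((x,y),z),(B,C));")
  expect_equal(length(g$tip.label),
               length(backbone$tip.label) - 1 + length(sub$tip.label))
  expect_true(mrpsupertree:::cluster_key(c("x", "y", "z")) %in%
                mrpsupertree:::cluster_key_set(g))
  # pruning the grafted taxa back to one leaf recovers the backbone shape
  back <- prune_to(g, c("x", "B", "C"))
  back$tip.label[back$tip.label == "x"] <- "N"
  expect_equal(rf_distance(back, backbone), 0)
  expect_error(graft(backbone, "Q", sub), "no placeholder")
  expect_error(graft(backbone, "N", parse_newick("((B,y),z);")), "disjoint")
})

test_that("partitioned and unpartitioned pipelines agree on clean data", {
  model <- generate_model_tree(16, seed = 7)
  cfg <- sim_config(n_taxa = 16, n_trees = 8, taxa_per_tree = c(8, 10),
                    perturb_moves = 0, collapse_prob = 0, seed = 7)
  cur <- curate(sample_input_trees(model, cfg))
  taxa <- all_taxa(cur$trees)
  pruned_model <- prune_to(model, taxa)
  cls <- tree_clusters(pruned_model)
  sizes <- vapply(cls, length, 0L)
  cl <- cls[[which(sizes >= 5 & sizes <= 8)[1]]]

  scfg <- search_config(n_reps = 20, seed = 3)
  un <- majority_consensus(heuristic_search(encode_matrix(cur$trees), scfg))
  pr <- run_partitioned(cur$trees, partition_spec(cladeA = cl), scfg)
  expect_equal(rf_distance(pr$supertree, un$tree), 0)
  expect_equal(rf_distance(pr$supertree, pruned_model), 0)
  # grafted members form a clade
  expect_true(mrpsupertree:::cluster_key(intersect(cl, pr$supertree$tip.label))
              %in% mrpsupertree:::cluster_key_set(pr$supertree))
})

test_that("a partition covering all taxa equals the unpartitioned run", {
  model <- generate_model_tree(12, seed = 15)
  cfg <- sim_config(n_taxa = 12, n_trees = 6, taxa_per_tree = c(6, 8),
                    perturb_moves = 0, collapse_prob = 0, seed = 15)
  cur <- curate(sample_input_trees(model, cfg))
  scfg <- search_config(n_reps = 10, seed = 1)
  un <- majority_consensus(heuristic_search(encode_matrix(cur$trees), scfg))
  pr <- run_partitioned(cur$trees, partition_spec(all = all_taxa(cur$trees)),
                        scfg)
  expect_equal(rf_distance(pr$supertree, un$tree), 0)
})

test_that("three-level nesting yields per-level analyses and placeholders", {
  model <- generate_model_tree(24, seed = 31)
  cfg <- sim_config(n_taxa = 24, n_trees = 10, taxa_per_tree = c(9, 12),
                    perturb_moves = 0, collapse_prob = 0, seed = 31)
  cur <- curate(sample_input_trees(model, cfg))
  taxa <- all_taxa(cur$trees)
  pm <- prune_to(model, taxa)
  cls <- tree_clusters(pm)
  sizes <- vapply(cls, length, 0L)
  # an inner clade nested in an outer clade, as in family-in-superfamily
  ok_outer <- which(sizes >= 8 & sizes <= length(taxa) - 4)
  outer <- NULL
  for (oi in ok_outer) {
    inner_cand <- which(vapply(cls, function(x)
      length(x) >= 4 && length(x) <= sizes[oi] - 2 &&
        all(x %in% cls[[oi]]), TRUE))
    if (length(inner_cand) > 0) {
      outer <- cls[[oi]]
      inner <- cls[[inner_cand[1]]]
      break
    }
  }
  skip_if(is.null(outer), "no usable nested clade pair in this fixture")
  scfg <- search_config(n_reps = 20, seed = 5)
  pr <- run_partitioned(cur$trees,
                        partition_spec(innerA = inner, outerA = outer), scfg)
  expect_setequal(names(pr$partitions), c("innerA", "outerA", "backbone"))
  expect_true("innerA" %in%
                all_taxa(pr$partitions$outerA$trees))
  expect_true("outerA" %in%
                all_taxa(pr$partitions$backbone$trees))
  expect_setequal(pr$supertree$tip.label, taxa)
  expect_equal(rf_distance(pr$supertree, pm), 0)
})
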