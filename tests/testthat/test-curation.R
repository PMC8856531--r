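test_that("overlap fractions are per-tree shares of the intersection", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(overlap_fractions(t1, t1), c(1, 1))
  expect_equal(overlap_fractions(t1, parse_newick("((E,F),(G,H));")), c(0, 0))
  t2 <- parse_newick("((C,D),(E,(F,(G,H))));")
  expect_equal(overlap_fractions(t1, t2), c(0.5, 1 / 3))
})

test_that("tied alternative trees share weight 1/n", {
  # four alternative trees from one study, same taxa, same data
  nw <- c("((A,B),(C,D),E);", "((A,C),(B,D),E);",
          "((A,D),(B,C),E);", "(((A,B),C),D,E);")
  its <- its_from_newick(nw, tags = list("COI", "COI", "COI", "COI"),
                         study_id = "S001", tree_id = paste0("alt", 1:4))
  res <- resolve_pseudoreplication(its)
  expect_equal(nrow(res$trees), 4)
  expect_equal(res$trees$weight_num, rep(1L, 4))
  expect_equal(res$trees$weight_den, rep(4L, 4))
  expect_equal(sum(tree_weights(res$trees)), 1)

  # two alternatives -> 50% each
  res2 <- resolve_pseudoreplication(
    its_from_newick(nw[1:2], tags = list("COI", "COI"), study_id = "S001"))
  expect_equal(tree_weights(res2$trees), c(0.5, 0.5))
})

test_that("the more comprehensive tree wins a pseudoreplicated pair", {
  big <- paste0("(", paste(sprintf("t%02d", 1:40), collapse = ","), ");")
  small <- paste0("(", paste(sprintf("t%02d", 1:25), collapse = ","), ");")
  # overlap 25/40 = 62.5% and 25/25 = 100%, same data type
  its <- its_from_newick(c(big, small), tags = list("COI", "COI"))
  res <- resolve_pseudoreplication(its)
  expect_equal(nrow(res$trees), 1)
  expect_equal(res$trees$n_taxa, 40L)
  expect_equal(tree_weights(res$trees), 1)
  rep <- res$report$trees
  expect_equal(rep$status[rep$tree_id == "tree02"], "discarded")
  expect_equal(rep$reason[rep$tree_id == "tree02"], "pseudoreplicate_dropped")
})

test_that("the overlap rule only applies within a shared data type", {
  nw <- c("((A,B),(C,D));", "((A,C),(B,D));")
  res <- resolve_pseudoreplication(
    its_from_newick(nw, tags = list("COI", "morphology")))
  expect_equal(nrow(res$trees), 2)
  expect_equal(tree_weights(res$trees), c(1, 1))
  # both fractions at most one half: retained even with a shared tag
  res2 <- resolve_pseudoreplication(its_from_newick(
    c("((A,B),(C,D));", "((C,D),(E,(F,(G,H))));"), tags = list("COI", "COI")))
  expect_equal(nrow(res2$trees), 2)
})

test_that("missing data-type tags are reported by tree", {
  its <- its_from_newick(c("((A,B),C);", "((A,C),B);"),
                         tags = list("COI", character(0)))
  expect_error(resolve_pseudoreplication(its), "tree02")
})

test_that("weights never exceed 1 and violating same-type pairs never co-survive", {
  set.seed(31)
  for (rep in 1:10) {
    model <- generate_model_tree(20, seed = rep)
    cfg <- sim_config(n_taxa = 20, n_trees = 8, taxa_per_tree = c(7, 10),
                      pseudoreplicate_groups = 1, group_size = 3, seed = rep)
    its <- sample_input_trees(model, cfg)
    res <- resolve_pseudoreplication(its)
    w <- tree_weights(res$trees)
    expect_true(all(w > 0 & w <= 1))
    kept <- res$trees
    if (nrow(kept) >= 2) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        shared_tag <- length(intersect(kept$data_types[[i]],
                                       kept$data_types[[j]])) > 0
        f <- overlap_fractions(kept$tree[[i]], kept$tree[[j]])
        if (shared_tag && max(f) > 0.5) {
          # only tied alternatives may co-survive a violation
          expect_equal(kept$n_taxa[i], kept$n_taxa[j])
          expect_gt(kept$weight_den[i], 1L)
        }
      }
    }
    # report is exhaustive
    expect_equal(nrow(res$report$trees), nrow(its))
    expect_equal(sum(res$report$trees$status == "retained"), nrow(res$trees))
  }
})

test_that("singleton taxa are pruned to a fixed point, with cascades", {
  its <- its_from_newick(c("((A,B),(C,X));", "((A,B),C);", "((A,C),B);"))
  res <- remove_singletons(its)
  expect_false("X" %in% all_taxa(res$trees))
  expect_equal(res$report$taxa$taxon, "X")
  expect_equal(res$report$taxa$reason, "singleton")
  expect_true("C" %in% all_taxa(res$trees))  # in two trees: retained

  # cascade: dropping a tree demotes another taxon to singleton
  cas <- its_from_newick(c("((A,Y),X);", "((A,B),(C,X));", "((B,C),A);"))
  # Y only in tree 1; X in trees 1 and 2.  Pruning Y leaves tree 1 with
  # 2 leaves -> dropped -> X becomes a singleton of tree 2 -> pruned too.
  res2 <- remove_singletons(cas)
  expect_setequal(res2$report$taxa$taxon, c("Y", "X"))
  expect_equal(nrow(res2$trees), 2)
  expect_setequal(all_taxa(res2$trees), c("A", "B", "C"))
  # fixed point: running again changes nothing
  res3 <- remove_singletons(res2$trees)
  expect_equal(nrow(res3$report$taxa), 0)
  expect_equal(nrow(res3$trees), nrow(res2$trees))
})

test_that("connectivity requires two shared taxa", {
  two_shared <- its_from_newick(c("((A,B),C);", "((B,C),D);"))
  expect_length(connectivity_check(two_shared), 1)
  disjoint <- its_from_newick(c("((A,B),C);", "((D,E),F);"))
  expect_warning(comps <- connectivity_check(disjoint), "unresolved")
  expect_length(comps, 2)
  chain <- its_from_newick(c("((A,B),C);", "((B,C),D);", "((C,D),E);"))
  expect_length(connectivity_check(chain), 1)
  one_shared <- its_from_newick(c("((A,B),C);", "((C,D),E);"))
  expect_warning(comps2 <- connectivity_check(one_shared), "unresolved")
  expect_length(comps2, 2)
})

test_that("representation filter removes starved taxa monotonically", {
  its <- its_from_newick(c("((A,B),(C,D));", "((A,B),C);", "((A,C),(B,E));"))
  fs <- matrix_fill_stats(encode_matrix(its))
  # D and E each occur in a single tree
  expect_setequal(representation_filter(fs, min_trees = 2, min_cells = 2),
                  c("D", "E"))
  # a taxon with 0 informative cells cannot occur (clusters always code
  # present taxa), but raising min_cells past a taxon's count removes it
  expect_true("C" %in% representation_filter(fs, min_trees = 2, min_cells = 6))
  # raising thresholds never removes fewer taxa
  set.seed(17)
  for (rep in 1:5) {
    model <- generate_model_tree(16, seed = rep)
    cfg <- sim_config(n_taxa = 16, n_trees = 6, taxa_per_tree = c(6, 8),
                      seed = rep)
    fs <- matrix_fill_stats(encode_matrix(sample_input_trees(model, cfg)))
    prev <- character(0)
    for (mc in 1:4) {
      cur <- representation_filter(fs, min_trees = 2, min_cells = mc)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("curate merges all stages into one exhaustive report", {
  model <- generate_model_tree(24, seed = 13)
  cfg <- sim_config(n_taxa = 24, n_trees = 8, taxa_per_tree = c(8, 11),
                    seed = 13)
  its <- sample_input_trees(model, cfg)
  res <- curate(its)
  expect_equal(nrow(res$report$trees), nrow(its))
  expect_equal(sum(res$report$trees$status == "retained") +
                 sum(res$report$trees$status == "discarded"), nrow(its))
  expect_gte(res$report$n_components, 1)
})
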