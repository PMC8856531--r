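test_that("classification follows the support/conflict/permit rules", {
  sl <- c("A", "B", "C", "D")
  expect_equal(classify_input_tree(parse_newick("((A,B),C);"), c("A", "B"), sl),
               "supports")
  expect_equal(classify_input_tree(parse_newick("((A,C),B);"), c("A", "B"), sl),
               "conflicts")
  expect_equal(classify_input_tree(parse_newick("(A,B,C);"), c("A", "B"), sl),
               "permits")
  # fewer than 2 clade members sampled, or no outside taxon: irrelevant
  expect_equal(classify_input_tree(parse_newick("((A,C),D);"), c("A", "B"), sl),
               "irrelevant")
  expect_equal(classify_input_tree(parse_newick("(A,B);"), c("A", "B"), sl),
               "irrelevant")
})

test_that("classification ignores taxa outside the clade-relevant region", {
  sl <- c("A", "B", "C", "D")
  base <- parse_newick("((A,B),C);")
  bigger <- parse_newick("(((A,Z1),(B,Z2)),(C,(Z3,Z4)));")
  # Z* are outside the supertree's leaf set entirely
  expect_equal(classify_input_tree(base, c("A", "B"), sl),
               classify_input_tree(bigger, c("A", "B"), sl))
})

test_that("V and V+ follow their defining ratios", {
  sl <- c("A", "B", "C", "D")
  # full support: every relevant tree supports
  v1 <- v_index(c("A", "B"), list(parse_newick("((A,B),C);"),
                                  parse_newick("((A,B),D);")), sl)
  expect_equal(v1$V, 1)
  expect_equal(v1$V_plus, 1)
  expect_false(v1$novel)

  # pure conflict: novel relationship
  v2 <- v_index(c("A", "B"), list(parse_newick("((A,C),B);"),
                                  parse_newick("((B,D),A);")), sl)
  expect_equal(v2$V, -1)
  expect_equal(v2$V_plus, -1)
  expect_true(v2$novel)

  # s=1, q=1, p=2 -> V = 0, V+ = 1/2
  trees <- list(parse_newick("((A,B),C);"), parse_newick("((A,C),B);"),
                parse_newick("(A,B,C);"), parse_newick("(A,B,D);"))
  v3 <- v_index(c("A", "B"), trees, sl)
  expect_equal(unlist(v3[, c("s", "q", "p")]), c(s = 1, q = 1, p = 2))
  expect_equal(v3$V, 0)
  expect_equal(v3$V_plus, 0.5)
  expect_false(v3$novel)

  # undefined cases
  v4 <- v_index(c("A", "B"), list(parse_newick("(A,B,C);")), sl)
  expect_true(is.na(v4$V))
  expect_equal(v4$V_plus, 1)
  v5 <- v_index(c("A", "B"), list(parse_newick("((C,D),A);")), sl)
  expect_true(is.na(v5$V))
  expect_true(is.na(v5$V_plus))
})

test_that("classification counts always sum to the tree count", {
  set.seed(71)
  for (i in 1:10) {
    model <- generate_model_tree(14, seed = i)
    cfg <- sim_config(n_taxa = 14, n_trees = 6, taxa_per_tree = c(6, 8),
                      collapse_prob = 0.3, seed = i)
    its <- sample_input_trees(model, cfg)
    sl <- all_taxa(its)
    cl <- sample(sl, 4)
    v <- v_index(cl, its, sl)
    expect_equal(v$s + v$q + v$p + v$irrelevant, nrow(its))
    expect_true(is.na(v$V) || (v$V >= -1 && v$V <= 1))
    expect_true(is.na(v$V_plus) || (v$V_plus >= -1 && v$V_plus <= 1))
    if (!is.na(v$V) && !is.na(v$V_plus) && v$p > 0)
      expect_gte(v$V_plus, v$V)
  }
})

test_that("a supertree equal to its only input scores +1 everywhere", {
  t <- generate_model_tree(10, seed = 42)
  sup <- score_supertree(t, list(t))
  expect_equal(nrow(sup), 8)
  expect_true(all(sup$V == 1))
  expect_true(all(sup$V_plus == 1))
  expect_false(any(sup$novel))
})

test_that("no-noise synthetic runs contain no novel clades", {
  model <- generate_model_tree(20, seed = 19)
  cfg <- sim_config(n_taxa = 20, n_trees = 8, taxa_per_tree = c(8, 10),
                    perturb_moves = 0, collapse_prob = 0, seed = 19)
  cur <- curate(sample_input_trees(model, cfg))
  sr <- heuristic_search(encode_matrix(cur$trees),
                         search_config(n_reps = 10, seed = 19))
  sup <- score_supertree(strict_consensus(sr), cur$trees)
  expect_false(any(sup$novel))
  expect_true(all(is.na(sup$V) | sup$V >= 0))
})

test_that("collapse_novel removes exactly the novel clades", {
  its <- conflict_fixture()
  m <- encode_matrix(its)
  sr <- heuristic_search(m, search_config(n_reps = 10, seed = 24,
                                          max_trees = 500))
  mj <- majority_consensus(sr)
  sup <- score_supertree(mj, its)
  expect_gte(sum(sup$novel), 1)
  collapsed <- collapse_novel(mj, sup)
  expect_equal(length(tree_clusters(collapsed)),
               length(tree_clusters(mj$tree)) - sum(sup$novel))
  # fully supported clades survive the collapse
  keys_before <- vapply(sup$clade[sup$V == 1 & !is.na(sup$V)],
                        mrpsupertree:::cluster_key, "")
  keys_after <- mrpsupertree:::cluster_key_set(collapsed)
  expect_true(all(keys_before %in% keys_after))
  # no novel clade remains
  expect_equal(sum(score_supertree(collapsed, its)$novel), 0)
  # identity when nothing is novel
  t <- generate_model_tree(8, seed = 3)
  sup2 <- score_supertree(t, list(t))
  expect_equal(rf_distance(collapse_novel(t, sup2), t), 0)
})

test_that("support tables export and plot", {
  t <- generate_model_tree(8, seed = 9)
  sup <- score_supertree(t, list(t))
  f <- withr::local_tempfile(fileext = ".csv")
  write_support_csv(sup, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(sup))
  expect_true(all(c("s", "q", "p", "V", "V_plus", "novel") %in% names(back)))
  p <- ggplot2::autoplot(sup)
  expect_s3_class(p, "ggplot")
})
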