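test_that("fitch_score matches hand-worked single characters", {
  taxa <- c("A", "B", "C", "D", "MRP_OUTGROUP")
  tr <- parse_newick("(((A,B),(C,D)),MRP_OUTGROUP);")
  m1 <- make_mrp(matrix(c("1", "1", "0", "0", "0"), 5, 1,
                        dimnames = list(taxa, NULL)))
  expect_equal(as.numeric(fitch_score(tr, m1)), 1)
  tr2 <- parse_newick("(((A,C),(B,D)),MRP_OUTGROUP);")
  expect_equal(as.numeric(fitch_score(tr2, m1)), 2)

  # missing data: the score is the minimum over resolutions of B
  m2 <- make_mrp(matrix(c("1", "?", "0", "0", "0"), 5, 1,
                        dimnames = list(taxa, NULL)))
  expect_equal(as.numeric(fitch_score(tr, m2)), 1)
  s_b0 <- fitch_score(tr, make_mrp(matrix(c("1", "0", "0", "0", "0"), 5, 1,
                                          dimnames = list(taxa, NULL))))
  s_b1 <- fitch_score(tr, make_mrp(matrix(c("1", "1", "0", "0", "0"), 5, 1,
                                          dimnames = list(taxa, NULL))))
  expect_equal(as.numeric(fitch_score(tr, m2)), min(s_b0, s_b1))

  expect_error(fitch_score(parse_newick("((A,B),C);"), m1), "mismatch")
})

test_that("fitch_score agrees with the enumeration oracle, with ? and polytomies", {
  set.seed(23)
  taxa <- c(sprintf("t%d", 1:5), "MRP_OUTGROUP")
  for (i in 1:25) {
    tr <- perturb_nni(generate_model_tree(6, seed = i), 0)
    tr$tip.label <- sample(taxa)
    if (i %% 3 == 0) {
      cl <- tree_clusters(tr)
      if (length(cl) > 0) tr <- collapse_clusters(tr, cl[1])
    }
    states <- sample(c("0", "1", "?"), 6, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    if (sum(states == "1") == 0) states[1] <- "1"
    m <- make_mrp(matrix(states, 6, 1, dimnames = list(taxa, NULL)))
    num_states <- as.integer(replace(states, states == "?", NA))
    names(num_states) <- taxa
    expect_equal(as.numeric(fitch_score(tr, m)),
                 oracle_char_steps(tr, num_states))
  }
})

test_that("fitch_score agrees with phangorn on random weighted matrices", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (i in 1:10) {
    m <- random_mrp_instance(n_ingroup = 7, n_chars = 12, seed = 400 + i)
    tr <- generate_model_tree(8, seed = i)
    tr$tip.label <- sample(rownames(m$matrix))
    dat <- phangorn::phyDat(m$matrix, type = "USER", levels = c("0", "1"))
    steps <- fitch_score(tr, m, per_character = TRUE)$steps
    ref <- phangorn::parsimony(ape::unroot(tr), dat, method = "fitch",
                               site = "site")
    expect_equal(steps, as.integer(ref))
    w <- m$weight_num / m$weight_den
    expect_equal(as.numeric(fitch_score(tr, m)), sum(w * steps))
  }
})

test_that("exhaustive search recovers a single source tree exactly", {
  nw <- "(((A,B),(C,D)),(E,F));"
  m <- encode_matrix(its_from_newick(nw))
  res <- exhaustive_search(m)
  expect_length(res$trees, 1)
  expect_equal(rf_distance(res$trees[[1]], parse_newick(nw)), 0)
  # every clade character fits in one step
  expect_equal(res$best_score, ncol(m$matrix))
})

test_that("two incompatible resolutions tie and both source trees are MPTs", {
  nw <- c("((A,B),(C,D));", "((A,C),(B,D));")
  m <- encode_matrix(its_from_newick(nw))
  res <- exhaustive_search(m)
  keys <- vapply(res$trees,
                 function(t) paste(sort(mrpsupertree:::cluster_key_set(t)),
                                   collapse = "|"), "")
  for (w in nw) {
    k <- paste(sort(mrpsupertree:::cluster_key_set(parse_newick(w))),
               collapse = "|")
    expect_true(k %in% keys)
  }
  # incompatible characters force extra steps beyond the 4-step bound
  expect_gt(res$best_score, 4)
})

test_that("exhaustive search rejects oversized problems", {
  m <- random_mrp_instance(n_ingroup = 10, n_chars = 5, seed = 1)
  expect_error(exhaustive_search(m), "heuristic_search")
})

test_that("non-binding constraints keep the optimum; binding ones hold", {
  nw <- "(((A,B),(C,D)),(E,F));"
  m <- encode_matrix(its_from_newick(nw))
  free <- exhaustive_search(m)
  con <- exhaustive_search(m, constraints = list(c("A", "B")))
  expect_equal(con$best_score, free$best_score)  # clade is in the optimum
  forced <- exhaustive_search(m, constraints = list(c("A", "C")))
  expect_gte(forced$best_score, free$best_score)
  for (t in forced$trees)
    expect_true(enforce_constraints(t, list(c("A", "C"))))
})

test_that("heuristic search matches the exhaustive optimum on random instances", {
  for (i in 1:25) {
    n_in <- sample(4:7, 1)
    m <- random_mrp_instance(n_ingroup = n_in, n_chars = sample(5:12, 1),
                             seed = 9000 + i)
    ex <- exhaustive_search(m)
    hs <- heuristic_search(m, search_config(n_reps = 10, seed = i,
                                            max_trees = 2000))
    expect_equal(hs$best_score, ex$best_score)
    # identical MPT sets when the cap is not hit
    if (!hs$hit_max_trees) {
      k1 <- sort(vapply(hs$trees, write_newick, ""))
      k2 <- sort(vapply(ex$trees, write_newick, ""))
      expect_identical(k1, k2)
    }
  }
})

test_that("a clean 20-taxon source tree is recovered uniquely at the bound", {
  model <- generate_model_tree(20, seed = 55)
  m <- encode_matrix(input_tree_set(list(model)))
  hs <- heuristic_search(m, search_config(n_reps = 5, seed = 2))
  expect_length(hs$trees, 1)
  expect_equal(rf_distance(hs$trees[[1]], model), 0)
  expect_equal(hs$best_score, ncol(m$matrix))  # = sum of unit weights
})

test_that("doubling weights doubles the score and keeps the MPT set", {
  m <- random_mrp_instance(n_ingroup = 6, n_chars = 8, seed = 321)
  m2 <- m
  m2$weight_num <- m$weight_num * 2L
  a <- heuristic_search(m, search_config(n_reps = 5, seed = 3))
  b <- heuristic_search(m2, search_config(n_reps = 5, seed = 3))
  expect_equal(b$best_score, 2 * a$best_score)
  expect_identical(sort(vapply(a$trees, write_newick, "")),
                   sort(vapply(b$trees, write_newick, "")))
})

test_that("scores stay exact under fractional weights", {
  taxa <- c("A", "B", "C", "D", "MRP_OUTGROUP")
  mat <- matrix(c("1", "1", "0", "0", "0",
                  "0", "1", "1", "0", "0",
                  "1", "0", "0", "1", "0"), 5, 3,
                dimnames = list(taxa, NULL))
  m <- make_mrp(mat, wnum = c(1L, 1L, 1L), wden = c(2L, 3L, 1L))
  tr <- parse_newick("(((A,B),(C,D)),MRP_OUTGROUP);")
  s <- fitch_score(tr, m)
  # steps are 1, 2, 2 -> score = 1/2 + 2/3 + 2 = 19/6
  expect_equal(attr(s, "num") / attr(s, "den"), 19 / 6)
  expect_equal(attr(s, "den"), 6)
})

test_that("search is deterministic given a seed", {
  m <- random_mrp_instance(n_ingroup = 7, n_chars = 10, seed = 777)
  a <- heuristic_search(m, search_config(n_reps = 10, seed = 42))
  b <- heuristic_search(m, search_config(n_reps = 10, seed = 42))
  expect_identical(vapply(a$trees, write_newick, ""),
                   vapply(b$trees, write_newick, ""))
  expect_identical(a$best_score, b$best_score)
})

test_that("enforce_constraints classifies clusters, leaves and misses", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(enforce_constraints(tr, list(c("A", "B"))))
  expect_false(enforce_constraints(tr, list(c("A", "C"))))
  expect_true(enforce_constraints(tr, list("A")))            # single leaf
  expect_true(enforce_constraints(tr, list(c("X", "Y"))))    # absent: vacuous
  expect_true(enforce_constraints(tr, list(c("A", "X"))))    # one present
  expect_error(search_config(constraints = list(c("A", "B"), c("B", "C"))),
               "nested or disjoint")
})

test_that("constrained heuristic search returns only compliant trees", {
  m <- random_mrp_instance(n_ingroup = 6, n_chars = 8, seed = 1234)
  cons <- list(c("t01", "t02", "t03"))
  hs <- heuristic_search(m, search_config(n_reps = 5, seed = 9,
                                          constraints = cons))
  ex <- exhaustive_search(m, constraints = cons)
  expect_equal(hs$best_score, ex$best_score)
  for (t in hs$trees) expect_true(enforce_constraints(t, cons))
})
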