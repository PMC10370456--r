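# shared small instance: strong signal for fast, informative climbs
search_fixture <- local({
  tr <- generate_model_tree(6, 2, seed = 42)
  mod <- hky_model(2, c(0.3, 0.2, 0.25, 0.25))
  aln <- simulate_alignment(tr, mod, 2000, seed = 43)
  list(tr = tr, mod = mod, aln = aln)
})

test_that("the NNI neighborhood has 2(m-3) distinct topologies", {
  set.seed(51)
  for (m in c(5, 8, 12)) {
    t <- random_tree(m)
    nb <- nni_neighbors(t)
    expect_length(nb, 2 * (m - 3))
    hashes <- vapply(nb, function(x) topology_hash(x$tree), "")
    expect_equal(anyDuplicated(hashes), 0)
    expect_false(topology_hash(t) %in% hashes)
    for (x in nb[1:2]) {
      expect_equal(rf_distance(t, x$tree), 2)
      expect_length(x$opt_edges, 5)
      # branch lengths travel with subtrees: multiset preserved
      expect_equal(sort(x$tree$edge.length), sort(t$edge.length))
    }
  }
})

test_that("starting trees are valid, seed-stable, and prefix-consistent", {
  aln <- search_fixture$aln
  s1 <- starting_trees(aln, 4, seed = 99)
  s2 <- starting_trees(aln, 4, seed = 99)
  expect_equal(lapply(s1, write_newick), lapply(s2, write_newick))
  s6 <- starting_trees(aln, 6, seed = 99)
  expect_equal(lapply(s6[1:4], write_newick), lapply(s1, write_newick))
  for (t in s1) {
    expect_setequal(t$tip.label, aln$taxa)
    expect_true(all(t$edge.length >= 0))
  }
  expect_false(identical(write_newick(starting_trees(aln, 1, 1)[[1]]),
                         write_newick(starting_trees(aln, 1, 2)[[1]])) &&
               identical(write_newick(starting_trees(aln, 2, 1)[[2]]),
                         write_newick(starting_trees(aln, 2, 2)[[2]])))
})

test_that("low-information data yield diverse starting trees", {
  tr <- generate_model_tree(16, 0.1, seed = 61)
  mod <- hky_model(2, rep(0.25, 4))
  aln <- simulate_alignment(tr, mod, 150, seed = 62)
  hashes <- vapply(starting_trees(aln, 50, seed = 5), topology_hash, "")
  expect_gt(length(unique(hashes)), 1)
})

test_that("hill climbing accepts only >epsilon improvements, monotonically", {
  aln <- search_fixture$aln; mod <- search_fixture$mod
  start <- starting_trees(aln, 1, seed = 3)[[1]]
  cfg <- search_config(seed = 3, retain_trace = TRUE)
  res <- hill_climb(start, aln, mod, cfg)
  acc <- res$trace[res$trace$accepted, ]
  expect_false(is.unsorted(acc$loglik))
  if (nrow(acc) > 1)
    expect_true(all(diff(acc$loglik) > cfg$epsilon))
  expect_equal(res$best_ll, max(acc$loglik))
  # the trace never records a candidate meaningfully above the result
  expect_lte(max(res$trace$loglik), res$best_ll + cfg$epsilon)
  expect_false(res$capped)
})

test_that("a climb started at the global optimum stays there", {
  aln <- search_fixture$aln; mod <- search_fixture$mod
  ex <- exhaustive_search(aln, mod)
  res <- hill_climb(ex$tree, aln, mod, search_config(seed = 8))
  expect_true(same_topology(res$best_tree, ex$tree))
})

test_that("heuristic search is deterministic for a fixed seed", {
  aln <- search_fixture$aln; mod <- search_fixture$mod
  cfg <- search_config(seed = 111L, n_starts = 2L)
  r1 <- heuristic_search(aln, mod, cfg)
  r2 <- heuristic_search(aln, mod, cfg)
  expect_identical(write_newick(r1$best_tree), write_newick(r2$best_tree))
  expect_identical(r1$best_ll, r2$best_ll)
  expect_gte(r1$best_ll, max(r1$start_lls) - 1e-9)
})

test_that("different seeds can disagree on very low-information data", {
  tr <- generate_model_tree(16, 0.1, seed = 71)
  mod <- hky_model(2, rep(0.25, 4))
  aln <- simulate_alignment(tr, mod, 150, seed = 72)
  cfg <- function(s) search_config(seed = s, n_starts = 2L)
  tops <- vapply(1:12, function(s) {
    topology_hash(heuristic_search(aln, mod, cfg(s))$best_tree)
  }, "")
  expect_gt(length(unique(tops)), 1)
})

test_that("exhaustive search is deterministic and dominates the heuristic", {
  aln <- search_fixture$aln; mod <- search_fixture$mod
  ex1 <- exhaustive_search(aln, mod, epsilon = 1e-6)
  ex2 <- exhaustive_search(aln, mod, epsilon = 1e-6)
  expect_identical(write_newick(ex1$tree), write_newick(ex2$tree))
  expect_equal(nrow(ex1$table), 105)
  for (s in c(4, 9, 14)) {
    r <- heuristic_search(aln, mod, search_config(seed = s, n_starts = 2L))
    expect_lte(r$best_ll, ex1$loglik + 0.01)
  }
})

test_that("exhaustive search refuses more than 8 taxa", {
  aln <- random_alignment(letters[1:9], 20)
  expect_error(exhaustive_search(aln, hky_model(2, rep(0.25, 4))),
               "m <= 8")
})

test_that("a long internal branch decides the 4-taxon problem", {
  tr <- read_newick(text = "((A:0.05,B:0.05):0.5,(C:0.05,D:0.05):0.5);")
  mod <- hky_model(2, rep(0.25, 4))
  aln <- simulate_alignment(tr, mod, 2000, seed = 77)
  ex <- exhaustive_search(aln, mod)
  expect_true(same_topology(ex$tree, tr))
  expect_equal(nrow(ex$table), 3)
  expect_equal(max(ex$table$loglik), ex$loglik)
})

test_that("retained traces carry rejected candidates for forest pooling", {
  aln <- search_fixture$aln; mod <- search_fixture$mod
  res <- heuristic_search(aln, mod,
                          search_config(seed = 5, n_starts = 2L,
                                        retain_trace = TRUE))
  expect_true(any(!res$trace$accepted))
  expect_true(all(c("hash", "newick", "loglik", "accepted", "start")
                  %in% names(res$trace)))
  # with traces retained, every evaluated topology has exactly one row
  expect_equal(res$n_topologies_evaluated, nrow(res$trace))
})
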