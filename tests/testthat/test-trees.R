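test_that("newick parsing handles the basic unrooted cases", {
  t4 <- read_newick(text = "(A:1,B:1,(C:1,D:1):1);")
  expect_equal(ape::Ntip(t4), 4)
  expect_equal(nrow(t4$edge), 5)

  # rooted input: the degree-2 root is suppressed, lengths merged
  t3 <- read_newick(text = "((A:1,B:1):0.5,C:1);")
  expect_false(ape::is.rooted(t3))
  expect_equal(nrow(t3$edge), 3)
  expect_equal(sum(t3$edge.length), 3.5)
  d <- ape::cophenetic.phylo(t3)
  expect_equal(unname(d["A", "B"]), 2)
})

test_that("malformed and duplicated input is rejected with context", {
  expect_error(read_newick(text = "((A,B,C);"), "character")
  expect_error(read_newick(text = "(A,B,(C,D)));"), "character")
  expect_error(read_newick(text = "(A,B,(A,C));"), "duplicate")
})

test_that("missing branch lengths default to zero", {
  t <- read_newick(text = "(A,B,(C,D));")
  expect_equal(t$edge.length, rep(0, 5))
})

test_that("comments, quoted labels and scientific notation parse", {
  t <- read_newick(text = "('sp one':1,B:2e-3,(C:1,D:1)[node note]:1);")
  expect_true("sp one" %in% t$tip.label)
  expect_true(any(abs(t$edge.length - 0.002) < 1e-12))
})

test_that("write/parse round-trip preserves topology and branch lengths", {
  set.seed(42)
  for (i in 1:100) {
    t <- random_tree(16)
    t2 <- read_newick(text = write_newick(t))
    expect_true(same_topology(t, t2))
    expect_equal(sort(t2$edge.length), sort(t$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("bipartition counts match tree shape", {
  t4 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(tree_bipartitions(t4), "A,B")
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  expect_length(tree_bipartitions(star), 0)
  set.seed(7)
  t <- random_tree(12)
  expect_length(tree_bipartitions(t), 12 - 3)
})

test_that("bipartitions are invariant to leaf order in the newick string", {
  nwk1 <- "((A:1,B:1):1,(C:1,(D:1,E:1):1):1,F:1);"
  nwk2 <- "(F:1,((E:1,D:1):1,C:1):1,(B:1,A:1):1);"
  expect_setequal(tree_bipartitions(read_newick(text = nwk1)),
                  tree_bipartitions(read_newick(text = nwk2)))
})

test_that("rf_distance equals brute-force split symmetric difference", {
  set.seed(11)
  for (i in 1:40) {
    t1 <- random_tree(8)
    t2 <- random_tree(8)
    b1 <- brute_force_splits(t1)
    b2 <- brute_force_splits(t2)
    expect_equal(rf_distance(t1, t2),
                 length(setdiff(b1, b2)) + length(setdiff(b2, b1)))
    # cross-check against the phangorn implementation as well
    expect_equal(rf_distance(t1, t2), as.numeric(phangorn::RF.dist(t1, t2)))
  }
})

test_that("rf_distance is a metric on random 8-taxon triples", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_tree(8); b <- random_tree(8); c <- random_tree(8)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, a), 0)
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
  }
})

test_that("rf_distance rejects mismatched taxon sets, naming the missing", {
  t1 <- random_tree(6, labels = letters[1:6])
  t2 <- random_tree(6, labels = letters[2:7])
  expect_error(rf_distance(t1, t2), "g")
})

test_that("rf_percent follows d_RF / (2(m-3)) * 100", {
  set.seed(3)
  t <- random_tree(10)
  expect_equal(rf_percent(t, t), 0)
  # caterpillar vs balanced 8-taxon trees sharing no splits
  cat8 <- read_newick(text =
    "(a:1,b:1,(c:1,(d:1,(e:1,(f:1,(g:1,h:1):1):1):1):1):1);")
  bal8 <- read_newick(text =
    "(((a:1,e:1):1,(c:1,g:1):1):1,((b:1,f:1):1,(d:1,h:1):1):1);")
  expect_equal(rf_distance(cat8, bal8), 2 * (8 - 3))
  expect_equal(rf_percent(cat8, bal8), 100)
  # the printed-formula case: m tips, d_RF splits moved
  t1 <- random_tree(10)
  nb <- nni_neighbors(t1)[[1]]$tree
  expect_equal(rf_percent(t1, nb), 2 / (2 * (10 - 3)) * 100)
})

test_that("rf_percent refuses tiny or unresolved trees", {
  t3 <- read_newick(text = "(A:1,B:1,C:1);")
  expect_error(rf_percent(t3, t3), "4 taxa")
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  expect_error(rf_percent(star, star), "resolved")
})

test_that("same_topology ignores branch lengths but sees NNI moves", {
  set.seed(5)
  t <- random_tree(10)
  t2 <- t
  t2$edge.length <- t$edge.length * runif(nrow(t$edge), 0.1, 10)
  expect_true(same_topology(t, t2))
  for (nb in nni_neighbors(t)[1:4])
    expect_false(same_topology(t, nb$tree))
})

test_that("topology enumeration counts follow (2m-5)!!", {
  expect_length(enumerate_topologies(letters[1:3]), 1)
  expect_length(enumerate_topologies(letters[1:4]), 3)
  expect_length(enumerate_topologies(letters[1:6]), 105)
  expect_length(enumerate_topologies(letters[1:7]), 945)
  hashes <- vapply(enumerate_topologies(letters[1:6]), topology_hash, "")
  expect_equal(anyDuplicated(hashes), 0)
  expect_error(enumerate_topologies(letters[1:9]), "m <= 8")
})
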