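test_that("model trees hit their target length and are seed-deterministic", {
  t1 <- generate_model_tree(4, 1, seed = 5)
  expect_equal(sum(t1$edge.length), 1, tolerance = 1e-12)
  t2 <- generate_model_tree(10, 0.37, seed = 9)
  expect_equal(sum(t2$edge.length), 0.37, tolerance = 1e-12)
  expect_equal(write_newick(generate_model_tree(10, 0.37, seed = 9)),
               write_newick(t2))
  expect_error(generate_model_tree(10, -1), "positive")
  expect_error(generate_model_tree(3, 1), "4 taxa")
})

test_that("Yule draws cover all six-taxon topologies", {
  hashes <- vapply(1:1000, function(i) {
    topology_hash(generate_model_tree(6, 1, seed = 100000 + i))
  }, "")
  expect_equal(length(unique(hashes)), 105)
})

test_that("strict clock leaves the tree untouched, autocorrelation perturbs", {
  tr <- generate_model_tree(10, 100, seed = 3)   # time-like lengths
  strict <- assign_autocorrelated_rates(tr, rate_model("strict"))
  expect_equal(strict$edge.length, tr$edge.length)
  expect_equal(attr(strict, "rate_multipliers"), rep(1, nrow(tr$edge)))
  auto <- assign_autocorrelated_rates(
    tr, rate_model("autocorrelated", autocorrelation_variance = 0.5),
    seed = 7)
  expect_true(all(attr(auto, "rate_multipliers") > 0))
  expect_gt(sd(attr(auto, "rate_multipliers")), 0)
  # vanishing-variance limit: multipliers collapse to 1
  tiny <- assign_autocorrelated_rates(
    tr, rate_model("autocorrelated", autocorrelation_variance = 1e-10),
    seed = 7)
  expect_equal(attr(tiny, "rate_multipliers"), rep(1, nrow(tr$edge)),
               tolerance = 1e-3)
  expect_error(rate_model("autocorrelated",
                          autocorrelation_variance = -1), "non-negative")
})

test_that("parent and child log-rates are positively correlated", {
  rm <- rate_model("autocorrelated", autocorrelation_variance = 0.2)
  pares <- NULL
  for (i in 1:60) {
    tr <- generate_model_tree(16, 400, seed = 9000 + i)
    out <- assign_autocorrelated_rates(tr, rm, seed = 9500 + i)
    logr <- attr(out, "node_log_rates")
    e <- ape::reorder.phylo(out, "cladewise")$edge
    internal <- e[, 2] > ape::Ntip(out)
    pares <- rbind(pares, cbind(logr[e[internal, 1]],
                                logr[e[internal, 2]]))
  }
  expect_gt(nrow(pares), 500)
  expect_gt(cor(pares[, 1], pares[, 2]), 0.3)
})

test_that("simulation with zero-length branches copies the root draw", {
  tr <- read_newick(text = "(a:0,b:0,(c:0,d:0):0);")
  mod <- hky_model(2, c(0.4, 0.1, 0.3, 0.2))
  aln <- simulate_alignment(tr, mod, 200, seed = 12)
  expect_true(all(apply(aln$mat, 2, function(col) length(unique(col)) == 1)))
})

test_that("simulated base composition converges to pi", {
  gc <- 0.7
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  mod <- hky_model(2, pi)
  tr <- read_newick(text = "(a:10,b:10);")   # saturated
  aln <- simulate_alignment(tr, mod, 100000, seed = 20)
  expect_equal(base_frequencies(aln), pi, tolerance = 0.02)
  # saturation: joint tip frequencies approach the pi outer product
  joint <- table(factor(aln$mat["a", ], levels = c("A", "C", "G", "T")),
                 factor(aln$mat["b", ], levels = c("A", "C", "G", "T")))
  expect_equal(as.numeric(joint / sum(joint)), as.numeric(outer(pi, pi)),
               tolerance = 0.01)
})

test_that("HKY with kappa 1 and uniform pi behaves as Jukes-Cantor", {
  d <- 0.4
  tr <- read_newick(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  mod <- hky_model(1, rep(0.25, 4))
  aln <- simulate_alignment(tr, mod, 100000, seed = 21)
  p_obs <- mean(aln$mat["a", ] != aln$mat["b", ])
  expect_equal(p_obs, 3 / 4 * (1 - exp(-4 * d / 3)), tolerance = 0.01)
})

test_that("simulated data recover the generating kappa", {
  tr <- generate_model_tree(8, 2, seed = 41)
  mod <- hky_model(2.6, c(0.3, 0.2, 0.25, 0.25))
  aln <- simulate_alignment(tr, mod, 100000, seed = 42)
  est <- estimate_model_params(tr, aln, hky_model(1.5, rep(0.25, 4)))
  expect_lt(abs(est$kappa - 2.6) / 2.6, 0.05)
})

test_that("phylo_information is the tree length times alignment length", {
  tr <- generate_model_tree(8, 2, seed = 1)
  expect_equal(phylo_information(tr, 1000), 2000, tolerance = 1e-9)
  tr0 <- tr
  tr0$edge.length[] <- 0
  expect_equal(phylo_information(tr0, 1000), 0)
  rerooted <- ape::unroot(ape::root(tr, outgroup = "t03",
                                    resolve.root = TRUE))
  expect_equal(phylo_information(rerooted, 500),
               phylo_information(tr, 500), tolerance = 1e-9)
})

test_that("collections honor their design and are byte-reproducible", {
  d <- design_hundred(n_datasets = 6, n_taxa = 8)
  col <- make_collection(d)
  expect_length(col$datasets, 6)
  for (x in col$datasets) {
    expect_equal(length(x$alignment$taxa), 8)
    expect_gte(x$n_sites, 258)
    expect_lte(x$n_sites, 2000)
    expect_gte(x$model$kappa, 1.35)
    expect_lte(x$model$kappa, 2.6)
    expect_gte(x$gc, 0.39)
    expect_lte(x$gc, 0.82)
    expect_equal(x$information,
                 phylo_information(x$tree, x$n_sites))
  }
  dir1 <- tempfile(); dir2 <- tempfile()
  write_collection(col, dir1)
  write_collection(make_collection(d), dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  for (f in f1) {
    expect_identical(readLines(f),
                     readLines(file.path(dir2, basename(f))))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("ladder designs order information levels strictly", {
  d <- design_ladder(n_levels = 4, n_per_level = 3, n_taxa = 8)
  col <- make_collection(d)
  expect_length(col$datasets, 12)
  lv <- vapply(col$datasets, function(x) x$info_level, 0)
  info <- vapply(col$datasets, function(x) x$information, 0)
  expect_equal(length(unique(lv)), 4)
  expect_equal(info, lv, tolerance = 0.02)
  means <- tapply(info, lv, mean)
  expect_false(is.unsorted(means[order(as.numeric(names(means)))]))
  # GTR+G4 per design
  expect_equal(col$datasets[[1]]$model$kind, "GTR")
  expect_equal(col$datasets[[1]]$model$gamma_shape, 1)
})
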