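test_that("pruning equals brute-force marginalization over internal states", {
  set.seed(21)
  for (i in 1:4) {
    tr <- random_tree(5, mean_bl = 0.3)
    mod <- if (i %% 2) hky_model(runif(1, 1, 4), c(0.3, 0.2, 0.25, 0.25))
           else gtr_model(runif(6, 0.5, 2), rep(0.25, 4), gamma_shape = 1.2)
    aln <- simulate_alignment(tr, mod, 30, seed = i)
    expect_equal(tree_loglik(tr, aln, mod),
                 brute_force_loglik(tr, aln, mod), tolerance = 1e-10)
  }
})

test_that("pruning agrees with an established independent implementation", {
  set.seed(22)
  tr <- random_tree(9, mean_bl = 0.2)
  mod <- hky_model(2.3, c(0.28, 0.22, 0.27, 0.23), gamma_shape = 0.7)
  aln <- simulate_alignment(tr, mod, 400, seed = 9)
  fit <- phangorn::pml(tr, phangorn::phyDat(aln$mat, type = "DNA"),
                       bf = mod$pi, Q = c(1, mod$kappa, 1, 1, mod$kappa, 1),
                       k = 4, shape = 0.7)
  expect_equal(tree_loglik(tr, aln, mod), fit$logLik, tolerance = 1e-8)
})

test_that("single constant site on a zero-length star tree gives log(1/4)", {
  m <- matrix("A", 4, 1, dimnames = list(letters[1:4], NULL))
  aln <- phylo_alignment(m)
  tr <- read_newick(text = "(a:0,b:0,(c:0,d:0):0);")
  mod <- hky_model(2, rep(0.25, 4))
  expect_equal(tree_loglik(tr, aln, mod), log(1 / 4), tolerance = 1e-12)
})

test_that("log-likelihood is negative and finite on real data", {
  set.seed(23)
  tr <- random_tree(7)
  aln <- random_alignment(tr$tip.label, 100)
  mod <- hky_model(2, rep(0.25, 4))
  ll <- tree_loglik(tr, aln, mod)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("likelihood is invariant to where the computation is rooted", {
  set.seed(24)
  tr <- random_tree(8, mean_bl = 0.2)
  mod <- hky_model(2, c(0.3, 0.2, 0.25, 0.25), gamma_shape = 1)
  aln <- simulate_alignment(tr, mod, 200, seed = 3)
  ll <- tree_loglik(tr, aln, mod)
  for (og in c("t02", "t05", "t08")) {
    rerooted <- ape::unroot(ape::root(tr, outgroup = og,
                                      resolve.root = TRUE))
    expect_equal(tree_loglik(rerooted, aln, mod), ll, tolerance = 1e-9)
  }
})

test_that("two-taxon JC likelihood matches the closed form", {
  # closed-form pairwise likelihood: n11 matching sites, n10 differing
  d <- 0.37
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 * d / 3)
  m <- rbind(a = c(rep("A", 70), rep("C", 30)),
             b = c(rep("A", 60), rep("G", 10), rep("C", 25), rep("T", 5)))
  aln <- phylo_alignment(m)
  n_same <- sum(m[1, ] == m[2, ])
  n_diff <- 100 - n_same
  tr <- read_newick(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  mod <- hky_model(1, rep(0.25, 4))
  closed <- n_same * log(p_same / 4) + n_diff * log(p_diff / 4)
  expect_equal(tree_loglik(tr, aln, mod), closed, tolerance = 1e-10)
})

test_that("two-taxon JC branch-length MLE matches -3/4 log(1 - 4p/3)", {
  for (n_diff in c(10, 25, 40)) {
    n <- 100
    m <- rbind(a = rep("A", n),
               b = c(rep("C", n_diff), rep("A", n - n_diff)))
    aln <- phylo_alignment(m)
    tr <- read_newick(text = "(a:0.1,b:0.1);")
    mod <- hky_model(1, rep(0.25, 4))
    fit <- optimize_branch_lengths(tr, aln, mod, epsilon = 1e-7)
    p <- n_diff / n
    expect_equal(sum(fit$tree$edge.length),
                 -3 / 4 * log(1 - 4 * p / 3), tolerance = 1e-4)
  }
})

test_that("branch optimization is monotone and a fixed point at the optimum", {
  set.seed(26)
  tr <- random_tree(7, mean_bl = 0.15)
  mod <- hky_model(2, c(0.3, 0.2, 0.25, 0.25))
  aln <- simulate_alignment(tr, mod, 500, seed = 11)
  fit <- optimize_branch_lengths(tr, aln, mod)
  expect_false(is.unsorted(fit$sweep_ll))
  expect_gte(fit$loglik, tree_loglik(tr, aln, mod))
  refit <- optimize_branch_lengths(fit$tree, aln, mod)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-3)
  expect_equal(refit$tree$edge.length, fit$tree$edge.length,
               tolerance = 1e-2)
  expect_true(all(fit$tree$edge.length >= 1e-8 - 1e-12))
  expect_true(all(fit$tree$edge.length <= 10 + 1e-12))
})

test_that("optimization matches an independent optimizer's optimum", {
  set.seed(27)
  tr <- random_tree(8, mean_bl = 0.2)
  mod <- gtr_model(runif(6, 0.5, 2.5), c(0.3, 0.2, 0.25, 0.25),
                   gamma_shape = 1)
  aln <- simulate_alignment(tr, mod, 600, seed = 13)
  fit <- optimize_branch_lengths(tr, aln, mod, epsilon = 1e-6)
  pfit <- phangorn::pml(tr, phangorn::phyDat(aln$mat, type = "DNA"),
                        bf = mod$pi, Q = mod$exchangeabilities, k = 4,
                        shape = 1)
  pfit <- phangorn::optim.pml(pfit, optEdge = TRUE,
                              control = phangorn::pml.control(
                                epsilon = 1e-9, trace = 0))
  expect_equal(fit$loglik, pfit$logLik, tolerance = 1e-4)
})

test_that("score_trees re-scores a tree file the way the forest needs", {
  set.seed(28)
  tr <- random_tree(6, mean_bl = 0.2)
  mod <- hky_model(2, rep(0.25, 4))
  aln <- simulate_alignment(tr, mod, 200, seed = 17)
  trees <- c(list(tr), lapply(nni_neighbors(tr)[1:3],
                              function(x) x$tree))
  tf <- tempfile(fileext = ".nwk")
  af <- tempfile(fileext = ".fasta")
  write_newick(trees, tf)
  write_alignment(aln, af)
  out <- tempfile(fileext = ".tsv")
  tab <- score_tree_file(tf, af, mod, out_tsv = out)
  expect_equal(nrow(read.delim(out)), 4)
  direct <- score_trees(trees, aln, mod)
  expect_equal(tab$loglik, direct$loglik)
  expect_equal(which.max(direct$loglik), 1)
  unlink(c(tf, af, out))
})

test_that("model parameters are recovered from simulated data", {
  tr <- generate_model_tree(8, 2, seed = 31)
  mod <- hky_model(2, c(0.3, 0.2, 0.25, 0.25))
  aln <- simulate_alignment(tr, mod, 50000, seed = 32)
  est <- estimate_model_params(tr, aln, hky_model(1.5, rep(0.25, 4)),
                               free = c("base_freqs", "kappa"))
  expect_lt(abs(est$kappa - 2) / 2, 0.05)
  expect_equal(est$pi, base_frequencies(aln))
  expect_lt(max(abs(est$pi - mod$pi)), 0.02)
  # fixing all parameters returns the template unchanged
  tmpl <- hky_model(1.5, rep(0.25, 4))
  expect_identical(estimate_model_params(tr, aln, tmpl,
                                         free = character(0)), tmpl)
})
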