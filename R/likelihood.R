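# default branch-length bounds and optimizer tolerances for the engine
BL_MIN <- 1e-8
BL_MAX <- 10
BRENT_TOL <- 1e-6
LL_EPSILON <- 1e-4

# marshal tree/alignment/model into the C++ engine's argument list
eng_args <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "phylo_alignment"),
            inherits(model, "subst_model"))
  if (ape::Ntip(tree) > 2) tree <- as_unrooted(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  states <- align_states(aln, tree)
  storage.mode(states) <- "integer"
  storage.mode(tree$edge) <- "integer"
  list(edge = tree$edge, el = as.numeric(tree$edge.length),
       ntip = ape::Ntip(tree), states = states,
       weights = as.numeric(aln$weights), pi = model$pi,
       U = model$U, Uinv = model$Uinv, eva = model$eva,
       rates = as.numeric(model$rates), tree = tree)
}

#' Phylogenetic log-likelihood
#'
#' Felsenstein's pruning algorithm over compressed site patterns, with the
#' discrete-gamma rate mixture averaged with equal category weights.  The
#' unrooted-tree likelihood is invariant to where the computation is rooted
#' (reversible, mean-rate-normalized Q).  Natural-log units.
#'
#' @param tree `phylo` with branch lengths in expected substitutions/site.
#' @param aln a [phylo_alignment] over the tree's taxa.
#' @param model a [subst_model].
#' @return log-likelihood (numeric scalar, `<= 0` for any data).
#' @export
tree_loglik <- function(tree, aln, model) {
  a <- eng_args(tree, aln, model)
  eng_loglik(a$edge, a$el, a$ntip, a$states, a$weights, a$pi, a$U, a$Uinv,
             a$eva, a$rates)
}

#' Per-site log-likelihoods
#'
#' @inheritParams tree_loglik
#' @return numeric vector, one log-likelihood per alignment site (pattern
#'   values expanded back to sites).
#' @export
site_log_likelihoods <- function(tree, aln, model) {
  a <- eng_args(tree, aln, model)
  per_pat <- eng_site_loglik(a$edge, a$el, a$ntip, a$states, a$weights, a$pi,
                             a$U, a$Uinv, a$eva, a$rates)
  per_pat[aln$pattern_index]
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Round-robin Brent optimization of each branch in turn (all branches, or
#' the subset in `edges`), sweeping until the log-likelihood gain of a full
#' sweep drops below `epsilon`.  Each Brent step never decreases the
#' likelihood, so the sweep trace is monotone non-decreasing.
#'
#' @inheritParams tree_loglik
#' @param epsilon log-likelihood convergence tolerance per sweep
#'   (default 0.0001).
#' @param max_sweeps sweep cap; if reached without converging the
#'   best-so-far fit is returned with a warning, not an error.
#' @param edges optional integer vector of edge-matrix rows to optimize
#'   (default: all edges).
#' @param min_bl,max_bl branch-length box constraints.
#' @param brent_tol per-branch Brent tolerance.
#' @return list with `tree` (optimized branch lengths), `loglik`,
#'   `sweep_ll` (log-likelihood after each sweep), `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, epsilon = LL_EPSILON,
                                    max_sweeps = 50L, edges = NULL,
                                    min_bl = BL_MIN, max_bl = BL_MAX,
                                    brent_tol = BRENT_TOL) {
  stopifnot(epsilon > 0)
  a <- eng_args(tree, aln, model)
  if (is.null(edges)) edges <- seq_len(nrow(a$edge))
  fit <- eng_optimize(a$edge, a$el, a$ntip, a$states, a$weights, a$pi, a$U,
                      a$Uinv, a$eva, a$rates, as.integer(edges), epsilon,
                      as.integer(max_sweeps), min_bl, max_bl, brent_tol)
  if (!fit$converged && max_sweeps > 1L)
    warning("branch-length optimization did not converge within ",
            max_sweeps, " sweeps; returning best-so-far")
  out_tree <- a$tree
  out_tree$edge.length <- fit$edge_length
  list(tree = out_tree, loglik = fit$loglik, sweep_ll = fit$sweep_ll,
       converged = fit$converged)
}

#' Score a set of trees against one alignment
#'
#' The re-scoring step of the optimality-forest protocol: evaluate (and
#' optionally re-optimize branch lengths of) each tree on the same
#' alignment.
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @inheritParams tree_loglik
#' @param optimize re-optimize branch lengths per tree (default TRUE).
#' @param epsilon convergence tolerance passed to
#'   [optimize_branch_lengths()].
#' @return data.frame with columns `index`, `loglik`.
#' @export
score_trees <- function(trees, aln, model, optimize = TRUE,
                        epsilon = LL_EPSILON) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ll <- vapply(trees, function(t) {
    if (optimize) optimize_branch_lengths(t, aln, model,
                                          epsilon = epsilon)$loglik
    else tree_loglik(t, aln, model)
  }, 0)
  data.frame(index = seq_along(ll), loglik = ll)
}

#' Score a Newick file of trees against an alignment file
#'
#' @param tree_file Newick file, one tree per line.
#' @param alignment_file FASTA or PHYLIP alignment.
#' @param model a [subst_model].
#' @param out_tsv optional path; when given, a TSV of (index, loglik) is
#'   written there.
#' @inheritParams score_trees
#' @return the score table, invisibly when writing.
#' @export
score_tree_file <- function(tree_file, alignment_file, model, out_tsv = NULL,
                            optimize = TRUE) {
  trees <- read_newick(file = tree_file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  aln <- read_alignment(alignment_file)
  tab <- score_trees(trees, aln, model, optimize = optimize)
  if (!is.null(out_tsv)) {
    write.table(tab, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Estimate free substitution-model parameters on a fixed topology
#'
#' Maximizes the log-likelihood over the parameters named in `free`, holding
#' the topology fixed.  Base frequencies are estimated as the empirical
#' alignment frequencies; `kappa` and `gamma_shape` by bounded
#' one-dimensional optimization alternated with branch-length
#' re-optimization.  With `free = character(0)` the template is returned
#' unchanged.
#'
#' @inheritParams tree_loglik
#' @param model template [subst_model] providing the fixed parameters.
#' @param free character subset of `c("base_freqs", "kappa", "gamma_shape")`.
#' @param rounds alternation rounds (default 2).
#' @return a fitted [subst_model].
#' @export
estimate_model_params <- function(tree, aln, model,
                                  free = c("base_freqs", "kappa"),
                                  rounds = 2L) {
  if (length(free) == 0) return(model)
  free <- match.arg(free, c("base_freqs", "kappa", "gamma_shape"),
                    several.ok = TRUE)
  rebuild <- function(kappa, shape, pi) {
    subst_model(model$kind, base_freqs = pi, kappa = kappa,
                exchangeabilities = model$exchangeabilities,
                gamma_shape = shape, n_categories = max(model$n_categories,
                                                        4L))
  }
  pi <- if ("base_freqs" %in% free) base_frequencies(aln) else model$pi
  kappa <- if (is.null(model$kappa)) 2 else model$kappa
  shape <- model$gamma_shape
  cur <- rebuild(kappa, shape, pi)
  fit <- optimize_branch_lengths(tree, aln, cur)
  for (r in seq_len(rounds)) {
    if ("kappa" %in% free && model$kind == "HKY") {
      opt <- optimize(function(k) {
        tree_loglik(fit$tree, aln, rebuild(k, shape, pi))
      }, interval = c(0.05, 100), maximum = TRUE, tol = 1e-4)
      kappa <- opt$maximum
    }
    if ("gamma_shape" %in% free) {
      opt <- optimize(function(s) {
        tree_loglik(fit$tree, aln, rebuild(kappa, s, pi))
      }, interval = c(0.05, 50), maximum = TRUE, tol = 1e-4)
      shape <- opt$maximum
    }
    cur <- rebuild(kappa, shape, pi)
    fit <- optimize_branch_lengths(fit$tree, aln, cur)
  }
  cur
}
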