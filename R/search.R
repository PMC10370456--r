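#' Heuristic-search configuration
#'
#' @param seed integer seed; together with the data it fully determines the
#'   search.
#' @param n_starts number of starting trees.
#' @param moves `"NNI"` (default) or `"SPR"`; with `"SPR"`, a sample of SPR
#'   rearrangements is screened in addition to the full NNI neighborhood.
#' @param epsilon log-likelihood acceptance/convergence tolerance
#'   (default 0.0001).
#' @param retain_trace keep every evaluated candidate topology
#'   (accepted and rejected) in the result's trace.
#' @param initial_tree optional `phylo` used as the first starting tree
#'   (its branch lengths are re-optimized first); remaining starts are
#'   random-NNI perturbations of it.
#' @param max_iterations cap on accepted moves per climb.
#' @param n_spr_samples SPR candidates sampled per iteration when
#'   `moves = "SPR"`.
#' @param start_method passed to [starting_trees()].
#' @return object of class `search_config`.
#' @export
search_config <- function(seed, n_starts = 6L, moves = c("NNI", "SPR"),
                          epsilon = LL_EPSILON, retain_trace = FALSE,
                          initial_tree = NULL, max_iterations = 200L,
                          n_spr_samples = 10L,
                          start_method = c("mixed", "stepwise",
                                           "bootstrap")) {
  moves <- match.arg(moves)
  start_method <- match.arg(start_method)
  stopifnot(epsilon > 0, n_starts >= 1, max_iterations >= 1)
  structure(list(seed = as.integer(seed), n_starts = as.integer(n_starts),
                 moves = moves, epsilon = epsilon,
                 retain_trace = isTRUE(retain_trace),
                 initial_tree = initial_tree,
                 max_iterations = as.integer(max_iterations),
                 n_spr_samples = as.integer(n_spr_samples),
                 start_method = start_method),
            class = "search_config")
}

#' NNI neighborhood of an unrooted binary tree
#'
#' All 2(m-3) nearest-neighbor-interchange rearrangements.  Branch lengths
#' travel with their subtrees; the swapped branches keep their lengths.
#'
#' @param tree fully resolved unrooted `phylo`.
#' @return list of candidates, each a list with `tree` and `opt_edges`, the
#'   edge-matrix rows incident to the rearranged edge (the branches a quick
#'   re-optimization should touch).
#' @export
nni_neighbors <- function(tree) {
  tree <- as_unrooted(tree)
  m <- ape::Ntip(tree)
  if (nrow(tree$edge) != 2 * m - 3)
    stop("NNI neighborhood requires a fully resolved tree")
  edge <- tree$edge
  internal <- which(edge[, 2] > m)
  out <- vector("list", 2 * length(internal))
  n_out <- 0L
  for (e in internal) {
    u <- edge[e, 1]; v <- edge[e, 2]
    v_children <- which(edge[, 1] == v)
    u_other <- setdiff(which(edge[, 1] == u), e)[1]
    for (ck in v_children) {
      ed <- edge
      ed[ck, 1] <- u
      ed[u_other, 1] <- v
      nt <- tree
      nt$edge <- ed
      attr(nt, "order") <- NULL
      nt <- ape::reorder.phylo(nt, "cladewise")
      opt <- which(nt$edge[, 1] %in% c(u, v) | nt$edge[, 2] %in% c(u, v))
      n_out <- n_out + 1L
      out[[n_out]] <- list(tree = nt, opt_edges = opt)
    }
  }
  out[seq_len(n_out)]
}

# k random NNI moves (used for perturbed restarts from an initial tree)
perturb_tree <- function(tree, k = 2L) {
  for (i in seq_len(k)) {
    nb <- nni_neighbors(tree)
    tree <- nb[[sample.int(length(nb), 1)]]$tree
  }
  tree
}

#' Starting trees for heuristic search
#'
#' A deterministic-per-seed mix of (i) parsimony stepwise-addition trees
#' under random taxon orders and (ii) neighbor-joining trees built from
#' bootstrap-resampled site columns (JC distances), alternating.  These are
#' the seed-sensitive entry points of the heuristic search: different seeds
#' give different starting trees, which is the mechanism behind
#' computational irreproducibility.
#'
#' @param aln a [phylo_alignment].
#' @param n number of starting trees.
#' @param seed integer seed; start `j` uses a seed derived from
#'   (`seed`, `j`), so the first `k` starts are identical for any `n >= k`.
#' @param method `"mixed"` (default), `"stepwise"` or `"bootstrap"`.
#' @return list of unrooted `phylo` trees with initial branch lengths.
#' @export
starting_trees <- function(aln, n, seed, method = c("mixed", "stepwise",
                                                    "bootstrap")) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  pd <- phangorn::phyDat(aln$mat, type = "DNA")
  lapply(seq_len(n), function(j) {
    kind <- switch(method, mixed = if (j %% 2 == 1) "stepwise"
                                   else "bootstrap",
                   stepwise = "stepwise", bootstrap = "bootstrap")
    withr::with_seed(derive_seed(seed, j), {
      if (kind == "stepwise") {
        tr <- phangorn::random.addition(pd)
        tr$edge.length <- rep(0.1, nrow(tr$edge))
      } else {
        idx <- sample.int(aln$n_sites, replace = TRUE)
        db <- ape::as.DNAbin(aln$mat[, idx, drop = FALSE])
        d <- ape::dist.dna(db, model = "JC69", pairwise.deletion = TRUE)
        bad <- !is.finite(d)
        if (any(bad)) d[bad] <- max(c(d[!bad], 1)) * 2
        tr <- ape::nj(d)
        tr$edge.length[tr$edge.length < 0] <- 0
      }
      as_unrooted(tr)
    })
  })
}

trace_row <- function(iteration, tree, loglik, accepted, note) {
  data.frame(iteration = iteration, hash = topology_hash(tree),
             newick = write_newick(tree), loglik = loglik,
             accepted = accepted, note = note,
             stringsAsFactors = FALSE)
}

#' Greedy NNI hill climb from one starting tree
#'
#' Steepest-ascent local search: at each iteration every NNI neighbor is
#' screened with a quick branch-length pass restricted to the rearranged
#' branches, the best candidate is fully re-optimized, and it is accepted
#' only if it improves the log-likelihood by more than `epsilon`.  The walk
#' stops at a local optimum (or at the iteration cap, flagged `capped`).
#'
#' @param start starting `phylo`.
#' @param aln a [phylo_alignment].
#' @param model a [subst_model].
#' @param config a [search_config]; the ambient RNG stream (or
#'   `config$seed` when `use_seed = TRUE`) drives the neighbor-order
#'   shuffle that makes tie-breaking seed-sensitive.
#' @param use_seed seed the climb with `config$seed` (single-climb use);
#'   [heuristic_search()] manages seeds itself and passes `FALSE`.
#' @return object of class `search_result`: `best_tree`, `best_ll`,
#'   `trace` (when retained), `n_topologies_evaluated`, `capped`, `seed`.
#' @export
hill_climb <- function(start, aln, model, config, use_seed = TRUE) {
  run <- function() {
    cur <- optimize_branch_lengths(start, aln, model,
                                   epsilon = config$epsilon)
    trace <- list(trace_row(0L, cur$tree, cur$loglik, TRUE, "start"))
    n_eval <- 1L
    capped <- FALSE
    iter <- 0L
    repeat {
      if (iter >= config$max_iterations) {
        capped <- TRUE
        break
      }
      iter <- iter + 1L
      cands <- nni_neighbors(cur$tree)
      if (config$moves == "SPR") {
        sprs <- lapply(seq_len(config$n_spr_samples), function(i) {
          t2 <- phangorn::rSPR(cur$tree, moves = 1)
          t2$edge.length <- rep(mean(cur$tree$edge.length),
                                nrow(t2$edge))
          list(tree = as_unrooted(t2), opt_edges = NULL)
        })
        cands <- c(cands, sprs)
      }
      ord <- sample.int(length(cands))
      quick <- vector("list", length(cands))
      for (k in ord) {
        cand <- cands[[k]]
        edges <- if (is.null(cand$opt_edges)) seq_len(nrow(cand$tree$edge))
                 else cand$opt_edges
        quick[[k]] <- optimize_branch_lengths(cand$tree, aln, model,
                                              epsilon = config$epsilon,
                                              max_sweeps = 1L,
                                              edges = edges)
      }
      n_eval <- n_eval + length(cands)
      qll <- vapply(quick, function(f) f$loglik, 0)
      best_k <- ord[which.max(qll[ord])]
      full <- optimize_branch_lengths(quick[[best_k]]$tree, aln, model,
                                      epsilon = config$epsilon)
      if (config$retain_trace) {
        for (k in ord) {
          if (k == best_k) next
          trace[[length(trace) + 1L]] <-
            trace_row(iter, quick[[k]]$tree, qll[k], FALSE, "screened")
        }
      }
      if (full$loglik > cur$loglik + config$epsilon) {
        cur <- full
        trace[[length(trace) + 1L]] <-
          trace_row(iter, cur$tree, cur$loglik, TRUE, "accepted")
      } else {
        if (config$retain_trace)
          trace[[length(trace) + 1L]] <-
            trace_row(iter, full$tree, full$loglik, FALSE, "best-rejected")
        break
      }
    }
    structure(list(best_tree = cur$tree, best_ll = cur$loglik,
                   trace = if (config$retain_trace)
                     do.call(rbind, trace) else NULL,
                   n_topologies_evaluated = n_eval, capped = capped,
                   seed = config$seed),
              class = "search_result")
  }
  if (use_seed) with_seed_maybe(config$seed, run()) else run()
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: best log-likelihood", format(x$best_ll), "(seed",
      x$seed, ",", x$n_topologies_evaluated, "topologies evaluated",
      if (x$capped) ", iteration-capped" else "", ")\n")
  invisible(x)
}

#' Seeded heuristic maximum-likelihood tree search
#'
#' Runs [hill_climb()] from each of `config$n_starts` starting trees (or
#' from `config$initial_tree` plus perturbed variants of it) and returns
#' the overall best local optimum.  Every random choice is derived from
#' `config$seed` by counter, so identical inputs and seed reproduce the
#' identical result, while different seeds may land on different local
#' optima: the engine's model of computational irreproducibility.
#'
#' @inheritParams hill_climb
#' @return a `search_result`; with `config$retain_trace` the traces of all
#'   climbs are row-bound with a `start` column.
#' @export
heuristic_search <- function(aln, model, config) {
  stopifnot(inherits(config, "search_config"))
  if (is.null(config$initial_tree)) {
    starts <- starting_trees(aln, config$n_starts, config$seed,
                             method = config$start_method)
  } else {
    # the supplied tree heads the start list; the engine still generates
    # its usual candidate starting trees, as the reference programs do
    # when an initial tree is passed in
    init <- as_unrooted(config$initial_tree)
    starts <- c(list(init),
                starting_trees(aln, config$n_starts - 1L, config$seed,
                               method = config$start_method))
  }
  climbs <- lapply(seq_along(starts), function(j) {
    withr::with_seed(derive_seed(config$seed, 10000L + j),
                     hill_climb(starts[[j]], aln, model, config,
                                use_seed = FALSE))
  })
  lls <- vapply(climbs, function(r) r$best_ll, 0)
  # ties within epsilon of the maximum are broken by a seed-shuffled start
  # order: equal-likelihood optima are reported seed-dependently, the same
  # tie-break principle the climb applies to its neighbor order
  shuffle <- withr::with_seed(derive_seed(config$seed, 999L),
                              sample.int(length(climbs)))
  tied <- which(lls >= max(lls) - config$epsilon)
  best <- shuffle[shuffle %in% tied][1]
  res <- climbs[[best]]
  res$start_lls <- lls
  res$start_index_best <- best
  res$capped <- any(vapply(climbs, function(r) r$capped, NA))
  res$n_topologies_evaluated <-
    sum(vapply(climbs, function(r) r$n_topologies_evaluated, 0L))
  if (config$retain_trace) {
    res$trace <- do.call(rbind, lapply(seq_along(climbs), function(j) {
      tr <- climbs[[j]]$trace
      tr$start <- j
      tr
    }))
  }
  res
}

#' Exhaustive maximum-likelihood search (small taxon sets)
#'
#' Optimizes branch lengths on every unrooted binary topology
#' ([enumerate_topologies], m <= 8) and returns the global optimum.  Fully
#' deterministic: no seed enters; exact log-likelihood ties are broken by
#' the canonical topology hash.
#'
#' @param aln a [phylo_alignment] with at most 8 taxa.
#' @param model a [subst_model].
#' @param epsilon branch-length convergence tolerance.
#' @return list with `tree`, `loglik`, and `table` (per-topology
#'   log-likelihoods).
#' @export
exhaustive_search <- function(aln, model, epsilon = LL_EPSILON) {
  topos <- enumerate_topologies(aln$taxa)
  fits <- lapply(topos, function(t) {
    t$edge.length <- rep(0.1, nrow(t$edge))
    optimize_branch_lengths(t, aln, model, epsilon = epsilon)
  })
  lls <- vapply(fits, function(f) f$loglik, 0)
  best <- which(lls == max(lls))
  if (length(best) > 1) {
    hashes <- vapply(fits[best], function(f) topology_hash(f$tree), "")
    best <- best[order(hashes)][1]
  }
  list(tree = fits[[best]]$tree, loglik = lls[best],
       table = data.frame(index = seq_along(lls), loglik = lls))
}
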