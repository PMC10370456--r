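# Independent oracles and small fixture builders used across the suite.

# Brute-force log-likelihood: marginalize over all internal-node state
# assignments explicitly, per site, using transition matrices only.
# Independent of the pruning recursion (no shared traversal code).
brute_force_loglik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "cladewise")
  ntip <- ape::Ntip(tree)
  n_internal <- tree$Nnode
  states <- match(aln$mat[tree$tip.label, , drop = FALSE],
                  c("A", "C", "G", "T"))
  states <- matrix(states, nrow = ntip)
  ncat <- length(model$rates)
  Ps <- lapply(seq_len(ncat), function(c) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      transition_matrix(model, tree$edge.length[e], model$rates[c])
    })
  })
  grid <- as.matrix(expand.grid(rep(list(1:4), n_internal)))
  total <- 0
  for (s in seq_len(ncol(states))) {
    site_lik <- 0
    for (c in seq_len(ncat)) {
      lik_c <- 0
      for (g in seq_len(nrow(grid))) {
        full <- c(states[, s], grid[g, ])
        p <- model$pi[full[ntip + 1]]
        for (e in seq_len(nrow(tree$edge))) {
          a <- full[tree$edge[e, 1]]
          b <- full[tree$edge[e, 2]]
          p <- p * Ps[[c]][[e]][a, b]
        }
        lik_c <- lik_c + p
      }
      site_lik <- site_lik + lik_c / ncat
    }
    total <- total + log(site_lik)
  }
  total
}

# random fully-resolved unrooted tree with exponential branch lengths
random_tree <- function(m, mean_bl = 0.1, labels = sprintf("t%02d", 1:m)) {
  tr <- ape::rtree(m, rooted = FALSE, tip.label = labels)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl)
  optforest:::as_unrooted(tr)
}

# random alignment (iid uniform sites; no tree signal)
random_alignment <- function(taxa, n_sites) {
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n_sites,
                     replace = TRUE), nrow = length(taxa))
  rownames(m) <- taxa
  phylo_alignment(m)
}

# enumerate the non-trivial splits of a tree the slow way: for every
# internal edge, flood-fill the graph with that edge removed
brute_force_splits <- function(tree) {
  tree <- ape::unroot(tree)
  m <- ape::Ntip(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  edges <- tree$edge
  internal <- which(edges[, 2] > m)
  out <- character(0)
  for (e in internal) {
    adj <- lapply(seq_len(m + tree$Nnode), function(i) integer(0))
    for (k in seq_len(nrow(edges))) {
      if (k == e) next
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(m + tree$Nnode)
    stack <- edges[e, 2]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    blk <- labs[which(seen[seq_len(m)])]
    if (length(blk) <= 1 || length(blk) >= m - 1) next
    if (!(ref %in% blk)) blk <- setdiff(labs, blk)
    out <- c(out, paste(sort(blk), collapse = ","))
  }
  unique(out)
}
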