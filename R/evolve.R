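#' Lineage rate models
#'
#' Either a strict clock (all lineages share one rate) or an autocorrelated
#' lognormal model in which the log-rate of a child node is normally
#' distributed around the parent's log-rate with variance proportional to
#' the elapsed branch duration (Kishino-Thorne style).
#'
#' @param kind `"strict"` or `"autocorrelated"`.
#' @param initial_rate rate at the root, substitutions/site/year.
#' @param autocorrelation_variance variance of the log-rate accumulated per
#'   100 million years of branch duration.
#' @return object of class `rate_model`.
#' @export
rate_model <- function(kind = c("strict", "autocorrelated"),
                       initial_rate = 2e-9,
                       autocorrelation_variance = 0.04) {
  kind <- match.arg(kind)
  if (initial_rate <= 0) stop("initial_rate must be positive")
  if (autocorrelation_variance < 0)
    stop("autocorrelation_variance must be non-negative")
  structure(list(kind = kind, initial_rate = initial_rate,
                 autocorrelation_variance = autocorrelation_variance),
            class = "rate_model")
}

#' Random model tree
#'
#' A Yule (pure-birth) topology on `n_taxa` tips, unrooted, with branch
#' lengths rescaled so that their sum equals `tree_length` (expected
#' substitutions per site summed over edges).
#'
#' @param n_taxa number of tips (>= 4).
#' @param tree_length target sum of branch lengths (> 0).
#' @param seed optional integer seed; the same (n_taxa, tree_length, seed)
#'   always yields the same tree.
#' @return unrooted `phylo`.
#' @export
generate_model_tree <- function(n_taxa, tree_length, seed = NULL) {
  if (n_taxa < 4) stop("need at least 4 taxa")
  if (tree_length <= 0) stop("tree_length must be positive")
  with_seed_maybe(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
    tr <- as_unrooted(tr)
    tr$edge.length <- tr$edge.length * tree_length / sum(tr$edge.length)
    tr
  })
}

#' Assign autocorrelated lineage rates to a time tree
#'
#' Walks the tree from the root drawing each node's log-rate from a normal
#' centred on its parent's log-rate with variance proportional to the
#' branch duration, then multiplies every branch length by the geometric
#' mean of its endpoint rates relative to the root rate.  Multipliers are
#' dimensionless (strict model: all exactly 1), so the input units are
#' preserved; converting durations to expected substitutions is the
#' caller's job (duration x rate).
#'
#' @param tree `phylo` with branch lengths in time units (million years).
#' @param rm a [rate_model].
#' @param seed optional integer seed.
#' @return `phylo` with perturbed branch lengths; attributes
#'   `rate_multipliers` (per edge) and `node_log_rates` carry the realized
#'   rates.
#' @export
assign_autocorrelated_rates <- function(tree, rm, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(rm, "rate_model"))
  if (rm$kind == "strict") {
    attr(tree, "rate_multipliers") <- rep(1, nrow(tree$edge))
    return(tree)
  }
  with_seed_maybe(seed, {
    nu <- rm$autocorrelation_variance / 100      # per My
    tr <- ape::reorder.phylo(tree, "cladewise")
    n_nodes <- ape::Ntip(tr) + tr$Nnode
    logr <- rep(NA_real_, n_nodes)
    root <- ape::Ntip(tr) + 1L
    logr[root] <- log(rm$initial_rate)
    mult <- numeric(nrow(tr$edge))
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      dt <- tr$edge.length[k]
      logr[ch] <- rnorm(1, mean = logr[p], sd = sqrt(nu * dt))
      mult[k] <- exp((logr[p] + logr[ch]) / 2 - log(rm$initial_rate))
    }
    tr$edge.length <- tr$edge.length * mult
    attr(tr, "rate_multipliers") <- mult
    attr(tr, "node_log_rates") <- logr
    tr
  })
}

#' Simulate a nucleotide alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' edge-wise with the model's transition matrices.  With discrete-gamma
#' rate heterogeneity, each site's rate category is drawn once and kept for
#' the whole tree.  Alignments are gap-free.
#'
#' @param tree `phylo`, branch lengths in expected substitutions per site.
#' @param model a [subst_model].
#' @param n_sites alignment length (>= 1).
#' @param seed optional integer seed; the same inputs and seed give the
#'   identical alignment.
#' @return a [phylo_alignment].
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"),
            n_sites >= 1)
  with_seed_maybe(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- ape::Ntip(tr)
    n_nodes <- ntip + tr$Nnode
    root <- ntip + 1L
    ncat <- length(model$rates)
    cat_of_site <- if (ncat > 1)
      sample.int(ncat, n_sites, replace = TRUE) else rep(1L, n_sites)
    states <- matrix(0L, n_nodes, n_sites)
    states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = model$pi)
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      for (c in seq_len(ncat)) {
        idx <- which(cat_of_site == c)
        if (length(idx) == 0) next
        P <- transition_matrix(model, tr$edge.length[k], model$rates[c])
        cum <- t(apply(P, 1, cumsum))
        u <- runif(length(idx))
        ps <- states[p, idx]
        states[ch, idx] <- 1L + (u > cum[cbind(ps, 1)]) +
          (u > cum[cbind(ps, 2)]) + (u > cum[cbind(ps, 3)])
      }
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip)
    rownames(m) <- tr$tip.label
    phylo_alignment(m)
  })
}

#' Phylogenetic information of a data set
#'
#' Expected number of substitutions in the alignment: the sum of the true
#' tree's branch lengths (substitutions/site) times the alignment length.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param n_sites alignment length.
#' @return expected substitution count.
#' @export
phylo_information <- function(tree, n_sites) {
  sum(tree$edge.length) * n_sites
}

#' Simulation designs
#'
#' A `sim_design` bundles the parameter ranges from which each data set of a
#' collection draws its own values.  Two presets mirror the two study
#' designs at desk scale:
#'
#' * `design_hundred()`: 100 data sets, 16 taxa, HKY, sequence lengths
#'   258-2,000 sites, GC content 0.39-0.82, kappa 1.35-2.6, lineage rates
#'   0.81-3.95e-9 substitutions/site/year on Yule time trees with
#'   autocorrelated lognormal rate variation.
#' * `design_ladder()`: an informativeness ladder: `n_levels` levels of
#'   target expected-substitution counts (geometrically spaced over
#'   `info_range`), `n_per_level` data sets each, GTR+G4 (shape 1).
#'   Each data set draws a moderate tree length and takes its alignment
#'   length from the information target, so higher levels mean more sites,
#'   not saturated branches.
#'
#' @param name design label.
#' @param n_taxa taxa per data set.
#' @param n_datasets number of data sets (single-level designs).
#' @param model_kind `"HKY"` or `"GTR"`.
#' @param site_range integer range of alignment lengths.
#' @param gc_range range of G+C content.
#' @param kappa_range HKY transition/transversion ratio range.
#' @param exch_range range from which each GTR exchangeability is drawn.
#' @param gamma_shape discrete-gamma shape (NULL for homogeneity).
#' @param rate_range lineage rate range, substitutions/site/year.
#' @param total_time_range total branch duration of the Yule time tree,
#'   million years.
#' @param tree_length_range tree lengths (substitutions/site) from which
#'   ladder data sets draw; alignment length then follows from the
#'   information target.
#' @param rate_kind lineage rate model kind.
#' @param autocorrelation_variance log-rate variance per 100 My.
#' @param info_levels explicit expected-substitution targets (ladder
#'   designs); overrides `info_range`.
#' @param info_range,n_levels,n_per_level ladder geometry.
#' @param master_seed integer master seed; per-dataset seeds are derived
#'   from it by counter.
#' @return object of class `sim_design`.
#' @export
sim_design <- function(name, n_taxa, n_datasets, model_kind = "HKY",
                       site_range = c(258L, 2000L),
                       gc_range = c(0.39, 0.82),
                       kappa_range = c(1.35, 2.6),
                       exch_range = c(0.5, 3),
                       gamma_shape = NULL,
                       rate_range = c(0.81e-9, 3.95e-9),
                       total_time_range = c(30, 150),
                       tree_length_range = c(0.4, 2.5),
                       rate_kind = "autocorrelated",
                       autocorrelation_variance = 0.04,
                       info_levels = NULL,
                       master_seed = 20230719L) {
  stopifnot(n_taxa >= 4, n_datasets >= 1,
            site_range[1] >= 1, diff(site_range) >= 0,
            diff(gc_range) >= 0, diff(kappa_range) >= 0)
  structure(list(name = name, n_taxa = as.integer(n_taxa),
                 n_datasets = as.integer(n_datasets),
                 model_kind = match.arg(model_kind, c("HKY", "GTR")),
                 site_range = as.integer(site_range), gc_range = gc_range,
                 kappa_range = kappa_range, exch_range = exch_range,
                 gamma_shape = gamma_shape, rate_range = rate_range,
                 total_time_range = total_time_range,
                 tree_length_range = tree_length_range,
                 rate_kind = rate_kind,
                 autocorrelation_variance = autocorrelation_variance,
                 info_levels = info_levels,
                 master_seed = as.integer(master_seed)),
            class = "sim_design")
}

#' @rdname sim_design
#' @export
design_hundred <- function(n_datasets = 100L, n_taxa = 16L,
                           site_range = c(258L, 2000L),
                           master_seed = 20230719L) {
  sim_design("hundred", n_taxa = n_taxa, n_datasets = n_datasets,
             model_kind = "HKY", site_range = site_range,
             master_seed = master_seed)
}

#' @rdname sim_design
#' @export
design_ladder <- function(n_levels = 5L, n_per_level = 20L, n_taxa = 16L,
                          info_range = c(150, 10000),
                          tree_length_range = c(0.4, 2.5),
                          master_seed = 20230719L) {
  stopifnot(n_levels >= 2)
  levels <- exp(seq(log(info_range[1]), log(info_range[2]),
                    length.out = n_levels))
  sim_design("ladder", n_taxa = n_taxa,
             n_datasets = as.integer(n_levels * n_per_level),
             model_kind = "GTR",
             gc_range = c(0.4, 0.6), gamma_shape = 1,
             rate_kind = "strict",
             tree_length_range = tree_length_range,
             info_levels = rep(levels, each = n_per_level),
             master_seed = master_seed)
}

#' @export
print.sim_design <- function(x, ...) {
  cat("sim_design '", x$name, "': ", x$n_datasets, " data sets, ",
      x$n_taxa, " taxa, ", x$model_kind,
      if (!is.null(x$gamma_shape)) paste0("+G", 4), "\n", sep = "")
  invisible(x)
}

runif1 <- function(range) runif(1, range[1], range[2])

# draw one data set's parameters, tree, model and alignment
make_dataset <- function(design, i) {
  seed <- derive_seed(design$master_seed, i)
  withr::with_seed(seed, {
    n_sites <- if (design$site_range[1] == design$site_range[2])
      design$site_range[1]
    else sample(seq(design$site_range[1], design$site_range[2]), 1)
    gc <- runif1(design$gc_range)
    pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    if (design$model_kind == "HKY") {
      kappa <- runif1(design$kappa_range)
      model <- hky_model(kappa, base_freqs = pi,
                         gamma_shape = design$gamma_shape)
      pars <- list(kappa = kappa)
    } else {
      ex <- runif(6, design$exch_range[1], design$exch_range[2])
      model <- gtr_model(ex, base_freqs = pi,
                         gamma_shape = design$gamma_shape)
      pars <- list(exchangeabilities = ex)
    }
    if (!is.null(design$info_levels)) {
      # ladder: hit the target expected-substitution count through the
      # alignment length, keeping branch lengths in the moderate range
      # where added sites translate into added signal (long saturated
      # branches would make high-information levels hard again)
      tree_len <- runif1(design$tree_length_range)
      n_sites <- max(50L, as.integer(round(design$info_levels[i] / tree_len)))
      tree <- generate_model_tree(design$n_taxa,
                                  design$info_levels[i] / n_sites)
      level <- design$info_levels[i]
    } else {
      # time tree in My -> lineage rates -> substitution lengths
      total_time <- runif1(design$total_time_range)
      rate <- runif1(design$rate_range)
      tt <- ape::rphylo(design$n_taxa, birth = 1, death = 0)
      tt$tip.label <- sprintf("t%02d", seq_len(design$n_taxa))
      tt <- as_unrooted(tt)
      tt$edge.length <- tt$edge.length * total_time / sum(tt$edge.length)
      rm <- rate_model(design$rate_kind, initial_rate = rate,
                       autocorrelation_variance =
                         design$autocorrelation_variance)
      tt <- assign_autocorrelated_rates(tt, rm)
      tree <- tt
      tree$edge.length <- tree$edge.length * rate * 1e6
      pars$rate <- rate
      pars$total_time <- total_time
      level <- NA_real_
    }
    aln <- simulate_alignment(tree, model, n_sites)
    list(id = sprintf("%s_%03d", design$name, i), seed = seed,
         tree = tree, alignment = aln, model = model,
         n_sites = n_sites, gc = gc, params = pars,
         info_level = level,
         information = phylo_information(tree, n_sites))
  })
}

#' Simulate a collection of data sets
#'
#' Draws `design$n_datasets` (true tree, alignment, metadata) records,
#' each from its own counter-derived seed, so the whole collection is
#' reproducible from the design's master seed and any single data set can
#' be regenerated in isolation.
#'
#' @param design a [sim_design].
#' @return object of class `sim_collection`: list with the `design` and a
#'   `datasets` list.
#' @export
make_collection <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  datasets <- lapply(seq_len(design$n_datasets),
                     function(i) make_dataset(design, i))
  structure(list(design = design, datasets = datasets),
            class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  info <- vapply(x$datasets, function(d) d$information, 0)
  cat("sim_collection '", x$design$name, "': ", length(x$datasets),
      " data sets, information ", round(min(info)), "-", round(max(info)),
      " expected substitutions\n", sep = "")
  invisible(x)
}

#' Write a collection to disk
#'
#' One FASTA and one Newick per data set plus a tab-separated manifest
#' (id, seed, model parameters, tree length, information).
#'
#' @param collection a [make_collection] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(collection$datasets, function(d) {
    write_alignment(d$alignment, file.path(dir, paste0(d$id, ".fasta")))
    write_newick(d$tree, file.path(dir, paste0(d$id, ".nwk")))
    data.frame(id = d$id, seed = d$seed, model = d$model$kind,
               kappa = if (is.null(d$params$kappa)) NA else d$params$kappa,
               gc = d$gc, n_sites = d$n_sites,
               tree_length = sum(d$tree$edge.length),
               information = d$information)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
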