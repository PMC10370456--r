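#' Two-run reproducibility protocol for one data set
#'
#' Runs the heuristic search twice on the same alignment and model,
#' differing only in the random seed (defaults 111 and 123, the first- and
#' second-run seeds of the protocol), and compares the two inferred trees
#' (Q1, Q2) with each other and with the true tree (T).  A data set is
#' "reproducible" when Q1 and Q2 have the same unrooted topology; branch
#' lengths are ignored.
#'
#' @param aln a [phylo_alignment].
#' @param model a [subst_model].
#' @param true_tree the generating `phylo`.
#' @param config_base a [search_config]; its seed is overridden per run.
#' @param seeds integer pair of distinct run seeds.
#' @param dataset_id optional identifier carried into the record.
#' @return object of class `repro_record`: trees `q1`, `q2`, the optimized
#'   true-tree fit, and a one-row `metrics` data.frame with rf percentages
#'   (`d_q1q2`, `d_q1t`, `d_q2t`), log-likelihoods (`ll1`, `ll2`,
#'   `true_ll`), their differences (`dll_12`, `dll_1t`, `dll_2t`) and the
#'   `reproducible` flag.
#' @export
two_run <- function(aln, model, true_tree, config_base,
                    seeds = c(111L, 123L), dataset_id = NA_character_) {
  stopifnot(inherits(config_base, "search_config"), length(seeds) == 2)
  if (seeds[1] == seeds[2])
    stop("the two run seeds must differ ",
         "(the same seed would mandatorily give the same phylogeny)")
  cfg1 <- config_base; cfg1$seed <- as.integer(seeds[1])
  cfg2 <- config_base; cfg2$seed <- as.integer(seeds[2])
  r1 <- heuristic_search(aln, model, cfg1)
  r2 <- heuristic_search(aln, model, cfg2)
  tf <- optimize_branch_lengths(true_tree, aln, model,
                                epsilon = config_base$epsilon)
  metrics <- data.frame(
    dataset_id = dataset_id,
    reproducible = same_topology(r1$best_tree, r2$best_tree),
    d_q1q2 = rf_percent(r1$best_tree, r2$best_tree),
    d_q1t = rf_percent(r1$best_tree, true_tree),
    d_q2t = rf_percent(r2$best_tree, true_tree),
    ll1 = r1$best_ll, ll2 = r2$best_ll, true_ll = tf$loglik,
    dll_12 = r1$best_ll - r2$best_ll,
    dll_1t = r1$best_ll - tf$loglik,
    dll_2t = r2$best_ll - tf$loglik,
    stringsAsFactors = FALSE)
  structure(list(q1 = r1$best_tree, q2 = r2$best_tree,
                 true_fit = tf$tree, metrics = metrics,
                 seeds = as.integer(seeds)),
            class = "repro_record")
}

#' @export
print.repro_record <- function(x, ...) {
  m <- x$metrics
  cat("repro_record", if (!is.na(m$dataset_id)) m$dataset_id, ":",
      if (m$reproducible) "reproducible" else "irreproducible",
      sprintf("(dQ1Q2 = %.1f%%, dQ1T = %.1f%%, dLL1T = %.2f)\n",
              m$d_q1q2, m$d_q1t, m$dll_1t))
  invisible(x)
}

#' Two-run protocol over a simulated collection
#'
#' @param collection a [make_collection] result.
#' @param config_base a [search_config] template (default: two starting
#'   trees, NNI moves).
#' @param seeds the two run seeds.
#' @param verbose print one progress line per data set.
#' @return object of class `repro_collection`: `records` (one metrics row
#'   per data set, with `information` and `info_level` columns) and the
#'   per-dataset `repro_record`s in `runs`.
#' @export
two_run_collection <- function(collection, config_base = NULL,
                               seeds = c(111L, 123L), verbose = FALSE) {
  stopifnot(inherits(collection, "sim_collection"))
  if (is.null(config_base)) config_base <- search_config(seed = 1L)
  runs <- lapply(collection$datasets, function(d) {
    rec <- two_run(d$alignment, d$model, d$tree, config_base,
                   seeds = seeds, dataset_id = d$id)
    if (verbose)
      cat(sprintf("%s: %s dQ1T=%.1f%%\n", d$id,
                  if (rec$metrics$reproducible) "repro" else "IRREPRO",
                  rec$metrics$d_q1t))
    rec
  })
  records <- do.call(rbind, lapply(runs, function(r) r$metrics))
  records$information <- vapply(collection$datasets,
                                function(d) d$information, 0)
  records$info_level <- vapply(collection$datasets,
                               function(d) d$info_level, 0)
  structure(list(records = records, runs = runs,
                 design = collection$design, seeds = as.integer(seeds)),
            class = "repro_collection")
}

#' Heuristic search seeded with the true topology
#'
#' The Q3 experiment: the true tree's topology (branch lengths
#' re-optimized first) is supplied as the initial tree of the heuristic
#' search, guaranteeing that the search explores the true tree's
#' topological neighborhood.  The returned log-likelihood therefore never
#' falls below the optimized true-tree log-likelihood.
#'
#' @inheritParams two_run
#' @param config a [search_config]; its `initial_tree` is overridden.
#' @return list with `q3` (best tree), `ll3`, and the full
#'   `search_result`.
#' @export
true_start_run <- function(aln, model, true_tree, config) {
  cfg <- config
  cfg$initial_tree <- true_tree
  res <- heuristic_search(aln, model, cfg)
  list(q3 = res$best_tree, ll3 = res$best_ll, result = res)
}

#' Q3 experiment over (a subset of) a collection
#'
#' @param collection a [make_collection] result.
#' @param tworun the matching [two_run_collection] result (Q1 metrics are
#'   joined in).
#' @param config a [search_config] for the true-start searches.
#' @param subset optional character vector of dataset ids (default: the
#'   irreproducible subset of `tworun`).
#' @return data.frame with per-dataset `ll3`, `d_q3t`, `d_q3q1` plus the
#'   joined Q1 columns.
#' @export
true_start_collection <- function(collection, tworun, config,
                                  subset = NULL) {
  stopifnot(inherits(tworun, "repro_collection"))
  recs <- tworun$records
  if (is.null(subset)) subset <- recs$dataset_id[!recs$reproducible]
  if (length(subset) == 0) stop("empty subset: nothing to run")
  ids <- vapply(collection$datasets, function(d) d$id, "")
  rows <- lapply(subset, function(id) {
    d <- collection$datasets[[match(id, ids)]]
    run <- tworun$runs[[match(id, recs$dataset_id)]]
    q3 <- true_start_run(d$alignment, d$model, d$tree, config)
    data.frame(dataset_id = id, ll3 = q3$ll3,
               d_q3t = rf_percent(q3$q3, d$tree),
               d_q3q1 = rf_percent(q3$q3, run$q1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  merge(out, recs, by = "dataset_id", sort = FALSE)
}

#' Aggregate two-run records into a collection summary
#'
#' Partitions the records into the reproducible and irreproducible subsets
#' and reports exact subset means of the topological and log-likelihood
#' differences.  Means over an empty subset are reported as `NA` (absent).
#'
#' @param records a `repro_collection` or its `records` data.frame.
#' @return object of class `collection_summary`.
#' @export
aggregate_runs <- function(records) {
  if (inherits(records, "repro_collection")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  subset_means <- function(df) {
    if (nrow(df) == 0)
      return(data.frame(n = 0L, d_q1q2 = NA_real_, d_q1t = NA_real_,
                        d_q2t = NA_real_, abs_dll_12 = NA_real_,
                        abs_dll_1t = NA_real_))
    data.frame(n = nrow(df), d_q1q2 = mean(df$d_q1q2),
               d_q1t = mean(df$d_q1t), d_q2t = mean(df$d_q2t),
               abs_dll_12 = mean(abs(df$dll_12)),
               abs_dll_1t = mean(abs(df$dll_1t)))
  }
  irre <- records[!records$reproducible, , drop = FALSE]
  repro <- records[records$reproducible, , drop = FALSE]
  structure(list(n_datasets = nrow(records),
                 pct_irreproducible = 100 * nrow(irre) / nrow(records),
                 irreproducible = subset_means(irre),
                 reproducible = subset_means(repro),
                 per_dataset = records),
            class = "collection_summary")
}

#' @export
print.collection_summary <- function(x, ...) {
  cat("collection_summary:", x$n_datasets, "data sets,",
      sprintf("%.1f%% irreproducible\n", x$pct_irreproducible))
  if (x$irreproducible$n > 0)
    cat(sprintf(
      "  irreproducible subset (n=%d): mean dQ1Q2 = %.1f%%, dQ1T = %.1f%%, dQ2T = %.1f%%\n",
      x$irreproducible$n, x$irreproducible$d_q1q2,
      x$irreproducible$d_q1t, x$irreproducible$d_q2t))
  if (x$reproducible$n > 0)
    cat(sprintf("  reproducible subset (n=%d): mean dQ1T = %.1f%%\n",
                x$reproducible$n, x$reproducible$d_q1t))
  invisible(x)
}
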