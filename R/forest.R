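#' Build the optimality forest for one data set
#'
#' Runs `n_starts` seeded hill climbs from bootstrap-derived starting trees
#' with full trace retention, pools every evaluated topology (accepted and
#' rejected candidates, starts and final trees), deduplicates by canonical
#' splits, re-optimizes branch lengths per distinct topology, and keeps the
#' topologies whose optimized log-likelihood strictly exceeds the optimized
#' log-likelihood of the true tree.  The true topology itself is never a
#' member.
#'
#' Re-optimization is restricted to pooled topologies whose screening
#' log-likelihood is above `true LL - rescore_margin`: the screening value
#' is a lower bound of the re-optimized value (the full optimization is
#' warm-started from the screened branch lengths and is monotone), so only
#' a candidate whose quick score undershoots its full score by more than
#' the margin could be missed.
#'
#' @param aln a [phylo_alignment].
#' @param model a [subst_model].
#' @param true_tree the generating `phylo`.
#' @param n_starts number of seeded hill climbs (the reference protocol
#'   used 100; desk-scale default 25).
#' @param seed integer seed for the whole construction.
#' @param epsilon log-likelihood tolerance.
#' @param rescore_margin log-likelihood guard band for re-optimization.
#' @param dataset_id optional identifier.
#' @return object of class `forest_record`: `true_ll`, `members`
#'   (data.frame: hash, newick, loglik, dll, rf_pct), `n_distinct`,
#'   `breadth` (max member LL - true LL; `NA` when the forest is empty),
#'   `n_pooled`, `n_rescored`.
#' @export
build_forest <- function(aln, model, true_tree, n_starts = 25L, seed = 1L,
                         epsilon = LL_EPSILON, rescore_margin = 10,
                         dataset_id = NA_character_) {
  stopifnot(n_starts >= 1)
  cfg <- search_config(seed = seed, n_starts = n_starts,
                       epsilon = epsilon, retain_trace = TRUE,
                       start_method = "bootstrap")
  res <- heuristic_search(aln, model, cfg)
  tf <- optimize_branch_lengths(true_tree, aln, model, epsilon = epsilon)
  true_hash <- topology_hash(true_tree)
  pool <- res$trace
  # deduplicate by canonical topology, keeping the best recorded LL
  ord <- order(pool$hash, -pool$loglik)
  pool <- pool[ord, , drop = FALSE]
  pool <- pool[!duplicated(pool$hash), , drop = FALSE]
  pool <- pool[pool$hash != true_hash, , drop = FALSE]
  cand <- pool[pool$loglik > tf$loglik - rescore_margin, , drop = FALSE]
  members <- NULL
  if (nrow(cand) > 0) {
    full_ll <- vapply(cand$newick, function(nwk) {
      optimize_branch_lengths(read_newick(text = nwk), aln, model,
                              epsilon = epsilon)$loglik
    }, 0, USE.NAMES = FALSE)
    keep <- full_ll > tf$loglik
    if (any(keep)) {
      members <- data.frame(hash = cand$hash[keep],
                            newick = cand$newick[keep],
                            loglik = full_ll[keep],
                            dll = full_ll[keep] - tf$loglik,
                            stringsAsFactors = FALSE)
      members$rf_pct <- vapply(members$newick, function(nwk) {
        rf_percent(read_newick(text = nwk), true_tree)
      }, 0, USE.NAMES = FALSE)
      members <- members[order(-members$loglik), , drop = FALSE]
      rownames(members) <- NULL
    }
  }
  if (is.null(members))
    members <- data.frame(hash = character(0), newick = character(0),
                          loglik = numeric(0), dll = numeric(0),
                          rf_pct = numeric(0), stringsAsFactors = FALSE)
  structure(list(dataset_id = dataset_id, true_ll = tf$loglik,
                 members = members, n_distinct = nrow(members),
                 breadth = if (nrow(members)) max(members$dll) else NA_real_,
                 n_pooled = nrow(pool), n_rescored = nrow(cand),
                 best_search_ll = res$best_ll, seed = as.integer(seed)),
            class = "forest_record")
}

#' @export
print.forest_record <- function(x, ...) {
  cat("forest_record", if (!is.na(x$dataset_id)) x$dataset_id, ":",
      x$n_distinct, "distinct topologies above the true tree",
      if (x$n_distinct > 0) sprintf("(breadth %.2f)", x$breadth)
      else "(empty forest)", "\n")
  invisible(x)
}

#' Breadth of the optimality forest
#'
#' Log-likelihood gap between the best tree found and the optimized true
#' tree: `max(member LL) - true LL`.  Absent (`NA`) for an empty forest.
#'
#' @param rec a [build_forest] record.
#' @return non-negative numeric, or `NA` when the forest is empty.
#' @export
forest_breadth <- function(rec) {
  stopifnot(inherits(rec, "forest_record"))
  if (rec$n_distinct == 0) return(NA_real_)
  max(rec$members$loglik) - rec$true_ll
}

#' Regression of inaccuracy on log-likelihood within a forest
#'
#' Ordinary least squares of each member's topological error
#' (`rf_percent` to the true tree) on its log-likelihood advantage over
#' the true tree.  A flat line (slope near 0, negligible correlation) is
#' the signature that extra likelihood buys no extra accuracy inside the
#' forest.
#'
#' @param rec a [build_forest] record with at least 3 members.
#' @return list with `slope`, `intercept`, `correlation` (`NA` when the
#'   predictor or response is degenerate).
#' @export
inaccuracy_ll_regression <- function(rec) {
  stopifnot(inherits(rec, "forest_record"))
  m <- rec$members
  if (nrow(m) < 3) stop("regression needs at least 3 forest members")
  if (stats::var(m$dll) == 0)
    return(list(slope = NA_real_, intercept = mean(m$rf_pct),
                correlation = NA_real_))
  fit <- lm(rf_pct ~ dll, data = m)
  r <- if (stats::var(m$rf_pct) == 0) NA_real_
       else cor(m$dll, m$rf_pct)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       correlation = r)
}

#' Forest breadth versus phylogenetic information
#'
#' Per-level mean breadth (empty forests contribute 0, keeping the level
#' means defined) and the Spearman rank correlation of breadth with
#' information across all data sets.  Negative correlation is the
#' low-information signature: less informative alignments carry wider
#' optimality forests.
#'
#' @param records list of [build_forest] records.
#' @param information numeric vector of expected-substitution counts, one
#'   per record.
#' @param levels optional grouping (defaults to the distinct information
#'   values); at least 2 levels required.
#' @return list with `table` (one row per level: information level, n,
#'   mean breadth, mean n_distinct) and `spearman`.
#' @export
breadth_vs_information <- function(records, information, levels = NULL) {
  stopifnot(length(records) == length(information))
  breadth0 <- vapply(records, function(r) {
    b <- forest_breadth(r)
    if (is.na(b)) 0 else b
  }, 0)
  nd <- vapply(records, function(r) r$n_distinct, 0L)
  if (is.null(levels)) levels <- information
  lv <- sort(unique(levels))
  if (length(lv) < 2) stop("need at least 2 information levels")
  tab <- do.call(rbind, lapply(lv, function(l) {
    k <- levels == l
    data.frame(level = l, n = sum(k), mean_breadth = mean(breadth0[k]),
               mean_n_distinct = mean(nd[k]))
  }))
  list(table = tab,
       spearman = suppressWarnings(cor(information, breadth0,
                                       method = "spearman")))
}
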