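# FNV-1a over the deparsed config: a cheap, stable fingerprint written into
# output-table headers so tables can be traced back to the run that made them
config_hash <- function(cfg) {
  if (inherits(cfg, "run_config"))
    cfg <- cfg[setdiff(names(cfg), c("out_dir", "resume"))]
  s <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_tsv_with_header <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# optforest config hash: ", config_hash(cfg)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [run_experiment()]
#'
#' @param path file path (a `#`-prefixed header comment is skipped).
#' @return data.frame.
#' @export
read_experiment_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' @param experiment one of `"simulate"`, `"tworun"`, `"q3"`, `"forest"`.
#' @param design a [sim_design].
#' @param out_dir output directory.
#' @param search_base a [search_config] template for the per-run searches.
#' @param seeds the two run seeds of the two-run protocol.
#' @param n_starts_forest hill climbs per data set for forest construction.
#' @param resume skip data sets whose outputs already exist (`TRUE`) or
#'   refuse to write into a non-empty experiment directory (`FALSE`).
#' @return object of class `run_config`.
#' @export
run_config <- function(experiment = c("simulate", "tworun", "q3", "forest"),
                       design, out_dir, search_base = NULL,
                       seeds = c(111L, 123L), n_starts_forest = 25L,
                       resume = FALSE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(design, "sim_design"))
  if (is.null(search_base)) search_base <- search_config(seed = 1L)
  structure(list(experiment = experiment, design = design,
                 out_dir = out_dir, search_base = search_base,
                 seeds = as.integer(seeds),
                 n_starts_forest = as.integer(n_starts_forest),
                 resume = isTRUE(resume)),
            class = "run_config")
}

#' Run an experiment end to end
#'
#' Generates the collection from the config's design and runs the requested
#' protocol, writing per-dataset and summary TSVs (each carrying the config
#' hash in a header comment) into `out_dir`.  Identical configs reproduce
#' identical outputs.
#'
#' * `simulate`: write the collection (FASTA, Newick, manifest).
#' * `tworun`: the two-run protocol; per-dataset metrics + summary.
#' * `q3`: `tworun` plus true-start searches on the irreproducible subset.
#' * `forest`: per-dataset optimality forests + breadth-vs-information.
#'
#' @param cfg a [run_config].
#' @return list with the written `paths` and the in-memory results.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.files(cfg$out_dir)
  if (length(existing) > 0 && !cfg$resume)
    stop("output directory not empty (set resume = TRUE to reuse): ",
         cfg$out_dir)
  collection <- make_collection(cfg$design)
  paths <- list()
  out <- list(collection = collection)
  if (cfg$experiment == "simulate") {
    write_collection(collection, file.path(cfg$out_dir, "data"))
    paths$manifest <- file.path(cfg$out_dir, "data", "manifest.tsv")
    return(invisible(list(paths = paths, results = out)))
  }
  tworun <- two_run_collection(collection, cfg$search_base,
                               seeds = cfg$seeds)
  summ <- aggregate_runs(tworun)
  paths$per_dataset <- file.path(cfg$out_dir, "tworun_per_dataset.tsv")
  write_tsv_with_header(tworun$records, paths$per_dataset, cfg)
  paths$summary <- file.path(cfg$out_dir, "tworun_summary.tsv")
  write_tsv_with_header(
    data.frame(n_datasets = summ$n_datasets,
               pct_irreproducible = summ$pct_irreproducible,
               irre_d_q1q2 = summ$irreproducible$d_q1q2,
               irre_d_q1t = summ$irreproducible$d_q1t,
               irre_d_q2t = summ$irreproducible$d_q2t,
               repro_d_q1t = summ$reproducible$d_q1t),
    paths$summary, cfg)
  out$tworun <- tworun
  out$summary <- summ
  if (cfg$experiment == "q3") {
    irre <- tworun$records$dataset_id[!tworun$records$reproducible]
    if (length(irre) > 0) {
      q3 <- true_start_collection(collection, tworun, cfg$search_base,
                                  subset = irre)
      paths$q3 <- file.path(cfg$out_dir, "q3_per_dataset.tsv")
      write_tsv_with_header(q3, paths$q3, cfg)
      out$q3 <- q3
    }
  }
  if (cfg$experiment == "forest") {
    forests <- lapply(collection$datasets, function(d) {
      build_forest(d$alignment, d$model, d$tree,
                   n_starts = cfg$n_starts_forest,
                   seed = derive_seed(cfg$design$master_seed, 7000L +
                                        match(d$id, vapply(collection$datasets,
                                                           function(x) x$id,
                                                           ""))),
                   dataset_id = d$id)
    })
    info <- vapply(collection$datasets, function(d) d$information, 0)
    lv <- vapply(collection$datasets, function(d) d$info_level, 0)
    bi <- breadth_vs_information(forests, info,
                                 levels = if (all(is.na(lv))) NULL else lv)
    per <- do.call(rbind, lapply(forests, function(f) {
      data.frame(dataset_id = f$dataset_id, true_ll = f$true_ll,
                 n_distinct = f$n_distinct, breadth = f$breadth)
    }))
    per$information <- info
    paths$forest <- file.path(cfg$out_dir, "forest_per_dataset.tsv")
    write_tsv_with_header(per, paths$forest, cfg)
    paths$forest_levels <- file.path(cfg$out_dir, "forest_levels.tsv")
    write_tsv_with_header(bi$table, paths$forest_levels, cfg)
    out$forests <- forests
    out$breadth_vs_information <- bi
  }
  invisible(list(paths = paths, results = out))
}

#' Evaluate the qualitative reproducibility patterns
#'
#' Checks the four structural patterns of the reproducibility study against
#' completed experiment outputs:
#'
#' * P1: among irreproducible data sets, the two runs differ from each
#'   other less than they differ from the true tree (one-sided paired
#'   bootstrap p < 0.05).
#' * P2: the two runs are equally inaccurate (overlapping 95% bootstrap
#'   CIs of mean dQ1T and dQ2T on the irreproducible subset).
#' * P3: the inferred tree's log-likelihood is at least the optimized true
#'   tree's in >= 90% of data sets.
#' * P4 (needs a ladder experiment): the irreproducibility fraction and
#'   the mean forest breadth are non-increasing across increasing
#'   information levels, with a negative breadth-information Spearman
#'   correlation.
#'
#' Patterns whose subset is empty are reported "not applicable", not
#' failed.
#'
#' @param tworun a `repro_collection`, its records data.frame, or the path
#'   to a `tworun_per_dataset.tsv`.
#' @param ladder optional: a list with elements `records` (ladder two-run
#'   records with `info_level`) and `breadth` (per-dataset breadth table
#'   with `information`), or the paths to the corresponding TSVs.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap resampling.
#' @return data.frame with one row per pattern: `pattern`, `applicable`,
#'   `pass`, `detail`.
#' @export
validate_against_patterns <- function(tworun, ladder = NULL,
                                      n_boot = 2000L, seed = 1L) {
  rec <- if (inherits(tworun, "repro_collection")) tworun$records
         else if (is.character(tworun)) read_experiment_tsv(tworun)
         else tworun
  irre <- rec[!rec$reproducible, , drop = FALSE]
  rows <- list()
  add <- function(pattern, applicable, pass, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pattern = pattern, applicable = applicable,
      pass = if (applicable) pass else NA, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (nrow(irre) >= 2) {
    p1 <- boot_p_mean_less(irre$d_q1q2, irre$d_q1t, n_boot = n_boot,
                           seed = derive_seed(seed, 1L))
    add("P1: dQ1Q2 < dQ1T (irreproducible subset)", TRUE, p1 < 0.05,
        sprintf("mean dQ1Q2 = %.1f%%, mean dQ1T = %.1f%%, bootstrap p = %.4f",
                mean(irre$d_q1q2), mean(irre$d_q1t), p1))
    ci1 <- boot_ci_mean(irre$d_q1t, n_boot = n_boot,
                        seed = derive_seed(seed, 2L))
    ci2 <- boot_ci_mean(irre$d_q2t, n_boot = n_boot,
                        seed = derive_seed(seed, 3L))
    overlap <- ci1[1] <= ci2[2] && ci2[1] <= ci1[2]
    add("P2: dQ1T and dQ2T equivalent (overlapping 95% CIs)", TRUE, overlap,
        sprintf("CI(dQ1T) = [%.1f, %.1f], CI(dQ2T) = [%.1f, %.1f]",
                ci1[1], ci1[2], ci2[1], ci2[2]))
  } else {
    add("P1: dQ1Q2 < dQ1T (irreproducible subset)", FALSE, NA,
        "fewer than 2 irreproducible data sets")
    add("P2: dQ1T and dQ2T equivalent (overlapping 95% CIs)", FALSE, NA,
        "fewer than 2 irreproducible data sets")
  }
  frac3 <- mean(rec$dll_1t >= -1e-6)
  add("P3: inferred LL >= true-tree LL in >= 90% of data sets", TRUE,
      frac3 >= 0.9, sprintf("fraction = %.3f (n = %d)", frac3, nrow(rec)))
  if (!is.null(ladder)) {
    lr <- if (is.character(ladder$records))
      read_experiment_tsv(ladder$records) else ladder$records
    lb <- if (is.character(ladder$breadth))
      read_experiment_tsv(ladder$breadth) else ladder$breadth
    lv <- sort(unique(lr$info_level))
    frac <- vapply(lv, function(l) {
      mean(!lr$reproducible[lr$info_level == l])
    }, 0)
    b0 <- ifelse(is.na(lb$breadth), 0, lb$breadth)
    level_of <- lr$info_level[match(lb$dataset_id, lr$dataset_id)]
    mean_b <- vapply(lv, function(l) mean(b0[level_of == l]), 0)
    rho <- suppressWarnings(cor(lb$information, b0, method = "spearman"))
    pass4 <- all(diff(frac) <= 0) && all(diff(mean_b) <= 0) && rho < 0
    add("P4: irreproducibility and breadth fall with information", TRUE,
        pass4,
        sprintf("irre fractions: %s; mean breadths: %s; Spearman = %.2f",
                paste(sprintf("%.2f", frac), collapse = "/"),
                paste(sprintf("%.2f", mean_b), collapse = "/"), rho))
  } else {
    add("P4: irreproducibility and breadth fall with information", FALSE,
        NA, "no ladder experiment supplied")
  }
  do.call(rbind, rows)
}
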