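# Counter-based derivation of per-dataset / per-start seeds from a master
# seed, so any single unit of work is re-runnable in isolation.  Kept below
# 2^31 (R integers are 32-bit).
derive_seed <- function(master, counter) {
  m <- 2147483647
  as.integer((((as.double(master) %% m) * 48271) %% m + 104729 * counter) %% m)
}

# run `expr` under a local RNG seeded with `seed`; NULL seed uses the
# ambient RNG stream
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(seed, expr)
}

#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap CI for `mean(x)`.
#'
#' @param x numeric vector.
#' @param level confidence level.
#' @param n_boot bootstrap replicates.
#' @param seed optional seed for the resampling.
#' @return numeric(2) lower/upper bounds.
#' @export
boot_ci_mean <- function(x, level = 0.95, n_boot = 2000L, seed = NULL) {
  stopifnot(length(x) >= 1)
  with_seed_maybe(seed, {
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(sample(x, replace = TRUE)), 0)
    unname(quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' One-sided paired bootstrap p-value for mean(x) < mean(y)
#'
#' Resamples paired observations and reports the fraction of bootstrap
#' replicates in which `mean(x) >= mean(y)`, i.e. the bootstrap evidence
#' against the claim that `x` has the smaller mean.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param n_boot bootstrap replicates.
#' @param seed optional seed.
#' @return p-value in `[0, 1]`.
#' @export
boot_p_mean_less <- function(x, y, n_boot = 2000L, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  with_seed_maybe(seed, {
    ge <- vapply(seq_len(n_boot), function(i) {
      k <- sample(seq_along(x), replace = TRUE)
      mean(x[k]) >= mean(y[k])
    }, NA)
    mean(ge)
  })
}
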