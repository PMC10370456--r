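#' Nucleotide substitution models
#'
#' Construct a time-reversible nucleotide substitution model (HKY or GTR)
#' with optional discrete-gamma rate heterogeneity across sites.  The rate
#' matrix Q is scaled so that the mean substitution rate at stationarity is
#' one, so branch lengths are in expected substitutions per site.
#'
#' @param kind `"HKY"` or `"GTR"`.
#' @param base_freqs numeric(4), stationary frequencies for A, C, G, T;
#'   must be positive and sum to 1.
#' @param kappa transition/transversion rate ratio (HKY only).
#' @param exchangeabilities numeric(6), GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (GTR only).
#' @param gamma_shape shape of the gamma distribution of site rates, or
#'   `NULL` for rate homogeneity.
#' @param n_categories number of discrete gamma categories (default 4, the
#'   usual "+G4" convention).
#' @return an object of class `subst_model` with components `kind`, `pi`,
#'   `Q` (normalized rate matrix), `rates` (category rates, mean 1),
#'   `gamma_shape`, and the eigensystem used for transition probabilities.
#' @examples
#' m <- hky_model(kappa = 2, base_freqs = rep(0.25, 4))
#' transition_matrix(m, 0.1)
#' @export
subst_model <- function(kind = c("HKY", "GTR"), base_freqs = rep(0.25, 4),
                        kappa = NULL, exchangeabilities = NULL,
                        gamma_shape = NULL, n_categories = 4L) {
  kind <- match.arg(kind)
  pi <- as.numeric(base_freqs)
  if (length(pi) != 4 || any(pi <= 0))
    stop("base_freqs must be 4 positive values")
  if (abs(sum(pi) - 1) > 1e-8) stop("base_freqs must sum to 1")
  pi <- pi / sum(pi)
  if (kind == "HKY") {
    if (is.null(kappa)) stop("HKY model requires kappa")
    if (kappa <= 0) stop("kappa must be positive")
    ex <- c(1, kappa, 1, 1, kappa, 1)
  } else {
    if (is.null(exchangeabilities)) stop("GTR model requires exchangeabilities")
    ex <- as.numeric(exchangeabilities)
    if (length(ex) != 6 || any(ex <= 0))
      stop("exchangeabilities must be 6 positive values (AC AG AT CG CT GT)")
  }
  Q <- matrix(0, 4, 4, dimnames = list(c("a", "c", "g", "t"),
                                       c("a", "c", "g", "t")))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- ex[k] * pi[j]
    Q[j, i] <- ex[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))         # mean rate at stationarity
  Q <- Q / mu
  # reversible Q: symmetrize with sqrt(pi) similarity, eigendecompose
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- diag(1 / d) %*% es$vectors
  Uinv <- t(es$vectors) %*% diag(d)
  if (!is.null(gamma_shape)) {
    if (gamma_shape <= 0) stop("gamma_shape must be positive")
    rates <- discrete_gamma_rates(gamma_shape, n_categories)
  } else {
    rates <- 1
  }
  structure(list(kind = kind, pi = pi, kappa = kappa,
                 exchangeabilities = ex, Q = Q,
                 gamma_shape = gamma_shape,
                 n_categories = if (is.null(gamma_shape)) 1L
                                else as.integer(n_categories),
                 rates = rates, U = U, Uinv = Uinv, eva = es$values),
            class = "subst_model")
}

#' @rdname subst_model
#' @export
hky_model <- function(kappa, base_freqs = rep(0.25, 4), gamma_shape = NULL,
                      n_categories = 4L) {
  subst_model("HKY", base_freqs = base_freqs, kappa = kappa,
              gamma_shape = gamma_shape, n_categories = n_categories)
}

#' @rdname subst_model
#' @export
gtr_model <- function(exchangeabilities, base_freqs = rep(0.25, 4),
                      gamma_shape = NULL, n_categories = 4L) {
  subst_model("GTR", base_freqs = base_freqs,
              exchangeabilities = exchangeabilities,
              gamma_shape = gamma_shape, n_categories = n_categories)
}

#' @export
print.subst_model <- function(x, ...) {
  cat(x$kind, "substitution model\n")
  cat("  base frequencies (ACGT):", signif(x$pi, 4), "\n")
  if (x$kind == "HKY") cat("  kappa:", x$kappa, "\n")
  else cat("  exchangeabilities:", signif(x$exchangeabilities, 4), "\n")
  if (!is.null(x$gamma_shape))
    cat("  discrete gamma: shape", x$gamma_shape, "with", x$n_categories,
        "categories\n")
  invisible(x)
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Category rates for the discrete-gamma approximation with `k`
#' equal-probability bins, each category carrying the mean of its quantile
#' bin of a Gamma(shape, rate = shape) distribution (mean 1).
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories.
#' @return numeric(k) category rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1) return(1)
  qb <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # E[X; a < X < b] for X ~ Gamma(a, a) via the shape+1 identity
  cum <- pgamma(qb, shape = shape + 1, rate = shape)
  k * diff(cum)
}

#' Transition probability matrix
#'
#' `P(d) = exp(Q d r)` for a mean-rate-normalized reversible `Q`, branch
#' length `d` in expected substitutions per site and rate multiplier `r`.
#'
#' @param model a [subst_model].
#' @param d branch length (>= 0).
#' @param rate_multiplier site-rate multiplier (default 1).
#' @return 4x4 stochastic matrix, rows A, C, G, T.
#' @export
transition_matrix <- function(model, d, rate_multiplier = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (d < 0) stop("branch length must be non-negative")
  P <- model$U %*% diag(exp(model$eva * d * rate_multiplier)) %*% model$Uinv
  P[P < 0] <- 0
  dimnames(P) <- list(c("a", "c", "g", "t"), c("a", "c", "g", "t"))
  P
}
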