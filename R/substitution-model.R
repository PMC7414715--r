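# Amino-acid substitution models with discrete-gamma rate heterogeneity.
#
# A model couples a symmetric exchangeability matrix with stationary
# frequencies into a reversible rate matrix Q = S diag(pi), normalized to
# one expected substitution per unit branch length.  Because Q is
# similar to a symmetric matrix via D^(1/2) Q D^(-1/2) (D = diag(pi)), its
# eigendecomposition is computed once with the stable symmetric routine and
# reused for every transition-probability matrix P(t) = exp(Qt).

#' Build a substitution model
#'
#' @param exchangeabilities Symmetric non-negative 20x20 matrix (diagonal
#'   ignored), residues in the order `ARNDCQEGHILKMFPSTWYV`.
#' @param frequencies Stationary frequencies, length 20, summing to 1.
#' @param gamma_shape Shape of the discrete-gamma distribution of site rates;
#'   `Inf` (or `n_categories = 1`) gives rate homogeneity.
#' @param n_categories Number of equal-probability gamma categories.
#' @param name Model label used in reports.
#' @return Object of class `substitution_model` with the normalized rate
#'   matrix, its eigensystem, and the category rates (mean 1).
#' @export
substitution_model <- function(exchangeabilities, frequencies,
                               gamma_shape = 1, n_categories = 10,
                               name = "custom") {
  S <- as.matrix(exchangeabilities)
  stopifnot(nrow(S) == 20L, ncol(S) == 20L)
  if (max(abs(S - t(S))) > 1e-8)
    rf_stop("refates_model_error", "exchangeability matrix must be symmetric")
  if (any(S[upper.tri(S)] < 0))
    rf_stop("refates_model_error", "exchangeabilities must be non-negative")
  pi <- as.numeric(frequencies)
  stopifnot(length(pi) == 20L)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-6)
    rf_stop("refates_model_error", "frequencies must be positive and sum to 1")
  pi <- pi / sum(pi)
  if (!(is.numeric(gamma_shape) && (gamma_shape > 0)))
    rf_stop("refates_model_error", "gamma_shape must be positive")
  n_categories <- as.integer(n_categories)
  stopifnot(n_categories >= 1L)

  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))          # expected rate at stationarity
  Q <- Q / scale

  # symmetric similarity transform for a numerically stable eigensystem
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  A <- diag(1 / sq) %*% es$vectors     # P(t) = A diag(exp(lambda t)) Ainv
  Ainv <- t(es$vectors) %*% diag(sq)

  structure(list(name = name, exchangeabilities = S, frequencies = pi,
                 Q = Q, gamma_shape = gamma_shape,
                 n_categories = n_categories,
                 category_rates = discrete_gamma_rates(gamma_shape, n_categories),
                 eigen = list(values = es$values, A = A, Ainv = Ainv)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution model %s (+G%d, shape %.4g)\n",
              x$name, x$n_categories, x$gamma_shape))
  invisible(x)
}

#' Discrete-gamma category rates
#'
#' Equal-probability categories whose rate is the exact within-category mean
#' of a Gamma(shape, shape) distribution, so the rates average to 1.
#'
#' @param shape Positive gamma shape parameter (`Inf` for homogeneity).
#' @param n Number of categories.
#' @return Numeric vector of `n` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, n) {
  n <- as.integer(n)
  if (n == 1L || !is.finite(shape)) return(rep(1, n))
  q <- stats::qgamma(seq(0, 1, length.out = n + 1L), shape = shape, rate = shape)
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  rates <- n * diff(p)
  rates / mean(rates)                  # exact to rounding; enforce mean 1
}

#' Transition probability matrix P(t)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site).
#' @param rate Rate multiplier (e.g. a gamma category rate).
#' @return 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  ev <- exp(model$eigen$values * (t * rate))
  if (any(!is.finite(ev)))
    rf_stop("refates_numeric_error",
            "non-finite transition matrix at t = %g, rate = %g", t, rate)
  P <- model$eigen$A %*% (ev * model$eigen$Ainv)
  P[P < 0] <- 0
  P / rowSums(P)
}

.expand_rates <- function(lower) {
  M <- matrix(0, 20, 20)
  M[lower.tri(M)] <- lower
  M + t(M)
}

#' The LG amino-acid model
#'
#' General-purpose replacement matrix of Le & Gascuel (2008), the default
#' model for all likelihood computations (LG+Gamma with 10 categories).
#'
#' @inheritParams substitution_model
#' @return A [substitution_model()].
#' @export
lg_model <- function(gamma_shape = 1, n_categories = 10) {
  substitution_model(.expand_rates(.lg_rates), .lg_freqs,
                     gamma_shape, n_categories, name = "LG")
}

#' The WAG amino-acid model
#' @inheritParams substitution_model
#' @return A [substitution_model()].
#' @export
wag_model <- function(gamma_shape = 1, n_categories = 10) {
  substitution_model(.expand_rates(.wag_rates), .wag_freqs,
                     gamma_shape, n_categories, name = "WAG")
}

#' The JTT amino-acid model
#' @inheritParams substitution_model
#' @return A [substitution_model()].
#' @export
jtt_model <- function(gamma_shape = 1, n_categories = 10) {
  substitution_model(.expand_rates(.jtt_rates), .jtt_freqs,
                     gamma_shape, n_categories, name = "JTT")
}

#' Read a substitution model from a JSON spec
#'
#' The JSON object may contain `name` (one of `LG`, `WAG`, `JTT`) or explicit
#' `exchangeabilities` (190 lower-triangle values or a 20x20 matrix) and
#' `frequencies`, plus optional `gamma_shape` and `n_categories`.
#'
#' @param path Path to the JSON file.
#' @return A [substitution_model()].
#' @export
read_model_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- spec$gamma_shape %||% 1
  ncat <- spec$n_categories %||% 10
  if (!is.null(spec$exchangeabilities)) {
    ex <- spec$exchangeabilities
    if (is.null(dim(ex))) ex <- .expand_rates(as.numeric(ex))
    return(substitution_model(ex, spec$frequencies, shape, ncat,
                              name = spec$name %||% "custom"))
  }
  builder <- switch(toupper(spec$name %||% "LG"),
                    LG = lg_model, WAG = wag_model, JTT = jtt_model,
                    rf_stop("refates_model_error", "unknown model %s", spec$name))
  builder(shape, ncat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replace the gamma shape of a model, reusing the cached eigensystem.
set_gamma_shape <- function(model, shape) {
  model$gamma_shape <- shape
  model$category_rates <- discrete_gamma_rates(shape, model$n_categories)
  model
}
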