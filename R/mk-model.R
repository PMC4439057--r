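# The Mk substitution model for discrete morphological characters:
# k states with uniform stationary frequencies, either unordered (all
# changes equally likely) or ordered (changes only between adjacent
# states), with optional discrete-gamma rate variation across
# characters. Generators are normalized to one expected change per unit
# branch length at stationarity.

#' Mk generator matrix
#'
#' Unordered: all off-diagonal rates equal. Ordered: nonzero rates only
#' between adjacent states i and i+/-1 (so a 3-state ordered character
#' cannot jump 0 -> 2 directly). Rows sum to zero and the matrix is
#' scaled so the mean substitution rate under the uniform stationary
#' distribution is 1.
#'
#' @param k Number of states (>= 2).
#' @param ordered Logical; restrict changes to adjacent states?
#' @return A `k x k` generator matrix.
#' @export
rate_matrix <- function(k, ordered = FALSE) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (!ordered) {
    Q <- matrix(1, k, k)
    diag(Q) <- 0
  } else {
    Q <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      Q[i, i + 1L] <- 1
      Q[i + 1L, i] <- 1
    }
  }
  diag(Q) <- -rowSums(Q)
  # mean rate at uniform frequencies: -sum_i (1/k) Q[i,i]
  mu <- -sum(diag(Q)) / k
  Q / mu
}

#' Mk model specification
#'
#' @param k Number of states (>= 2).
#' @param ordered Logical; ordered character?
#' @param alpha Gamma shape for across-character rate variation;
#'   `Inf` (default) means no rate variation.
#' @param ncat Number of discrete gamma categories (default 4).
#' @param conditioning `"none"` for the plain Mk likelihood or
#'   `"variable"` to condition on characters being variable (the usual
#'   ascertainment correction when invariant characters are never
#'   collected).
#' @return An object of class `mk_model` with the generator and its
#'   eigendecomposition precomputed.
#' @export
mk_model <- function(k, ordered = FALSE, alpha = Inf, ncat = 4L,
                     conditioning = c("none", "variable")) {
  conditioning <- match.arg(conditioning)
  if (!is.infinite(alpha) && alpha <= 0) stop("alpha must be positive")
  Q <- rate_matrix(k, ordered)
  eig <- eigen(Q, symmetric = TRUE)
  rates <- if (is.infinite(alpha) || ncat == 1L) 1
           else discrete_gamma_rates(alpha, ncat)
  structure(list(k = as.integer(k), ordered = ordered, alpha = alpha,
                 ncat = length(rates), rates = rates,
                 conditioning = conditioning,
                 Q = Q, eig = eig, pi = rep(1 / k, k)),
            class = "mk_model")
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t r)` via the (symmetric) eigendecomposition of the Mk
#' generator.
#'
#' @param model An [mk_model()].
#' @param t Branch length (expected substitutions, >= 0).
#' @param r Rate multiplier (>= 0), e.g. a gamma category rate.
#' @return A `k x k` stochastic matrix; entry (i, j) is the probability
#'   of ending in state j after time t starting from state i.
#' @export
transition_probs <- function(model, t, r = 1) {
  stopifnot(inherits(model, "mk_model"))
  if (t < 0) stop("negative branch length")
  if (r < 0) stop("negative rate multiplier")
  if (!is.finite(t * r)) {
    # stationary limit
    return(matrix(1 / model$k, model$k, model$k))
  }
  V <- model$eig$vectors
  P <- V %*% (exp(model$eig$values * t * r) * t(V))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate categories
#'
#' Mean-of-category discretization with equal-probability classes of a
#' gamma distribution with shape `alpha` and mean 1; the returned rates
#' average exactly to 1.
#'
#' @param alpha Gamma shape (> 0). Small values give strong rate
#'   variation; large values approach rate homogeneity.
#' @param n Number of categories (>= 1).
#' @return Numeric vector of `n` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n) {
  if (alpha <= 0) stop("alpha must be positive")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L || is.infinite(alpha)) return(rep(1, n))
  bounds <- qgamma(seq(0, 1, length.out = n + 1L), shape = alpha, rate = alpha)
  # mean of a gamma(alpha, alpha) over (a, b], times n (class prob 1/n):
  # integral x f(x) dx = pgamma(b, alpha+1, alpha) - pgamma(a, alpha+1, alpha)
  upper <- pgamma(bounds[-1L], shape = alpha + 1, rate = alpha)
  lower <- pgamma(bounds[-(n + 1L)], shape = alpha + 1, rate = alpha)
  rates <- n * (upper - lower)
  rates / mean(rates)
}
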