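# Intersection matrix I and probability matrix P.
#
# I_ij counts the neurons active in both bins i and j. Under the null of
# independent Poisson trains, I_ij is a sum of independent Bernoulli
# variables with success probabilities
#   p_ij^(k) = (1 - exp(-lambda_i^(k) D)) (1 - exp(-lambda_j^(k) D)),
# i.e. Poisson-binomial. P_ij is the cumulative probability of observing
# an intersection STRICTLY below I_ij, so 1 - P_ij is a valid p-value.
# The pmf is computed exactly by iterative convolution or approximated by
# a Poisson with rate sum_k p_ij^(k) (Le Cam's approximation).

#' Intersection matrix of binned spike data
#'
#' `I[i, j]` is the number of neurons active in both bins `i` and `j`. In
#' symmetric mode (one data segment against itself) the main diagonal is
#' the population histogram; in cross mode the two segments must share the
#' same neuron set.
#'
#' @param binned_x a [bin_spikes] result.
#' @param binned_y optional second segment (cross mode); defaults to
#'   `binned_x` (symmetric mode).
#' @return Integer matrix with attributes `mode` (`"symmetric"` or
#'   `"cross"`) and `bin_width`.
#' @examples
#' st <- generate_model(0, seed = 1)
#' I <- intersection_matrix(bin_spikes(st, 0.005))
#' @export
intersection_matrix <- function(binned_x, binned_y = NULL) {
  stopifnot(inherits(binned_x, "binned_spikes"))
  sym <- is.null(binned_y)
  if (sym) binned_y <- binned_x
  stopifnot(inherits(binned_y, "binned_spikes"))
  if (nrow(binned_x$occupancy) != nrow(binned_y$occupancy) ||
      !identical(binned_x$ids, binned_y$ids))
    stop("both segments must cover the same neuron set")
  I <- crossprod(binned_x$occupancy * 1L, binned_y$occupancy * 1L)
  storage.mode(I) <- "integer"
  attr(I, "mode") <- if (sym) "symmetric" else "cross"
  attr(I, "bin_width") <- binned_x$bin_width
  I
}

#' Probability that one neuron is active in two given bins
#'
#' The product of the two per-bin "at least one spike" probabilities of a
#' Poisson neuron: `(1 - exp(-l1 * bin_width)) * (1 - exp(-l2 * bin_width))`.
#'
#' @param l1,l2 firing rates (Hz) in the two bins; vectors recycle.
#' @param bin_width bin width in seconds.
#' @export
pair_probability <- function(l1, l2, bin_width) {
  if (any(l1 < 0) || any(l2 < 0)) stop("rates must be non-negative")
  (1 - exp(-l1 * bin_width)) * (1 - exp(-l2 * bin_width))
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of a sum of independent Bernoulli variables with success
#' probabilities `p`, computed by iterative convolution in O(N^2) —
#' mathematically identical to the direct sum over all 2^N subsets, which
#' is infeasible beyond small N.
#'
#' @param p vector of success probabilities in `[0, 1]`.
#' @return Numeric vector of length `length(p) + 1`; element `k + 1` is
#'   `Pr(sum = k)`.
#' @examples
#' poisson_binomial_pmf(c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pmf <- 1
  for (pk in p) pmf <- c(pmf * (1 - pk), 0) + c(0, pmf * pk)
  pmf
}

#' Poisson (Le Cam) approximation to the Poisson-binomial pmf
#'
#' Poisson pmf with rate equal to the sum of the Bernoulli success
#' probabilities. By Le Cam's theorem the total-variation error is bounded
#' by the sum of the squared probabilities, so the approximation is
#' accurate whenever individual probabilities are small.
#'
#' @param lambda Poisson rate (the sum of the success probabilities).
#' @param support integer values at which to evaluate (default `0:ceiling`
#'   of a generous upper tail).
#' @export
lecam_pmf <- function(lambda, support = NULL) {
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (is.null(support))
    support <- 0:max(10, ceiling(lambda + 10 * sqrt(lambda + 1)))
  stats::dpois(support, lambda)
}

#' Cumulative probability matrix of the intersection values
#'
#' Maps each intersection count to its cumulative null probability
#' `P_ij = Pr(I < I_ij)` (strict, so `1 - P_ij` is a valid p-value;
#' `I_ij = 0` gives `P_ij = 0`). `method = "exact"` evaluates the
#' Poisson-binomial cdf per entry; `"lecam"` the Poisson approximation
#' with rate `sum_k p_ij^(k)`; `"auto"` selects exact for `N <= 30`.
#' In symmetric mode only the strict upper triangle carries a test; it is
#' mirrored into the lower triangle for display and the main diagonal is
#' set to 0.
#'
#' @param I intersection matrix from [intersection_matrix].
#' @param rates `rate_profiles` matrix (N x B, Hz) covering the bins of
#'   `I` (both axes in symmetric mode; for cross mode a list of two).
#' @param bin_width analysis bin width in seconds.
#' @param method `"auto"`, `"exact"` or `"lecam"`.
#' @return Numeric matrix of cumulative probabilities in `[0, 1)` with
#'   attributes `method` and `lecam_rate` (the per-entry rate matrix).
#' @export
probability_matrix <- function(I, rates, bin_width,
                               method = c("auto", "exact", "lecam")) {
  method <- match.arg(method)
  sym <- identical(attr(I, "mode"), "symmetric")
  if (is.list(rates) && !inherits(rates, "rate_profiles")) {
    rx <- rates[[1]]; ry <- rates[[2]]
  } else rx <- ry <- rates
  if (ncol(rx) != nrow(I) || ncol(ry) != ncol(I))
    stop("rate profiles do not cover the bins of I")
  if (nrow(rx) != nrow(ry)) stop("rate profiles disagree on N")
  N <- nrow(rx)
  if (method == "auto") method <- if (N <= 30) "exact" else "lecam"
  ax <- 1 - exp(-rx * bin_width)    # N x B1 no-silence probabilities
  ay <- 1 - exp(-ry * bin_width)
  L <- crossprod(ax, ay)            # Le Cam rate: sum_k p_ij^(k)
  if (method == "lecam") {
    P <- matrix(stats::ppois(as.vector(I) - 1, as.vector(L)),
                nrow(I), ncol(I))   # ppois(-1, .) = 0 handles I = 0
  } else {
    P <- matrix(0, nrow(I), ncol(I))
    idx <- if (sym) which(upper.tri(I) & I > 0L) else which(I > 0L)
    for (e in idx) {
      i <- (e - 1L) %% nrow(I) + 1L
      j <- (e - 1L) %/% nrow(I) + 1L
      pmf <- poisson_binomial_pmf(ax[, i] * ay[, j])
      P[e] <- sum(pmf[seq_len(I[i, j])])
    }
    if (sym) P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  if (sym) diag(P) <- 0
  P <- pmin(pmax(P, 0), 1)
  attr(P, "method") <- method
  attr(P, "lecam_rate") <- L
  attr(P, "mode") <- attr(I, "mode")
  attr(P, "bin_width") <- bin_width
  P
}
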