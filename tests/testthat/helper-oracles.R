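# Independent oracles used across the test files. These deliberately use
# naive constructions (brute force, enumeration, Monte Carlo) so they
# never share code paths with the implementation they check.

# Brute-force bin membership: which neurons have >= 1 spike in bin i.
brute_bin_members <- function(trains, t_start, bin_width, i) {
  lo <- t_start + (i - 1) * bin_width
  hi <- lo + bin_width
  which(vapply(trains, function(t) any(t >= lo & t < hi), logical(1)))
}

# Brute-force intersection count by a double loop over neurons.
brute_intersection <- function(occ, i, j) {
  n <- 0L
  for (k in seq_len(nrow(occ))) if (occ[k, i] && occ[k, j]) n <- n + 1L
  n
}

# Exact Poisson-binomial pmf by literal 2^N subset enumeration.
subset_pmf <- function(p) {
  N <- length(p)
  pmf <- numeric(N + 1)
  for (mask in 0:(2^N - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))
    pmf[sum(inset) + 1] <- pmf[sum(inset) + 1] +
      prod(p[inset]) * prod(1 - p[!inset])
  }
  pmf
}

# Literal nested-sum evaluation of the joint survival function of the d
# largest of n uniform order statistics: log-space recursion over the
# index tuples n >= i_1 >= ... >= i_d >= 1 with i_k >= d - k + 1, term
# prod_{k=0}^{d} D_k^{i_k - i_{k+1}} / (i_k - i_{k+1})!  (i_0 = n,
# i_{d+1} = 0, D_k consecutive differences of (0, x, 1)). Exponential in
# the tuple count; independent of the package's dynamic program.
nested_sum_survival <- function(x, n) {
  d <- length(x)
  D <- diff(c(0, x, 1))                # D_0 .. D_d
  logfac <- function(dx, e) {
    if (e == 0) return(0)
    if (dx <= 0) return(-Inf)
    e * log(dx) - lgamma(e + 1)
  }
  walk <- function(k, prev, logprod) {
    if (k > d) {                       # close with D_d^{i_d}/i_d!
      return(logprod + logfac(D[d + 1], prev))
    }
    out <- numeric(0)
    for (ik in (d - k + 1):prev) {
      term <- logfac(D[k], prev - ik)  # D_{k-1} in 0-based naming
      if (!is.finite(term)) next
      out <- c(out, walk(k + 1, ik, logprod + term))
    }
    out
  }
  lt <- walk(1, n, 0)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(0)
  m <- max(lt)
  exp(lgamma(n + 1) + m + log(sum(exp(lt - m))))
}

# Monte-Carlo estimate of the joint order-statistic survival.
mc_survival <- function(x, n, n_mc = 2e5, seed = 1) {
  set.seed(seed)
  d <- length(x)
  hits <- 0L
  for (b in seq_len(ceiling(n_mc / 2e4))) {
    m <- min(2e4, n_mc - (b - 1) * 2e4)
    X <- matrix(stats::runif(m * n), m)
    Xs <- t(apply(X, 1, sort))
    ok <- rep(TRUE, m)
    for (r in seq_len(d)) ok <- ok & (Xs[, n - d + r] >= x[r])
    hits <- hits + sum(ok)
  }
  hits / n_mc
}

# Tiny deterministic spike set used in several files.
toy_spikes <- function() {
  spike_trains(list(c(0.011, 0.052), c(0.012, 0.031), 0.053, numeric(0)),
               t_start = 0, t_stop = 0.06)
}
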