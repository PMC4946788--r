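# Firing-rate profile estimation. All estimators return an N x B matrix of
# per-neuron rates (Hz) evaluated at the centers of the analysis bins, with
# a "provenance" attribute. Kernel estimators use truncate-and-renormalize
# boundary handling: the part of each spike's kernel mass falling inside
# the observation window is rescaled to unit mass, so total estimated mass
# stays close to the spike count and edge rates are not biased downward.

rate_profiles_matrix <- function(lam, provenance, bin_width) {
  structure(lam, provenance = provenance, bin_width = bin_width,
            class = c("rate_profiles", "matrix", "array"))
}

as_trial_list <- function(trials) {
  if (inherits(trials, "spike_trains")) list(trials) else trials
}

check_trials <- function(trials) {
  durs <- vapply(trials, duration, numeric(1))
  if (max(durs) - min(durs) > 1e-9) stop("trials have mismatched durations")
  ns <- vapply(trials, n_neurons, integer(1))
  if (length(unique(ns)) != 1L) stop("trials have mismatched neuron counts")
  invisible(trials)
}

bin_centers <- function(trial, bin_width) {
  B <- floor(duration(trial) / bin_width)
  trial$t_start + (seq_len(B) - 0.5) * bin_width
}

#' Peri-stimulus time histogram rate estimate
#'
#' Spike counts in `psth_bin`-wide bins, averaged over trials and divided
#' by the bin width, then resampled piecewise-constant onto the (finer)
#' analysis bins: each analysis bin inherits the rate of the PSTH bin
#' covering its center.
#'
#' @param trials a [spike_trains] object or a list of them (independent
#'   trials of the same `N` neurons and duration).
#' @param psth_bin PSTH bin width in seconds (at least the analysis bin
#'   width).
#' @param bin_width analysis bin width in seconds.
#' @return A `rate_profiles` matrix (N x B, Hz).
#' @export
psth_rate <- function(trials, psth_bin, bin_width) {
  trials <- check_trials(as_trial_list(trials))
  if (psth_bin < bin_width)
    stop("'psth_bin' must be at least the analysis bin width")
  tr1 <- trials[[1]]
  N <- n_neurons(tr1)
  centers <- bin_centers(tr1, bin_width)
  Tlen <- duration(tr1)
  nb <- ceiling(Tlen / psth_bin - 1e-9)
  edges <- tr1$t_start + c(psth_bin * (seq_len(nb) - 1L), Tlen)
  widths <- diff(edges)
  lam <- matrix(0, N, length(centers))
  for (k in seq_len(N)) {
    counts <- numeric(nb)
    for (tr in trials) {
      t <- tr$trains[[k]]
      if (length(t))
        counts <- counts + tabulate(findInterval(t, edges,
                                                 rightmost.closed = TRUE), nb)
    }
    rate <- counts / (length(trials) * widths)
    lam[k, ] <- rate[pmin(findInterval(centers, edges), nb)]
  }
  rate_profiles_matrix(lam, "psth", bin_width)
}

kernel_eval <- function(spikes, centers, t_start, t_stop, shape, width) {
  # sum of unit-mass kernels at the bin centers, edge mass renormalized
  if (!length(spikes)) return(numeric(length(centers)))
  if (shape == "boxcar") {
    h <- width / 2
    lo <- pmax(spikes - h, t_start)
    hi <- pmin(spikes + h, t_stop)
    mass <- (hi - lo) / width           # kernel mass inside the window
    out <- numeric(length(centers))
    for (s in seq_along(spikes)) {
      inside <- centers >= spikes[s] - h & centers < spikes[s] + h
      out[inside] <- out[inside] + 1 / (width * mass[s])
    }
    out
  } else {                              # truncated gaussian, width = 5.4 sigma
    sigma <- width / 5.4
    cut <- 2.7 * sigma
    out <- numeric(length(centers))
    for (s in seq_along(spikes)) {
      lo <- max(spikes[s] - cut, t_start)
      hi <- min(spikes[s] + cut, t_stop)
      mass <- stats::pnorm(hi, spikes[s], sigma) -
        stats::pnorm(lo, spikes[s], sigma)
      inside <- centers >= lo & centers <= hi
      out[inside] <- out[inside] +
        stats::dnorm(centers[inside], spikes[s], sigma) / mass
    }
    out
  }
}

#' Fixed-width kernel convolution rate estimate
#'
#' Each spike is replaced by a unit-mass kernel centered on the spike time;
#' the trial-averaged kernel sum, sampled at analysis-bin centers, is the
#' rate estimate. The boxcar kernel has total width `width`; the gaussian
#' kernel is truncated at +/- 2.7 standard deviations with total width
#' `width = 5.4 * sigma`.
#'
#' @inheritParams psth_rate
#' @param shape `"boxcar"` or `"gaussian"`.
#' @param width kernel width in seconds (default 0.2).
#' @return A `rate_profiles` matrix (N x B, Hz).
#' @export
kernel_rate <- function(trials, shape = c("boxcar", "gaussian"),
                        width = 0.2, bin_width) {
  shape <- match.arg(shape)
  if (width <= 0) stop("'width' must be positive")
  trials <- check_trials(as_trial_list(trials))
  tr1 <- trials[[1]]
  N <- n_neurons(tr1)
  centers <- bin_centers(tr1, bin_width)
  lam <- matrix(0, N, length(centers))
  for (k in seq_len(N)) {
    acc <- numeric(length(centers))
    for (tr in trials)
      acc <- acc + kernel_eval(tr$trains[[k]], centers, tr$t_start,
                               tr$t_stop, shape, width)
    lam[k, ] <- acc / length(trials)
  }
  rate_profiles_matrix(lam, "kernel_fixed", bin_width)
}

lscv_bandwidth <- function(x, grid) {
  # least-squares cross-validation score for a gaussian kernel density
  n <- length(x)
  d <- as.vector(stats::dist(x))      # pairwise |xi - xj|, i < j
  score <- vapply(grid, function(h) {
    term1 <- (n * stats::dnorm(0, sd = sqrt(2) * h) +
                2 * sum(stats::dnorm(d, sd = sqrt(2) * h))) / n^2
    term2 <- 2 / (n * (n - 1)) * 2 * sum(stats::dnorm(d, sd = h))
    term1 - term2
  }, numeric(1))
  grid[which.min(score)]
}

#' Optimized-bandwidth gaussian kernel rate estimate
#'
#' Per neuron, spikes are pooled across trials and a gaussian kernel
#' bandwidth is selected by minimizing the unbiased least-squares
#' cross-validation score over a log-spaced grid spanning
#' `[2 * bin_width, T / 2]`; the rate is the gaussian kernel estimate at
#' that bandwidth (edge mass renormalized), scaled to spikes per trial.
#' Neurons with fewer than two pooled spikes fall back to a flat rate
#' `count / T`.
#'
#' @inheritParams psth_rate
#' @param grid_size number of candidate bandwidths (default 25).
#' @return A `rate_profiles` matrix (N x B, Hz) with attribute
#'   `bandwidths` (selected sigma per neuron, seconds).
#' @export
optimized_kernel_rate <- function(trials, bin_width, grid_size = 25) {
  trials <- check_trials(as_trial_list(trials))
  tr1 <- trials[[1]]
  N <- n_neurons(tr1)
  R <- length(trials)
  Tlen <- duration(tr1)
  centers <- bin_centers(tr1, bin_width)
  grid <- exp(seq(log(2 * bin_width), log(Tlen / 2), length.out = grid_size))
  lam <- matrix(0, N, length(centers))
  bw <- rep(NA_real_, N)
  for (k in seq_len(N)) {
    x <- sort(unlist(lapply(trials, function(tr) tr$trains[[k]]),
                     use.names = FALSE))
    if (length(x) < 2L) {
      lam[k, ] <- length(x) / (R * Tlen)
      next
    }
    h <- lscv_bandwidth(x, grid)
    bw[k] <- h
    est <- numeric(length(centers))
    lo <- pmax(x - 5 * h, tr1$t_start)
    hi <- pmin(x + 5 * h, tr1$t_stop)
    mass <- stats::pnorm(hi, x, h) - stats::pnorm(lo, x, h)
    for (s in seq_along(x))
      est <- est + stats::dnorm(centers, x[s], h) / mass[s]
    lam[k, ] <- est / R
  }
  out <- rate_profiles_matrix(lam, "kernel_optimized", bin_width)
  attr(out, "bandwidths") <- bw
  out
}

#' Wrap externally known rate profiles
#'
#' @param lam N x B matrix of non-negative rates (Hz) on the analysis grid.
#' @param bin_width analysis bin width in seconds.
#' @export
true_rate_profiles <- function(lam, bin_width) {
  if (any(lam < 0)) stop("rates must be non-negative")
  rate_profiles_matrix(as.matrix(lam), "true", bin_width)
}
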