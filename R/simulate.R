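# Stochastic generators for the validation models and SSE injection.
#
# Ten background models of parallel spiking activity are provided, covering
# stationary/non-stationary Poisson firing, heterogeneous rates across
# neurons, gamma-renewal (regular) inter-spike intervals, staggered
# rate-jump propagation, compound-Poisson population synchrony and
# multiple single-interaction-process group synchrony. A repeated sequence
# of synchronous events (SSE) can be injected on top of any background.

#' Piecewise-constant rate profile
#'
#' @param breaks increasing vector of segment boundaries in seconds,
#'   starting at the window start and ending at the window stop.
#' @param rates firing rate (Hz) on each segment; `length(breaks) - 1`.
#' @return An object of class `rate_profile`.
#' @export
rate_profile <- function(breaks, rates) {
  if (length(breaks) != length(rates) + 1L || any(diff(breaks) <= 0))
    stop("'breaks' must be increasing with length(rates) + 1 elements")
  if (any(rates < 0)) stop("rates must be non-negative")
  structure(list(breaks = as.numeric(breaks), rates = as.numeric(rates)),
            class = "rate_profile")
}

profile_at <- function(p, t) {
  i <- findInterval(t, p$breaks, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(p$rates))
  p$rates[i]
}

profile_integral <- function(p, t) {
  # cumulative integral of the rate from breaks[1] to each t
  cs <- c(0, cumsum(p$rates * diff(p$breaks)))
  i <- findInterval(t, p$breaks, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(p$rates))
  cs[i] + (t - p$breaks[i]) * p$rates[i]
}

profile_integral_inverse <- function(p, s) {
  # map operational time s back to clock time (rate must integrate past s)
  cs <- c(0, cumsum(p$rates * diff(p$breaks)))
  i <- findInterval(s, cs, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), length(p$rates))
  p$breaks[i] + (s - cs[i]) / p$rates[i]
}

#' Simulate an (inhomogeneous) Poisson spike train
#'
#' @param profile a [rate_profile], or a single non-negative rate in Hz
#'   (interpreted as stationary over `[0, t_stop)`).
#' @param t_stop end of the observation window (seconds, start is 0).
#' @param seed optional integer seed.
#' @return Sorted numeric vector of spike times.
#' @export
poisson_process <- function(profile, t_stop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(profile))
    profile <- rate_profile(c(0, t_stop), profile)
  stopifnot(inherits(profile, "rate_profile"))
  out <- numeric(0)
  b <- pmin(pmax(profile$breaks, 0), t_stop)
  for (s in seq_along(profile$rates)) {
    len <- b[s + 1] - b[s]
    if (len <= 0 || profile$rates[s] <= 0) next
    n <- stats::rpois(1L, profile$rates[s] * len)
    if (n) out <- c(out, b[s] + stats::runif(n, 0, len))
  }
  sort(out)
}

# Equilibrium forward-recurrence draw for a gamma renewal process with
# shape a and unit mean: CDF F_e(x) = x (1 - F(x)) + F_{a+1}(x), inverted
# numerically. Keeps the count rate stationary from t = 0.
equilibrium_gamma_wait <- function(a) {
  u <- stats::runif(1)
  Fe <- function(x) x * (1 - stats::pgamma(x, a, rate = a)) +
    stats::pgamma(x, a + 1, rate = a) - u
  upper <- 1
  while (Fe(upper) < 0) upper <- upper * 2
  stats::uniroot(Fe, c(0, upper), tol = 1e-10)$root
}

#' Simulate a gamma renewal spike train
#'
#' Inter-spike intervals are gamma distributed with shape `shape` and mean
#' `mean_isi` (coefficient of variation `1/sqrt(shape)`); `shape = 1`
#' reduces to a Poisson process. The process is started in equilibrium
#' (first interval from the residual-life distribution) so the count rate
#' equals `1/mean_isi` from `t = 0`. When `profile` is supplied the process
#' is generated in operational time (unit mean) and warped so that the
#' instantaneous rate follows the profile while intervals remain gamma in
#' operational time.
#'
#' @param shape gamma shape `>= 1`.
#' @param mean_isi mean inter-spike interval in seconds (stationary case).
#' @param t_stop window end (seconds).
#' @param profile optional [rate_profile] for a non-stationary process;
#'   overrides `mean_isi`.
#' @param seed optional integer seed.
#' @return Sorted numeric vector of spike times.
#' @export
gamma_renewal <- function(shape, mean_isi, t_stop, profile = NULL,
                          seed = NULL) {
  if (shape < 1) stop("'shape' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  horizon <- if (is.null(profile)) t_stop / mean_isi else
    profile_integral(profile, t_stop)
  # unit-mean renewal on [0, horizon] in operational time; draw intervals
  # in blocks until the horizon is passed
  t <- equilibrium_gamma_wait(shape)
  times <- numeric(0)
  block <- max(16L, ceiling(horizon * 1.5))
  while (t < horizon) {
    isi <- stats::rgamma(block, shape, rate = shape)
    times <- c(times, t + c(0, cumsum(isi[-block])))
    t <- t + sum(isi)
  }
  times <- times[times < horizon]
  if (is.null(profile)) times * mean_isi
  else profile_integral_inverse(profile, times)
}

#' Simulate correlated spike trains from a compound Poisson process
#'
#' A mother Poisson process of rate `lambda_m = N * lambda_single / E[xi]`
#' emits events; each event draws a size `xi` from the amplitude
#' distribution `A` and deposits one synchronous spike in `xi` distinct,
#' uniformly chosen neurons. The construction matches each neuron's
#' marginal rate to `lambda_single`.
#'
#' @param n_neurons number of neurons `N`.
#' @param amplitude named numeric vector: `amplitude[["k"]]` is the
#'   probability `A(k)` of an event of size `k`; must sum to 1 and the
#'   support must not exceed `N`.
#' @param lambda_single per-neuron total firing rate in Hz.
#' @param t_stop window end (seconds).
#' @param seed optional integer seed.
#' @param lambda_m optional override of the mother rate (Hz).
#' @return A [spike_trains] object.
#' @export
compound_poisson <- function(n_neurons, amplitude, lambda_single, t_stop,
                             seed = NULL, lambda_m = NULL) {
  sizes <- as.integer(names(amplitude))
  if (any(is.na(sizes)) || any(sizes < 1L))
    stop("'amplitude' must be named by positive integer sizes")
  if (any(sizes > n_neurons)) stop("amplitude support exceeds N")
  if (abs(sum(amplitude) - 1) > 1e-8) stop("'amplitude' must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  e_xi <- sum(sizes * amplitude)
  if (is.null(lambda_m)) lambda_m <- n_neurons * lambda_single / e_xi
  n_ev <- stats::rpois(1L, lambda_m * t_stop)
  trains <- vector("list", n_neurons)
  for (k in seq_len(n_neurons)) trains[[k]] <- numeric(0)
  if (n_ev) {
    tt <- stats::runif(n_ev, 0, t_stop)
    xi <- sample(sizes, n_ev, replace = TRUE, prob = amplitude)
    for (e in seq_len(n_ev)) {
      who <- sample.int(n_neurons, xi[e])
      for (k in who) trains[[k]] <- c(trains[[k]], tt[e])
    }
  }
  spike_trains(trains, 0, t_stop)
}

#' Simulate multiple single-interaction processes (group synchrony)
#'
#' `n_groups` disjoint groups of `group_size` neurons each receive
#' perfectly synchronous spikes in `events_per_group` randomly selected
#' time bins (independently per group); independent Poisson background
#' fills every neuron's total rate to `lambda_single`. Groups occupy the
#' last `n_groups * group_size` neuron ids so that they are disjoint from
#' the default injected-SSE groups (low ids).
#'
#' @param n_neurons total neuron count.
#' @param n_groups,group_size group layout; `n_groups * group_size` must
#'   not exceed `n_neurons`.
#' @param events_per_group number of synchronous bins per group.
#' @param lambda_single per-neuron total rate (Hz).
#' @param t_stop window end (seconds).
#' @param bin_width width of the event bins (seconds).
#' @param seed optional integer seed.
#' @return A [spike_trains] object.
#' @export
multiple_sip <- function(n_neurons = 100, n_groups = 7, group_size = 5,
                         events_per_group = 2, lambda_single = 15,
                         t_stop = 1, bin_width = 0.005, seed = NULL) {
  if (n_groups * group_size > n_neurons)
    stop("groups exceed the available neurons")
  if (!is.null(seed)) set.seed(seed)
  B <- floor(t_stop / bin_width)
  in_group_rate <- lambda_single - events_per_group / t_stop
  if (in_group_rate < 0) stop("events_per_group too large for lambda_single")
  first_gid <- n_neurons - n_groups * group_size + 1L
  trains <- vector("list", n_neurons)
  for (k in seq_len(n_neurons))
    trains[[k]] <- poisson_process(
      if (k >= first_gid) in_group_rate else lambda_single, t_stop)
  for (g in seq_len(n_groups)) {
    members <- first_gid + (g - 1L) * group_size + seq_len(group_size) - 1L
    if (events_per_group == 0) next
    bins <- sample.int(B, events_per_group)
    centers <- (bins - 0.5) * bin_width
    for (k in members) trains[[k]] <- sort(c(trains[[k]], centers))
  }
  spike_trains(trains, 0, t_stop)
}

#' Simulate staggered rate-jump propagation
#'
#' Independent Poisson trains organized in groups; group `l` jumps from
#' `lambda_base` to `lambda_jump` for `jump_len` seconds starting at
#' `t1 + (l-1) * jump_len` and again at `t2 + (l-1) * jump_len`, mimicking
#' a wave of rate transients that repeats once.
#'
#' @param n_neurons,n_groups,group_size layout (defaults 100 = 20 x 5).
#' @param lambda_base,lambda_jump baseline and jump rates (Hz).
#' @param jump_len jump duration (seconds).
#' @param t1,t2 onset times of the two propagation waves (seconds).
#' @param t_stop window end (seconds).
#' @param seed optional integer seed.
#' @return A [spike_trains] object.
#' @export
rate_jump_propagation <- function(n_neurons = 100, n_groups = 20,
                                  group_size = 5, lambda_base = 14,
                                  lambda_jump = 100, jump_len = 0.005,
                                  t1 = 0.05, t2 = 0.5, t_stop = 1,
                                  seed = NULL) {
  if (n_groups * group_size != n_neurons)
    stop("n_groups * group_size must equal n_neurons")
  if (t2 + n_groups * jump_len > t_stop || t1 + n_groups * jump_len > t2)
    stop("jump schedule does not fit in [0, t_stop]")
  if (!is.null(seed)) set.seed(seed)
  trains <- vector("list", n_neurons)
  for (g in seq_len(n_groups)) {
    off <- (g - 1) * jump_len
    p <- rate_profile(c(0, t1 + off, t1 + off + jump_len,
                        t2 + off, t2 + off + jump_len, t_stop),
                      c(lambda_base, lambda_jump, lambda_base,
                        lambda_jump, lambda_base))
    for (k in (g - 1L) * group_size + seq_len(group_size))
      trains[[k]] <- poisson_process(p, t_stop)
  }
  spike_trains(trains, 0, t_stop)
}

#' Generate one realization of a validation background model
#'
#' Dispatches to the generators above with the standard study conditions:
#' `N = 100` neurons, `T = 1` s, population-average rate 15 Hz.
#'
#' \describe{
#'   \item{0}{independent Poisson, stationary 15 Hz.}
#'   \item{1}{Poisson, common profile 10 Hz + 50 Hz on (600, 700) ms.}
#'   \item{2}{Poisson, heterogeneous stationary rates 5..25 Hz
#'     (`lambda_k = 5 + 20 (k-1)/(N-1)` Hz).}
#'   \item{3}{gamma renewal (shape 5), stationary 15 Hz.}
#'   \item{4}{gamma renewal (shape 5) with the model-1 rate profile.}
#'   \item{5}{gamma renewal (shape 5), heterogeneous rates as model 2.}
#'   \item{6}{rate-jump propagation, 20 groups of 5, 14 to 100 Hz.}
#'   \item{7}{compound Poisson population synchrony, A(1) = 0.938,
#'     A(5) = 0.062, per-neuron rate 15 Hz.}
#'   \item{8}{multiple SIP: 7 groups of 5 with 2 synchronous bins each,
#'     total per-neuron rate 15 Hz.}
#'   \item{9}{Poisson, `lambda_k(t) = 5 + 10 (k-1)/(N-1) + 50 *
#'     1\{600 < t < 700 ms\}` Hz.}
#' }
#'
#' @param model_id integer 0..9.
#' @param n_neurons neuron count (default 100).
#' @param t_stop window end in seconds (default 1).
#' @param bin_width bin width used by models that place events on a bin
#'   grid (model 8); default 5 ms.
#' @param seed optional integer seed.
#' @return A [spike_trains] object.
#' @export
generate_model <- function(model_id, n_neurons = 100, t_stop = 1,
                           bin_width = 0.005, seed = NULL) {
  if (!model_id %in% 0:9) stop("unknown model id: ", model_id)
  if (!is.null(seed)) set.seed(seed)
  N <- n_neurons
  hetero <- function(k, lo, span) lo + span * (k - 1) / (N - 1)
  jump <- function(base) rate_profile(c(0, 0.6, 0.7, t_stop),
                                      c(base, base + 50, base))
  one <- function(gen) spike_trains(lapply(seq_len(N), gen), 0, t_stop)
  switch(as.character(model_id),
    "0" = one(function(k) poisson_process(15, t_stop)),
    "1" = one(function(k) poisson_process(jump(10), t_stop)),
    "2" = one(function(k) poisson_process(hetero(k, 5, 20), t_stop)),
    "3" = one(function(k) gamma_renewal(5, 1 / 15, t_stop)),
    "4" = one(function(k) gamma_renewal(5, NA, t_stop, profile = jump(10))),
    "5" = one(function(k) gamma_renewal(5, 1 / hetero(k, 5, 20), t_stop)),
    "6" = rate_jump_propagation(n_neurons = N, t_stop = t_stop),
    "7" = compound_poisson(N, c("1" = 0.938, "5" = 0.062), 15, t_stop),
    "8" = multiple_sip(n_neurons = N, t_stop = t_stop,
                       bin_width = bin_width),
    "9" = one(function(k) poisson_process(jump(hetero(k, 5, 10)), t_stop)))
}

#' True generative rate profiles of a background model
#'
#' Returns the per-neuron, per-bin firing rates (Hz) that parameterize
#' [generate_model], evaluated at bin centers on the analysis grid — the
#' "true rates" used to bypass estimation. For the renewal models the
#' count-rate profile (reciprocal mean interval) is returned; for the
#' synchrony models (7, 8) the stationary marginal rate.
#'
#' @inheritParams generate_model
#' @return `rate_profiles` matrix (N x B, Hz), provenance `"true"`.
#' @export
model_rate_profiles <- function(model_id, n_neurons = 100, t_stop = 1,
                                bin_width = 0.005) {
  if (!model_id %in% 0:9) stop("unknown model id: ", model_id)
  N <- n_neurons
  B <- floor(t_stop / bin_width)
  centers <- (seq_len(B) - 0.5) * bin_width
  hetero <- function(k, lo, span) lo + span * (k - 1) / (N - 1)
  jump_at <- function(base) base + 50 * (centers > 0.6 & centers < 0.7)
  lam <- matrix(0, N, B)
  if (model_id %in% c(0, 3, 7, 8)) lam[] <- 15
  else if (model_id %in% c(1, 4)) lam <- matrix(jump_at(10), N, B,
                                                byrow = TRUE)
  else if (model_id %in% c(2, 5)) lam[] <- hetero(row(lam), 5, 20)
  else if (model_id == 9)
    for (k in seq_len(N)) lam[k, ] <- jump_at(hetero(k, 5, 10))
  else { # model 6
    jump_len <- 0.005
    for (g in seq_len(20)) {
      off <- (g - 1) * jump_len
      prof <- rep(14, B)
      for (t0 in c(0.05, 0.5) + off)
        prof[centers > t0 & centers < t0 + jump_len] <- 100
      for (k in (g - 1L) * 5L + 1:5) lam[k, ] <- prof
    }
  }
  structure(lam, provenance = "true", bin_width = bin_width,
            class = c("rate_profiles", "matrix", "array"))
}

#' Specify a repeated sequence of synchronous events to inject
#'
#' @param n_events number of synchronous events in the sequence
#'   (`l_SSE`, default 7).
#' @param event_size neurons per event (`xi_SSE`, default 5).
#' @param groups optional list of `n_events` pairwise-disjoint integer
#'   vectors of member neuron ids; defaults to ids `1..5, 6..10, ...`.
#' @param spacing inter-event spacing in bins (default 1: consecutive
#'   bins).
#' @param holes integer vector of event indices after which an extra
#'   one-bin gap is inserted in the FIRST repetition only (creates holes
#'   and raises the diagonal-structure wiggliness).
#' @param wiggle integer vector of per-event bin offsets applied to the
#'   second repetition (same length as `n_events`), default all 0.
#' @return An object of class `sse_spec`.
#' @export
sse_spec <- function(n_events = 7, event_size = 5, groups = NULL,
                     spacing = 1, holes = integer(0),
                     wiggle = integer(n_events)) {
  if (is.null(groups))
    groups <- lapply(seq_len(n_events),
                     function(e) (e - 1L) * event_size + seq_len(event_size))
  if (length(groups) != n_events) stop("need one neuron group per event")
  if (anyDuplicated(unlist(groups))) stop("groups must be pairwise disjoint")
  if (spacing < 1) stop("'spacing' must be >= 1 bin")
  if (length(wiggle) != n_events) stop("'wiggle' must have one offset per event")
  structure(list(n_events = as.integer(n_events),
                 event_size = as.integer(event_size), groups = groups,
                 spacing = as.integer(spacing), holes = as.integer(holes),
                 wiggle = as.integer(wiggle)),
            class = "sse_spec")
}

sse_event_bins <- function(spec, start_bin, with_holes) {
  # bin index of each event relative to a given start bin (1-based)
  rel <- (seq_len(spec$n_events) - 1L) * spec$spacing
  if (with_holes && length(spec$holes))
    for (h in spec$holes) rel[(h + 1L):spec$n_events] <-
      rel[(h + 1L):spec$n_events] + 1L
  start_bin + rel
}

#' Inject a repeated SSE into background activity
#'
#' Adds, for each of two repetitions and each event, one spike per member
#' neuron at the center of the target bin (spikes are added to the
#' background; coincidences are absorbed by binary bin clipping). The two
#' occurrence windows are placed at `start_bins` or, when `NULL`, drawn
#' uniformly among admissible positions with a minimum separation of
#' `min_separation` bins so that the repetitions never fall inside a
#' single analysis kernel.
#'
#' @param x background [spike_trains].
#' @param spec an [sse_spec].
#' @param bin_width analysis bin width in seconds.
#' @param start_bins optional integer vector of two 1-based start bins.
#' @param min_separation minimum gap (bins) between the two occurrence
#'   windows when drawing at random (default 5, one kernel length).
#' @param seed optional integer seed.
#' @return The modified [spike_trains] with attribute `truth`: a list with
#'   `entries` (the ground-truth diagonal-structure bin pairs, columns
#'   `i`, `j`), `groups`, and `start_bins`.
#' @export
inject_sse <- function(x, spec, bin_width, start_bins = NULL,
                       min_separation = 5L, seed = NULL) {
  stopifnot(inherits(x, "spike_trains"), inherits(spec, "sse_spec"))
  if (max(unlist(spec$groups)) > n_neurons(x))
    stop("SSE group ids exceed the number of neurons")
  if (!is.null(seed)) set.seed(seed)
  B <- floor(duration(x) / bin_width)
  span1 <- max(sse_event_bins(spec, 1L, TRUE))   # window length, rep 1
  span2 <- max(sse_event_bins(spec, 1L, FALSE) + spec$wiggle)
  if (is.null(start_bins)) {
    for (try in 1:1000) {
      s1 <- sample.int(B - span1 + 1L, 1L)
      s2 <- sample.int(B - span2 + 1L, 1L)
      if (s1 + span1 + min_separation <= s2) break
      if (try == 1000) stop("could not place two non-overlapping occurrences")
    }
    start_bins <- c(s1, s2)
  }
  bins1 <- sse_event_bins(spec, start_bins[1], TRUE)
  bins2 <- sse_event_bins(spec, start_bins[2], FALSE) + spec$wiggle
  if (max(bins1, bins2) > B || min(bins1, bins2) < 1L)
    stop("SSE occurrence window does not fit into the binned window")
  if (max(bins1) >= min(bins2))
    stop("occurrence windows overlap")
  trains <- x$trains
  for (e in seq_len(spec$n_events))
    for (b in c(bins1[e], bins2[e])) {
      centre <- x$t_start + (b - 0.5) * bin_width
      for (k in spec$groups[[e]])
        trains[[k]] <- sort(c(trains[[k]], centre))
    }
  out <- spike_trains(trains, x$t_start, x$t_stop, x$ids)
  attr(out, "truth") <- list(entries = cbind(i = bins1, j = bins2),
                             groups = spec$groups,
                             start_bins = start_bins)
  out
}
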