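# Monte-Carlo estimation of the joint-probability matrix under the
# bin-shuffling null: within-bin synchrony patterns are preserved, their
# temporal order is destroyed, so any diagonal structure is broken while
# non-sequential correlations survive into the null distribution.

#' Shuffle the bins of a binned data set
#'
#' Applies one uniform random permutation to the bin axis of the occupancy
#' table (all neurons together), preserving every within-bin pattern.
#'
#' @param binned a [bin_spikes] result.
#' @param perm optional explicit permutation of `1:B` (overrides `seed`).
#' @param seed optional integer seed.
#' @return A `binned_spikes` object with permuted bins and attribute
#'   `perm`.
#' @export
shuffle_bins <- function(binned, perm = NULL, seed = NULL) {
  stopifnot(inherits(binned, "binned_spikes"))
  if (is.null(perm)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(binned$n_bins)
  }
  out <- binned
  out$occupancy <- binned$occupancy[, perm, drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' Kernel-filtered probability matrix
#'
#' For each entry, the `d` largest probabilities inside the diagonal
#' kernel neighborhood (invalid positions dropped) are combined as
#' `F_ij = 1 - prod_k (1 - P^(k))`. This cheap filter is the
#' per-surrogate summary statistic of the Monte-Carlo null; no `p_max`
#' cap is applied since the rank comparison between data and surrogates
#' is cap-invariant.
#'
#' @param P probability matrix.
#' @param kernel a [kernel_spec].
#' @return Matrix `F` on the testable region (upper triangle in symmetric
#'   mode, mirrored).
#' @export
filtered_probability_matrix <- function(P, kernel) {
  mode <- attr(P, "mode")
  if (is.null(mode)) mode <- "symmetric"
  st <- neighbor_value_stack(P, kernel, mode)
  td <- top_d_values(st$U, kernel$d)
  v <- td$values
  v[!is.finite(v)] <- 0
  FF <- matrix(0, nrow(P), ncol(P))
  FF[st$idx] <- 1 - apply(1 - v, 1, prod)
  if (mode == "symmetric") {
    FF[lower.tri(FF)] <- t(FF)[lower.tri(FF)]
    diag(FF) <- 0
  }
  FF
}

#' Monte-Carlo joint probability matrix under bin shuffling
#'
#' For each of `n_surrogates` surrogates: shuffle the bins, rebuild the
#' intersection and probability matrices (with the ORIGINAL, unshuffled
#' rate profiles, which simply permutes the rows and columns of `P`),
#' filter with [filtered_probability_matrix], and count how often the
#' surrogate filtered value stays at or below the observed one:
#' `Jtilde_ij = (1/S) * #\{s : Ftilde_s;ij <= F_ij\}`. Values lie on the
#' grid `0, 1/S, ..., 1`; significance requires `Jtilde > alpha2`.
#'
#' @param binned a [bin_spikes] result.
#' @param rates `rate_profiles` matrix for the original data.
#' @param bin_width analysis bin width (seconds).
#' @param kernel a [kernel_spec].
#' @param n_surrogates number of surrogates `S` (default 1000).
#' @param seed integer master seed; per-surrogate permutations are drawn
#'   from `seed + s` so results do not depend on execution order.
#' @param alpha2 significance threshold the caller will apply; a warning
#'   is emitted when `1/S > 1 - alpha2`, i.e. when the Monte-Carlo
#'   resolution cannot represent tail probabilities below the threshold
#'   (only the degenerate value `Jtilde = 1` can then be significant).
#' @param method probability-matrix method.
#' @return Matrix `Jtilde` (symmetric, diagonal 0) with attribute `F`
#'   (the observed filtered matrix).
#' @export
surrogate_joint_matrix <- function(binned, rates, bin_width, kernel,
                                   n_surrogates = 1000, seed = NULL,
                                   alpha2 = 0.99999, method = "lecam") {
  stopifnot(inherits(binned, "binned_spikes"))
  S <- as.integer(n_surrogates)
  if (S < 1L) stop("'n_surrogates' must be >= 1")
  if (1 / S > 1 - alpha2)
    warning(sprintf(paste0("with S = %d surrogates the finest attainable ",
                           "tail probability 1/S exceeds 1 - alpha2 = %g; ",
                           "only Jtilde = 1 can cross the threshold"),
                    S, 1 - alpha2))
  I <- intersection_matrix(binned)
  P <- probability_matrix(I, rates, bin_width, method)
  FF <- filtered_probability_matrix(P, kernel)
  counts <- matrix(0L, nrow(P), ncol(P))
  Psym <- P
  Psym[lower.tri(Psym)] <- t(Psym)[lower.tri(Psym)]
  base_seed <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)
  for (s in seq_len(S)) {
    set.seed((base_seed + s) %% 2147483647L)
    perm <- sample.int(binned$n_bins)
    Ps <- Psym[perm, perm]
    attr(Ps, "mode") <- "symmetric"
    Fs <- filtered_probability_matrix(Ps, kernel)
    counts <- counts + (Fs <= FF)
  }
  Jt <- counts / S
  diag(Jt) <- 0
  attr(Jt, "F") <- FF
  attr(Jt, "mode") <- "symmetric"
  Jt
}
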