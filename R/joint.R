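# Joint significance of the largest neighbors inside a diagonally
# oriented rectangular kernel.
#
# For each entry (i, j), the kernel covers, on each of the w_K diagonals
# at offset c in {-floor(w_K/2), ..., +floor(w_K/2)} from the diagonal of
# (i, j), the l_K - |c| consecutive entries centered on the projection of
# (i, j) onto that diagonal. Among the covered P-values (the neighborhood
# is the full set of kernel-covered entries, the center included) the d
# largest, capped at p_max, enter the joint survival function of the
# top-d order statistics of n iid uniforms:
#
#   Fbar(x_1 <= ... <= x_d) =
#     n! * sum over n >= i_1 >= ... >= i_d >= 1, i_k >= d-k+1, of
#       prod_{k=0}^{d} (x_{k+1} - x_k)^{i_k - i_{k+1}} / (i_k - i_{k+1})!
#
# with x_0 = 0, x_{d+1} = 1, i_0 = n, i_{d+1} = 0. The sum is evaluated by
# an exact dynamic program over the partial sums i_k (identical terms,
# grouped), which is polynomial in n and vectorizes across matrix entries.
# All terms are non-negative so the linear-space evaluation is stable; for
# the kernel sizes in use (n <= ~50) no under- or overflow can occur.

#' Rectangular diagonal kernel specification
#'
#' @param l_k kernel length in bins along the diagonal (odd, `>= 1`).
#' @param w_k kernel width in diagonals (odd, `>= 1`).
#' @param d number of largest neighbors whose joint significance is
#'   evaluated; at most the interior neighborhood size
#'   `n = l_k * w_k - floor(w_k/2) * (floor(w_k/2) + 1)`.
#' @param p_max cap applied to each selected probability before the joint
#'   survival function (guards against a single isolated extreme entry
#'   dominating the joint test). Default 0.999.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(l_k = 5, w_k = 5, d = 5, p_max = 0.999) {
  if (l_k < 1 || l_k %% 2 == 0 || w_k < 1 || w_k %% 2 == 0)
    stop("'l_k' and 'w_k' must be odd and >= 1")
  h <- w_k %/% 2
  n <- l_k * w_k - h * (h + 1)
  if (d < 1 || d > n)
    stop("'d' must lie in 1..", n, " for this kernel")
  if (p_max <= 0 || p_max >= 1) stop("'p_max' must lie in (0, 1)")
  structure(list(l_k = as.integer(l_k), w_k = as.integer(w_k),
                 d = as.integer(d), p_max = p_max, n = as.integer(n)),
            class = "kernel_spec")
}

kernel_offsets <- function(kernel) {
  # (di, dj) offsets of the kernel positions relative to the center,
  # including the center (0, 0); row order is the deterministic scan
  # order used for tie-breaking.
  h <- kernel$w_k %/% 2
  out <- NULL
  for (cc in -h:h) {
    L <- kernel$l_k - abs(cc)
    a_center <- floor(-cc / 2)          # projection, floor rounding
    a <- a_center - floor((L - 1) / 2) + seq_len(L) - 1L
    out <- rbind(out, cbind(di = a, dj = a + cc))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Kernel neighborhood of a matrix entry
#'
#' Returns the positions covered by the diagonal rectangular kernel
#' centered on `(i, j)` (the center included), removing positions outside
#' the matrix and — in symmetric mode — positions on or below the main
#' diagonal. For interior entries in cross mode the count equals
#' `n = l_k * w_k - floor(w_k/2) * (floor(w_k/2) + 1)`.
#'
#' @param i,j entry position (1-based; `i < j` required in symmetric mode).
#' @param kernel a [kernel_spec].
#' @param shape dimensions of the matrix, `c(nrow, ncol)`.
#' @param mode `"symmetric"` or `"cross"`.
#' @return Integer matrix with columns `i`, `j`.
#' @export
diagonal_neighborhood <- function(i, j, kernel, shape,
                                  mode = c("symmetric", "cross")) {
  mode <- match.arg(mode)
  if (mode == "symmetric" && i >= j)
    stop("(i, j) must lie strictly above the main diagonal in symmetric mode")
  off <- kernel_offsets(kernel)
  pos <- cbind(i = i + off[, 1], j = j + off[, 2])
  keep <- pos[, 1] >= 1 & pos[, 1] <= shape[1] &
    pos[, 2] >= 1 & pos[, 2] <= shape[2]
  if (mode == "symmetric") keep <- keep & pos[, 1] < pos[, 2]
  pos[keep, , drop = FALSE]
}

#' Joint survival function of the d largest of n uniform order statistics
#'
#' Evaluates `Pr(X_(n-d+1) >= x_1, ..., X_(n) >= x_d)` for `n` iid
#' standard uniforms, after capping each `x_r` at `p_max`. Inputs must be
#' sorted ascending.
#'
#' @param x ascending vector of `d` values in `[0, 1]`.
#' @param n sample size (`n >= d`).
#' @param p_max cap on the individual values (default 1: no cap).
#' @return The joint upper-tail probability, clipped to `[0, 1]`.
#' @examples
#' joint_survival(0.5, 3)            # 1 - 0.5^3
#' joint_survival(c(0.3, 0.6), 2)    # 0.4
#' @export
joint_survival <- function(x, n, p_max = 1) {
  d <- length(x)
  if (is.unsorted(x)) stop("'x' must be sorted ascending")
  if (any(x < 0 | x > 1)) stop("'x' values must lie in [0, 1]")
  if (n < d) stop("'n' must be at least length(x)")
  x <- pmin(x, p_max)
  D <- matrix(c(x[1], diff(x), 1 - x[d]), nrow = 1)
  out <- joint_survival_batch(D, n)
  min(max(out, 0), 1)
}

joint_survival_batch <- function(D, n) {
  # D: M x (d+1) matrix of consecutive differences D_0..D_d of the capped,
  # ascending values (D_0 = x_1, D_k = x_{k+1}-x_k, D_d = 1-x_d).
  # Returns Fbar for all M rows at once.
  d <- ncol(D) - 1L
  M <- nrow(D)
  # level k = d: h_d(s) = D_d^s / s!, s >= 1 (constraint i_d >= 1)
  h <- matrix(0, M, n + 1L)
  pw <- D[, d + 1L]
  h[, 2L] <- pw
  if (n >= 2L) for (s in 2:n) {
    pw <- pw * D[, d + 1L] / s
    h[, s + 1L] <- pw
  }
  if (d >= 2L) for (k in (d - 1L):1L) {
    lb_next <- d - k            # minimum of i_{k+1}
    lb <- d - k + 1L            # minimum of i_k
    g <- matrix(0, M, n + 1L)
    pw <- rep(1, M)
    for (jj in 0:(n - lb_next)) {
      if (jj > 0L) pw <- pw * D[, k + 1L] / jj
      s_lo <- max(lb, lb_next + jj)
      if (s_lo > n) break
      s <- s_lo:n
      g[, s + 1L] <- g[, s + 1L] + h[, s - jj + 1L] * pw
    }
    h <- g
  }
  # close with level 0: i_0 = n fixed, exponent n - i_1
  res <- numeric(M)
  pw <- rep(1, M)
  for (i1 in n:max(1L, if (d >= 1L) d else 1L)) {
    jj <- n - i1
    if (jj > 0L) pw <- pw * D[, 1L] / jj
    res <- res + pw * h[, i1 + 1L]
  }
  res * exp(lgamma(n + 1))
}

# Stack of neighborhood P-values for every strict-upper-triangle entry.
# Returns a K x O matrix (K upper-triangle entries in column-major order,
# O kernel offsets including the center: the neighborhood is the full set
# of entries covered by the kernel), -Inf marking invalid positions.
neighbor_value_stack <- function(P, kernel, mode = "symmetric") {
  B1 <- nrow(P); B2 <- ncol(P)
  off <- kernel_offsets(kernel)
  if (mode == "symmetric") {
    Psym <- P
    Psym[lower.tri(Psym)] <- t(Psym)[lower.tri(Psym)]
    idx <- which(upper.tri(P))
  } else {
    Psym <- P
    idx <- seq_len(B1 * B2)
  }
  ii <- (idx - 1L) %% B1 + 1L
  jj <- (idx - 1L) %/% B1 + 1L
  U <- matrix(-Inf, length(idx), nrow(off))
  for (o in seq_len(nrow(off))) {
    ni <- ii + off[o, 1]
    nj <- jj + off[o, 2]
    ok <- ni >= 1L & ni <= B1 & nj >= 1L & nj <= B2
    if (mode == "symmetric") ok <- ok & ni < nj
    w <- which(ok)
    U[w, o] <- Psym[cbind(ni[w], nj[w])]
  }
  list(U = U, idx = idx)
}

# d largest values per row of U (descending), -Inf = missing; also the
# per-row count of valid values. max.col with ties.method "first" makes
# the scan order deterministic.
top_d_values <- function(U, d) {
  K <- nrow(U)
  n_valid <- rowSums(is.finite(U))
  vals <- matrix(-Inf, K, d)
  for (r in seq_len(d)) {
    mc <- max.col(U, ties.method = "first")
    sel <- cbind(seq_len(K), mc)
    vals[, r] <- U[sel]
    U[sel] <- -Inf
  }
  list(values = vals, n_valid = n_valid)
}

#' Joint probability matrix
#'
#' For every testable entry of the probability matrix, selects the `d`
#' largest probabilities inside the diagonal kernel neighborhood (all
#' covered entries including the center; near edges and the main diagonal
#' the reduced count `n'` replaces `n`, and `d` is reduced to `n'` when
#' fewer positions remain), caps them at `p_max`, and sets
#' `J_ij = 1 - Fbar(P_(1), ..., P_(d))` with [joint_survival]. Entries
#' with no valid neighbor get `J = 0`.
#'
#' @param P probability matrix from [probability_matrix].
#' @param kernel a [kernel_spec].
#' @param entries optional two-column matrix of `(i, j)` positions at
#'   which to evaluate `J` (others are left at `NA`); by default the full
#'   strict upper triangle (symmetric mode) or the full matrix (cross
#'   mode) is evaluated.
#' @return Matrix `J` with the same shape as `P`; in symmetric mode the
#'   upper triangle is mirrored into the lower and the diagonal is 0.
#' @export
joint_probability_matrix <- function(P, kernel, entries = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"))
  mode <- attr(P, "mode")
  if (is.null(mode)) mode <- "symmetric"
  st <- neighbor_value_stack(P, kernel, mode)
  U <- st$U
  idx <- st$idx
  partial <- !is.null(entries)
  if (partial) {
    want <- (entries[, 2] - 1L) * nrow(P) + entries[, 1]
    rows <- match(want, idx)
    if (anyNA(rows)) stop("'entries' must lie in the testable region")
    U <- U[rows, , drop = FALSE]
    idx <- idx[rows]
  }
  td <- top_d_values(U, kernel$d)
  J <- matrix(if (partial) NA_real_ else 0, nrow(P), ncol(P))
  fb <- rep(1, length(idx))
  groups <- split(seq_along(idx),
                  list(n = td$n_valid, d = pmin(td$n_valid, kernel$d)),
                  drop = TRUE)
  for (g in groups) {
    n_g <- td$n_valid[g[1]]
    if (n_g == 0L) next
    d_g <- min(n_g, kernel$d)
    x <- td$values[g, seq_len(d_g), drop = FALSE]
    x <- x[, rev(seq_len(d_g)), drop = FALSE]   # ascending
    x <- pmin(x, kernel$p_max)
    D <- cbind(x[, 1], if (d_g > 1) x[, -1, drop = FALSE] -
                 x[, -d_g, drop = FALSE], 1 - x[, d_g])
    fb[g] <- joint_survival_batch(D, n_g)
  }
  jv <- pmin(pmax(1 - fb, 0), 1)
  jv[jv < 1e-12] <- 0     # numerical floor: DP residue of order n! * eps
  J[idx] <- jv
  if (mode == "symmetric" && !partial) {
    J[lower.tri(J)] <- t(J)[lower.tri(J)]
    diag(J) <- 0
  }
  attr(J, "mode") <- mode
  attr(J, "kernel") <- kernel
  J
}
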