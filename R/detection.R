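# Dual-threshold masking, density-based clustering of significant entries
# under an anisotropic elliptical metric, and reconstruction of the
# sequences of synchronous events.

#' Mask of jointly significant matrix entries
#'
#' `M_ij = 1` iff `P_ij > alpha1` and `J_ij > alpha2`; both thresholds
#' must be exceeded, so isolated large entries whose neighbors are at
#' chance are rejected. In symmetric mode the lower triangle and main
#' diagonal are forced to 0. Requires `0 < alpha1 < alpha2 < 1`.
#'
#' @param P,J probability and joint probability matrices (same shape).
#' @param alpha1 individual-entry threshold (default 0.99).
#' @param alpha2 joint threshold (default 0.99999).
#' @return Binary integer matrix.
#' @export
mask_matrix <- function(P, J, alpha1 = 0.99, alpha2 = 0.99999) {
  if (!all(dim(P) == dim(J))) stop("'P' and 'J' must have the same shape")
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1))
    stop("need 0 < alpha1 < alpha2 < 1")
  M <- (P > alpha1) & (J > alpha2)
  M[is.na(M)] <- FALSE
  mode <- attr(P, "mode")
  if (is.null(mode) || mode == "symmetric") {
    M[lower.tri(M, diag = TRUE)] <- FALSE
  }
  storage.mode(M) <- "integer"
  M
}

#' Elliptical distance between matrix positions
#'
#' `d_rho = [1 + (rho - 1) |sin(theta - pi/4)|] * max(|di|, |dj|)`, where
#' `theta` is the angle of the connecting line and the radial factor
#' counts lattice steps (Chebyshev). Positions on a common 45-degree
#' diagonal are at distance `k` per step for any `rho`; anti-diagonal
#' steps are stretched to `rho * k`; a purely horizontal or vertical step
#' of `k` bins is at `[1 + (sqrt(2)/2) (rho - 1)] * k`.
#'
#' @param a,b positions `c(i, j)` (or two-column matrices; rows pair up).
#' @param rho stretching factor `>= 1`.
#' @export
elliptical_distance <- function(a, b, rho) {
  if (rho < 1) stop("'rho' must be >= 1")
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  di <- b[, 1] - a[, 1]; dj <- b[, 2] - a[, 2]
  theta <- atan2(dj, di)
  (1 + (rho - 1) * abs(sin(theta - pi / 4))) * pmax(abs(di), abs(dj))
}

#' Cluster masked entries into diagonal structures
#'
#' Density-based scan (DBSCAN) over the 1-entries of the mask under the
#' elliptical metric: two entries are neighbors if their distance is at
#' most `eps`; a point with at least `min_size` neighbors (itself
#' included) is a core point; clusters are the connected unions of core
#' neighborhoods, border points join the first cluster that reaches them,
#' and clusters keep at least `min_size` entries. Points are processed in
#' row-major order, making the labeling deterministic. Isolated entries
#' are returned as noise.
#'
#' @param M binary mask matrix.
#' @param rho anti-diagonal stretching factor (default 5).
#' @param eps maximum neighbor distance (default 3.5). Along one diagonal
#'   this tolerates `floor(eps) - 1` holes between consecutive entries.
#' @param min_size minimum cluster size `l_0` (default 3).
#' @param kernel optional [kernel_spec]; when supplied, a warning is
#'   emitted if the eps-ellipse is not contained in the kernel
#'   (`floor(eps) > l_k` or short ellipse axis wider than `w_k`).
#' @return List with `clusters` (list of two-column entry matrices,
#'   ordered by first entry), `noise` (two-column matrix) and `labels`
#'   (matrix of cluster ids, 0 = background/noise).
#' @export
dbscan_diagonal <- function(M, rho = 5, eps = 3.5, min_size = 3,
                            kernel = NULL) {
  if (eps <= 0 || min_size < 1) stop("invalid clustering parameters")
  if (!is.null(kernel)) {
    short_axis <- 2 * eps / rho / sqrt(2)  # anti-diagonal extent in bins
    if (floor(eps) > kernel$l_k || short_axis > kernel$w_k)
      warning("eps-ellipse is not contained in the joint-test kernel; ",
              "clusters may join entries the joint test never saw together")
  }
  pts <- which(M != 0, arr.ind = TRUE)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  m <- nrow(pts)
  labels <- rep(0L, m)
  if (m) {
    dmat <- matrix(0, m, m)
    for (q in seq_len(m))
      dmat[, q] <- elliptical_distance(pts, pts[rep(q, m), , drop = FALSE],
                                       rho)
    nb <- dmat <= eps
    core <- rowSums(nb) >= min_size
    cl <- 0L
    for (p in seq_len(m)) {
      if (labels[p] != 0L || !core[p]) next
      cl <- cl + 1L
      queue <- p
      labels[p] <- cl
      while (length(queue)) {
        q <- queue[1]; queue <- queue[-1]
        for (r in which(nb[q, ])) {
          if (labels[r] == 0L) {
            labels[r] <- cl
            if (core[r]) queue <- c(queue, r)
          }
        }
      }
    }
    # enforce the minimum cardinality on final clusters as well
    keep <- which(tabulate(labels, cl) >= min_size)
    labels <- ifelse(labels %in% keep, match(labels, keep), 0L)
    labels[is.na(labels)] <- 0L
  }
  n_cl <- if (m) max(labels) else 0L
  clusters <- lapply(seq_len(n_cl), function(cid)
    pts[labels == cid, , drop = FALSE])
  lab_mat <- matrix(0L, nrow(M), ncol(M))
  if (m) lab_mat[pts] <- labels
  list(clusters = clusters,
       noise = pts[labels == 0L, , drop = FALSE],
       labels = lab_mat)
}

#' Diagonal-structure geometry
#'
#' Length along the diagonal (`l_ds`, bin span) and wiggliness (`w_ds`,
#' number of adjacent off-diagonals spanned) of a cluster of matrix
#' entries.
#'
#' @param entries two-column matrix of `(i, j)` positions.
#' @export
ds_geometry <- function(entries) {
  di <- entries[, 1] - entries[1, 1]
  dj <- entries[, 2] - entries[1, 2]
  list(l_ds = max(entries[, 1]) - min(entries[, 1]) + 1L,
       w_ds = max(di - dj) - min(di - dj) + 1L)
}

#' Reconstruct SSEs from clustered diagonal structures
#'
#' Each cluster entry `(i, j)` contributes one synchronous event whose
#' neuron set is the intersection of the neurons active in bins `i` and
#' `j`; events are ordered by `i`.
#'
#' @param clusters list of two-column entry matrices (from
#'   [dbscan_diagonal]).
#' @param binned the [bin_spikes] result the matrices were derived from.
#' @return List of SSEs; each is a list with `entries`, `events` (a list
#'   of `list(bin_i, bin_j, time_i, time_j, neurons)`), `l_ds`, `w_ds`.
#' @export
extract_sses <- function(clusters, binned) {
  stopifnot(inherits(binned, "binned_spikes"))
  lapply(clusters, function(ent) {
    ent <- ent[order(ent[, 1], ent[, 2]), , drop = FALSE]
    events <- lapply(seq_len(nrow(ent)), function(r) {
      i <- ent[r, 1]; j <- ent[r, 2]
      list(bin_i = i, bin_j = j,
           time_i = binned$t_start + (i - 0.5) * binned$bin_width,
           time_j = binned$t_start + (j - 0.5) * binned$bin_width,
           neurons = intersect(bin_members(binned, i),
                               bin_members(binned, j)))
    })
    geo <- ds_geometry(ent)
    list(entries = ent, events = events, l_ds = geo$l_ds, w_ds = geo$w_ds)
  })
}

#' Run the full detection pipeline
#'
#' Bins the spike trains, builds the intersection matrix `I`, the
#' probability matrix `P` (Le Cam or exact), the joint probability matrix
#' `J`, the significance mask `M`, clusters the mask into diagonal
#' structures `C`, and reconstructs the associated SSEs. Defaults are the
#' standard analysis parameters: 5 ms bins, kernel `l_k = w_k = d = 5`,
#' `p_max = 0.999`, thresholds `alpha1 = 0.99`, `alpha2 = 0.99999`,
#' clustering `rho = 5`, `eps = 3.5`, `min_size = 3`.
#'
#' @param spikes a [spike_trains] object.
#' @param rates a `rate_profiles` matrix (N x B, Hz); see [kernel_rate],
#'   [psth_rate], [optimized_kernel_rate], [true_rate_profiles].
#' @param bin_width analysis bin width in seconds.
#' @param kernel a [kernel_spec].
#' @param alpha1,alpha2 mask thresholds.
#' @param rho,eps,min_size clustering parameters.
#' @param method probability-matrix method (`"auto"`, `"exact"`,
#'   `"lecam"`).
#' @param j_entries `"all"` computes `J` over the whole testable region;
#'   `"candidates"` only where `P > alpha1` (the detection output is
#'   identical, since the mask requires `P > alpha1` anyway, and the
#'   skipped entries are reported as `NA` in `J`).
#' @return An object of class `sse_result`: list with matrices `I`, `P`,
#'   `J`, `M`, `C` (cluster labels), `binned`, `sses`, `noise`, and
#'   `params`.
#' @examples
#' st <- inject_sse(generate_model(0, seed = 7), sse_spec(), 0.005, seed = 7)
#' rates <- kernel_rate(st, "boxcar", 0.2, 0.005)
#' res <- detect_sses(st, rates, 0.005)
#' length(res$sses)
#' @export
detect_sses <- function(spikes, rates, bin_width = 0.005,
                        kernel = kernel_spec(), alpha1 = 0.99,
                        alpha2 = 0.99999, rho = 5, eps = 3.5,
                        min_size = 3, method = "auto",
                        j_entries = c("all", "candidates")) {
  j_entries <- match.arg(j_entries)
  binned <- bin_spikes(spikes, bin_width)
  I <- intersection_matrix(binned)
  P <- probability_matrix(I, rates, bin_width, method)
  entries <- NULL
  if (j_entries == "candidates") {
    entries <- which(P > alpha1 & upper.tri(P), arr.ind = TRUE)
    colnames(entries) <- NULL
  }
  J <- joint_probability_matrix(P, kernel, entries = entries)
  M <- mask_matrix(P, J, alpha1, alpha2)
  cl <- dbscan_diagonal(M, rho, eps, min_size, kernel = kernel)
  sses <- extract_sses(cl$clusters, binned)
  structure(list(I = I, P = P, J = J, M = M, C = cl$labels,
                 binned = binned, sses = sses, noise = cl$noise,
                 params = list(bin_width = bin_width, kernel = kernel,
                               alpha1 = alpha1, alpha2 = alpha2, rho = rho,
                               eps = eps, min_size = min_size,
                               method = method)),
            class = "sse_result")
}

#' @export
print.sse_result <- function(x, ...) {
  cat(sprintf(paste0("<sse_result> %d x %d bins, %d significant entries, ",
                     "%d SSE(s) found\n"),
              nrow(x$I), ncol(x$I), sum(x$M), length(x$sses)))
  for (s in seq_along(x$sses)) {
    ss <- x$sses[[s]]
    cat(sprintf("  SSE %d: %d events, l_ds = %d, w_ds = %d, bins %d-%d vs %d-%d\n",
                s, nrow(ss$entries), ss$l_ds, ss$w_ds,
                min(ss$entries[, 1]), max(ss$entries[, 1]),
                min(ss$entries[, 2]), max(ss$entries[, 2])))
  }
  invisible(x)
}
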