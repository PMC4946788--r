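# Core domain types: parallel spike trains, bin configuration, binned
# occupancy. All times are in seconds; neuron ids are 1-based integers.

#' Construct a set of parallel spike trains
#'
#' Container for `N` parallel spike trains observed on a common window
#' `[t_start, t_stop)`. Each train is a numeric vector of spike times in
#' seconds; trains are sorted on construction.
#'
#' @param trains list of numeric vectors of spike times (seconds), one per
#'   neuron. Empty vectors are allowed (silent neurons are retained).
#' @param t_start,t_stop observation window in seconds. Every spike time `t`
#'   must satisfy `t_start <= t < t_stop`.
#' @param ids optional integer neuron labels; defaults to `1:N`.
#' @return An object of class `spike_trains`: a list with elements `trains`,
#'   `t_start`, `t_stop`, `ids`.
#' @examples
#' st <- spike_trains(list(c(0.01, 0.4), numeric(0), 0.2), t_stop = 1)
#' n_neurons(st)
#' @export
spike_trains <- function(trains, t_start = 0, t_stop, ids = NULL) {
  if (!is.list(trains) || length(trains) < 1L)
    stop("'trains' must be a non-empty list of numeric vectors")
  if (!is.numeric(t_start) || !is.numeric(t_stop) || t_stop <= t_start)
    stop("need t_stop > t_start")
  trains <- lapply(trains, function(x) sort(as.numeric(x)))
  bad <- vapply(trains, function(x)
    length(x) && (any(!is.finite(x)) || x[1] < t_start || x[length(x)] >= t_stop),
    logical(1))
  if (any(bad))
    stop("spike times outside [t_start, t_stop) or non-finite in train(s): ",
         paste(which(bad), collapse = ", "))
  if (is.null(ids)) ids <- seq_along(trains)
  structure(list(trains = trains, t_start = t_start, t_stop = t_stop,
                 ids = as.integer(ids)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d neurons on [%g, %g) s, %d spikes\n",
              length(x$trains), x$t_start, x$t_stop,
              sum(lengths(x$trains))))
  invisible(x)
}

#' @rdname spike_trains
#' @param x a `spike_trains` object.
#' @export
n_neurons <- function(x) length(x$trains)

#' @rdname spike_trains
#' @export
duration <- function(x) x$t_stop - x$t_start

#' Discretize spike trains into binary bin occupancy
#'
#' Time is partitioned into `B = floor((t_stop - t_start) / bin_width)`
#' adjacent half-open bins `[t_start + (i-1) * bin_width, t_start + i *
#' bin_width)`. Occupancy is binary: a neuron spiking two or more times
#' within one bin is counted once, so that bin contents are sets of neuron
#' ids. A trailing remainder shorter than one bin is dropped with a warning
#' (spikes falling there are discarded from the binned view).
#'
#' @param x a [spike_trains] object.
#' @param bin_width bin width in seconds (`> 0`, at most the window length).
#' @return An object of class `binned_spikes`: a list with `occupancy`
#'   (N x B logical matrix), `bin_width`, `t_start`, `n_bins`, `ids`.
#' @examples
#' st <- spike_trains(list(c(0.001, 0.002)), t_stop = 0.01)
#' b <- bin_spikes(st, 0.005)
#' population_histogram(b)  # 1 0
#' @export
bin_spikes <- function(x, bin_width) {
  stopifnot(inherits(x, "spike_trains"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a positive scalar")
  span <- x$t_stop - x$t_start
  if (bin_width > span) stop("'bin_width' exceeds the observation window")
  B <- floor(span / bin_width + 1e-9)
  if (abs(span - B * bin_width) > 1e-9 * span)
    warning(sprintf("window not a multiple of bin_width; dropping trailing %.3g s",
                    span - B * bin_width))
  N <- length(x$trains)
  occ <- matrix(FALSE, N, B)
  for (k in seq_len(N)) {
    t <- x$trains[[k]]
    if (!length(t)) next
    idx <- floor((t - x$t_start) / bin_width) + 1L
    idx <- idx[idx >= 1L & idx <= B]
    occ[k, unique(idx)] <- TRUE
  }
  structure(list(occupancy = occ, bin_width = bin_width, t_start = x$t_start,
                 n_bins = B, ids = x$ids),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes> %d neurons x %d bins (bin width %g s)\n",
              nrow(x$occupancy), x$n_bins, x$bin_width))
  invisible(x)
}

#' Per-bin population counts and bin membership
#'
#' `population_histogram()` returns the number of active neurons in each
#' bin (the main diagonal of the symmetric intersection matrix);
#' `bin_members()` the set of neuron indices active in one bin.
#'
#' @param b a [bin_spikes] result.
#' @param i bin index (1-based).
#' @export
population_histogram <- function(b) {
  stopifnot(inherits(b, "binned_spikes"))
  colSums(b$occupancy)
}

#' @rdname population_histogram
#' @export
bin_members <- function(b, i) {
  stopifnot(inherits(b, "binned_spikes"))
  which(b$occupancy[, i])
}

#' Read parallel spike trains from a plain-text file
#'
#' Two dialects are supported. `"two_column"`: one spike per line as
#' `"<time_seconds> <neuron_id>"`, `#` starts a comment, ids are 1-based;
#' `n_neurons` declares the number of trains (ids above it are an error),
#' otherwise the maximum id found is used. `"per_neuron_rows"`: line `k`
#' holds the whitespace-separated spike times of neuron `k` (a blank line
#' is a silent neuron).
#'
#' @param path file to read.
#' @param dialect `"two_column"` or `"per_neuron_rows"`.
#' @param t_start,t_stop observation window; spikes outside
#'   `[t_start, t_stop)` raise an error naming the offenders.
#' @param n_neurons optional declared neuron count (two-column dialect);
#'   neurons with no spikes are retained as empty trains.
#' @return A [spike_trains] object.
#' @export
read_spikes <- function(path, dialect = c("two_column", "per_neuron_rows"),
                        t_start = 0, t_stop, n_neurons = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "two_column") {
    raw <- sub("#.*$", "", lines)
    keep <- which(nzchar(trimws(raw)))
    times <- numeric(length(keep)); ids <- integer(length(keep))
    for (m in seq_along(keep)) {
      ln <- keep[m]
      tok <- strsplit(trimws(raw[ln]), "[[:space:]]+")[[1]]
      if (length(tok) != 2L)
        stop(sprintf("parse error at line %d: expected '<time> <id>'", ln))
      tt <- suppressWarnings(as.numeric(tok[1]))
      id <- suppressWarnings(as.integer(tok[2]))
      if (!is.finite(tt) || is.na(id))
        stop(sprintf("parse error at line %d: non-numeric field", ln))
      times[m] <- tt; ids[m] <- id
    }
    N <- if (is.null(n_neurons)) max(ids, 1L) else as.integer(n_neurons)
    if (length(ids) && any(ids < 1L | ids > N))
      stop("neuron id out of range 1..", N)
    out <- any(times < t_start | times >= t_stop)
    if (out)
      stop("spike times outside [t_start, t_stop): ",
           paste(utils::head(times[times < t_start | times >= t_stop], 5),
                 collapse = ", "))
    trains <- split(times, factor(ids, levels = seq_len(N)))
    spike_trains(unname(lapply(trains, as.numeric)), t_start, t_stop)
  } else {
    trains <- vector("list", length(lines))
    for (ln in seq_along(lines)) {
      tok <- strsplit(trimws(sub("#.*$", "", lines[ln])), "[[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      tt <- suppressWarnings(as.numeric(tok))
      if (length(tt) && any(!is.finite(tt)))
        stop(sprintf("parse error at line %d: non-numeric spike time", ln))
      if (length(tt) && any(tt < t_start | tt >= t_stop))
        stop(sprintf("line %d: spike outside [t_start, t_stop)", ln))
      trains[[ln]] <- tt
    }
    if (!is.null(n_neurons)) length(trains) <- n_neurons
    trains <- lapply(trains, function(x) if (is.null(x)) numeric(0) else x)
    spike_trains(trains, t_start, t_stop)
  }
}

#' Write parallel spike trains to a plain-text file
#'
#' Inverse of [read_spikes]; both dialects are emitted.
#'
#' @inheritParams read_spikes
#' @param x a [spike_trains] object.
#' @export
write_spikes <- function(x, path, dialect = c("two_column", "per_neuron_rows")) {
  stopifnot(inherits(x, "spike_trains"))
  dialect <- match.arg(dialect)
  if (dialect == "two_column") {
    tt <- unlist(x$trains, use.names = FALSE)
    id <- rep(seq_along(x$trains), lengths(x$trains))
    o <- order(tt, id)
    writeLines(sprintf("%.9g %d", tt[o], id[o]), path)
  } else {
    writeLines(vapply(x$trains, function(t) paste(sprintf("%.9g", t),
                                                  collapse = " "),
                      character(1)), path)
  }
  invisible(path)
}

#' Read/write an analysis matrix as tab-delimited text
#'
#' Matrices are exported with a one-line `#` header naming the matrix kind
#' and the bin width, then one tab-separated row per matrix row.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @param kind short label (e.g. `"intersection"`, `"probability"`).
#' @param bin_width analysis bin width in seconds (recorded in the header).
#' @export
write_matrix_tsv <- function(m, path, kind = "matrix", bin_width = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# kind=%s bin_width=%g nrow=%d ncol=%d",
                     kind, bin_width, nrow(m), ncol(m)), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(m) <- NULL
  attr(m, "kind") <- sub(".*kind=([^ ]+).*", "\\1", hdr)
  attr(m, "bin_width") <- as.numeric(sub(".*bin_width=([^ ]+).*", "\\1", hdr))
  m
}
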