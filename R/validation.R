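# True/false-positive classification and benchmarking across the
# stochastic background models.

entry_keys <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0) character(0)
  else paste(entries[, 1], entries[, 2], sep = ",")
}

#' Classify a found diagonal structure against the ground truth
#'
#' A found structure is a true positive iff it contains at least 50% of
#' the true entries AND at least 50% of its own entries belong to the
#' truth; otherwise (or whenever the truth is empty) it is a false
#' positive.
#'
#' @param found two-column matrix of found `(i, j)` entries.
#' @param truth two-column matrix of ground-truth entries (may be empty).
#' @return `"TP"` or `"FP"`.
#' @export
classify_detection <- function(found, truth) {
  fk <- entry_keys(found); tk <- entry_keys(truth)
  if (!length(tk) || !length(fk)) return("FP")
  hits <- length(intersect(fk, tk))
  if (hits >= 0.5 * length(tk) && hits >= 0.5 * length(fk)) "TP" else "FP"
}

#' Fraction of true events inside a found structure
#' @inheritParams classify_detection
#' @export
true_event_fraction <- function(found, truth) {
  fk <- entry_keys(found); tk <- entry_keys(truth)
  if (!length(fk)) return(NA_real_)
  length(intersect(fk, tk)) / length(fk)
}

# Rate estimation per the benchmark's rate_source; trials are
# injection-free realizations used only for estimation.
benchmark_rates <- function(rate_source, analyzed, trials, model_id,
                            n_neurons, t_stop, bin_width, kernel_width,
                            psth_bin) {
  switch(rate_source,
    "true" = true_rate_profiles(
      model_rate_profiles(model_id, n_neurons, t_stop, bin_width),
      bin_width),
    "kernel" = kernel_rate(trials, "boxcar", kernel_width, bin_width),
    "psth" = psth_rate(trials, psth_bin, bin_width),
    "kernel-opt" = optimized_kernel_rate(trials, bin_width),
    stop("unknown rate_source: ", rate_source))
}

#' Benchmark the pipeline on a background model
#'
#' Per realization: generate the background, optionally inject the
#' repeated SSE at random positions, estimate rates, run [detect_sses],
#' and classify every found structure with the 50% rules. `rate_source`
#' `"kernel"` (single-train 200 ms boxcar by default) and `"true"` mirror
#' the single-trial protocols; `"psth"` and `"kernel-opt"` estimate from
#' `n_trials` independent injection-free trials, the first of which is
#' the analyzed realization.
#'
#' @param model_id background model 0..9.
#' @param inject logical: inject the SSE of `spec`?
#' @param n_runs number of realizations.
#' @param rate_source `"true"`, `"kernel"`, `"psth"` or `"kernel-opt"`.
#' @param spec an [sse_spec] (used when `inject = TRUE`).
#' @param n_trials trials for multi-trial estimators (default 1).
#' @param n_neurons,t_stop,bin_width study conditions (defaults 100, 1 s,
#'   5 ms).
#' @param kernel_width boxcar width for `rate_source = "kernel"`
#'   (default 0.2 s).
#' @param psth_bin PSTH bin for `rate_source = "psth"` (default 0.01 s).
#' @param seed integer master seed; run `r` uses `seed + r`.
#' @param ... further arguments passed to [detect_sses].
#' @return An object of class `benchmark_result`: list with `runs` (data
#'   frame of per-run TP/FP/disjoint-FP counts and true-event fractions)
#'   and aggregate `tp_rate`, `fp_rate`, `fp_disjoint_rate`,
#'   `tp_event_fraction`, `sd_tp`, `sd_fp`.
#' @export
benchmark_model <- function(model_id, inject, n_runs = 20,
                            rate_source = "kernel", spec = sse_spec(),
                            n_trials = 1, n_neurons = 100, t_stop = 1,
                            bin_width = 0.005, kernel_width = 0.2,
                            psth_bin = 0.01, seed = 1, ...) {
  runs <- data.frame(run = seq_len(n_runs), tp = 0L, fp = 0L,
                     fp_disjoint = 0L, tp_event_fraction = NA_real_)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    trials <- lapply(seq_len(max(1L, n_trials)), function(s)
      generate_model(model_id, n_neurons, t_stop, bin_width))
    analyzed <- trials[[1]]
    truth <- NULL
    if (inject) {
      analyzed <- inject_sse(analyzed, spec, bin_width)
      truth <- attr(analyzed, "truth")$entries
    }
    est_input <- if (rate_source %in% c("psth", "kernel-opt")) trials
      else list(analyzed)
    rates <- benchmark_rates(rate_source, analyzed, est_input, model_id,
                             n_neurons, t_stop, bin_width, kernel_width,
                             psth_bin)
    res <- detect_sses(analyzed, rates, bin_width,
                       j_entries = "candidates", ...)
    cls <- vapply(res$sses, function(s)
      classify_detection(s$entries, truth), character(1))
    runs$tp[r] <- sum(cls == "TP")
    runs$fp[r] <- sum(cls == "FP")
    if (length(res$sses)) {
      fr <- vapply(res$sses, function(s)
        true_event_fraction(s$entries, truth), numeric(1))
      runs$tp_event_fraction[r] <- mean(fr, na.rm = TRUE)
      runs$fp_disjoint[r] <- sum(cls == "FP" & fr == 0)
    }
  }
  structure(list(runs = runs,
                 tp_rate = mean(runs$tp), fp_rate = mean(runs$fp),
                 fp_disjoint_rate = mean(runs$fp_disjoint),
                 tp_event_fraction = mean(runs$tp_event_fraction,
                                          na.rm = TRUE),
                 sd_tp = stats::sd(runs$tp), sd_fp = stats::sd(runs$fp),
                 model_id = model_id, inject = inject,
                 rate_source = rate_source, n_runs = n_runs),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(paste0("<benchmark> model %d%s, %d runs, rates '%s': ",
                     "TP rate %.2f (sd %.2f), FP rate %.2f (sd %.2f)\n"),
              x$model_id, if (x$inject) " + SSE" else "", x$n_runs,
              x$rate_source, x$tp_rate, x$sd_tp, x$fp_rate, x$sd_fp))
  invisible(x)
}

#' Performance sweep over N, SSE length and event size
#'
#' Full-factorial benchmark on the model-0 background with an injected
#' SSE, varying the total neuron count and the injected SSE's number of
#' events and neurons per event.
#'
#' @param n_neurons_list,l_sse_list,xi_sse_list factor levels.
#' @param n_runs realizations per cell.
#' @param seed master seed.
#' @param ... passed to [benchmark_model].
#' @return Data frame with one row per cell: factors plus `tp_rate`,
#'   `fp_rate`, `fp_disjoint_rate`, `tp_event_fraction`.
#' @export
sweep_performance <- function(n_neurons_list = c(50, 100),
                              l_sse_list = 3:7, xi_sse_list = 2:5,
                              n_runs = 20, seed = 1, ...) {
  cells <- expand.grid(n_neurons = n_neurons_list, l_sse = l_sse_list,
                       xi_sse = xi_sse_list)
  out <- lapply(seq_len(nrow(cells)), function(cc) {
    b <- benchmark_model(0, inject = TRUE, n_runs = n_runs,
                         spec = sse_spec(cells$l_sse[cc], cells$xi_sse[cc]),
                         n_neurons = cells$n_neurons[cc],
                         seed = seed + 1000 * cc, ...)
    cbind(cells[cc, ], tp_rate = b$tp_rate, fp_rate = b$fp_rate,
          fp_disjoint_rate = b$fp_disjoint_rate,
          tp_event_fraction = b$tp_event_fraction)
  })
  do.call(rbind, out)
}

#' Trial-count study of the rate estimators
#'
#' For each estimator and trial count `R`, rates are estimated from `R`
#' simulated trials (the first being the analyzed realization, before
#' injection) and the pipeline runs on the analyzed realization with the
#' injected SSE.
#'
#' @param model_id background model (default 4: coherent rate jump with
#'   regular intervals, the worst case for rate estimation).
#' @param estimators subset of `c("psth", "kernel", "kernel-opt")`.
#' @param trial_counts trial counts to test.
#' @param n_runs realizations per condition.
#' @param seed master seed.
#' @param ... passed to [benchmark_model].
#' @return Data frame: estimator, trials, tp_rate, fp_rate.
#' @export
trial_count_study <- function(model_id = 4,
                              estimators = c("psth", "kernel",
                                             "kernel-opt"),
                              trial_counts = c(1, 3, 10), n_runs = 20,
                              seed = 1, ...) {
  grid <- expand.grid(estimator = estimators, trials = trial_counts,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(gg) {
    b <- benchmark_model(model_id, inject = TRUE, n_runs = n_runs,
                         rate_source = grid$estimator[gg],
                         n_trials = grid$trials[gg],
                         seed = seed + 1000 * gg, ...)
    data.frame(estimator = grid$estimator[gg], trials = grid$trials[gg],
               tp_rate = b$tp_rate, fp_rate = b$fp_rate)
  })
  do.call(rbind, out)
}
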