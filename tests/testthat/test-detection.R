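test_that("mask requires both thresholds and respects the symmetric region", {
  P <- matrix(0, 10, 10); J <- matrix(0, 10, 10)
  attr(P, "mode") <- "symmetric"
  P[2, 8] <- 0.999; J[2, 8] <- 0.9999999
  P[3, 9] <- 0.999; J[3, 9] <- 0.5       # isolated large entry rejected
  P[8, 2] <- 0.999; J[8, 2] <- 0.9999999 # lower triangle forced off
  M <- mask_matrix(P, J)
  expect_equal(which(M == 1), which(row(M) == 2 & col(M) == 8))
  expect_true(all(mask_matrix(matrix(0, 5, 5), matrix(1, 5, 5)) == 0))
  expect_error(mask_matrix(P, J[1:5, 1:5]), "shape")
  expect_error(mask_matrix(P, J, alpha1 = 0.9999, alpha2 = 0.99), "alpha1")
})

test_that("raising either threshold never adds mask entries", {
  set.seed(51)
  P <- matrix(runif(400), 20, 20); J <- matrix(runif(400), 20, 20)
  attr(P, "mode") <- "cross"
  M0 <- mask_matrix(P, J, 0.5, 0.7)
  expect_true(all(mask_matrix(P, J, 0.6, 0.7) <= M0))
  expect_true(all(mask_matrix(P, J, 0.5, 0.8) <= M0))
})

test_that("elliptical distance reproduces the closed-form examples", {
  expect_equal(elliptical_distance(c(0, 0), c(3, 3), 5), 3)
  expect_equal(elliptical_distance(c(0, 0), c(3, 3), 1.5), 3)
  expect_equal(elliptical_distance(c(0, 0), c(1, -1), 5), 5)
  expect_equal(elliptical_distance(c(0, 0), c(2, -2), 5), 10)
  expect_equal(elliptical_distance(c(2, 7), c(2, 7), 5), 0)
  expect_equal(elliptical_distance(c(0, 0), c(0, 2), 5),
               (1 + sqrt(2) / 2 * 4) * 2)
  # symmetry
  expect_equal(elliptical_distance(c(1, 5), c(4, 9), 5),
               elliptical_distance(c(4, 9), c(1, 5), 5))
  expect_error(elliptical_distance(c(0, 0), c(1, 1), 0.5), "rho")
})

test_that("diagonal runs cluster, isolated entries are noise, distant runs split", {
  M <- matrix(0L, 30, 30)
  M[cbind(5:7, 10:12)] <- 1L            # three consecutive diagonal steps
  M[20, 3] <- 1L                        # isolated entry
  M[cbind(15:17, 25:27)] <- 1L          # far-away second run
  cl <- dbscan_diagonal(M)
  expect_length(cl$clusters, 2)
  expect_equal(nrow(cl$noise), 1)
  expect_equal(unname(cl$noise[1, ]), c(20, 3))
  sizes <- sort(vapply(cl$clusters, nrow, integer(1)))
  expect_equal(sizes, c(3L, 3L))
})

test_that("up to floor(eps) - 1 holes are bridged along a diagonal, more are not", {
  # entries at diagonal positions 0, 3, 6: gaps of 2 holes (distance 3)
  M <- matrix(0L, 40, 40)
  M[cbind(c(5, 8, 11), c(15, 18, 21))] <- 1L
  cl <- dbscan_diagonal(M)
  expect_length(cl$clusters, 1)
  expect_equal(nrow(cl$clusters[[1]]), 3)
  # gaps of 3 holes (distance 4) break the chain
  M2 <- matrix(0L, 40, 40)
  M2[cbind(c(5, 9, 13), c(15, 19, 23))] <- 1L
  cl2 <- dbscan_diagonal(M2)
  expect_length(cl2$clusters, 0)
  expect_equal(nrow(cl2$noise), 3)
})

test_that("an eps-ellipse wider than the kernel triggers the containment warning", {
  M <- matrix(0L, 10, 10)
  expect_warning(dbscan_diagonal(M, rho = 5, eps = 6.5,
                                 kernel = kernel_spec()), "contained")
  expect_silent(dbscan_diagonal(M, kernel = kernel_spec()))
})

test_that("extracted SSEs recover the injected neuron groups exactly on silence", {
  spec <- sse_spec()
  silent <- spike_trains(rep(list(numeric(0)), 100), t_stop = 1)
  st <- inject_sse(silent, spec, 0.005, start_bins = c(10, 120))
  binned <- bin_spikes(st, 0.005)
  tr <- attr(st, "truth")
  sses <- extract_sses(list(tr$entries), binned)
  expect_length(sses, 1)
  expect_length(sses[[1]]$events, 7)
  for (e in 1:7)
    expect_equal(sses[[1]]$events[[e]]$neurons, spec$groups[[e]])
  expect_equal(sses[[1]]$l_ds, 7L)
  expect_equal(sses[[1]]$w_ds, 1L)
  expect_length(extract_sses(list(), binned), 0)
})

test_that("the pipeline finds an injected SSE and stays silent without one", {
  st <- inject_sse(generate_model(0, seed = 52), sse_spec(), 0.005,
                   seed = 53)
  truth <- attr(st, "truth")$entries
  rates <- kernel_rate(st, "boxcar", 0.2, 0.005)
  res <- detect_sses(st, rates, 0.005)
  expect_length(res$sses, 1)
  expect_equal(classify_detection(res$sses[[1]]$entries, truth), "TP")
  # events contain their injected groups
  spec <- sse_spec()
  found <- res$sses[[1]]$entries
  for (r in seq_len(nrow(found))) {
    e <- match(found[r, 1], truth[, 1])
    if (!is.na(e))
      expect_true(all(spec$groups[[e]] %in% res$sses[[1]]$events[[r]]$neurons))
  }
  # silence in, silence out
  quiet <- spike_trains(rep(list(numeric(0)), 20), t_stop = 1)
  res0 <- detect_sses(quiet, true_rate_profiles(matrix(0, 20, 200), 0.005),
                      0.005)
  expect_length(res0$sses, 0)
  expect_true(all(res0$M == 0))
})

test_that("candidate-mode J gives identical detections to the full evaluation", {
  st <- inject_sse(generate_model(2, seed = 54), sse_spec(), 0.005,
                   seed = 55)
  rates <- kernel_rate(st, "boxcar", 0.2, 0.005)
  full <- detect_sses(st, rates, 0.005, j_entries = "all")
  part <- detect_sses(st, rates, 0.005, j_entries = "candidates")
  expect_identical(full$M, part$M)
  expect_identical(full$C, part$C)
  expect_equal(lapply(full$sses, `[[`, "entries"),
               lapply(part$sses, `[[`, "entries"))
})

test_that("the full pipeline is deterministic given a seed", {
  run <- function() {
    st <- inject_sse(generate_model(7, seed = 56), sse_spec(), 0.005,
                     seed = 57)
    detect_sses(st, kernel_rate(st, "boxcar", 0.2, 0.005), 0.005,
                j_entries = "candidates")
  }
  a <- run(); b <- run()
  expect_identical(a$M, b$M)
  expect_equal(a$sses, b$sses)
})
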