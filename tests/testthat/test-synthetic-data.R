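# The generators define the study conditions; these tests pin their
# marginal statistics against closed-form or counting oracles.

test_that("generators are seed-reproducible", {
  for (m in c(0, 3, 6, 7, 8)) {
    a <- generate_model(m, seed = 42)
    b <- generate_model(m, seed = 42)
    expect_identical(a$trains, b$trains, label = paste("model", m))
  }
})

test_that("poisson process matches its rate profile in mean and is empty at rate 0", {
  expect_length(poisson_process(0, 1, seed = 1), 0)
  set.seed(2)
  counts <- replicate(400, length(poisson_process(15, 1)))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 400))
  # model-1 profile averages 15 Hz over the second
  prof <- rate_profile(c(0, 0.6, 0.7, 1), c(10, 60, 10))
  counts <- replicate(400, length(poisson_process(prof, 1)))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 400))
  expect_error(rate_profile(c(0, 1), -1), "non-negative")
})

test_that("gamma renewal has the stated mean ISI and CV, and shape 1 is Poisson", {
  set.seed(3)
  long <- gamma_renewal(5, 1 / 15, 100)
  isi <- diff(long)
  expect_lt(abs(mean(isi) - 1 / 15), 3 * sd(isi) / sqrt(length(isi)))
  expect_lt(abs(sd(isi) / mean(isi) - 1 / sqrt(5)), 0.03)
  # equilibrium start: rate correct from t = 0 (first decile of the window)
  expect_lt(abs(sum(long < 10) / 10 - 15), 3 * sqrt(15 / 10))
  pois <- gamma_renewal(1, 1 / 15, 100, seed = 4)
  isi <- diff(pois)
  expect_lt(abs(sd(isi) / mean(isi) - 1), 0.05)
})

test_that("compound poisson matches marginal rates and the size-5 event rate", {
  expect_error(compound_poisson(3, c("5" = 1), 10, 1), "exceeds N")
  set.seed(5)
  st <- compound_poisson(100, c("1" = 0.938, "5" = 0.062), 15, 40)
  rate <- mean(lengths(st$trains)) / 40
  expect_lt(abs(rate - 15), 0.5)
  # count synchronous size-5 events: spike times shared by exactly 5 trains
  tt <- table(unlist(st$trains))
  lam_m <- 100 * 15 / (0.938 + 5 * 0.062)
  expected5 <- lam_m * 0.062 * 40
  expect_lt(abs(sum(tt == 5) - expected5), 4 * sqrt(expected5))
  # degenerate amplitude = independent Poisson
  st1 <- compound_poisson(20, c("1" = 1), 15, 20, seed = 6)
  expect_lt(abs(mean(lengths(st1$trains)) / 20 - 15), 1)
})

test_that("multiple SIP embeds full-group synchronous bins and keeps 15 Hz totals", {
  st <- multiple_sip(seed = 7)
  b <- bin_spikes(st, 0.005)
  first_gid <- 100 - 35 + 1
  for (g in 1:7) {
    members <- first_gid + (g - 1) * 5 + 0:4
    # the two event bins contain the whole group
    joint <- colSums(b$occupancy[members, ]) == 5
    expect_gte(sum(joint), 2)
  }
  set.seed(8)
  rates <- rowMeans(replicate(40, lengths(multiple_sip()$trains)))
  expect_lt(abs(mean(rates) - 15), 0.5)
  st0 <- multiple_sip(events_per_group = 0, seed = 9)
  expect_lt(max(population_histogram(bin_spikes(st0, 0.005))), 30)
  expect_error(multiple_sip(n_neurons = 10, n_groups = 7), "exceed")
})

test_that("rate-jump propagation has the analytic per-bin firing probabilities", {
  # closed form: 1 - exp(-lambda * delta)
  expect_equal(round(1 - exp(-100 * 0.005), 2), 0.39)
  expect_lt(abs((1 - exp(-14 * 0.005)) - 0.067), 1e-3)
  set.seed(10)
  occ_jump <- occ_base <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    b <- bin_spikes(rate_jump_propagation(), 0.005)
    # group l jumps in bins 11 + (l-1) and 101 + (l-1)
    jump_occ <- vapply(1:20, function(l)
      mean(b$occupancy[(l - 1) * 5 + 1:5, c(10 + l, 100 + l)]), numeric(1))
    occ_jump <- occ_jump + mean(jump_occ)
    occ_base <- occ_base + mean(b$occupancy[1:5, 30:90])
  }
  expect_lt(abs(occ_jump / reps - 0.39), 0.02)
  expect_lt(abs(occ_base / reps - 0.067), 0.005)
})

test_that("model dispatch reproduces the printed marginal rates", {
  set.seed(11)
  r0 <- mean(replicate(20, mean(lengths(generate_model(0)$trains))))
  expect_lt(abs(r0 - 15), 0.5)
  r2 <- mean(replicate(20, length(generate_model(2)$trains[[100]])))
  expect_lt(abs(r2 - 25), 3 * sqrt(25 / 20))
  r9 <- mean(replicate(20, mean(lengths(generate_model(9)$trains))))
  expect_lt(abs(r9 - 15), 0.5)
  expect_error(generate_model(12), "unknown model")
})

test_that("model rate profiles integrate to the model's expected counts", {
  for (m in 0:9) {
    lam <- model_rate_profiles(m)
    expect_true(all(lam >= 0))
    expect_equal(dim(lam), c(100, 200))
  }
  expect_equal(mean(model_rate_profiles(0)), 15)
  expect_equal(round(mean(model_rate_profiles(1)) , 1), 15)
  expect_equal(round(mean(model_rate_profiles(6)), 2),
               14 + (100 - 14) * (40 / (200 * 20)))
})

test_that("injected SSEs are recoverable from the ground-truth entries", {
  spec <- sse_spec()
  silent <- spike_trains(rep(list(numeric(0)), 100), t_stop = 1)
  out <- inject_sse(silent, spec, 0.005, seed = 12)
  tr <- attr(out, "truth")
  b <- bin_spikes(out, 0.005)
  for (e in 1:7) {
    expect_equal(bin_members(b, tr$entries[e, 1]), spec$groups[[e]])
    expect_equal(bin_members(b, tr$entries[e, 2]), spec$groups[[e]])
  }
  # one off-diagonal, w_ds = 1
  expect_equal(ds_geometry(tr$entries)$w_ds, 1L)
  # on a live background the recovered sets contain the groups
  bg <- inject_sse(generate_model(0, seed = 13), spec, 0.005, seed = 14)
  tb <- attr(bg, "truth")
  bb <- bin_spikes(bg, 0.005)
  for (e in 1:7)
    expect_true(all(spec$groups[[e]] %in%
                      bin_members(bb, tb$entries[e, 1])))
})

test_that("holes shift later events and raise the wiggliness to 2", {
  spec <- sse_spec(holes = 2L)
  silent <- spike_trains(rep(list(numeric(0)), 100), t_stop = 1)
  out <- inject_sse(silent, spec, 0.005, start_bins = c(20, 100))
  tr <- attr(out, "truth")
  expect_equal(tr$entries[, 1], c(20, 21, 23, 24, 25, 26, 27))
  expect_equal(tr$entries[, 2], 100:106)
  expect_equal(ds_geometry(tr$entries)$w_ds, 2L)
})

test_that("single-spike events give a spatio-temporal pattern without synchrony", {
  spec <- sse_spec(n_events = 7, event_size = 1)
  silent <- spike_trains(rep(list(numeric(0)), 10), t_stop = 1)
  out <- inject_sse(silent, spec, 0.005, start_bins = c(10, 60))
  expect_equal(max(population_histogram(bin_spikes(out, 0.005))), 1)
})
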