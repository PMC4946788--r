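test_that("intersection matrix equals brute-force set intersections", {
  b <- bin_spikes(toy_spikes(), 0.01)
  I <- intersection_matrix(b)
  expect_equal(diag(I), population_histogram(b), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(I)))
  set.seed(31)
  st <- spike_trains(lapply(1:12, function(k) sort(runif(15))), t_stop = 1)
  b <- bin_spikes(st, 0.02)
  I <- intersection_matrix(b)
  for (pair in list(c(1, 2), c(3, 40), c(17, 17)))
    expect_equal(I[pair[1], pair[2]],
                 brute_intersection(b$occupancy, pair[1], pair[2]))
  expect_true(all(I <= outer(population_histogram(b),
                             population_histogram(b), pmin)))
  # an empty bin zeroes its row and column
  empty <- which(population_histogram(b) == 0)[1]
  if (!is.na(empty)) expect_true(all(I[empty, ] == 0))
})

test_that("pair probability follows the no-silence product formula", {
  expect_equal(pair_probability(100, 100, 0.005), (1 - exp(-0.5))^2)
  expect_equal(round(1 - exp(-100 * 0.005), 2), 0.39)
  expect_equal(pair_probability(0, 50, 0.005), 0)
  expect_equal(pair_probability(1e9, 1e9, 0.005), 1, tolerance = 1e-12)
  expect_error(pair_probability(-1, 5, 0.005), "non-negative")
})

test_that("poisson-binomial pmf matches subset enumeration, binomial and sums to 1", {
  expect_equal(poisson_binomial_pmf(0.5), c(0.5, 0.5))
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(poisson_binomial_pmf(rep(0.01, 100)),
               dbinom(0:100, 100, 0.01), tolerance = 1e-12)
  set.seed(32)
  for (rep in 1:4) {
    p <- runif(sample(3:11, 1))
    pmf <- poisson_binomial_pmf(p)
    expect_equal(pmf, subset_pmf(p), tolerance = 1e-12)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("le cam pmf is the poisson law and obeys the total-variation bound", {
  expect_equal(lecam_pmf(1, 0), exp(-1))
  expect_equal(lecam_pmf(0, 0:3), c(1, 0, 0, 0))
  set.seed(33)
  for (rep in 1:5) {
    p <- runif(40, 0, 0.2)
    exact <- poisson_binomial_pmf(p)
    approx <- lecam_pmf(sum(p), 0:40)
    tv <- 0.5 * (sum(abs(exact - approx)) +
                   stats::ppois(40, sum(p), lower.tail = FALSE))
    expect_lte(tv, sum(p^2))
  }
})

test_that("probability matrix uses the strict cdf and matches subset enumeration", {
  set.seed(34)
  st <- spike_trains(lapply(1:5, function(k) sort(runif(4, 0, 0.1))),
                     t_stop = 0.1)
  b <- bin_spikes(st, 0.02)
  I <- intersection_matrix(b)
  lam <- matrix(runif(5 * 5, 5, 60), 5, 5)
  rates <- true_rate_profiles(lam, 0.02)
  P <- probability_matrix(I, rates, 0.02, method = "exact")
  a <- 1 - exp(-lam * 0.02)
  for (i in 1:4) for (j in (i + 1):5) {
    pmf <- subset_pmf(a[, i] * a[, j])
    want <- if (I[i, j] == 0) 0 else sum(pmf[seq_len(I[i, j])])
    expect_equal(P[i, j], want, tolerance = 1e-12)
  }
  expect_true(all(P[I == 0] == 0))
  expect_true(all(P >= 0 & P < 1))
  # I = N: P = 1 - pmf(N) < 1
  full <- spike_trains(list(c(0.01, 0.03), c(0.011, 0.031)), t_stop = 0.04)
  bf <- bin_spikes(full, 0.02)
  If <- intersection_matrix(bf)
  Pf <- probability_matrix(If, true_rate_profiles(matrix(50, 2, 2), 0.02),
                           0.02, "exact")
  pmf <- poisson_binomial_pmf((1 - exp(-50 * 0.02))^2 * c(1, 1))
  expect_equal(Pf[1, 2], 1 - pmf[3], tolerance = 1e-12)
})

test_that("auto method selects exact for small N and lecam for large N", {
  set.seed(35)
  st <- spike_trains(lapply(1:5, function(k) sort(runif(3))), t_stop = 1)
  b <- bin_spikes(st, 0.1)
  I <- intersection_matrix(b)
  r <- true_rate_profiles(matrix(10, 5, 10), 0.1)
  expect_equal(attr(probability_matrix(I, r, 0.1), "method"), "exact")
  stL <- spike_trains(lapply(1:40, function(k) sort(runif(3))), t_stop = 1)
  bL <- bin_spikes(stL, 0.1)
  expect_equal(attr(probability_matrix(intersection_matrix(bL),
                                       true_rate_profiles(matrix(10, 40, 10),
                                                          0.1), 0.1),
                    "method"), "lecam")
})

test_that("1 - P is conservative under the independent-poisson null with true rates", {
  set.seed(36)
  exceed <- matrix(0, 3, 0)
  ys <- c(0.01, 0.05, 0.2)
  reps <- 12
  tot <- 0
  for (r in seq_len(reps)) {
    st <- generate_model(0, n_neurons = 50, t_stop = 0.5)
    b <- bin_spikes(st, 0.005)
    P <- probability_matrix(intersection_matrix(b),
                            true_rate_profiles(matrix(15, 50, 100), 0.005),
                            0.005, "lecam")
    pv <- 1 - P[upper.tri(P)]
    exceed <- cbind(exceed, vapply(ys, function(y) sum(pv <= y), numeric(1)))
    tot <- tot + length(pv)
  }
  for (k in seq_along(ys)) {
    frac <- sum(exceed[k, ]) / tot
    # conservativeness: attained level at most nominal plus binomial noise
    expect_lte(frac, ys[k] + 3 * sqrt(ys[k] / tot) + 0.002)
  }
})
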