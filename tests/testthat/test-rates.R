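test_that("transfer kernel has the calibrated exponential decay", {
  expect_equal(transfer_prob(0), 0.01)
  expect_equal(transfer_prob(50) / transfer_prob(500), 6)
  flat <- transfer_params(lambda_transfer = 0)
  expect_equal(transfer_prob(c(0, 100, 4000), flat), rep(0.01, 3))
  d <- seq(0, 4000, by = 50)
  expect_true(all(diff(transfer_prob(d)) <= 0))
  expect_error(transfer_prob(-1))
})

test_that("fitness shapes are normalized, positive and non-increasing", {
  expect_equal(fitness(0), 1)  # exponential at zero distance
  neutral <- fitness_params(lambda_fitness = 0)
  expect_equal(fitness(c(0, 500, 4000), neutral), rep(1, 3))
  sig <- fitness_params("sigmoidal")
  expect_gt(fitness(5, sig) / fitness(20, sig), 10)  # steep drop 5 -> 20 kb
  d <- seq(0, 1200, by = 10)
  for (p in list(fitness_params(lambda_fitness = 0.002), sig)) {
    w <- fitness(d, p)
    expect_true(all(diff(w) <= 0))
    expect_true(all(w > 0))
    expect_true(all(w <= 1))
  }
})

test_that("selection coefficients follow the ratio-minus-one convention", {
  p <- fitness_params(lambda_fitness = 0.001)
  expect_equal(selection_coefficient(700, 700, p), 0)
  expect_equal(selection_coefficient(1000, 500, p), exp(0.5) - 1)
  expect_lt(selection_coefficient(500, 1000, p), 0)
  expect_gt(selection_coefficient(500, 1000, p), -1)
  # stays finite and accurate where raw fitness underflows
  sig <- fitness_params("sigmoidal")
  expect_equal(selection_coefficient(1900, 1902, sig), expm1(-1), tolerance = 1e-6)
})

test_that("fixation probability matches the diffusion formula and limits", {
  expect_equal(fixation_probability(0, 1000), 1e-3)
  expect_equal(fixation_probability(0.01, 1000),
               (1 - exp(-0.02)) / (1 - exp(-20)), tolerance = 1e-12)
  expect_equal(fixation_probability(50, 1000), 1, tolerance = 1e-10)
  expect_lt(fixation_probability(-0.05, 1000), 1e-20)
  # continuity at s = 0: numeric limits agree with 1/N to 1e-10 relative
  # (pi deviates from 1/N by ~Ns to first order, so probe at s << 1/N)
  for (N in c(10, 1000, 1e6)) {
    expect_equal(fixation_probability(1e-12 / N, N) * N, 1, tolerance = 1e-10)
    expect_equal(fixation_probability(-1e-12 / N, N) * N, 1, tolerance = 1e-10)
  }
  s <- c(-0.1, -0.01, 0, 0.01, 0.1, 1)
  expect_true(all(diff(fixation_probability(s, 200)) > 0))
  # overflow-safe far in the deleterious tail
  expect_equal(fixation_probability(-0.5, 1e4), 0)
  expect_error(fixation_probability(-1.5, 100))
})

test_that("diffusion fixation probability agrees with the exact Moran
           birth-death chain under weak selection", {
  # the diffusion (Wright-Fisher variance) and Moran offspring-number
  # variance differ, so agreement is a weak-selection property: compare on
  # |2Ns| <= 0.4 where both reduce to the near-neutral limit
  set.seed(29)
  pairs <- expand.grid(N = c(20, 50, 100, 150, 200),
                       Ns = c(-0.15, -0.05, 0.05, 0.15))
  for (k in seq_len(nrow(pairs))) {
    N <- pairs$N[k]; s <- pairs$Ns[k] / N
    exact <- moran_absorption(1 + s, 1, N)
    expect_equal(fixation_probability(s, N), exact, tolerance = 0.1)
  }
})

test_that("conditional fixation time has the neutral limit, monotonicity,
           and matches a Wright-Fisher simulation", {
  # neutral limit ~ 4 Ne = 2N generations
  expect_equal(fixation_time(0, 100), 200, tolerance = 0.01)
  expect_equal(fixation_time(1e-13, 100), fixation_time(0, 100),
               tolerance = 1e-6)
  # stronger selection fixes faster
  expect_lt(fixation_time(0.1, 500), fixation_time(0.01, 500))
  # even in s (Maruyama-Kimura symmetry)
  expect_equal(fixation_time(-0.05, 50), fixation_time(0.05, 50))
  # brute-force haploid Wright-Fisher oracle, >= 2000 conditional fixations
  set.seed(31)
  times <- wf_fixation_times(N = 50, s = 0.05, n_fix = 2000)
  se <- sd(times) / sqrt(length(times))
  expect_lt(abs(fixation_time(0.05, 50) - mean(times)), 3 * se)
})

test_that("waiting times are geometric with parameter 1-(1-rho)^N", {
  set.seed(37)
  w <- waiting_time(1e-8, 1e4, n = 10000)
  expect_true(all(w >= 1))
  expect_equal(mean(w), 1e4, tolerance = 0.04)  # mean 1/p, p ~ N*rho = 1e-4
  expect_equal(waiting_time(1, 50, n = 5), rep(1, 5))
  expect_error(waiting_time(0, 100), "zero")
  set.seed(41); a <- waiting_time(1e-3, 100, n = 20)
  set.seed(41); b <- waiting_time(1e-3, 100, n = 20)
  expect_identical(a, b)
})

test_that("popgen parameters apply the haploid effective-size mapping", {
  pg <- popgen_params(1000)
  expect_equal(pg$effective_size, 500)
  expect_error(popgen_params(1))
})
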