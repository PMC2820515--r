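two_class_population <- function(n_a, n_b, arr_a, arr_b, params) {
  moran_population(c(rep(list(arr_a), n_a), rep(list(arr_b), n_b)), params)
}

test_that("with no inversions an identical population is invariant and the
           set of distinct genomes never grows", {
  set.seed(79)
  params <- moran_params(pop_size = 12, rho = 0, n_generations = 5)
  popn <- moran_population(random_arrangement(params$genome), params)
  out <- popn
  for (t in 1:60) out <- moran_step(out, params)
  expect_identical(out$positions, popn$positions)
  # two classes: copying can only reduce the number of distinct genomes
  cfg <- genome_config(200, 3)
  p2 <- moran_params(pop_size = 10, rho = 0, genome = cfg)
  popn <- two_class_population(5, 5, arrangement(c(1, 5, 9), cfg),
                               arrangement(c(1, 50, 100), cfg), p2)
  for (t in 1:200) {
    popn <- moran_step(popn, p2)
    n_distinct <- nrow(unique(t(popn$positions)))
    expect_lte(n_distinct, 2)
  }
})

test_that("population size is invariant and the fitness cache stays in sync
           with the genomes", {
  set.seed(83)
  params <- moran_params(pop_size = 25, rho = 0.3,
                         fitness = fitness_params(lambda_fitness = 0.002),
                         genome = genome_config(500, 4))
  popn <- moran_population(random_arrangement(params$genome), params)
  for (t in 1:300) popn <- moran_step(popn, params)
  expect_equal(ncol(popn$positions), 25)
  d <- apply(popn$positions, 2, function(p)
    min_arc_distance(arrangement(p, params$genome)))
  expect_equal(popn$dist, d)
  expect_equal(popn$log_fit, log(fitness(d, params$fitness)))
})

test_that("neutral fixation probability equals the initial frequency", {
  set.seed(89)
  cfg <- genome_config(200, 3)
  params <- moran_params(pop_size = 20, rho = 0,
                         fitness = fitness_params(lambda_fitness = 0),
                         genome = cfg)
  arr_a <- arrangement(c(1, 5, 9), cfg)
  arr_b <- arrangement(c(1, 50, 100), cfg)
  wins <- vapply(1:2000, function(r) {
    popn <- two_class_population(10, 10, arr_a, arr_b, params)
    moran_fix_class(popn, params, arr_a$positions)
  }, logical(1))
  p_hat <- mean(wins)
  expect_lt(abs(p_hat - 0.5), 3.5 * sqrt(0.25 / 2000))
})

test_that("selective fixation matches the exact Moran birth-death formula", {
  set.seed(97)
  cfg <- genome_config(100, 2)
  lam <- 0.02
  params <- moran_params(pop_size = 20, rho = 0,
                         fitness = fitness_params(lambda_fitness = lam),
                         genome = cfg)
  arr_a <- arrangement(c(10, 20), cfg)  # d = 10
  arr_b <- arrangement(c(10, 40), cfg)  # d = 30
  r <- fitness(10, params$fitness) / fitness(30, params$fitness)  # e^0.4
  expected <- moran_absorption(r, 1, 20)
  wins <- vapply(1:2000, function(rep) {
    popn <- two_class_population(1, 19, arr_a, arr_b, params)
    moran_fix_class(popn, params, arr_a$positions)
  }, logical(1))
  p_hat <- mean(wins)
  expect_lt(abs(p_hat - expected),
            3.5 * sqrt(expected * (1 - expected) / 2000))
})

test_that("a zero-generation run records only the initial distance", {
  tr <- run_moran(moran_params(pop_size = 10, n_generations = 0), seed = 3)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$generation, 0)
})

test_that("neutral trajectories are flat in expectation", {
  # uniform initial arrangement + measure-preserving inversions + neutral
  # drift: E[mean distance] is constant over time
  set.seed(101)
  params <- moran_params(pop_size = 20, rho = 0.1,
                         fitness = fitness_params(lambda_fitness = 0),
                         n_generations = 30)
  trajs <- vapply(1:50, function(r)
    run_moran(params, seed = 3000 + r)$mean_min_arc_kb,
    numeric(31))
  # per-replicate net change is iid with mean zero under neutrality
  # (within-replicate time points are autocorrelated, so the martingale is
  # tested on the independent end-minus-start differences)
  delta <- trajs[31, ] - trajs[1, ]
  expect_gt(t.test(delta, mu = 0)$p.value, 0.01)
  # and per-replicate least-squares slopes are centred at zero
  slopes <- apply(trajs, 2, function(y) coef(lm(y ~ I(0:30)))[2])
  expect_gt(t.test(slopes, mu = 0)$p.value, 0.01)
})

test_that("strong selection drives clustering through selective sweeps under
           both fitness shapes", {
  set.seed(103)
  for (shape in c("exponential", "sigmoidal")) {
    fp <- if (shape == "exponential")
      fitness_params(lambda_fitness = 0.01) else fitness_params("sigmoidal")
    params <- moran_params(pop_size = 40, rho = 0.05, fitness = fp,
                           n_generations = 120)
    finals <- vapply(1:8, function(r) {
      tr <- run_moran(params, seed = 4000 + r)
      tail(tr$mean_min_arc_kb, 1) / tr$mean_min_arc_kb[1]
    }, numeric(1))
    # distance shrinks in the clear majority of runs
    expect_gte(sum(finals < 0.8), 6)
    expect_lt(median(finals), 0.6)
  }
})
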