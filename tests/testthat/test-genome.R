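test_that("minimum arc distance matches hand examples and conventions", {
  expect_equal(min_arc_distance(arrangement(c(10, 30), genome_config(100, 2))),
               20)
  # circular gaps of {1,2,3,11} on L=20 are 1,1,8,10; arc = 20 - 10
  expect_equal(min_arc_distance(arrangement(c(1, 2, 3, 11),
                                            genome_config(20, 4))), 10)
  # equally spaced genes attain the maximum L(n-1)/n
  expect_equal(min_arc_distance(arrangement(c(1, 7, 13),
                                            genome_config(18, 3))), 12)
  # fewer than two genes: 0 by convention
  expect_equal(min_arc_distance(arrangement(5, genome_config(100, 1))), 0)
})

test_that("minimum arc distance equals the covering-arc oracle and is
           invariant under rotation and reflection", {
  set.seed(101)
  for (rep in 1:1000) {
    L <- sample(10:60, 1)
    n <- sample(2:min(6, L), 1)
    cfg <- genome_config(L, n)
    pos <- sample.int(L, n)
    d <- min_arc_distance(arrangement(pos, cfg))
    expect_equal(d, oracle_min_arc(pos, L))
    off <- sample.int(L, 1)
    rotated <- ((pos - 1 + off) %% L) + 1
    reflected <- ((L - pos) %% L) + 1
    expect_equal(min_arc_distance(arrangement(rotated, cfg)), d)
    expect_equal(min_arc_distance(arrangement(reflected, cfg)), d)
  }
})

test_that("random arrangements are distinct, reproducible and uniform", {
  cfg <- genome_config(10, 10)
  expect_equal(random_arrangement(cfg)$positions, 1:10)  # forced
  set.seed(7); a <- random_arrangement(genome_config())
  set.seed(7); b <- random_arrangement(genome_config())
  expect_identical(a$positions, b$positions)
  expect_error(genome_config(10, 11), "n_genes")
  # three uniform genes: E[min arc] = 7L/18 (largest-gap expectation)
  set.seed(11)
  d <- replicate(4000, min_arc_distance(random_arrangement(genome_config())))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - arc_expectation_3(default_L)), 4 * se)
})

test_that("breakpoints are ordered half-integers off gene positions", {
  cfg <- genome_config(50, 3)
  set.seed(3)
  for (rep in 1:200) {
    bp <- draw_breakpoints(cfg)
    expect_lte(bp[1], bp[2])
    expect_true(all(bp %in% (seq_len(50) - 0.5)))
  }
})

test_that("inversion viability implements the origin/terminus imbalance rule", {
  cfg <- genome_config(100, 3, tolerance_kb = 10)
  expect_true(inversion_viable(5.5, 25.5, cfg))    # segment before terminus
  expect_true(inversion_viable(60.5, 80.5, cfg))   # segment after terminus
  expect_false(inversion_viable(40.5, 70.5, cfg))  # terminus moved 11 kb
  expect_true(inversion_viable(45.5, 60.5, cfg))   # terminus moved 6 kb
  expect_error(inversion_viable(25.5, 5.5, cfg))
  # tolerance L: everything viable; tolerance 0: only same-side or
  # terminus-symmetric segments
  loose <- genome_config(100, 3, tolerance_kb = 100)
  strict <- genome_config(100, 3, tolerance_kb = 0)
  set.seed(5)
  for (rep in 1:200) {
    bp <- draw_breakpoints(loose)
    expect_true(inversion_viable(bp[1], bp[2], loose))
    ok <- inversion_viable(bp[1], bp[2], strict)
    expect_equal(ok, bp[2] < 50 || bp[1] > 50 || bp[1] + bp[2] == 100)
  }
})

test_that("inversion reflects interior genes and is an involution", {
  cfg <- genome_config(100, 3)
  arr <- arrangement(c(10, 20, 90), cfg)
  expect_equal(apply_inversion(arr, 5.5, 25.5)$positions, c(11, 21, 90))
  expect_equal(apply_inversion(arr, 0.5, 0.5)$positions, arr$positions)
  set.seed(13)
  for (rep in 1:300) {
    L <- sample(20:100, 1)
    cfg <- genome_config(L, 4)
    arr <- random_arrangement(cfg)
    bp <- draw_breakpoints(cfg)
    inv <- apply_inversion(arr, bp[1], bp[2])
    expect_equal(length(inv$positions), 4)
    expect_false(anyDuplicated(inv$positions) > 0)
    expect_equal(apply_inversion(inv, bp[1], bp[2])$positions, arr$positions)
  }
})

test_that("translocation moves one gene to a uniform unoccupied slot", {
  cfg4 <- genome_config(4, 3)
  set.seed(17)
  for (rep in 1:100) {
    out <- apply_translocation(arrangement(c(1, 2, 3), cfg4))$positions
    expect_equal(length(out), 3)
    expect_true(4 %in% out)  # the single free slot must receive the mover
  }
  # destination uniform over unoccupied slots (chi-square over many draws)
  cfg <- genome_config(30, 3)
  arr <- arrangement(c(5, 10, 15), cfg)
  set.seed(19)
  dests <- replicate(10000, setdiff(apply_translocation(arr)$positions,
                                    arr$positions))
  expect_true(all(!dests %in% c(5, 10, 15)))
  free <- setdiff(1:30, c(5, 10, 15))
  p <- chisq.test(table(factor(dests, levels = free)))$p.value
  expect_gt(p, 1e-4)
  set.seed(23); x <- apply_translocation(arr)$positions
  set.seed(23); y <- apply_translocation(arr)$positions
  expect_identical(x, y)
})

test_that("proportion clustered counts distances under the threshold", {
  cfg <- genome_config(4900, 3)
  arrs <- list(arrangement(c(1, 3, 5), cfg),          # d = 4
               arrangement(c(1, 100, 200), cfg),      # d = 199
               arrangement(c(1, 150, 299), cfg))      # d = 298
  expect_equal(proportion_clustered(arrs, threshold_kb = 1000), 1)
  expect_equal(proportion_clustered(arrs, threshold_kb = 2), 0)
  expect_equal(proportion_clustered(c(10, 200, 300), threshold_kb = 147),
               1 / 3)
  # default threshold is 3 minutes = 147 kb at L = 4900
  expect_equal(proportion_clustered(arrs), 1 / 3)
  expect_error(proportion_clustered(list()), "empty")
  expect_error(proportion_clustered(numeric(0)), "empty")
})

test_that("arrangements round-trip through their TSV record", {
  arr <- arrangement(c(7, 19, 23), genome_config(100, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_arrangement(arr, path)
  back <- read_arrangement(path)
  expect_equal(back$positions, arr$positions)
  expect_equal(back$config$length_kb, 100L)
  writeLines("garbled", path)
  expect_error(read_arrangement(path), "malformed")
})
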