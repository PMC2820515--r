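# Independent oracles used across the test files. Each is a deliberately
# naive implementation kept separate from the package's code paths.

# Minimum covering arc by brute force: for each gene taken as the arc start,
# walk clockwise to the furthest gene; the answer is the smallest such arc.
oracle_min_arc <- function(positions, L) {
  n <- length(positions)
  if (n < 2L) return(0)
  min(vapply(seq_len(n), function(i) {
    arcs <- (positions - positions[i]) %% L
    max(arcs)
  }, numeric(1)))
}

# Kendall tau-b by O(n^2) pair counting with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0L && dy == 0L) next
    if (dx == 0L) tx <- tx + 1L
    else if (dy == 0L) ty <- ty + 1L
    else if (dx == dy) C <- C + 1L
    else D <- D + 1L
  }
  n0 <- n * (n - 1L) / 2
  (C - D) / sqrt((n0 - tally_ties(x)) * (n0 - tally_ties(y)))
}
tally_ties <- function(v) {
  t <- table(v)
  sum(t * (t - 1L) / 2)
}

# Absorption probability of the exact Moran birth-death chain for a mutant
# class with relative fitness r starting at i copies out of N.
moran_absorption <- function(r, i, N) {
  if (r == 1) return(i / N)
  (1 - r^(-i)) / (1 - r^(-N))
}

# Haploid Wright-Fisher simulation of conditional fixation times for a
# single new mutant with selection coefficient s.
wf_fixation_times <- function(N, s, n_fix) {
  times <- numeric(0)
  while (length(times) < n_fix) {
    x <- 1L; t <- 0L
    repeat {
      x <- rbinom(1L, N, x * (1 + s) / (N + s * x))
      t <- t + 1L
      if (x == 0L || x == N) break
    }
    if (x == N) times <- c(times, t)
  }
  times
}

# Run moran_step until one of two genome classes fixes; returns TRUE if the
# class matching `ref_positions` fixed.
moran_fix_class <- function(popn, params, ref_positions) {
  repeat {
    k <- sum(colSums(popn$positions == ref_positions) ==
               length(ref_positions))
    if (k == 0L) return(FALSE)
    if (k == ncol(popn$positions)) return(TRUE)
    popn <- moran_step(popn, params)
  }
}

default_L <- 4900
arc_expectation_3 <- function(L) 7 * L / 18  # largest of 3 circular gaps:
# E[max gap] = (L/3)(1 + 1/2 + 1/3) = 11L/18, so E[min arc] = 7L/18
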