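#' Parameters of the Moran model with inversions
#'
#' Individual-based model of a constant-size population of `pop_size`
#' bacterial cells under direct selection for gene proximity. At each
#' elementary time step one individual is chosen uniformly; with probability
#' `rho` an inversion is attempted on its genome (viable inversions are
#' applied, lethal ones kill the individual, which is replaced by the
#' offspring of a fitness-proportional parent); otherwise the chosen
#' individual dies and is replaced by the offspring of a fitness-proportional
#' parent. Following the classical Moran convention, one generation is
#' `pop_size` elementary steps.
#'
#' @param pop_size Population size `N` (at least 2).
#' @param rho Inversion probability per chosen individual per time step.
#' @param fitness A [fitness_params()].
#' @param genome A [genome_config()].
#' @param n_generations Run length in generations (one generation =
#'   `pop_size` steps).
#' @param record_every Sampling stride in elementary steps; defaults to once
#'   per generation (`pop_size` steps).
#' @param lethal_excludes_self Should the replacement parent after a lethal
#'   inversion be drawn from the other `N - 1` individuals (default `TRUE`;
#'   the focal genome is dead) rather than the whole population?
#' @return An object of class `moran_params`.
#' @export
moran_params <- function(pop_size = 100L, rho = 0.01,
                         fitness = fitness_params(),
                         genome = genome_config(),
                         n_generations = 100L, record_every = NULL,
                         lethal_excludes_self = TRUE) {
  stopifnot(is.numeric(pop_size), pop_size >= 2,
            is.numeric(rho), rho >= 0, rho <= 1,
            inherits(fitness, "fitness_params"),
            inherits(genome, "genome_config"),
            n_generations >= 0)
  if (is.null(record_every)) record_every <- as.integer(pop_size)
  stopifnot(record_every >= 1)
  structure(list(pop_size = as.integer(pop_size), rho = rho,
                 fitness = fitness, genome = genome,
                 n_generations = as.integer(n_generations),
                 record_every = as.integer(record_every),
                 lethal_excludes_self = isTRUE(lethal_excludes_self)),
            class = "moran_params")
}

#' Moran population
#'
#' Fixed-size collection of `pop_size` gene arrangements with cached
#' minimum arc distances and log-fitness values (the cache is invalidated
#' whenever a genome changes; cached and recomputed values are identical by
#' contract). Fitness is cached on the log scale so that
#' fitness-proportional sampling stays exact even where the fitness values
#' themselves underflow (steep sigmoidal shapes at large distances).
#'
#' @param arrangements List of [arrangement()] objects, recycled to
#'   `pop_size` if a single arrangement is given.
#' @param params A [moran_params()].
#' @return An object of class `moran_population` with fields `positions`
#'   (`n_genes x N` matrix), `dist`, `log_fit` and `config`.
#' @export
moran_population <- function(arrangements, params) {
  stopifnot(inherits(params, "moran_params"))
  if (inherits(arrangements, "arrangement"))
    arrangements <- rep(list(arrangements), params$pop_size)
  stopifnot(length(arrangements) == params$pop_size,
            all(vapply(arrangements, inherits, logical(1), "arrangement")))
  config <- arrangements[[1L]]$config
  pos <- matrix(vapply(arrangements, function(a) a$positions,
                       integer(config$n_genes)),
                nrow = config$n_genes)
  d <- arc_dist_cols(pos, config$length_kb)
  structure(list(positions = pos, dist = d,
                 log_fit = log_fitness(d, params$fitness), config = config),
            class = "moran_population")
}

#' One elementary step of the Moran process with inversions
#'
#' Chooses one individual uniformly and draws a breakpoint pair. With
#' probability `rho` an inversion is attempted: if viable, the individual's
#' genome is replaced by the inverted genome; if lethal, the individual dies
#' and is replaced by the offspring of a parent drawn fitness-proportionally
#' (by default from the other `N - 1` individuals). With probability
#' `1 - rho` the chosen individual dies and is replaced by the offspring of
#' a fitness-proportional parent drawn from the whole population. The
#' population size is invariant.
#'
#' @param popn A [moran_population()].
#' @param params A [moran_params()].
#' @return The updated [moran_population()].
#' @export
moran_step <- function(popn, params) {
  N <- ncol(popn$positions)
  i <- sample.int(N, 1L)
  bp <- draw_breakpoints(popn$config)
  if (stats::runif(1L) < params$rho) {
    if (inversion_viable(bp[1L], bp[2L], popn$config)) {
      popn$positions[, i] <- invert_positions(popn$positions[, i],
                                              bp[1L], bp[2L])
      popn$dist[i] <- arc_dist_cols(popn$positions[, i, drop = FALSE],
                                    popn$config$length_kb)
      popn$log_fit[i] <- log_fitness(popn$dist[i], params$fitness)
    } else {
      # lethal inversion: the individual dies; replacement birth from a
      # fitness-proportional parent
      if (params$lethal_excludes_self && N > 1L) {
        others <- if (i == 1L) 2:N else if (i == N) 1:(N - 1L)
                  else c(1:(i - 1L), (i + 1L):N)
        parent <- others[fitness_parent(popn$log_fit[others])]
      } else {
        parent <- fitness_parent(popn$log_fit)
      }
      popn$positions[, i] <- popn$positions[, parent]
      popn$dist[i] <- popn$dist[parent]
      popn$log_fit[i] <- popn$log_fit[parent]
    }
  } else {
    # random death of the chosen individual, fitness-proportional birth
    parent <- fitness_parent(popn$log_fit)
    popn$positions[, i] <- popn$positions[, parent]
    popn$dist[i] <- popn$dist[parent]
    popn$log_fit[i] <- popn$log_fit[parent]
  }
  popn
}

# fitness-proportional index draw from cached log-fitness values,
# normalized by the maximum so weights never underflow to all-zero
fitness_parent <- function(log_fit) {
  sample.int(length(log_fit), 1L, prob = exp(log_fit - max(log_fit)))
}

#' Run the Moran simulation
#'
#' Initializes all `pop_size` cells with one shared uniform random
#' arrangement, runs `n_generations * pop_size` elementary steps, and
#' records the population-mean minimum arc distance every `record_every`
#' steps (once per generation by default). The initial state is recorded at
#' generation 0.
#'
#' @param params A [moran_params()].
#' @param seed Integer seed (drawn at random and recorded if omitted).
#' @param init Optional [arrangement()] (or list of `pop_size` of them) to
#'   start from instead of a random one.
#' @return A `trajectory` data frame with columns `generation` and
#'   `mean_min_arc_kb`, and attributes `model` (`"moran"`), `status`,
#'   `seed`, `params`.
#' @examples
#' tr <- run_moran(moran_params(pop_size = 10, n_generations = 5), seed = 1)
#' @export
run_moran <- function(params = moran_params(), seed = NULL, init = NULL) {
  stopifnot(inherits(params, "moran_params"))
  seed <- resolve_seed(seed)
  set.seed(seed)
  if (is.null(init)) init <- random_arrangement(params$genome)
  popn <- moran_population(init, params)
  n_steps <- params$n_generations * params$pop_size
  rec_at <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %%
                                            params$record_every == 0L],
                     n_steps))
  gen_v <- rec_at / params$pop_size
  dist_v <- numeric(length(rec_at))
  dist_v[1L] <- mean(popn$dist)
  j <- 2L
  if (n_steps > 0L) {
    for (t in seq_len(n_steps)) {
      popn <- moran_step(popn, params)
      if (j <= length(rec_at) && t == rec_at[j]) {
        dist_v[j] <- mean(popn$dist)
        j <- j + 1L
      }
    }
  }
  new_trajectory(data.frame(generation = gen_v, mean_min_arc_kb = dist_v),
                 model = "moran", status = "completed", seed = seed,
                 params = params)
}
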