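#' Parameters of the rearrangement-substitution model
#'
#' Origin-fixation model: the population is assumed monomorphic except
#' during brief substitution episodes, so only a single resident arrangement
#' is tracked. Waiting times to the next proposed inversion are geometric
#' (see [waiting_time()]); viable proposals fix with the diffusion-theory
#' probability [fixation_probability()] and, upon fixing, advance the clock
#' by the conditional [fixation_time()]. Monomorphism requires `N * rho` to
#' be small; a warning is issued when `N * rho > 0.1`.
#'
#' @param rho Per-individual per-generation inversion probability.
#' @param pop_size Population size `N`.
#' @param fitness A [fitness_params()].
#' @param genome A [genome_config()].
#' @param t_end Total number of generations to simulate (default 50000).
#' @return An object of class `subst_params`.
#' @export
subst_params <- function(rho = 1e-8, pop_size = 1e4,
                         fitness = fitness_params(),
                         genome = genome_config(), t_end = 50000) {
  stopifnot(is.numeric(rho), rho >= 0, rho <= 1,
            is.numeric(pop_size), pop_size >= 2,
            inherits(fitness, "fitness_params"),
            inherits(genome, "genome_config"), t_end >= 0)
  if (pop_size * rho > 0.1)
    warning("N * rho = ", pop_size * rho, " is not small: the monomorphic-",
            "population assumption of the substitution model is strained")
  structure(list(rho = rho, pop_size = pop_size,
                 popgen = popgen_params(pop_size),
                 fitness = fitness, genome = genome, t_end = t_end),
            class = "subst_params")
}

#' State of the rearrangement-substitution process
#'
#' @param arr The resident [arrangement()].
#' @return An object of class `subst_state` with fields `positions`, `dist`,
#'   `elapsed_generations`, `config`, and `last_event` (a one-row data frame
#'   describing the most recent event, or `NULL`).
#' @export
subst_state <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  structure(list(positions = arr$positions,
                 dist = min_arc_distance(arr),
                 elapsed_generations = 0,
                 config = arr$config,
                 last_event = NULL),
            class = "subst_state")
}

#' One proposal event of the substitution model
#'
#' Draws the geometric waiting time to the next rearrangement event and
#' advances the clock; draws breakpoints. A non-viable inversion consumes
#' the waiting interval and changes nothing else. A viable inversion is
#' evaluated: the selection coefficient `s` compares the proposed and
#' resident arc distances, fixation occurs with probability
#' [fixation_probability()]`(s)`, and on fixation the resident arrangement
#' is replaced and the clock additionally advances by [fixation_time()]
#' `(s)`. The event (time, resident distance after the event, `s`, fixed
#' flag, viability) is stored in `last_event`.
#'
#' @param state A [subst_state()].
#' @param params A [subst_params()].
#' @return The updated [subst_state()].
#' @export
subst_event <- function(state, params) {
  stopifnot(inherits(state, "subst_state"),
            inherits(params, "subst_params"))
  state$elapsed_generations <- state$elapsed_generations +
    waiting_time(params$rho, params$pop_size)
  bp <- draw_breakpoints(state$config)
  if (!inversion_viable(bp[1L], bp[2L], state$config)) {
    state$last_event <- data.frame(time = state$elapsed_generations,
                                   distance_kb = state$dist, s = NA_real_,
                                   fixed = FALSE, viable = FALSE)
    return(state)
  }
  new_pos <- invert_positions(state$positions, bp[1L], bp[2L])
  d_new <- as.numeric(arc_dist_cols(matrix(new_pos, ncol = 1L),
                                    state$config$length_kb))
  s <- selection_coefficient(state$dist, d_new, params$fitness)
  fixed <- stats::runif(1L) < fixation_probability(s, params$popgen)
  if (fixed) {
    state$elapsed_generations <- state$elapsed_generations +
      fixation_time(s, params$popgen)
    state$positions <- new_pos
    state$dist <- d_new
  }
  state$last_event <- data.frame(time = state$elapsed_generations,
                                 distance_kb = state$dist, s = s,
                                 fixed = fixed, viable = TRUE)
  state
}

#' Run the rearrangement-substitution simulation
#'
#' Initializes a uniform random resident arrangement (positions drawn
#' without replacement) and iterates [subst_event()] until the elapsed time
#' reaches `t_end` generations. The returned trajectory is the event log;
#' the final resident distance is also available as attribute
#' `final_distance_kb`.
#'
#' @param params A [subst_params()].
#' @param seed Integer seed (drawn at random and recorded if omitted).
#' @param init Optional starting [arrangement()].
#' @return A `trajectory` data frame with columns `time`, `distance_kb`,
#'   `s`, `fixed` (one row per proposal event) and attributes `model`
#'   (`"subst"`), `status`, `seed`, `params`, `final_distance_kb`.
#' @examples
#' tr <- run_subst(subst_params(rho = 1e-6, pop_size = 100, t_end = 1000),
#'                 seed = 1)
#' attr(tr, "final_distance_kb")
#' @export
run_subst <- function(params = subst_params(), seed = NULL, init = NULL) {
  stopifnot(inherits(params, "subst_params"))
  seed <- resolve_seed(seed)
  set.seed(seed)
  if (is.null(init)) init <- random_arrangement(params$genome)
  state <- subst_state(init)
  cap <- 256L
  time_v <- numeric(cap); dist_v <- numeric(cap)
  s_v <- numeric(cap); fix_v <- logical(cap)
  m <- 0L
  while (state$elapsed_generations < params$t_end) {
    state <- subst_event(state, params)
    m <- m + 1L
    if (m > cap) {  # geometric growth of the event log
      cap <- cap * 2L
      length(time_v) <- cap; length(dist_v) <- cap
      length(s_v) <- cap; length(fix_v) <- cap
    }
    ev <- state$last_event
    time_v[m] <- ev$time; dist_v[m] <- ev$distance_kb
    s_v[m] <- ev$s; fix_v[m] <- ev$fixed
  }
  idx <- seq_len(m)
  new_trajectory(data.frame(time = time_v[idx], distance_kb = dist_v[idx],
                            s = s_v[idx], fixed = fix_v[idx]),
                 model = "subst", status = "completed", seed = seed,
                 params = params, final_distance_kb = state$dist)
}
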