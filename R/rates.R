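#' Horizontal-transfer kernel parameters
#'
#' The probability that a positive species recruits a negative species (i.e.
#' donates its gene arrangement by horizontal transfer) decays exponentially
#' with the minimum arc distance `d` spanned by the pathway genes:
#' `P(d) = p_max * exp(-lambda_transfer * d)`. The default decay is pinned to
#' `log(6) / 450` per kb, under which a 50 kb fragment is exactly 6 times
#' more likely to transfer than one of 500 kb. `p_loss` is the probability
#' per genome per time step that a species loses the pathway function.
#'
#' @param p_max Maximum transfer probability, attained when all genes lie in
#'   the same minute of the chromosome (default 0.01 per genome per step).
#' @param lambda_transfer Exponential decay of transfer with distance, per kb
#'   (default `log(6)/450`).
#' @param p_loss Probability of loss of function per genome per time step
#'   (default 0.001).
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(p_max = 0.01, lambda_transfer = log(6) / 450,
                            p_loss = 0.001) {
  stopifnot(is.numeric(p_max), p_max >= 0, p_max <= 1,
            is.numeric(lambda_transfer), lambda_transfer >= 0,
            is.numeric(p_loss), p_loss >= 0, p_loss <= 1)
  structure(list(p_max = p_max, lambda_transfer = lambda_transfer,
                 p_loss = p_loss),
            class = "transfer_params")
}

#' Transfer probability at a given gene distance
#'
#' Evaluates the exponential transfer kernel `p_max * exp(-lambda * d)`.
#'
#' @param d Minimum arc distance in kb (non-negative; vectorized).
#' @param params A [transfer_params()].
#' @return Transfer probability, monotone non-increasing in `d`.
#' @examples
#' transfer_prob(0)                       # 0.01
#' transfer_prob(50) / transfer_prob(500) # 6
#' @export
transfer_prob <- function(d, params = transfer_params()) {
  stopifnot(inherits(params, "transfer_params"), all(d >= 0))
  params$p_max * exp(-params$lambda_transfer * d)
}

#' Fitness-function parameters
#'
#' Relative fitness of a cell as a function of the minimum arc distance of
#' its pathway genes. Two shapes are supported: exponential decay
#' `w(d) = exp(-lambda_fitness * d)` and a steep sigmoidal (logistic in
#' distance) `w(d) = 1 / (1 + exp(sig_steepness * (d - sig_midpoint_kb)))`.
#' The sigmoidal defaults (midpoint 12.5 kb, steepness 0.5 per kb) make
#' fitness drop markedly between distances of 5 and 20 kb.
#'
#' @param shape `"exponential"` or `"sigmoidal"`.
#' @param lambda_fitness Decay in fitness per kb (exponential shape; default
#'   0.001).
#' @param sig_midpoint_kb,sig_steepness Midpoint (kb) and steepness (per kb)
#'   of the sigmoidal shape.
#' @return An object of class `fitness_params`.
#' @export
fitness_params <- function(shape = c("exponential", "sigmoidal"),
                           lambda_fitness = 0.001,
                           sig_midpoint_kb = 12.5, sig_steepness = 0.5) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(lambda_fitness), lambda_fitness >= 0,
            is.numeric(sig_midpoint_kb), sig_midpoint_kb > 0,
            is.numeric(sig_steepness), sig_steepness > 0)
  structure(list(shape = shape, lambda_fitness = lambda_fitness,
                 sig_midpoint_kb = sig_midpoint_kb,
                 sig_steepness = sig_steepness),
            class = "fitness_params")
}

#' Relative fitness at a given gene distance
#'
#' Mathematically positive for every finite distance, though the sigmoidal
#' shape underflows double precision beyond a few thousand kb; computations
#' that need fitness *ratios* (selection coefficients, Moran sampling
#' weights) therefore work on the log scale internally and never underflow.
#'
#' @param d Minimum arc distance in kb (non-negative; vectorized).
#' @param params A [fitness_params()].
#' @return Relative fitness in `(0, 1]`, non-increasing in `d`.
#' @examples
#' fitness(0)  # 1 (exponential shape)
#' @export
fitness <- function(d, params = fitness_params()) {
  exp(log_fitness(d, params))
}

# log relative fitness; numerically stable for both shapes at any distance
log_fitness <- function(d, params = fitness_params()) {
  stopifnot(inherits(params, "fitness_params"), all(d >= 0))
  switch(params$shape,
         exponential = -params$lambda_fitness * d,
         sigmoidal = stats::plogis(-params$sig_steepness *
                                     (d - params$sig_midpoint_kb),
                                   log.p = TRUE))
}

#' Selection coefficient of a new arrangement
#'
#' Ratio-minus-one convention: `s = w(d_new) / w(d_old) - 1`, so `s > 0` when
#' the new arrangement brings the genes closer together. For the exponential
#' fitness shape this is `exp(-lambda * (d_new - d_old)) - 1`. Always
#' `s > -1`. Evaluated on the log-fitness scale, so it remains accurate
#' where the fitness values themselves underflow.
#'
#' @param d_old,d_new Minimum arc distances (kb) of the resident and proposed
#'   arrangements.
#' @param params A [fitness_params()].
#' @return The selection coefficient `s`.
#' @examples
#' selection_coefficient(1000, 500, fitness_params(lambda_fitness = 0.001))
#' # exp(0.5) - 1
#' @export
selection_coefficient <- function(d_old, d_new, params = fitness_params()) {
  expm1(log_fitness(d_new, params) - log_fitness(d_old, params))
}

#' Population-genetic parameters
#'
#' Haploid population size `N` and the effective size used in the diffusion
#' formulas. The diploid diffusion results are applied to haploids via the
#' substitution `N_e = N / 2`, which yields the standard neutral fixation
#' probability `1/N` for a single new mutant.
#'
#' @param pop_size Haploid population size `N` (at least 2).
#' @return An object of class `popgen_params` with fields `pop_size` and
#'   `effective_size`.
#' @export
popgen_params <- function(pop_size) {
  stopifnot(is.numeric(pop_size), length(pop_size) == 1, pop_size >= 2)
  structure(list(pop_size = pop_size, effective_size = pop_size / 2),
            class = "popgen_params")
}

as_popgen <- function(params) {
  if (inherits(params, "popgen_params")) params else popgen_params(params)
}

#' Diffusion-theory fixation probability
#'
#' Probability that a single new arrangement with selection coefficient `s`
#' fixes in a haploid population of size `N` (Kimura's diffusion result with
#' `N_e = N/2`): `pi(s) = (1 - exp(-2s)) / (1 - exp(-2Ns))`. Continuous at
#' `s = 0` with the neutral limit `1/N`; strictly increasing in `s`.
#' Evaluation is overflow-safe for large `|Ns|` (log-space branch when
#' `2N|s| > 700`).
#'
#' @param s Selection coefficient(s), each `>= -1` (vectorized; `-1` is the
#'   fully-deleterious limit, where the probability underflows to 0 — finite
#'   precision rounds extreme coefficients to the boundary).
#' @param params A [popgen_params()], or a bare population size.
#' @return Fixation probability in `[0, 1)`.
#' @examples
#' fixation_probability(0, 1000)     # 1/1000
#' fixation_probability(0.01, 1000)  # ~0.0198
#' @export
fixation_probability <- function(s, params) {
  pg <- as_popgen(params)
  stopifnot(all(s >= -1))
  N <- pg$pop_size
  num <- -2 * s          # exponents of the stable form expm1(-2s)/expm1(-2Ns)
  den <- -2 * N * s
  pi_s <- ifelse(s == 0, 1 / N, expm1(num) / expm1(den))
  # strongly deleterious: expm1 overflows; work in logs
  big <- den > 700
  if (any(big)) {
    lognum <- ifelse(num[big] > 700, num[big], log(expm1(num[big])))
    pi_s[big] <- exp(lognum - den[big])
  }
  pi_s
}

#' Diffusion-theory conditional mean fixation time
#'
#' Expected number of generations for a single new mutant with selection
#' coefficient `s` to reach fixation, conditional on fixing, in a haploid
#' population of size `N`. Computed by numerical integration of the
#' conditional sojourn-time density of the diffusion (the Kimura--Ohta
#' Green-function result) with the haploid substitution `N_e = N/2` and
#' initial frequency `1/N`. The neutral limit is
#' `-2N (1-p) log(1-p) / p` with `p = 1/N`, i.e. approximately `4 N_e = 2N`
#' generations. The conditional time is an even function of `s`
#' (Maruyama--Kimura symmetry), which is exploited for deleterious mutants.
#'
#' @param s Selection coefficient, `> -1` (scalar).
#' @param params A [popgen_params()], or a bare population size.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return Expected conditional fixation time in generations.
#' @examples
#' fixation_time(0, 100)  # ~200 generations
#' @export
fixation_time <- function(s, params, rel_tol = 1e-9) {
  pg <- as_popgen(params)
  stopifnot(length(s) == 1, s >= -1)
  N <- pg$pop_size
  p <- 1 / N
  if (abs(s) < 1e-10)
    return(-2 * N * (1 - p) * log1p(-p) / p)
  s <- abs(s)
  S <- 2 * N * s
  # numeric guard: beyond S ~ 1e6 the boundary layers defeat the quadrature
  # while the conditional time is already down to a few generations; capping
  # S overstates such times by O(1) generations at most
  if (S > 1e6) S <- 1e6
  u <- function(x) expm1(-S * x) / expm1(-S)   # fixation prob from freq x
  upper <- function(x) {  # conditional sojourn density, x in (p, 1)
    f <- ifelse(1 - x < 1e-12, S, -expm1(-S * (1 - x)) / (1 - x))
    2 * N * f * u(x) / (S * x)
  }
  up <- u(p)
  lower <- function(x) {  # x in (0, p)
    g <- ifelse(x < 1e-12, S, expm1(S * x) / x)
    2 * N * g * (1 - up) * u(x) / (S * (1 - x) * up)
  }
  quad <- function(tol) {
    i1 <- stats::integrate(upper, p, 1, rel.tol = tol,
                           subdivisions = 2000L)$value
    i2 <- if (1 - up <= 0) 0 else
      stats::integrate(lower, 0, p, rel.tol = tol,
                       subdivisions = 2000L)$value
    i1 + i2
  }
  res <- tryCatch(quad(rel_tol), error = function(e1)
    tryCatch(quad(1e-6), error = function(e2)
      stop("fixation_time: sojourn-time integral did not converge (s = ", s,
           ", N = ", N, "): ", conditionMessage(e2))))
  max(res, 0)
}

#' Geometric waiting time until the next rearrangement event
#'
#' In a population of `N` individuals each rearranging with probability
#' `rho` per generation, the probability that at least one rearrangement
#' occurs in a generation is `p = 1 - (1 - rho)^N` (approximately `N * rho`
#' for small `rho`). The waiting time until the next event is geometric on
#' `{1, 2, ...}` with parameter `p` and mean `1/p`. Sampled by uniform
#' inversion, which is stable for very small `p`.
#'
#' @param rho Per-individual per-generation rearrangement probability
#'   (`0 < rho <= 1`).
#' @param pop_size Population size `N`.
#' @param n Number of waiting times to draw.
#' @return Integer-valued waiting time(s) in generations.
#' @export
waiting_time <- function(rho, pop_size, n = 1L) {
  stopifnot(rho >= 0, rho <= 1, pop_size >= 1)
  p <- -expm1(pop_size * log1p(-rho))
  if (rho == 1) p <- 1
  if (p <= 0) stop("waiting_time: event probability is zero ",
                   "(rho = ", rho, ", N = ", pop_size, ")")
  if (p >= 1) return(rep(1, n))
  floor(log(stats::runif(n)) / log1p(-p)) + 1
}
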