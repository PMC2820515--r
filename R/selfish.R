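#' Parameters of the selfish-operon species-pool simulation
#'
#' Configuration for the Lawrence--Roth style simulation in which a pool of
#' "positive" species (each monomorphic for one gene arrangement) evolves by
#' rearrangement, loss of function, and distance-biased horizontal transfer
#' from a limitless supply of negative species.
#'
#' Three rearrangement variants are available:
#' \describe{
#'   \item{`original_translocation`}{with probability `rho` a random pathway
#'     gene moves to a random new position (a rearrangement event always
#'     affects the pathway genes).}
#'   \item{`corrected_translocation`}{the rearrangement affects the pathway
#'     genes only with probability `n/L` (their share of the genome, genes
#'     being 1 kb), i.e. a gene moves with probability `rho * n_genes /
#'     length_kb`. This correction lowers the effective rearrangement
#'     probability by a few orders of magnitude.}
#'   \item{`inversion`}{with probability `rho` two breakpoints are drawn and
#'     the segment inverted if viable; a lethal inversion leaves the
#'     species' arrangement unchanged (the species survives at the expense
#'     of the rearranged individual).}
#' }
#'
#' @param rho Rearrangement probability per genome per time step (default
#'   `1e-5`, a deliberately low value; the historical simulations used much
#'   higher ones).
#' @param variant Rearrangement variant, see Details.
#' @param transfer A [transfer_params()].
#' @param genome A [genome_config()].
#' @param init_species Initial number of positive species (default 100).
#' @param max_species Cap on the number of positive species: horizontal
#'   transfer switches off when the pool reaches this size and resumes as
#'   soon as it drops below it (default 900).
#' @param min_species Historical lower bound on the pool size (default 10).
#'   Reported in trajectories but not enforced by any intervention: the
#'   mechanism the original simulation used at this floor is undocumented.
#' @param n_steps Number of time steps to simulate (default 50000).
#' @return An object of class `selfish_params`.
#' @export
selfish_params <- function(rho = 1e-5,
                           variant = c("corrected_translocation",
                                       "original_translocation",
                                       "inversion"),
                           transfer = transfer_params(),
                           genome = genome_config(),
                           init_species = 100L, max_species = 900L,
                           min_species = 10L, n_steps = 50000L) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(rho), rho >= 0, rho <= 1,
            inherits(transfer, "transfer_params"),
            inherits(genome, "genome_config"),
            init_species >= 1, max_species >= 1, n_steps >= 0,
            init_species <= max_species)
  structure(list(rho = rho, variant = variant, transfer = transfer,
                 genome = genome, init_species = as.integer(init_species),
                 max_species = as.integer(max_species),
                 min_species = as.integer(min_species),
                 n_steps = as.integer(n_steps)),
            class = "selfish_params")
}

#' Pool of positive species
#'
#' Each positive species is monomorphically associated with a single gene
#' arrangement (fixation within a species is treated as instantaneous).
#' Internally the pool stores arrangements column-wise in a position matrix
#' with cached minimum arc distances.
#'
#' @param arrangements A non-empty list of [arrangement()] objects sharing
#'   one genome configuration.
#' @return An object of class `species_pool` with fields `positions`
#'   (`n_genes x n_species` matrix of sorted positions), `dist` (cached arc
#'   distances) and `config`.
#' @export
species_pool <- function(arrangements) {
  stopifnot(length(arrangements) >= 1,
            all(vapply(arrangements, inherits, logical(1), "arrangement")))
  config <- arrangements[[1L]]$config
  pos <- vapply(arrangements, function(a) a$positions,
                integer(config$n_genes))
  pos <- matrix(pos, nrow = config$n_genes)
  structure(list(positions = pos,
                 dist = arc_dist_cols(pos, config$length_kb),
                 config = config),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool: ", ncol(x$positions), " positive species, ",
      "mean min arc ", round(mean(x$dist), 1), " kb\n", sep = "")
  invisible(x)
}

random_pool <- function(params) {
  species_pool(replicate(params$init_species,
                         random_arrangement(params$genome),
                         simplify = FALSE))
}

#' One time step of the selfish-operon simulation
#'
#' Sweeps over the species in index order. Each species in turn (a)
#' rearranges its genome according to the chosen variant, (b) is lost from
#' the pool with probability `p_loss` (loss applies immediately: a lost
#' species does not donate), and (c) if the current positive-species count
#' (including recruits accrued earlier in the sweep) is below `max_species`,
#' recruits a negative species with probability `transfer_prob(d)`, where `d`
#' is its minimum arc distance. Recruits carry the donor's arrangement, are
#' appended after the sweep, and are not themselves iterated this step.
#'
#' @param pool A [species_pool()].
#' @param params A [selfish_params()].
#' @return The updated [species_pool()]; may be empty (0 species) after
#'   losses.
#' @export
selfish_step <- function(pool, params) {
  stopifnot(inherits(pool, "species_pool"),
            inherits(params, "selfish_params"))
  k <- ncol(pool$positions)
  if (k == 0L) return(pool)
  L <- pool$config$length_kb
  n <- pool$config$n_genes

  # (a) rearrangement, variant-specific probability per species
  p_re <- switch(params$variant,
                 original_translocation = params$rho,
                 corrected_translocation = params$rho * n / L,
                 inversion = params$rho)
  re <- stats::runif(k) < p_re
  if (any(re)) {
    for (i in which(re)) {
      if (params$variant == "inversion") {
        bp <- draw_breakpoints(pool$config)
        if (!inversion_viable(bp[1L], bp[2L], pool$config)) next
        pool$positions[, i] <- invert_positions(pool$positions[, i],
                                                bp[1L], bp[2L])
      } else {
        pool$positions[, i] <- translocate_positions(pool$positions[, i], L)
      }
      pool$dist[i] <- arc_dist_cols(pool$positions[, i, drop = FALSE], L)
    }
  }

  # (b) loss of function, applied in index order
  lost <- stats::runif(k) < params$transfer$p_loss
  # (c) recruitment by horizontal transfer while the running count (initial
  # size minus losses so far plus recruits granted so far) is under the cap
  cand <- !lost & (stats::runif(k) < transfer_prob(pool$dist, params$transfer))
  cnt_base <- k - cumsum(lost)   # count when species i reaches sub-step (c)
  donors <- integer(0)
  if (any(cand)) {
    granted <- 0L
    for (i in which(cand)) {
      if (cnt_base[i] + granted < params$max_species) {
        donors <- c(donors, i)
        granted <- granted + 1L
      }
    }
  }
  keep <- which(!lost)
  pool$positions <- cbind(pool$positions[, keep, drop = FALSE],
                          pool$positions[, donors, drop = FALSE])
  pool$dist <- c(pool$dist[keep], pool$dist[donors])
  pool
}

#' Run the selfish-operon simulation
#'
#' Initializes `init_species` species with independent uniform random gene
#' arrangements and iterates [selfish_step()] for `n_steps` steps, recording
#' after every step the positive-species count, the mean minimum arc
#' distance across the pool, and the proportion of species clustered under
#' 3 minutes (`3 * length_kb / 100` kb). If the pool goes extinct the
#' trajectory is truncated at the extinction step and flagged.
#'
#' The time step of this model is not calibrated to a physical unit; the
#' trajectory is indexed by "steps".
#'
#' @param params A [selfish_params()].
#' @param seed Integer seed for the run (drawn at random and recorded if
#'   omitted).
#' @return A `trajectory` data frame with columns `step`, `pop_size`,
#'   `mean_min_arc_kb`, `prop_clustered` and attributes `model`
#'   (`"selfish"`), `status` (`"completed"` or `"extinct"`), `seed` and
#'   `params`.
#' @examples
#' tr <- run_selfish(selfish_params(n_steps = 50, init_species = 20), seed = 1)
#' head(tr)
#' @export
run_selfish <- function(params = selfish_params(), seed = NULL) {
  stopifnot(inherits(params, "selfish_params"))
  seed <- resolve_seed(seed)
  set.seed(seed)
  pool <- random_pool(params)
  thr <- 3 * params$genome$minute_kb
  n_steps <- params$n_steps
  step_v <- seq_len(n_steps)
  size_v <- integer(n_steps)
  dist_v <- numeric(n_steps)
  prop_v <- numeric(n_steps)
  status <- "completed"
  last <- n_steps
  for (t in step_v) {
    pool <- selfish_step(pool, params)
    sz <- ncol(pool$positions)
    if (sz == 0L) {
      status <- "extinct"
      last <- t - 1L
      break
    }
    size_v[t] <- sz
    dist_v[t] <- mean(pool$dist)
    prop_v[t] <- mean(pool$dist < thr)
  }
  idx <- seq_len(last)
  new_trajectory(data.frame(step = step_v[idx], pop_size = size_v[idx],
                            mean_min_arc_kb = dist_v[idx],
                            prop_clustered = prop_v[idx]),
                 model = "selfish", status = status, seed = seed,
                 params = params)
}
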