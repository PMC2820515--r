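#' Latin hypercube design over simulation parameters
#'
#' Stratified design: each parameter's range is divided into `k_points`
#' equiprobable strata and exactly one design value falls in each stratum,
#' with uniform placement within the stratum and independent stratum
#' permutations across parameters (sampling the grid "without replacement").
#' Stratification is performed by [lhs::randomLHS()]. Parameters whose range
#' spans at least two orders of magnitude are sampled on the log scale by
#' default (the stratification then applies to the log-transformed range).
#'
#' @param parameters A data frame with columns `name`, `lower`, `upper`
#'   (and optionally logical `log`), or a named list of `c(lower, upper)`
#'   ranges.
#' @param k_points Number of design points (at least 1).
#' @param sims_per_point Replicate simulations to run at each point.
#' @return An object of class `lhs_design`: list with `parameters`,
#'   `k_points`, `sims_per_point` and `matrix` (a `k_points x n_params`
#'   matrix of parameter values on the natural scale).
#' @examples
#' set.seed(1)
#' lhs_sample(list(rho = c(1e-10, 1e-6), pop_size = c(1e2, 1e6)), 10)
#' @export
lhs_sample <- function(parameters, k_points, sims_per_point = 1L) {
  parameters <- as_param_table(parameters)
  stopifnot(k_points >= 1, sims_per_point >= 1)
  u <- lhs::randomLHS(as.integer(k_points), nrow(parameters))
  m <- matrix(NA_real_, k_points, nrow(parameters),
              dimnames = list(NULL, parameters$name))
  for (j in seq_len(nrow(parameters))) {
    lo <- parameters$lower[j]; hi <- parameters$upper[j]
    m[, j] <- if (parameters$log[j])
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    else lo + u[, j] * (hi - lo)
  }
  structure(list(parameters = parameters,
                 k_points = as.integer(k_points),
                 sims_per_point = as.integer(sims_per_point),
                 matrix = m),
            class = "lhs_design")
}

as_param_table <- function(parameters) {
  if (is.list(parameters) && !is.data.frame(parameters)) {
    stopifnot(!is.null(names(parameters)),
              all(vapply(parameters, length, integer(1)) == 2L))
    parameters <- data.frame(
      name = names(parameters),
      lower = vapply(parameters, `[`, numeric(1), 1L),
      upper = vapply(parameters, `[`, numeric(1), 2L))
  }
  stopifnot(is.data.frame(parameters),
            all(c("name", "lower", "upper") %in% names(parameters)))
  if (is.null(parameters$log))
    parameters$log <- parameters$lower > 0 &
      parameters$upper / parameters$lower >= 100
  if (any(parameters$lower >= parameters$upper))
    stop("invalid parameter range: lower must be < upper")
  if (any(parameters$log & parameters$lower <= 0))
    stop("log-scale sampling requires positive ranges")
  rownames(parameters) <- NULL
  parameters
}

#' Kendall rank correlation with p-value
#'
#' Tau-b (with tie correction) and a two-sided p-value, as used to screen
#' the direction and detectability of parameter effects in latin-hypercube
#' sensitivity analyses. Wraps [stats::cor()] and [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A list with elements `tau` and `p_value`.
#' @examples
#' kendall_tau(1:3, c(3, 1, 2))$tau  # -1/3
#' @export
kendall_tau <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("kendall_tau: tau is undefined for a constant input vector")
  tau <- stats::cor(x, y, method = "kendall")
  p <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))$p.value
  list(tau = tau, p_value = p)
}

# map a canonical parameter name to its slot in a params object
apply_param <- function(params, name, value) {
  g <- params$genome
  switch(name,
    rho = { params$rho <- value },
    pop_size = {
      params$pop_size <- if (inherits(params, "moran_params"))
        as.integer(round(value)) else value
      if (!is.null(params$popgen)) params$popgen <- popgen_params(params$pop_size)
    },
    p_max = { params$transfer$p_max <- value },
    lambda_transfer = { params$transfer$lambda_transfer <- value },
    p_loss = { params$transfer$p_loss <- value },
    lambda_fitness = { params$fitness$lambda_fitness <- value },
    sig_midpoint_kb = { params$fitness$sig_midpoint_kb <- value },
    sig_steepness = { params$fitness$sig_steepness <- value },
    n_genes = {
      params$genome <- genome_config(g$length_kb, as.integer(round(value)),
                                     g$tolerance_kb)
    },
    length_kb = {
      params$genome <- genome_config(as.integer(round(value)), g$n_genes,
                                     g$tolerance_kb)
    },
    tolerance_kb = {
      params$genome <- genome_config(g$length_kb, g$n_genes, value)
    },
    stop("unknown sweep parameter: ", name)
  )
  params
}

final_distance <- function(traj) {
  model <- attr(traj, "model")
  if (model == "subst") return(attr(traj, "final_distance_kb"))
  if (nrow(traj) == 0L) return(NA_real_)
  traj$mean_min_arc_kb[nrow(traj)]
}

#' Parameter sweep over one of the simulators
#'
#' Runs `sims_per_point` replicate simulations at every design point of a
#' latin hypercube design (or every row of a plain parameter grid), records
#' the final mean minimum arc distance of each replicate, and summarizes
#' each point by the replicate mean and the central 90% interval (5th--95th
#' percentiles), the convention used for the simulation error bars. Runs
#' that end in extinction contribute `NA` and are counted in `n_failed`,
#' never silently dropped.
#'
#' Replicate seeds are derived from `master_seed` by a counter scheme
#' (`master_seed + (point - 1) * sims_per_point + replicate - 1`), so
#' results are reproducible and independent of execution order.
#'
#' @param model One of `"selfish"`, `"moran"`, `"subst"`.
#' @param design An [lhs_sample()] design, or a data frame / matrix whose
#'   columns are canonical parameter names (`rho`, `pop_size`, `p_max`,
#'   `lambda_transfer`, `p_loss`, `lambda_fitness`, `n_genes`, `length_kb`,
#'   `tolerance_kb`, ...).
#' @param base_params Base parameter object for the model (defaults to the
#'   model's default constructor); design columns override its fields
#'   point by point.
#' @param master_seed Integer master seed.
#' @param sims_per_point Replicates per design point (taken from the design
#'   if it is an `lhs_design`).
#' @return A data frame with one row per design point: the parameter
#'   columns, `mean_final_kb`, `q05_kb`, `q95_kb`, `n_ok`, `n_failed`.
#' @export
param_sweep <- function(model = c("selfish", "moran", "subst"), design,
                        base_params = NULL, master_seed = 1L,
                        sims_per_point = NULL) {
  model <- match.arg(model)
  if (inherits(design, "lhs_design")) {
    if (is.null(sims_per_point)) sims_per_point <- design$sims_per_point
    grid <- design$matrix
  } else {
    grid <- as.matrix(design)
    if (is.null(sims_per_point)) sims_per_point <- 1L
  }
  stopifnot(!is.null(colnames(grid)), sims_per_point >= 1)
  if (is.null(base_params))
    base_params <- switch(model, selfish = selfish_params(),
                          moran = moran_params(), subst = subst_params())
  runner <- switch(model, selfish = run_selfish, moran = run_moran,
                   subst = run_subst)
  master_seed <- as.integer(master_seed)
  k <- nrow(grid)
  out <- data.frame(grid)
  mean_v <- q05 <- q95 <- numeric(k)
  n_ok <- n_failed <- integer(k)
  for (i in seq_len(k)) {
    params <- base_params
    for (nm in colnames(grid)) params <- apply_param(params, nm, grid[i, nm])
    finals <- vapply(seq_len(sims_per_point), function(j) {
      seed <- master_seed + (i - 1L) * sims_per_point + (j - 1L)
      final_distance(suppressWarnings(runner(params, seed = seed)))
    }, numeric(1))
    ok <- finals[!is.na(finals)]
    n_ok[i] <- length(ok); n_failed[i] <- sims_per_point - length(ok)
    if (length(ok) > 0L) {
      mean_v[i] <- mean(ok)
      qq <- stats::quantile(ok, c(0.05, 0.95), names = FALSE, type = 7)
      q05[i] <- qq[1L]; q95[i] <- qq[2L]
    } else {
      mean_v[i] <- q05[i] <- q95[i] <- NA_real_
    }
  }
  out$mean_final_kb <- mean_v
  out$q05_kb <- q05
  out$q95_kb <- q95
  out$n_ok <- n_ok
  out$n_failed <- n_failed
  out
}
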