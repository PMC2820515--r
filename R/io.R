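# trajectory class and run serialization ------------------------------------

new_trajectory <- function(df, model, status, seed, params,
                           final_distance_kb = NULL) {
  structure(df, model = model, status = status, seed = seed,
            params = params, final_distance_kb = final_distance_kb,
            class = c("trajectory", "data.frame"))
}

resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  as.integer(seed)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory [", attr(x, "model"), "], ", nrow(x), " rows, status ",
      attr(x, "status"), ", seed ", attr(x, "seed"), "\n", sep = "")
  NextMethod()
}

trajectory_schemas <- list(
  selfish = c("step", "pop_size", "mean_min_arc_kb", "prop_clustered"),
  moran = c("generation", "mean_min_arc_kb"),
  subst = c("time", "distance_kb", "s", "fixed"))

#' Write / read a trajectory as TSV
#'
#' Plain UTF-8 TSV with a header row, tab delimiter, `.` decimal separator
#' and one row per sampling time. Distances and other numeric summaries are
#' serialized with 6 significant digits, so `read_trajectory(write_trajectory(x))`
#' recovers values to within 1e-6 relative error. Run metadata (model,
#' seed, parameters) belongs in the run manifest, not the data file.
#'
#' @param traj A trajectory as returned by [run_selfish()], [run_moran()]
#'   or [run_subst()] (any data frame matching one of their schemas).
#' @param path Output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory data frame (with the `model` attribute inferred
#'   from the header).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  out <- as.data.frame(traj)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                      fileEncoding = "UTF-8"),
    warning = function(w) stop("malformed trajectory file ", path, ": ",
                               conditionMessage(w)),
    error = function(e) stop("malformed trajectory file ", path, ": ",
                             conditionMessage(e)))
  model <- NULL
  for (m in names(trajectory_schemas))
    if (identical(names(df), trajectory_schemas[[m]])) model <- m
  if (is.null(model))
    stop("trajectory file ", path, " does not match any known schema; ",
         "header was: ", paste(names(df), collapse = ", "))
  for (col in setdiff(names(df), c("s", "fixed"))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L)
      stop("malformed trajectory row at line ", bad[1L] + 1L, " of ", path,
           " (column '", col, "')")
    df[[col]] <- vals
  }
  if ("fixed" %in% names(df)) df$fixed <- as.logical(df$fixed)
  attr(df, "model") <- model
  df
}

#' Write / read a run manifest
#'
#' Every simulation output directory carries one JSON manifest recording
#' the model, the full flattened parameter set, the seed, the package
#' version, timestamps and the output file list — enough to reproduce the
#' run exactly.
#'
#' @param path Manifest path (conventionally `manifest.json`).
#' @param model Model name.
#' @param params The run's parameter object.
#' @param seed The run's seed.
#' @param outputs Character vector of output file names.
#' @param started,finished Timestamps (default: now).
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest as a list.
#' @export
write_manifest <- function(path, model, params, seed, outputs = character(),
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    model = model,
    parameters = flatten_params(params),
    seed = seed,
    package = "operonevo",
    version = as.character(utils::packageVersion("operonevo")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

flatten_params <- function(params) {
  flat <- list()
  rec <- function(x, prefix = "") {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(v)) rec(v, key) else flat[[key]] <<- v
    }
  }
  rec(unclass(params))
  flat
}

# configuration --------------------------------------------------------------

config_sections <- c("genome", "transfer", "fitness", "selfish", "moran",
                     "subst")

#' Load a simulation configuration file
#'
#' Configurations are YAML with one section per parameter group (`genome`,
#' `transfer`, `fitness`, `selfish`, `moran`, `subst`); keys within a
#' section are the arguments of the corresponding `_params()`/`_config()`
#' constructor (`selfish`, `moran` and `subst` sections take their scalar
#' arguments; the nested `genome`, `transfer` and `fitness` objects come
#' from their own sections). Missing sections and keys take the package
#' defaults; an empty file yields the full default set. Unknown sections or
#' keys, and values violating a constructor's invariants, are rejected with
#' an error naming the offender.
#'
#' @param path Path to a YAML configuration file.
#' @return A named list with elements `genome`, `transfer`, `fitness`,
#'   `selfish`, `moran`, `subst` — fully validated parameter objects.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("genome:\n  length_kb: 1000\n  n_genes: 4", cfg_file)
#' load_config(cfg_file)$genome$n_genes  # 4
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown) > 0L)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         "; valid sections are ", paste(config_sections, collapse = ", "))
  take <- function(section, constructor, drop = character()) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    valid <- setdiff(names(formals(constructor)), drop)
    bad <- setdiff(names(args), valid)
    if (length(bad) > 0L)
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "))
    tryCatch(do.call(constructor, args),
             error = function(e)
               stop("invalid value in config section '", section, "': ",
                    conditionMessage(e)),
             warning = function(w)
               stop("invalid value in config section '", section, "': ",
                    conditionMessage(w)))
  }
  genome <- take("genome", genome_config)
  transfer <- take("transfer", transfer_params)
  fitness <- take("fitness", fitness_params)
  nested <- c("genome", "transfer", "fitness")
  build <- function(section, constructor, extra) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    valid <- setdiff(names(formals(constructor)), nested)
    bad <- setdiff(names(args), valid)
    if (length(bad) > 0L)
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "))
    tryCatch(do.call(constructor, c(args, extra)),
             error = function(e)
               stop("invalid value in config section '", section, "': ",
                    conditionMessage(e)))
  }
  list(genome = genome, transfer = transfer, fitness = fitness,
       selfish = build("selfish", selfish_params,
                       list(transfer = transfer, genome = genome)),
       moran = build("moran", moran_params,
                     list(fitness = fitness, genome = genome)),
       subst = build("subst", subst_params,
                     list(fitness = fitness, genome = genome)))
}

#' Default configuration
#'
#' The full default parameter set, as produced by loading an empty
#' configuration file.
#'
#' @return Same structure as [load_config()].
#' @export
default_config <- function() {
  genome <- genome_config()
  transfer <- transfer_params()
  fitness <- fitness_params()
  list(genome = genome, transfer = transfer, fitness = fitness,
       selfish = selfish_params(transfer = transfer, genome = genome),
       moran = moran_params(fitness = fitness, genome = genome),
       subst = subst_params(fitness = fitness, genome = genome))
}
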