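#' Circular-chromosome configuration
#'
#' Defines the shared genome representation used by all simulators: a circular
#' chromosome of `length_kb` kilobases carrying `n_genes` pathway genes, each
#' 1 kb long and identified with its (1-based, integer) midpoint position.
#' The replication origin sits at position 0 (equivalently `length_kb`) and
#' the terminus at `length_kb / 2`. Inversions that displace the terminus or
#' origin by more than `tolerance_kb` are treated as lethal (replichore
#' imbalance). One "minute" is 1/100 of the chromosome, the classical
#' *E. coli* mapping unit.
#'
#' @param length_kb Chromosome length in kb (positive integer-valued scalar).
#' @param n_genes Number of pathway genes (integer, at least 2 for a
#'   meaningful arc distance; 1 is allowed but degenerate).
#' @param tolerance_kb Maximum tolerated origin/terminus displacement after an
#'   inversion, in kb (non-negative).
#'
#' @return An object of class `genome_config`: a list with fields
#'   `length_kb`, `n_genes`, `origin_kb` (0), `terminus_kb` (`length_kb/2`),
#'   `tolerance_kb` and the derived `minute_kb` (`length_kb/100`).
#' @examples
#' cfg <- genome_config(length_kb = 4900, n_genes = 3)
#' cfg$minute_kb  # 49
#' @export
genome_config <- function(length_kb = 4900, n_genes = 3, tolerance_kb = 100) {
  stopifnot(is.numeric(length_kb), length(length_kb) == 1, length_kb >= 1,
            length_kb == round(length_kb),
            is.numeric(n_genes), length(n_genes) == 1,
            n_genes == round(n_genes), n_genes >= 1,
            is.numeric(tolerance_kb), length(tolerance_kb) == 1,
            tolerance_kb >= 0)
  if (n_genes > length_kb)
    stop("invalid genome config: n_genes (", n_genes,
         ") exceeds length_kb (", length_kb,
         "); only a single gene can occupy any given position")
  structure(
    list(length_kb = as.integer(length_kb),
         n_genes = as.integer(n_genes),
         origin_kb = 0,
         terminus_kb = length_kb / 2,
         tolerance_kb = tolerance_kb,
         minute_kb = length_kb / 100),
    class = "genome_config")
}

#' @export
print.genome_config <- function(x, ...) {
  cat("Circular genome: ", x$length_kb, " kb, ", x$n_genes,
      " pathway genes, imbalance tolerance ", x$tolerance_kb,
      " kb (1 minute = ", x$minute_kb, " kb)\n", sep = "")
  invisible(x)
}

#' Gene arrangement on a circular chromosome
#'
#' An arrangement is a set of distinct integer gene positions in
#' `[1, length_kb]` together with its genome configuration. Positions are
#' stored sorted; genes are identified with their positions.
#'
#' @param positions Integer vector of distinct gene positions.
#' @param config A [genome_config()].
#' @return An object of class `arrangement`.
#' @examples
#' arrangement(c(10, 30, 90), genome_config(100, 3))
#' @export
arrangement <- function(positions, config) {
  stopifnot(inherits(config, "genome_config"))
  positions <- as.integer(positions)
  if (length(positions) != config$n_genes)
    stop("arrangement must carry exactly n_genes = ", config$n_genes,
         " positions, got ", length(positions))
  if (anyDuplicated(positions))
    stop("gene positions must be distinct: only a single gene can occupy ",
         "any given position")
  if (any(positions < 1L | positions > config$length_kb))
    stop("gene positions must lie in [1, ", config$length_kb, "]")
  structure(list(positions = sort(positions), config = config),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat("Arrangement on ", x$config$length_kb, " kb circle: positions ",
      paste(x$positions, collapse = ", "),
      " (min arc ", min_arc_distance(x), " kb)\n", sep = "")
  invisible(x)
}

#' Draw a uniform random gene arrangement
#'
#' Places `n_genes` genes uniformly at random on the circle, without
#' replacement (no two genes share a position). Uses the current R random
#' number stream; seed with [set.seed()] for reproducibility.
#'
#' @param config A [genome_config()].
#' @return An [arrangement()].
#' @examples
#' set.seed(1)
#' random_arrangement(genome_config(100, 3))
#' @export
random_arrangement <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  arrangement(sample.int(config$length_kb, config$n_genes), config)
}

# Vectorized arc distance over the columns of an n x k matrix of sorted
# positions. Internal hot path shared by the simulators.
arc_dist_cols <- function(pos, length_kb) {
  n <- nrow(pos)
  if (n < 2L) return(rep(0, ncol(pos)))
  gaps <- rbind(pos[-1L, , drop = FALSE] - pos[-n, , drop = FALSE],
                length_kb - pos[n, ] + pos[1L, ])
  length_kb - apply(gaps, 2L, max)
}

#' Minimum arc distance of an arrangement
#'
#' The length (kb) of the shortest contiguous arc of the circle containing
#' all pathway genes; equivalently the genome length minus the largest gap
#' between neighbouring genes. This is the clustering statistic tracked by
#' all three simulators. With fewer than two genes the distance is 0 by
#' convention.
#'
#' @param arr An [arrangement()].
#' @return Distance in kb, in `[0, length_kb)`.
#' @examples
#' min_arc_distance(arrangement(c(10, 30), genome_config(100, 2)))  # 20
#' @export
min_arc_distance <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  as.numeric(arc_dist_cols(matrix(arr$positions, ncol = 1L),
                           arr$config$length_kb))
}

#' Draw a pair of inversion breakpoints
#'
#' Two integers are drawn uniformly on `{1, ..., length_kb}` and 0.5 is
#' subtracted from each so that breakpoints fall between genes and can never
#' coincide with a gene position. Returned ordered, `a <= b`.
#'
#' @param config A [genome_config()].
#' @return Numeric vector `c(a, b)` of half-integer breakpoints.
#' @export
draw_breakpoints <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  sort(sample.int(config$length_kb, 2L, replace = TRUE) - 0.5)
}

#' Is an inversion viable?
#'
#' An inversion of the segment `(a, b)` is viable when it leaves both
#' replication landmarks (origin at 0, terminus at L/2) displaced by at most
#' the configured tolerance. With the origin fixed at 0 it is never interior
#' to a linear segment, so the rule is the three-clause disjunction: the
#' segment lies entirely before the terminus, or entirely after it, or the
#' reflected terminus `a + b - L/2` is within `tolerance_kb` of its original
#' position (displacement `|a + b - L|`).
#'
#' @param a,b Half-integer breakpoints with `a <= b` (see
#'   [draw_breakpoints()]).
#' @param config A [genome_config()].
#' @return `TRUE` if viable, `FALSE` if the rearrangement is lethal.
#' @examples
#' cfg <- genome_config(100, 3, tolerance_kb = 10)
#' inversion_viable(5.5, 25.5, cfg)   # TRUE: terminus untouched
#' inversion_viable(40.5, 70.5, cfg)  # FALSE: terminus moved 11 kb
#' @export
inversion_viable <- function(a, b, config) {
  stopifnot(inherits(config, "genome_config"), a <= b,
            a > 0, b < config$length_kb)
  half <- config$length_kb / 2
  (b < half) || (a > half) ||
    (abs(a + b - config$length_kb) <= config$tolerance_kb)
}

#' Apply an inversion to an arrangement
#'
#' Every gene at position `g` strictly between the breakpoints is reflected
#' to `a + b - g`; genes outside the segment are unchanged. The operator is
#' total (viability is the caller's concern) and is an involution: applying
#' the same inversion twice restores the original arrangement.
#'
#' @param arr An [arrangement()].
#' @param a,b Half-integer breakpoints with `a <= b`.
#' @return The rearranged [arrangement()].
#' @examples
#' arr <- arrangement(c(10, 20, 90), genome_config(100, 3))
#' apply_inversion(arr, 5.5, 25.5)$positions  # 11 21 90
#' @export
apply_inversion <- function(arr, a, b) {
  stopifnot(inherits(arr, "arrangement"), a <= b)
  arrangement(invert_positions(arr$positions, a, b), arr$config)
}

# reflection a + b - g for positions inside (a, b); returns sorted integers
invert_positions <- function(positions, a, b) {
  inside <- positions > a & positions < b
  positions[inside] <- as.integer(a + b - positions[inside])
  sort(positions)
}

#' Apply a random translocation to an arrangement
#'
#' One pathway gene is chosen uniformly and moved to a position chosen
#' uniformly among the unoccupied positions of the chromosome (co-occupancy
#' is forbidden, and the gene's own current slot does not count as a
#' destination). In the degenerate case where every position is occupied the
#' arrangement is returned unchanged.
#'
#' @param arr An [arrangement()].
#' @return The rearranged [arrangement()].
#' @export
apply_translocation <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  arrangement(translocate_positions(arr$positions, arr$config$length_kb),
              arr$config)
}

translocate_positions <- function(positions, length_kb) {
  free_n <- length_kb - length(positions)
  if (free_n == 0L) return(positions)
  mover <- positions[sample.int(length(positions), 1L)]
  # j-th unoccupied slot, without materializing setdiff(1:L, positions);
  # the mover's own current slot counts as occupied
  dest <- sample.int(free_n, 1L)
  for (p in positions) if (p <= dest) dest <- dest + 1L
  sort(c(positions[positions != mover], as.integer(dest)))
}

#' Proportion of arrangements clustered under a threshold
#'
#' Fraction of arrangements whose minimum arc distance is strictly below
#' `threshold_kb`. The default threshold is 3 minutes (`3 * length_kb / 100`
#' kb), the clustering criterion used throughout the simulators.
#'
#' @param arrs A list of [arrangement()] objects, or a numeric vector of
#'   precomputed minimum arc distances (in which case `threshold_kb` is
#'   required).
#' @param threshold_kb Clustering threshold in kb; defaults to
#'   `3 * minute_kb` of the arrangements' genome configuration.
#' @return A fraction in `[0, 1]`.
#' @export
proportion_clustered <- function(arrs, threshold_kb = NULL) {
  if (is.numeric(arrs)) {
    if (length(arrs) == 0L) stop("empty input: proportion undefined")
    if (is.null(threshold_kb))
      stop("threshold_kb is required when passing raw distances")
    return(mean(arrs < threshold_kb))
  }
  if (length(arrs) == 0L) stop("empty input: proportion undefined")
  stopifnot(all(vapply(arrs, inherits, logical(1), "arrangement")))
  if (is.null(threshold_kb))
    threshold_kb <- 3 * arrs[[1L]]$config$minute_kb
  mean(vapply(arrs, min_arc_distance, numeric(1)) < threshold_kb)
}

#' Serialize an arrangement to a one-line TSV record
#'
#' The record is `length_kb<TAB>comma-separated-positions`. No standard
#' bioinformatics format applies to abstract gene positions, so this minimal
#' plain-text form is used.
#'
#' @param arr An [arrangement()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_arrangement <- function(arr, path) {
  stopifnot(inherits(arr, "arrangement"))
  writeLines(paste0(arr$config$length_kb, "\t",
                    paste(arr$positions, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_arrangement
#' @param tolerance_kb Imbalance tolerance for the reconstructed
#'   [genome_config()] (not stored in the record).
#' @return For `read_arrangement`, the [arrangement()] read from `path`.
#' @export
read_arrangement <- function(path, tolerance_kb = 100) {
  line <- readLines(path, n = 1L)
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("malformed arrangement record in ", path,
         ": expected 'length_kb<TAB>positions'")
  positions <- as.integer(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
  cfg <- genome_config(length_kb = as.integer(parts[1L]),
                       n_genes = length(positions),
                       tolerance_kb = tolerance_kb)
  arrangement(positions, cfg)
}
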