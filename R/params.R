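#' Simulation parameters
#'
#' Describes one parameter combination for the lattice simulator: a
#' `grid_width` x `grid_height` landscape with one diploid hermaphrodite per
#' cell, `n_loci` unlinked codominant loci, per-transmission mutation
#' probability `mu` (infinite-alleles model), and dispersal controlled by the
#' mean parent-offspring distance `delta`.  Parents of the individual filling
#' a cell are drawn from a discretized bivariate normal kernel centred on the
#' cell with axial scale `sigma = delta / sqrt(pi/2)`, so that the mean
#' Euclidean parent-offspring distance equals `delta`.
#'
#' @param grid_width,grid_height Landscape dimensions in cells; must be even
#'   so the two barrier midlines split the landscape into four equal
#'   quadrants.
#' @param n_loci Number of unlinked loci tracked.
#' @param mu Per-allele, per-transmission mutation probability in `[0, 1]`.
#' @param delta Mean parent-offspring Euclidean distance in cells; `> 0`.
#' @param b Barrier permeability in `[0, 1]`: the proportion of attempted
#'   cross-barrier parent draws that are allowed. `b = 0` is an impermeable
#'   barrier.
#' @param burn_in_generations Generations run before barriers are imposed.
#' @param export_generations Sorted post-barrier generation stamps at which
#'   samples are exported; must include 0 (the pre-barrier state).
#' @param sample_size Individuals sampled per exported data set.
#' @param n_replicates Independent simulation replicates.
#' @param seed Master seed; every random stream is derived from it.
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(grid_width = 20, grid_height = 20, n_loci = 5,
#'                 burn_in_generations = 100, sample_size = 50)
#' p$sigma
#' @export
sim_params <- function(grid_width = 100, grid_height = 100, n_loci = 20,
                       mu = 1e-4, delta = 11, b = 0,
                       burn_in_generations = 20000,
                       export_generations = c(0, 100, 500, 1000, 3000, 5000),
                       sample_size = 200, n_replicates = 25, seed = 1) {
  if (grid_width < 2 || grid_height < 2 ||
      grid_width %% 2 != 0 || grid_height %% 2 != 0)
    stop("grid_width and grid_height must be even and >= 2", call. = FALSE)
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]", call. = FALSE)
  if (b < 0 || b > 1) stop("b must be in [0, 1]", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (burn_in_generations < 0) stop("burn_in_generations must be >= 0",
                                    call. = FALSE)
  eg <- as.integer(export_generations)
  if (is.unsorted(eg, strictly = TRUE) || eg[1] != 0)
    stop("export_generations must be strictly ascending and include 0",
         call. = FALSE)
  if (sample_size < 1 || sample_size > grid_width * grid_height)
    stop("sample_size must be in [1, grid_width * grid_height]",
         call. = FALSE)
  structure(list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    n_loci = as.integer(n_loci),
    mu = mu,
    delta = delta,
    sigma = delta / sqrt(pi / 2),
    b = b,
    burn_in_generations = as.integer(burn_in_generations),
    export_generations = eg,
    sample_size = as.integer(sample_size),
    n_replicates = as.integer(n_replicates),
    seed = seed
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Lattice simulation parameters\n")
  cat(sprintf("  landscape : %d x %d cells (N = %d)\n", x$grid_width,
              x$grid_height, x$grid_width * x$grid_height))
  cat(sprintf("  loci      : %d, mu = %g (theta = %g)\n", x$n_loci, x$mu,
              4 * x$grid_width * x$grid_height * x$mu))
  cat(sprintf("  dispersal : delta = %g cells (sigma = %.4f)\n", x$delta,
              x$sigma))
  cat(sprintf("  barrier   : permeability b = %g\n", x$b))
  cat(sprintf("  schedule  : %d burn-in generations, exports at %s\n",
              x$burn_in_generations,
              paste(x$export_generations, collapse = ", ")))
  cat(sprintf("  sampling  : %d individuals, %d replicates, seed %s\n",
              x$sample_size, x$n_replicates, format(x$seed)))
  invisible(x)
}

#' Barrier specification
#'
#' A cross-shaped pair of barrier lines splitting the landscape into four
#' quadrants.  With 0-based cells the vertical line runs between columns
#' `split_x - 1` and `split_x` (i.e. at map coordinate `split_x - 0.5`), the
#' horizontal line between rows `split_y - 1` and `split_y`.
#'
#' @param split_x,split_y Cell-boundary positions of the two midlines;
#'   defaults to the landscape midlines of `params`.
#' @param active Whether the barrier currently restricts movement.
#' @param b Permeability in `[0, 1]`.
#' @param params Optional `sim_params` supplying defaults.
#' @return An object of class `barrier_spec`.
#' @examples
#' barrier_spec(params = sim_params(grid_width = 20, grid_height = 20,
#'                                  burn_in_generations = 0))
#' @export
barrier_spec <- function(split_x = NULL, split_y = NULL, active = TRUE,
                         b = if (!is.null(params)) params$b else 0,
                         params = NULL) {
  if (is.null(split_x))
    split_x <- if (!is.null(params)) params$grid_width %/% 2L else
      stop("split_x required when params is NULL", call. = FALSE)
  if (is.null(split_y))
    split_y <- if (!is.null(params)) params$grid_height %/% 2L else
      stop("split_y required when params is NULL", call. = FALSE)
  if (b < 0 || b > 1) stop("b must be in [0, 1]", call. = FALSE)
  structure(list(split_x = as.integer(split_x),
                 split_y = as.integer(split_y),
                 active = isTRUE(active), b = b),
            class = "barrier_spec")
}

#' Quadrant of a cell
#'
#' Maps 0-based cell coordinates onto quadrant labels `0:3`
#' (`(x >= split_x) + 2 * (y >= split_y)`).
#'
#' @param x,y Cell coordinates (0-based; vectors recycled).
#' @param barrier A `barrier_spec`.
#' @return Integer vector of quadrant labels in `0:3`.
#' @examples
#' b <- barrier_spec(split_x = 50, split_y = 50)
#' quadrant_of(c(0, 99, 0, 99), c(0, 0, 99, 99), b)
#' @export
quadrant_of <- function(x, y, barrier) {
  as.integer(x >= barrier$split_x) + 2L * as.integer(y >= barrier$split_y)
}

# The five study parameter combinations.  Burn-in is 20,000 generations for
# mu = 1e-4 and 80,000 for mu = 2.5e-5 (lower mutation rates need longer to
# equilibrate).
.bb_presets <- list(
  "d1-mu1e4"      = list(delta = 1,  mu = 1e-4,   b = 0,    burn_in_generations = 20000L),
  "d1-mu2.5e5"    = list(delta = 1,  mu = 2.5e-5, b = 0,    burn_in_generations = 80000L),
  "d11-mu1e4"     = list(delta = 11, mu = 1e-4,   b = 0,    burn_in_generations = 20000L),
  "d11-mu2.5e5"   = list(delta = 11, mu = 2.5e-5, b = 0,    burn_in_generations = 80000L),
  "d11-mu1e4-b03" = list(delta = 11, mu = 1e-4,   b = 0.03, burn_in_generations = 20000L)
)

#' Study parameter presets
#'
#' The five shipped parameter combinations (dispersal `delta` in `{1, 11}`,
#' mutation rate `mu` in `{1e-4, 2.5e-5}` with impermeable barriers, plus a
#' permeable-barrier combination `delta = 11`, `mu = 1e-4`, `b = 0.03`), each
#' on the default 100 x 100 landscape with 20 loci and samples of 200.
#'
#' @param name Preset name, one of `preset_names()`.
#' @param ... Overrides passed on to [sim_params()] (e.g. smaller grids or
#'   fewer replicates for quick runs).
#' @return A `sim_params` object.
#' @examples
#' preset_names()
#' sim_preset("d11-mu1e4", n_replicates = 3)
#' @export
sim_preset <- function(name, ...) {
  if (!name %in% names(.bb_presets))
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  args <- .bb_presets[[name]]
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

#' @rdname sim_preset
#' @export
preset_names <- function() names(.bb_presets)
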