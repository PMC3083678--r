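#' Initialize a genotype lattice
#'
#' Creates the starting landscape: every individual carries identical
#' homozygous genotypes (allele ID 0 at every locus), so initial
#' heterozygosity is 0 and initial fixation is complete.  Diversity then
#' builds up by mutation and drift during burn-in.
#'
#' @param params A `sim_params` object.
#' @return An object of class `genotype_lattice` with elements `alleles`
#'   (integer array, dim `c(2, n_loci, grid_width, grid_height)`),
#'   `generation` (burn-in clock, starts at 0), `next_allele_id` (per-locus
#'   count of allelic states ever created) and the landscape dimensions.
#' @examples
#' lat <- init_lattice(sim_params(grid_width = 10, grid_height = 10,
#'                                n_loci = 5, burn_in_generations = 0))
#' all(lat$alleles == 0L)
#' @export
init_lattice <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  W <- params$grid_width; H <- params$grid_height; L <- params$n_loci
  structure(list(
    alleles = array(0L, dim = c(2L, L, W, H)),
    generation = 0L,
    next_allele_id = rep(1L, L),
    grid_width = W, grid_height = H, n_loci = L
  ), class = "genotype_lattice")
}

#' @export
print.genotype_lattice <- function(x, ...) {
  cat(sprintf("Genotype lattice: %d x %d cells, %d loci, generation %d\n",
              x$grid_width, x$grid_height, x$n_loci, x$generation))
  cat(sprintf("  allelic states created per locus: %s\n",
              paste(range(x$next_allele_id), collapse = " - ")))
  invisible(x)
}

#' Draw parent cells for an offspring cell
#'
#' Samples candidate parent locations from the discretized bivariate normal
#' dispersal kernel centred on cell `(x, y)`.  Draws landing outside the
#' landscape are rejected and redrawn.  With an active barrier, a draw in a
#' quadrant different from the focal cell's is kept with probability
#' `barrier$b` and otherwise the whole draw is repeated, so `b` is the
#' proportion of attempted barrier crossings that are allowed.
#'
#' @param x,y Focal 0-based cell coordinates.
#' @param sigma Axial kernel scale in cells (`delta / sqrt(pi/2)`);
#'   `sigma = 0` degenerates to always returning the focal cell.
#' @param grid_width,grid_height Landscape dimensions.
#' @param barrier Optional `barrier_spec`; `NULL` (or `active = FALSE`)
#'   disables the crossing rule.
#' @param n Number of independent draws.
#' @param seed Seed for the draw stream.
#' @return An `n` x 2 integer matrix of 0-based parent cells (columns
#'   `x`, `y`).
#' @examples
#' draw_parent_cell(5, 5, sigma = 0, grid_width = 10, grid_height = 10)
#' @export
draw_parent_cell <- function(x, y, sigma, grid_width, grid_height,
                             barrier = NULL, n = 1, seed = 1) {
  if (x < 0 || x >= grid_width || y < 0 || y >= grid_height)
    stop("focal cell outside the landscape", call. = FALSE)
  act <- !is.null(barrier) && isTRUE(barrier$active)
  out <- .bb_draw_parents(as.integer(n), as.integer(x), as.integer(y),
                          as.double(sigma), as.integer(grid_width),
                          as.integer(grid_height), act,
                          if (act) barrier$b else 0,
                          if (act) barrier$split_x else 0L,
                          if (act) barrier$split_y else 0L,
                          as.double(seed))
  colnames(out) <- c("x", "y")
  out
}

# Advance a lattice ngen generations; internal engine shared by
# step_generation / run_burn_in / run_post_barrier.
advance_lattice <- function(lattice, params, barrier, ngen, seed,
                            snapshot_gens = integer(0), diag_every = 0L) {
  act <- !is.null(barrier) && isTRUE(barrier$active)
  res <- .bb_sim_run(as.integer(lattice$alleles),
                     lattice$grid_width, lattice$grid_height,
                     lattice$n_loci,
                     lattice$next_allele_id,
                     as.double(params$sigma), as.double(params$mu),
                     as.integer(ngen), act,
                     if (act) barrier$b else 0,
                     if (act) barrier$split_x else 0L,
                     if (act) barrier$split_y else 0L,
                     as.double(seed),
                     as.integer(snapshot_gens), as.integer(diag_every))
  out <- lattice
  out$alleles <- array(res$alleles,
                       dim = c(2L, lattice$n_loci, lattice$grid_width,
                               lattice$grid_height))
  out$next_allele_id <- res$next_allele_id
  out$generation <- lattice$generation + as.integer(ngen)
  attr(out, "snapshots") <- res$snapshots
  attr(out, "diagnostics") <- res$diagnostics
  out
}

#' Advance the lattice by whole generations
#'
#' Synchronous, non-overlapping generations: each cell of the new landscape
#' is filled by a zygote whose two parents are drawn independently with
#' [draw_parent_cell()] (self-fertilization is possible), each parent
#' transmitting one uniformly chosen allele per unlinked locus, and each
#' transmitted allele mutating with probability `mu` to a brand-new allelic
#' state (infinite-alleles model).
#'
#' @param lattice A `genotype_lattice`.
#' @param params A `sim_params`.
#' @param barrier Optional `barrier_spec`.
#' @param n_generations Number of generations to advance.
#' @param seed Seed for this stream.
#' @return The advanced `genotype_lattice`.
#' @examples
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 2, mu = 0,
#'                 delta = 1, burn_in_generations = 0, sample_size = 10)
#' lat <- step_generation(init_lattice(p), p, n_generations = 3)
#' lat$generation
#' @export
step_generation <- function(lattice, params, barrier = NULL,
                            n_generations = 1, seed = 1) {
  out <- advance_lattice(lattice, params, barrier, n_generations, seed)
  attr(out, "snapshots") <- NULL
  attr(out, "diagnostics") <- NULL
  out
}

#' Run the burn-in phase
#'
#' Advances a freshly initialized lattice `burn_in_generations` generations
#' with no barrier, recording the lattice-wide mean number of alleles (Na)
#' and mean gene diversity (H) at regular checkpoints so that the approach
#' to mutation-drift quasi-equilibrium can be inspected.  At the end the
#' final values are compared with the neutral-theory expectations for a
#' panmictic population of the same size (Ewens expectation for Na,
#' `theta / (1 + theta)` for H, `theta = 4 N mu`); a deviation beyond
#' `3 * warn_sd_factor` approximate standard deviations raises a warning
#' (never an error): under strong spatial structure (small `delta`) the
#' landscape-wide diversity legitimately exceeds the panmictic expectation.
#'
#' @param params A `sim_params`.
#' @param seed Seed for the burn-in stream; defaults to a stream derived
#'   from `params$seed`.
#' @param diag_every Checkpoint cadence in generations (0 disables all but
#'   the final checkpoint).
#' @param equilibrium_warn Set `FALSE` to skip the deviation warning.
#' @param warn_sd_factor Multiplier on the approximate SDs used in the check.
#' @return The burned-in `genotype_lattice`, with a `diagnostics` attribute
#'   (matrix with columns `generation`, `mean_na`, `mean_h`).
#' @examples
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 3, mu = 1e-3,
#'                 delta = 3, burn_in_generations = 50, sample_size = 20)
#' lat <- run_burn_in(p, equilibrium_warn = FALSE)
#' attr(lat, "diagnostics")
#' @export
run_burn_in <- function(params, seed = derive_seed(params$seed, 1),
                        diag_every = 1000L, equilibrium_warn = TRUE,
                        warn_sd_factor = 1) {
  lattice <- init_lattice(params)
  ngen <- params$burn_in_generations
  if (ngen == 0L) {
    attr(lattice, "diagnostics") <-
      matrix(numeric(0), 0, 3,
             dimnames = list(NULL, c("generation", "mean_na", "mean_h")))
    return(lattice)
  }
  out <- advance_lattice(lattice, params, barrier = NULL, ngen = ngen,
                         seed = seed,
                         diag_every = max(as.integer(diag_every), 0L))
  attr(out, "snapshots") <- NULL
  if (equilibrium_warn) {
    dg <- attr(out, "diagnostics")
    n2 <- 2 * params$grid_width * params$grid_height
    theta <- 2 * n2 * params$mu
    if (theta > 0 && nrow(dg) > 0) {
      exp_na <- ewens_expected_alleles(theta, n2)
      exp_h <- expected_heterozygosity(theta)
      # per-locus SDs shrink by sqrt(n_loci) in the means
      sd_na <- sqrt(ewens_allele_variance(theta, n2) / params$n_loci)
      sd_h <- sqrt(2 * theta / ((1 + theta)^2 * (2 + theta) * (3 + theta)) /
                     params$n_loci)
      fin <- dg[nrow(dg), ]
      dev_na <- abs(fin["mean_na"] - exp_na) / sd_na
      dev_h <- abs(fin["mean_h"] - exp_h) / sd_h
      lim <- 3 * warn_sd_factor
      if (dev_na > lim || dev_h > lim)
        warning(sprintf(paste0(
          "burn-in diversity deviates from panmictic expectation: ",
          "Na %.2f vs %.2f, H %.3f vs %.3f (spatial structure inflates ",
          "landscape-wide diversity; expected for small delta)"),
          fin["mean_na"], exp_na, fin["mean_h"], exp_h), call. = FALSE)
    }
  }
  out
}

#' Impose barriers and export time-stamped snapshots
#'
#' Resets the generation clock to 0 at barrier imposition, then advances the
#' quasi-equilibrium lattice under the barrier-crossing rule, returning one
#' lattice snapshot per requested post-barrier export generation.  The
#' generation-0 snapshot is the pre-barrier input state.
#'
#' @param lattice A burned-in `genotype_lattice`.
#' @param params A `sim_params` (supplies `export_generations`).
#' @param barrier A `barrier_spec`; defaults to the landscape midlines with
#'   permeability `params$b`.
#' @param seed Seed for the post-barrier stream.
#' @return A named list of `genotype_lattice` snapshots, one per export
#'   generation, each with its post-barrier `generation` stamp.
#' @examples
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 2, mu = 1e-3,
#'                 delta = 2, burn_in_generations = 20,
#'                 export_generations = c(0, 10), sample_size = 10)
#' lat <- run_burn_in(p, equilibrium_warn = FALSE)
#' snaps <- run_post_barrier(lat, p)
#' names(snaps)
#' @export
run_post_barrier <- function(lattice, params,
                             barrier = barrier_spec(params = params),
                             seed = derive_seed(params$seed, 3)) {
  eg <- params$export_generations
  lattice$generation <- 0L   # post-barrier clock
  snaps <- vector("list", length(eg))
  names(snaps) <- paste0("gen", eg)
  snaps[[1]] <- lattice
  pos <- eg[eg > 0L]
  if (length(pos)) {
    res <- advance_lattice(lattice, params, barrier, max(pos), seed,
                           snapshot_gens = pos)
    raw <- attr(res, "snapshots")
    for (i in seq_along(pos)) {
      sl <- lattice
      sl$alleles <- array(raw[[i]],
                          dim = c(2L, lattice$n_loci, lattice$grid_width,
                                  lattice$grid_height))
      sl$generation <- pos[i]
      # next_allele_id at intermediate snapshots is only needed to continue
      # a simulation; keep the final-state counters as an upper bound.
      sl$next_allele_id <- res$next_allele_id
      snaps[[i + 1L]] <- sl
    }
  }
  snaps
}

# genotype rows for 0-based cells given as a matrix [, c(x, y)]
extract_genotypes <- function(lattice, cells) {
  W <- lattice$grid_width; L <- lattice$n_loci
  base <- 2L * L * (cells[, 1] + W * cells[, 2])   # 0-based flat offsets
  idx <- outer(seq_len(2L * L), base, "+")
  geno <- matrix(as.vector(lattice$alleles)[idx], nrow = nrow(cells),
                 ncol = 2L * L, byrow = TRUE)
  colnames(geno) <- paste0("L", rep(seq_len(L), each = 2), ".",
                           rep(1:2, L))
  geno
}

#' Sample individuals from lattice snapshots
#'
#' Draws one set of cell coordinates without replacement and reuses the same
#' coordinates for every snapshot of the replicate, so exported data sets at
#' different time points are longitudinally comparable.  True quadrant
#' labels are attached from the barrier geometry.
#'
#' @param snapshots A list of `genotype_lattice` snapshots (the output of
#'   [run_post_barrier()]), or a single lattice.
#' @param sample_size Number of individuals to sample.
#' @param barrier A `barrier_spec` used for the true quadrant labels.
#' @param seed Seed for the coordinate draw.
#' @param replicate_id Identifier stored in each returned sample.
#' @return A list of `sample_set` objects (one per snapshot), each with
#'   elements `coords` (data.frame `id`, `x`, `y`, `quadrant`; 0-based
#'   cells), `genotypes` (`sample_size` x `2 * n_loci` integer matrix),
#'   `n_loci`, `generation` and `replicate_id`.
#' @examples
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 2, mu = 1e-3,
#'                 delta = 2, burn_in_generations = 10,
#'                 export_generations = 0L, sample_size = 15)
#' lat <- run_burn_in(p, equilibrium_warn = FALSE)
#' s <- sample_individuals(list(gen0 = lat), 15,
#'                         barrier_spec(params = p), seed = 1)
#' s[[1]]
#' @export
sample_individuals <- function(snapshots, sample_size, barrier, seed = 1,
                               replicate_id = 1L) {
  if (inherits(snapshots, "genotype_lattice")) snapshots <- list(snapshots)
  lat0 <- snapshots[[1]]
  N <- lat0$grid_width * lat0$grid_height
  if (sample_size > N)
    stop("sample_size exceeds the number of individuals", call. = FALSE)
  set.seed(derive_seed31(seed, 0))
  flat <- sample.int(N, sample_size) - 1L
  cells <- cbind(x = flat %% lat0$grid_width,
                 y = flat %/% lat0$grid_width)
  coords <- data.frame(id = seq_len(sample_size),
                       x = cells[, 1], y = cells[, 2],
                       quadrant = quadrant_of(cells[, 1], cells[, 2],
                                              barrier))
  lapply(snapshots, function(lat) {
    structure(list(coords = coords,
                   genotypes = extract_genotypes(lat, cells),
                   n_loci = lat$n_loci,
                   generation = lat$generation,
                   replicate_id = as.integer(replicate_id),
                   grid_width = lat$grid_width,
                   grid_height = lat$grid_height),
              class = "sample_set")
  })
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(paste0("Sample set: %d individuals, %d loci, generation %d,",
                     " replicate %d\n"),
              nrow(x$coords), x$n_loci, x$generation, x$replicate_id))
  cat(sprintf("  quadrant counts: %s\n",
              paste(tabulate(x$coords$quadrant + 1L, 4L), collapse = " / ")))
  invisible(x)
}

#' Run one full simulation replicate
#'
#' Burn-in, barrier imposition, snapshot export and sampling for a single
#' replicate, with all random streams derived deterministically from
#' `params$seed` and `replicate_id` (burn-in, sampling and post-barrier
#' phases use split streams, so exported samples are reproducible).
#'
#' @param params A `sim_params`.
#' @param replicate_id Replicate number (1-based).
#' @param barrier Barrier to impose after burn-in.
#' @param equilibrium_warn Passed to [run_burn_in()].
#' @param burned_in Optional pre-computed burned-in lattice for this
#'   replicate (lets callers reuse one burn-in across barrier
#'   permeabilities, which share the pre-barrier history).
#' @return A list with `samples` (list of `sample_set`, one per export
#'   generation), `diagnostics` (burn-in trajectory) and `burned_in`
#'   (the pre-barrier lattice).
#' @examples
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 2, mu = 1e-3,
#'                 delta = 2, burn_in_generations = 10,
#'                 export_generations = c(0, 5), sample_size = 10)
#' r <- run_replicate(p, 1, equilibrium_warn = FALSE)
#' names(r$samples)
#' @export
run_replicate <- function(params, replicate_id = 1L,
                          barrier = barrier_spec(params = params),
                          equilibrium_warn = FALSE, burned_in = NULL) {
  rep_seed <- derive_seed(params$seed, replicate_id)
  if (is.null(burned_in))
    burned_in <- run_burn_in(params, seed = derive_seed(rep_seed, 1),
                             equilibrium_warn = equilibrium_warn)
  snaps <- run_post_barrier(burned_in, params, barrier,
                            seed = derive_seed(rep_seed, 3))
  samples <- sample_individuals(snaps, params$sample_size, barrier,
                                seed = derive_seed(rep_seed, 2),
                                replicate_id = replicate_id)
  list(samples = samples,
       diagnostics = attr(burned_in, "diagnostics"),
       burned_in = burned_in)
}
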