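#' Cluster result container
#'
#' Holds the estimated number of clusters and a hard assignment per
#' individual, as produced by a Bayesian clustering program (Q-matrices are
#' hardened by argmax, ties towards the lower cluster index).
#'
#' @param k_estimated Estimated number of clusters.
#' @param membership Integer assignment per individual (values in
#'   `1:k_estimated`).
#' @param source Method label.
#' @return An object of class `cluster_result`.
#' @examples
#' cluster_result(2, c(1, 1, 2, 2), "toy")
#' @export
cluster_result <- function(k_estimated, membership, source = "external") {
  membership <- as.integer(membership)
  if (any(membership < 1 | membership > k_estimated))
    stop("membership values must lie in 1:k_estimated", call. = FALSE)
  structure(list(k_estimated = as.integer(k_estimated),
                 membership = membership, source = source),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result (%s): K = %d, %d individuals\n", x$source,
              x$k_estimated, length(x$membership)))
  invisible(x)
}

#' Score a clustering result against the true quadrants
#'
#' Post-barrier generations: correct iff exactly four clusters were
#' estimated and the assignment equals the true quadrant partition up to a
#' relabelling of clusters (every individual correctly assigned).
#' Generation 0 (no barrier yet): correct iff a single cluster was
#' estimated.  Near-misses (right boundaries, wrong K) count as incorrect.
#'
#' @param result A `cluster_result` (or a bare membership vector, in which
#'   case `k_estimated` is taken as the number of distinct labels).
#' @param truth A `sample_set` carrying the true quadrant labels.
#' @param generation Post-barrier generation stamp; defaults to the
#'   sample's.
#' @return Logical correctness flag.
#' @examples
#' tr <- structure(list(coords = data.frame(quadrant = c(0, 1, 2, 3))),
#'                 class = "sample_set")
#' score_clustering(cluster_result(4, 1:4), tr, generation = 100)
#' @export
score_clustering <- function(result, truth, generation = truth$generation) {
  if (!inherits(result, "cluster_result")) {
    m <- as.integer(factor(result))
    result <- cluster_result(max(m), m)
  }
  q <- truth$coords$quadrant
  if (length(result$membership) != length(q))
    stop("membership length does not match the sample", call. = FALSE)
  if (generation == 0) return(result$k_estimated == 1L)
  if (result$k_estimated != 4L) return(FALSE)
  tab <- table(q, result$membership)
  # bijection: one nonzero cell per row and per column
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1) &&
    ncol(tab) == 4
}

# unit-spaced reference points along the two true midlines (map units)
midline_points <- function(barrier, grid_width, grid_height, spacing = 1) {
  vx <- barrier$split_x - 0.5
  hy <- barrier$split_y - 0.5
  v <- cbind(x = vx, y = seq(0, grid_height - 1, by = spacing))
  h <- cbind(x = seq(0, grid_width - 1, by = spacing), y = hy)
  list(vertical = v, horizontal = h)
}

# for each row of `a`, the distance to the nearest row of `b`
nearest_dist <- function(a, b) {
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Score detected boundary elements against the true barrier geometry
#'
#' A quantified surrogate for visual inspection of edge-detection output.
#' For post-barrier generations the detection is correct iff (a) at least
#' `coverage` of each true midline's length lies within `tolerance` of a
#' detected element, and (b) at least `coverage` of the detected elements
#' lie within `tolerance` of a true midline.  At generation 0 the detection
#' is correct iff there are no detected elements at all (for Monmonier
#' output, barriers with fewer than `min_edges` crossed edges are treated as
#' not detected).
#'
#' For *ranked* barrier output (a list of `boundary_path` objects) the
#' criterion is applied to the smallest rank prefix whose elements achieve
#' the line coverage: the visual protocol asks whether the main boundaries
#' were detected, and a method asked for more barriers than the landscape
#' contains necessarily pads its output with low-rank noise that an
#' inspector disregards.  If no prefix covers the midlines the detection is
#' incorrect.  Point matrices and significance masks carry no ranking and
#' are scored whole.
#'
#' @param output Detected boundary elements: a two-column matrix of points,
#'   a list of `boundary_path` objects, or a tested `systemic_surface`.
#' @param truth A `barrier_spec` giving the true midlines.
#' @param generation Post-barrier generation stamp.
#' @param grid_width,grid_height Landscape extent in cells.
#' @param tolerance Match distance in map units (default 5, of the order of
#'   the wombling bandwidth).
#' @param coverage Required two-sided coverage fraction (default 0.8).
#' @param min_edges Minimum crossed edges for a Monmonier barrier to count
#'   as detected.
#' @return Logical correctness flag, with attributes `line_coverage` and
#'   `element_precision`.
#' @examples
#' b <- barrier_spec(split_x = 50, split_y = 50)
#' pts <- rbind(cbind(49.5, 0:99), cbind(0:99, 49.5))
#' score_edges(pts, b, generation = 100, grid_width = 100,
#'             grid_height = 100)
#' @export
score_edges <- function(output, truth, generation, grid_width = 100,
                        grid_height = 100, tolerance = 5, coverage = 0.8,
                        min_edges = 5) {
  ranked <- NULL
  if (inherits(output, "boundary_path")) output <- list(output)
  if (is.list(output) && !is.matrix(output) &&
      !inherits(output, "systemic_surface") &&
      all(vapply(output, inherits, logical(1), "boundary_path")))
    ranked <- output[order(vapply(output, `[[`, numeric(1), "rank"))]
  pts <-
    if (is.matrix(output)) output
    else if (inherits(output, "systemic_surface")) significant_pixels(output)
    else if (!is.null(ranked)) barrier_elements(ranked,
                                                min_edges = min_edges)
    else stop("unsupported output type", call. = FALSE)

  if (generation == 0) {
    out <- nrow(pts) == 0
    attr(out, "line_coverage") <- c(vertical = NA_real_,
                                    horizontal = NA_real_)
    attr(out, "element_precision") <- NA_real_
    return(out)
  }
  ml <- midline_points(truth, grid_width, grid_height)
  score_set <- function(p) {
    cov_v <- mean(nearest_dist(ml$vertical, p) <= tolerance)
    cov_h <- mean(nearest_dist(ml$horizontal, p) <= tolerance)
    prec <- if (nrow(p) == 0) 0
            else mean(nearest_dist(p, rbind(ml$vertical, ml$horizontal)) <=
                        tolerance)
    list(cov_v = cov_v, cov_h = cov_h, prec = prec,
         ok = cov_v >= coverage && cov_h >= coverage && prec >= coverage)
  }
  sc <- score_set(pts)
  if (!is.null(ranked) && length(ranked) > 1) {
    # smallest rank prefix that covers both midlines decides the verdict
    for (k in seq_along(ranked)) {
      pk <- barrier_elements(ranked[seq_len(k)], min_edges = min_edges)
      sk <- score_set(pk)
      if (sk$cov_v >= coverage && sk$cov_h >= coverage) {
        sc <- sk
        break
      }
    }
  }
  out <- sc$ok
  attr(out, "line_coverage") <- c(vertical = sc$cov_v,
                                  horizontal = sc$cov_h)
  attr(out, "element_precision") <- sc$prec
  out
}

#' Run the boundary-detection benchmark
#'
#' Full factorial sweep over parameter combinations, replicates and export
#' generations: simulates each replicate (burn-in, barrier imposition,
#' sampling), runs the configured internal methods (Monmonier, wombling)
#' on every exported sample, optionally scores externally produced cluster
#' memberships, and aggregates per-cell correctness into a percent-correct
#' table (rows = combination x generation, columns = methods).
#'
#' @param config A configuration list (see [read_config()]) or the path to
#'   a YAML configuration file.  Recognized top-level fields: `seed`,
#'   `replicates`, `combos` (list of [sim_params()] argument lists or
#'   preset names), `methods` (named list with optional `monmonier` and
#'   `wombling` parameter blocks), `scoring` (`tolerance`, `coverage`,
#'   `min_edges`), `external` (directory of membership files named
#'   `<combo>_gen<g>_rep<r>.csv`), `output` (directory for CSV results).
#' @param progress Print per-replicate progress lines.
#' @return An object of class `benchmark_result`: `records` (one row per
#'   method x combo x generation x replicate) and `table` (percent correct,
#'   with mean estimated K for clustering methods).
#' @examples
#' \donttest{
#' cfg <- list(seed = 7, replicates = 2,
#'             combos = list(list(name = "tiny", grid_width = 20,
#'                                grid_height = 20, n_loci = 5, mu = 1e-3,
#'                                delta = 2, burn_in_generations = 200,
#'                                export_generations = c(0, 50),
#'                                sample_size = 40)),
#'             methods = list(wombling = list(grid_nx = 20, grid_ny = 20,
#'                                            bandwidth = 3)))
#' run_benchmark(cfg, progress = FALSE)$table
#' }
#' @export
run_benchmark <- function(config, progress = TRUE) {
  if (is.character(config)) config <- read_config(config)
  seed <- if (is.null(config$seed)) 1 else config$seed
  n_rep <- if (is.null(config$replicates)) 5L else as.integer(config$replicates)
  sc <- config$scoring
  tolerance <- if (is.null(sc$tolerance)) 5 else sc$tolerance
  cover <- if (is.null(sc$coverage)) 0.8 else sc$coverage
  min_edges <- if (is.null(sc$min_edges)) 5 else sc$min_edges
  methods <- config$methods
  if (is.null(methods)) methods <- list(monmonier = list(), wombling = list())

  combos <- lapply(config$combos, function(cb) {
    if (is.character(cb)) {
      p <- sim_preset(cb, seed = seed, n_replicates = n_rep)
      attr(p, "combo_name") <- cb
      p
    } else {
      nm <- cb$name
      cb$name <- NULL
      p <- do.call(sim_params, c(cb, list(seed = seed,
                                          n_replicates = n_rep)))
      attr(p, "combo_name") <- if (is.null(nm)) "combo" else nm
      p
    }
  })

  records <- list()
  warned_external <- FALSE
  for (params in combos) {
    combo_name <- attr(params, "combo_name")
    barrier <- barrier_spec(params = params)
    for (rep_i in seq_len(n_rep)) {
      if (progress)
        message(sprintf("[benchmark] %s replicate %d/%d", combo_name,
                        rep_i, n_rep))
      res <- run_replicate(params, rep_i, barrier)
      for (s in res$samples) {
        gen <- s$generation
        if ("monmonier" %in% names(methods)) {
          mp <- methods$monmonier
          mm <- monmonier(s,
                          n_barriers = if (is.null(mp$n_barriers)) 4
                                       else mp$n_barriers,
                          distance = if (is.null(mp$distance)) "residual"
                                     else mp$distance)
          ok <- score_edges(mm$barriers, barrier, gen,
                            params$grid_width, params$grid_height,
                            tolerance, cover, min_edges)
          records[[length(records) + 1L]] <-
            data.frame(method = "monmonier", combo = combo_name,
                       generation = gen, replicate = rep_i,
                       correct = as.logical(ok), k_estimated = NA_real_)
        }
        if ("wombling" %in% names(methods)) {
          wp_args <- methods$wombling
          wp <- do.call(womble_params,
                        wp_args[names(wp_args) %in%
                                  names(formals(womble_params))])
          ws <- womble(s, wp)
          ok <- score_edges(ws, barrier, gen, params$grid_width,
                            params$grid_height, tolerance, cover)
          records[[length(records) + 1L]] <-
            data.frame(method = "wombling", combo = combo_name,
                       generation = gen, replicate = rep_i,
                       correct = as.logical(ok), k_estimated = NA_real_)
        }
        if (!is.null(config$external)) {
          f <- file.path(config$external,
                         sprintf("%s_gen%d_rep%d.csv", combo_name, gen,
                                 rep_i))
          if (file.exists(f)) {
            cr <- read_qmatrix(f)
            records[[length(records) + 1L]] <-
              data.frame(method = cr$source, combo = combo_name,
                         generation = gen, replicate = rep_i,
                         correct = score_clustering(cr, s, gen),
                         k_estimated = cr$k_estimated)
          } else if (!warned_external) {
            warning("external membership file(s) missing, e.g. ", f,
                    "; method skipped", call. = FALSE)
            warned_external <- TRUE
          }
        }
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(method = character(0), combo = character(0),
               generation = integer(0), replicate = integer(0),
               correct = logical(0), k_estimated = numeric(0))
  out <- structure(list(records = records,
                        table = benchmark_table(records)),
                   class = "benchmark_result")
  if (!is.null(config$output)) {
    dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(config$output, "benchmark_records.csv"),
              row.names = FALSE)
    write.csv(out$table, file.path(config$output, "benchmark_table.csv"),
              row.names = FALSE)
  }
  out
}

#' Aggregate benchmark records into a percent-correct table
#'
#' @param records A records data.frame as produced by [run_benchmark()].
#' @return A data.frame with one row per combination x generation and one
#'   `pct_correct` column per method (plus `mean_k` columns where estimated
#'   cluster counts are available).
#' @export
benchmark_table <- function(records) {
  if (!nrow(records))
    return(data.frame(combo = character(0), generation = integer(0)))
  agg <- aggregate(cbind(correct, k_estimated) ~ method + combo + generation,
                   data = records,
                   FUN = function(v) mean(v, na.rm = TRUE),
                   na.action = stats::na.pass)
  out <- NULL
  for (m in unique(agg$method)) {
    sub <- agg[agg$method == m, c("combo", "generation", "correct",
                                  "k_estimated")]
    names(sub)[3] <- paste0(m, "_pct_correct")
    sub[[3]] <- 100 * sub[[3]]
    if (all(is.na(sub$k_estimated))) sub$k_estimated <- NULL
    else names(sub)[4] <- paste0(m, "_mean_k")
    out <- if (is.null(out)) sub else
      merge(out, sub, by = c("combo", "generation"), all = TRUE)
  }
  out[order(out$combo, out$generation), , drop = FALSE]
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark result:", nrow(x$records), "records\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
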