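#' Build a Delaunay neighbour graph weighted by genetic distance
#'
#' Triangulates the sample coordinates (Delaunay, with the Voronoi dual
#' attached) and weights every Delaunay edge by the genetic distance between
#' its endpoint individuals: either the raw distance, or the residual of
#' genetic distance regressed on Euclidean geographic distance across the
#' graph's edges (residual distances remove the isolation-by-distance trend
#' so that barriers stand out against the background gradient).
#'
#' @param sample A `sample_set`, or a coordinate matrix/data.frame with
#'   columns `x`, `y` (then `genotypes` and `n_loci` must be given).
#' @param distance `"raw"` or `"residual"`.
#' @param metric Pairwise genetic distance metric, see [genetic_distance()].
#' @param genotypes,n_loci Used when `sample` is a bare coordinate set.
#' @param rw Optional enclosing rectangle `c(xmin, xmax, ymin, ymax)` for
#'   the Voronoi tessellation (defaults to the landscape extent for a
#'   `sample_set`).
#' @return An object of class `delaunay_graph`: `nodes` (coordinates),
#'   `edges` (data.frame with endpoints `ind1`/`ind2`, genetic `weight`,
#'   Voronoi segment endpoints `vx1`/`vy1`/`vx2`/`vy2`, boundary flags
#'   `bp1`/`bp2` and adjacent third vertices `tv1`/`tv2`), and `distance`.
#' @examples
#' xy <- cbind(x = c(0, 4, 0, 4), y = c(0, 0, 4, 4))
#' g <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 2L))
#' gr <- build_graph(xy, genotypes = g, n_loci = 1)
#' nrow(gr$edges)   # 5: four sides plus one diagonal
#' @export
build_graph <- function(sample, distance = c("raw", "residual"),
                        metric = c("dps", "rousset"),
                        genotypes = NULL, n_loci = NULL, rw = NULL) {
  distance <- match.arg(distance)
  metric <- match.arg(metric)
  if (inherits(sample, "sample_set")) {
    xy <- as.matrix(sample$coords[, c("x", "y")])
    genotypes <- sample$genotypes
    n_loci <- sample$n_loci
    if (is.null(rw))
      rw <- c(-0.5, sample$grid_width - 0.5, -0.5, sample$grid_height - 0.5)
  } else {
    xy <- as.matrix(sample)[, 1:2, drop = FALSE]
    colnames(xy) <- c("x", "y")
    if (is.null(genotypes) || is.null(n_loci))
      stop("genotypes and n_loci required for bare coordinates",
           call. = FALSE)
  }
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  # collinearity check via the rank of centred coordinates
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    stop("all points are collinear; cannot triangulate", call. = FALSE)
  dup <- duplicated(xy)
  if (any(dup)) {
    warning(sum(dup), " duplicated coordinate(s) jittered", call. = FALSE)
    k <- which(dup)
    xy[k, 1] <- xy[k, 1] + 1e-4 * seq_along(k)
    xy[k, 2] <- xy[k, 2] + 1.7e-4 * seq_along(k)
  }
  dd <- if (is.null(rw)) deldir::deldir(xy[, 1], xy[, 2])
        else deldir::deldir(xy[, 1], xy[, 2], rw = rw)
  seg <- dd$dirsgs
  G <- .bb_pairwise_dist(genotypes, as.integer(n_loci), metric)
  i1 <- pmin(seg$ind1, seg$ind2)
  i2 <- pmax(seg$ind1, seg$ind2)
  w <- G[cbind(i1, i2)]
  if (distance == "residual") {
    geo <- sqrt((xy[i1, 1] - xy[i2, 1])^2 + (xy[i1, 2] - xy[i2, 2])^2)
    w <- resid(lm(w ~ geo))
  }
  edges <- data.frame(ind1 = i1, ind2 = i2, weight = as.numeric(w),
                      vx1 = seg$x1, vy1 = seg$y1, vx2 = seg$x2,
                      vy2 = seg$y2, bp1 = seg$bp1, bp2 = seg$bp2,
                      tv1 = seg$thirdv1, tv2 = seg$thirdv2)
  structure(list(nodes = xy, edges = edges, distance = distance,
                 metric = metric),
            class = "delaunay_graph")
}

#' @export
print.delaunay_graph <- function(x, ...) {
  cat(sprintf("Delaunay graph: %d nodes, %d edges (%s %s distances)\n",
              nrow(x$nodes), nrow(x$edges), x$distance, x$metric))
  invisible(x)
}

# triangle key for a Delaunay edge side: the sorted vertex triple as a
# string, or NA for the convex hull side (thirdv <= 0 in deldir)
.tri_key <- function(i, j, tv) {
  ifelse(tv <= 0, NA_character_,
         vapply(seq_along(tv), function(k) {
           paste(sort(c(i[k], j[k], tv[k])), collapse = "-")
         }, character(1)))
}

#' Trace Monmonier barriers
#'
#' Greedy maximum-difference barrier tracing: each barrier is seeded at the
#' not-yet-crossed Delaunay edge with the largest genetic distance and grows
#' from both ends of that edge's Voronoi segment; at each growth step the
#' barrier crosses the adjacent same-triangle edge with the largest distance
#' among those not yet crossed by any barrier.  A growth front stops when it
#' reaches the convex hull, closes a loop (revisits a Voronoi vertex) or
#' meets an existing barrier.  Ties are broken towards the lexicographically
#' smallest node-index pair, so runs are fully deterministic.
#'
#' @param graph A `delaunay_graph`.
#' @param n_barriers Number of barriers to trace (default 4).
#' @return A list of `boundary_path` objects, each with `edges` (row
#'   indices into `graph$edges`, in path order), `segments` (matrix of
#'   Voronoi segment endpoints per crossed edge) and `rank`.
#' @examples
#' xy <- cbind(x = c(0, 1, 0, 1, 4, 5, 4, 5),
#'             y = c(0, 0, 1, 1, 0, 0, 1, 1))
#' g <- matrix(rep(c(1L, 1L, 2L, 2L), each = 4), ncol = 2)
#' gr <- build_graph(xy, genotypes = g, n_loci = 1)
#' b <- trace_barriers(gr, 1)
#' b[[1]]
#' @export
trace_barriers <- function(graph, n_barriers = 4) {
  stopifnot(inherits(graph, "delaunay_graph"))
  if (n_barriers < 1) stop("n_barriers must be >= 1", call. = FALSE)
  e <- graph$edges
  nE <- nrow(e)
  keyA <- .tri_key(e$ind1, e$ind2, e$tv1)
  keyB <- .tri_key(e$ind1, e$ind2, e$tv2)
  # adjacency: triangle key -> edge indices
  adj <- split(rep(seq_len(nE), 2), c(keyA, keyB))
  used <- logical(nE)
  visited <- character(0)

  # deterministic ordering for seeding and tie-breaks:
  # weight desc, then (ind1, ind2) asc
  ord <- order(-e$weight, e$ind1, e$ind2)
  pick_best <- function(cand) {
    # smallest position in `ord` among candidates
    cand[which.min(match(cand, ord))]
  }

  grow_front <- function(edge_idx, side_key) {
    path <- integer(0)
    cur <- side_key
    repeat {
      if (is.na(cur)) break                  # reached the convex hull
      cand <- setdiff(adj[[cur]], edge_idx)
      cand <- cand[!used[cand]]
      if (!length(cand)) break               # dead end (all crossed)
      nxt <- pick_best(cand)
      used[nxt] <<- TRUE
      path <- c(path, nxt)
      # move to the other side of the crossed edge
      other <- if (identical(keyA[nxt], cur)) keyB[nxt] else keyA[nxt]
      edge_idx <- nxt
      if (is.na(other)) break                # hull
      if (other %in% visited) break          # loop or met another barrier
      visited <<- c(visited, other)
      cur <- other
    }
    path
  }

  barriers <- list()
  for (k in seq_len(n_barriers)) {
    avail <- which(!used)
    if (!length(avail)) {
      warning("only ", length(barriers), " barrier(s) could be traced",
              call. = FALSE)
      break
    }
    seed <- pick_best(avail)
    used[seed] <- TRUE
    visited <- c(visited, stats::na.omit(c(keyA[seed], keyB[seed])))
    pA <- grow_front(seed, keyA[seed])
    pB <- grow_front(seed, keyB[seed])
    edges_ordered <- c(rev(pA), seed, pB)
    segs <- as.matrix(e[edges_ordered, c("vx1", "vy1", "vx2", "vy2")])
    barriers[[k]] <- structure(list(edges = edges_ordered,
                                    segments = segs, rank = k),
                               class = "boundary_path")
  }
  barriers
}

#' @export
print.boundary_path <- function(x, ...) {
  cat(sprintf("Boundary path (rank %d): %d crossed edges\n", x$rank,
              length(x$edges)))
  invisible(x)
}

#' Points along traced barriers
#'
#' Samples each barrier's Voronoi segments at (at most) `spacing` map-unit
#' intervals, discarding barriers with fewer than `min_edges` crossed edges
#' (a short fragment is treated as "no barrier detected", see
#' [score_edges()]).
#'
#' @param barriers A list of `boundary_path` objects (or a single one).
#' @param spacing Sampling interval along segments, in map units.
#' @param min_edges Minimum number of crossed edges for a barrier to count.
#' @return A numeric matrix with columns `x`, `y` (0 rows if nothing
#'   qualifies).
#' @export
barrier_elements <- function(barriers, spacing = 1, min_edges = 1) {
  if (inherits(barriers, "boundary_path")) barriers <- list(barriers)
  pts <- lapply(barriers, function(b) {
    if (length(b$edges) < min_edges) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(b$segments)), function(i) {
      s <- b$segments[i, ]
      len <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
      k <- max(2L, ceiling(len / spacing) + 1L)
      t <- seq(0, 1, length.out = k)
      cbind(s[1] + t * (s[3] - s[1]), s[2] + t * (s[4] - s[2]))
    }))
  })
  out <- do.call(rbind, pts)
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  colnames(out) <- c("x", "y")
  out
}

#' Monmonier barrier detection in one call
#'
#' Convenience wrapper: builds the Delaunay graph and traces barriers.
#'
#' @inheritParams build_graph
#' @inheritParams trace_barriers
#' @return A list with `graph` and `barriers`.
#' @export
monmonier <- function(sample, n_barriers = 4,
                      distance = c("residual", "raw"),
                      metric = c("dps", "rousset")) {
  distance <- match.arg(distance)
  metric <- match.arg(metric)
  graph <- build_graph(sample, distance = distance, metric = metric)
  list(graph = graph, barriers = trace_barriers(graph, n_barriers))
}

#' @export
plot.delaunay_graph <- function(x, barriers = NULL, ...) {
  plot(x$nodes, pch = 16, cex = 0.5, asp = 1, ...)
  segments(x$nodes[x$edges$ind1, 1], x$nodes[x$edges$ind1, 2],
           x$nodes[x$edges$ind2, 1], x$nodes[x$edges$ind2, 2],
           col = "grey80")
  if (!is.null(barriers)) {
    if (inherits(barriers, "boundary_path")) barriers <- list(barriers)
    cols <- hcl.colors(max(1, length(barriers)), "Dark 3")
    for (b in barriers)
      segments(b$segments[, 1], b$segments[, 2], b$segments[, 3],
               b$segments[, 4], col = cols[b$rank], lwd = 2)
  }
  invisible(x)
}

#' Write traced barriers to CSV
#'
#' One row per crossed edge: barrier rank, path position, the crossed
#' Delaunay edge's endpoint indices, and the Voronoi segment endpoints.
#'
#' @param barriers List of `boundary_path` objects.
#' @param graph The `delaunay_graph` they were traced on.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_barriers <- function(barriers, graph, path) {
  rows <- do.call(rbind, lapply(barriers, function(b) {
    data.frame(rank = b$rank, step = seq_along(b$edges),
               ind1 = graph$edges$ind1[b$edges],
               ind2 = graph$edges$ind2[b$edges],
               weight = graph$edges$weight[b$edges],
               vx1 = b$segments[, 1], vy1 = b$segments[, 2],
               vx2 = b$segments[, 3], vy2 = b$segments[, 4])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
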