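#' Wombling parameters
#'
#' The four tunable quantities of individual-based wombling: the raster
#' resolution, the smoothing bandwidth (in map units; typically of the order
#' of the species' mean dispersal distance), the percentile `p` defining
#' per-allele candidate boundary elements (the top `p` fraction of each
#' allele's gradient-norm distribution), and the significance level of the
#' per-pixel binomial test.
#'
#' @param grid_nx,grid_ny Raster resolution (default 100 x 100).
#' @param bandwidth Kernel bandwidth in map units (default 7).
#' @param percentile Candidate threshold `p` in `(0, 1)` (default 0.3).
#' @param alpha Significance level in `(0, 1)` (default 0.05).
#' @param kernel `"gaussian"` (scale `bandwidth / 2`, untruncated) or
#'   `"disc"` (uniform within `bandwidth`).
#' @return An object of class `womble_params`.
#' @examples
#' womble_params(bandwidth = 7)
#' @export
womble_params <- function(grid_nx = 100, grid_ny = 100, bandwidth = 7,
                          percentile = 0.3, alpha = 0.05,
                          kernel = c("gaussian", "disc")) {
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  structure(list(grid_nx = as.integer(grid_nx),
                 grid_ny = as.integer(grid_ny),
                 bandwidth = bandwidth, percentile = percentile,
                 alpha = alpha, kernel = kernel),
            class = "womble_params")
}

#' @export
print.womble_params <- function(x, ...) {
  cat(sprintf(paste0("Wombling parameters: grid %d x %d, bandwidth %g, ",
                     "binomial threshold %g, significance %g (%s kernel)\n"),
              x$grid_nx, x$grid_ny, x$bandwidth, x$percentile, x$alpha,
              x$kernel))
  invisible(x)
}

# per-individual allele dosage matrix (0 / 0.5 / 1), one column per
# (locus, allele) pair observed in the sample
allele_dosage <- function(genotypes, n_loci) {
  cols <- lapply(seq_len(n_loci), function(l) {
    m <- genotypes[, c(2 * l - 1, 2 * l), drop = FALSE]
    alleles <- sort(unique(as.vector(m)))
    d <- sapply(alleles, function(al)
      ((m[, 1] == al) + (m[, 2] == al)) / 2)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(m))
    colnames(d) <- paste0("L", l, ".A", alleles)
    list(dosage = d, locus = rep(l, length(alleles)))
  })
  list(dosage = do.call(cbind, lapply(cols, `[[`, "dosage")),
       locus = unlist(lapply(cols, `[[`, "locus")))
}

#' Kernel-smoothed allele-frequency surfaces
#'
#' Interpolates each allele's per-individual dosage (0, 0.5 or 1 copies,
#' halved) onto a regular raster by local-linear kernel regression: at each
#' pixel a weighted plane is fitted to the dosages of nearby individuals and
#' its value at the pixel taken as the frequency estimate.  Because the
#' local-linear smoother reproduces constants, the per-locus allele surfaces
#' sum to one at every pixel; estimates are clipped to `[0, 1]` and
#' renormalized per locus, preserving that property.  Pixels whose kernel
#' neighbourhood is empty borrow the value of the nearest non-empty pixel
#' and are flagged; pixels whose neighbourhood is too sparse for a stable
#' plane fit fall back to the kernel-weighted mean.
#'
#' @param sample A `sample_set`.
#' @param params A `womble_params`.
#' @param extent Raster extent `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   sample's landscape.
#' @return An object of class `freq_surfaces`: `freq` (pixels x alleles
#'   matrix), `px`, `py` (pixel-centre coordinate vectors of length
#'   `grid_nx * grid_ny`, x varying fastest), `locus` (locus index per
#'   allele column), `empty` (logical flag per pixel), grid metadata.
#' @examples
#' \donttest{
#' p <- sim_params(grid_width = 20, grid_height = 20, n_loci = 2, mu = 1e-2,
#'                 delta = 2, burn_in_generations = 100, sample_size = 60)
#' s <- run_replicate(p)$samples[[1]]
#' fs <- estimate_frequency_surfaces(s, womble_params(grid_nx = 20,
#'                                                    grid_ny = 20,
#'                                                    bandwidth = 3))
#' range(rowsum(t(fs$freq), fs$locus))   # per-locus sums are 1
#' }
#' @export
estimate_frequency_surfaces <- function(sample, params = womble_params(),
                                        extent = NULL) {
  stopifnot(inherits(sample, "sample_set"), inherits(params, "womble_params"))
  n <- nrow(sample$coords)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  if (is.null(extent))
    extent <- c(0, sample$grid_width - 1, 0, sample$grid_height - 1)
  nx <- params$grid_nx; ny <- params$grid_ny
  gx <- seq(extent[1], extent[2], length.out = nx)
  gy <- seq(extent[3], extent[4], length.out = ny)
  px <- rep(gx, times = ny)
  py <- rep(gy, each = nx)
  xi <- sample$coords$x
  yi <- sample$coords$y

  # kernel weight matrix: pixels x individuals
  DX <- outer(px, xi, "-")
  DY <- outer(py, yi, "-")
  D2 <- DX^2 + DY^2
  # The Gaussian kernel is deliberately not truncated: a hard cutoff makes
  # rare-allele frequency surfaces exactly zero (and exactly flat) outside
  # the cutoff, so the per-allele gradient-norm quantile degenerates on the
  # tie plateau and the candidate fraction drops far below the nominal p,
  # breaking the Binomial(n, p) calibration of the boundary test.
  if (params$kernel == "gaussian") {
    sc <- params$bandwidth / 2
    W <- exp(-D2 / (2 * sc^2))
  } else {
    W <- (D2 <= params$bandwidth^2) * 1
  }

  dos <- allele_dosage(sample$genotypes, sample$n_loci)
  nAll <- ncol(dos$dosage)

  # local-linear equivalent weights, vectorized over pixels via the moment
  # matrices S_pq = sum_i w_i dx_i^p dy_i^q
  S00 <- rowSums(W)
  SWx <- W %*% xi;  SWy <- W %*% yi
  SWxx <- W %*% (xi^2); SWyy <- W %*% (yi^2); SWxy <- W %*% (xi * yi)
  S10 <- SWx - px * S00
  S01 <- SWy - py * S00
  S20 <- SWxx - 2 * px * SWx + px^2 * S00
  S02 <- SWyy - 2 * py * SWy + py^2 * S00
  S11 <- SWxy - px * SWy - py * SWx + px * py * S00

  # first row of (X'WX)^{-1} by cofactors of the symmetric 3x3 moment matrix
  det3 <- S00 * (S20 * S02 - S11^2) - S10 * (S10 * S02 - S11 * S01) +
    S01 * (S10 * S11 - S20 * S01)
  A <- (S20 * S02 - S11^2)
  B <- -(S10 * S02 - S11 * S01)
  C <- (S10 * S11 - S20 * S01)

  empty <- S00 <= .Machine$double.eps * n
  # the moment matrix is PSD: a vanishing determinant (relative to its
  # diagonal scale) means too few / collinear neighbours for a plane fit
  dscale <- pmax(S00 * pmax(S20, .Machine$double.eps) *
                   pmax(S02, .Machine$double.eps), .Machine$double.eps)
  singular <- !empty & (det3 <= 1e-10 * dscale)

  Lw <- W * (as.vector(A / det3) +
               as.vector(B / det3) * DX + as.vector(C / det3) * DY)
  # fallback: kernel-weighted mean where the plane fit is unstable
  if (any(singular))
    Lw[singular, ] <- W[singular, , drop = FALSE] /
      S00[singular]
  Lw[empty, ] <- 0

  fhat <- Lw %*% dos$dosage

  # nearest non-empty pixel fills empty neighbourhoods
  if (any(empty)) {
    if (all(empty)) stop("bandwidth covers no individuals anywhere",
                         call. = FALSE)
    ok <- which(!empty)
    for (i in which(empty)) {
      j <- ok[which.min((px[ok] - px[i])^2 + (py[ok] - py[i])^2)]
      fhat[i, ] <- fhat[j, ]
    }
  }

  # clip and renormalize within each locus
  fhat[fhat < 0] <- 0
  fhat[fhat > 1] <- 1
  for (l in unique(dos$locus)) {
    cols <- which(dos$locus == l)
    tot <- rowSums(fhat[, cols, drop = FALSE])
    fhat[, cols] <- fhat[, cols, drop = FALSE] / tot
  }

  structure(list(freq = fhat, px = px, py = py, gx = gx, gy = gy,
                 nx = nx, ny = ny, locus = dos$locus, empty = empty,
                 params = params),
            class = "freq_surfaces")
}

#' Systemic function from frequency surfaces
#'
#' Computes per-allele spatial gradients of the frequency surfaces by
#' central finite differences (one-sided at the raster borders), takes each
#' allele's Euclidean gradient norm, and averages the norms over all alleles
#' to form the systemic function: a surface whose high values mark zones of
#' rapid multi-allele frequency change, i.e. candidate genetic boundaries.
#'
#' @param fs A `freq_surfaces` object.
#' @return An object of class `systemic_surface`: `systemic` (vector over
#'   pixels), `gradient_norms` (pixels x alleles), `n_alleles`, plus the
#'   grid metadata and the input surfaces.
#' @export
systemic_function <- function(fs) {
  stopifnot(inherits(fs, "freq_surfaces"))
  nx <- fs$nx; ny <- fs$ny
  np <- nx * ny
  ix <- (seq_len(np) - 1L) %% nx          # 0-based pixel column
  iy <- (seq_len(np) - 1L) %/% nx         # 0-based pixel row
  dx <- if (nx > 1) fs$gx[2] - fs$gx[1] else 1
  dy <- if (ny > 1) fs$gy[2] - fs$gy[1] else 1

  xp <- pmin(ix + 1L, nx - 1L); xm <- pmax(ix - 1L, 0L)
  yp <- pmin(iy + 1L, ny - 1L); ym <- pmax(iy - 1L, 0L)
  idx_xp <- xp + nx * iy + 1L; idx_xm <- xm + nx * iy + 1L
  idx_yp <- ix + nx * yp + 1L; idx_ym <- ix + nx * ym + 1L
  span_x <- (xp - xm) * dx
  span_y <- (yp - ym) * dy

  GX <- (fs$freq[idx_xp, , drop = FALSE] -
           fs$freq[idx_xm, , drop = FALSE]) / span_x
  GY <- (fs$freq[idx_yp, , drop = FALSE] -
           fs$freq[idx_ym, , drop = FALSE]) / span_y
  gn <- sqrt(GX^2 + GY^2)

  structure(list(freq_surfaces = fs, gradient_norms = gn,
                 systemic = rowMeans(gn), n_alleles = ncol(gn),
                 px = fs$px, py = fs$py, gx = fs$gx, gy = fs$gy,
                 nx = nx, ny = ny, params = fs$params),
            class = "systemic_surface")
}

#' Binomial boundary-element test
#'
#' For every allele, pixels whose gradient norm exceeds that allele's upper
#' `p`-quantile (over pixels) are candidate boundary elements, so each
#' allele flags a fraction `p` of the raster.  At each pixel the number of
#' alleles flagging it, `c`, is compared with the null distribution
#' `Binomial(n, p)` (`n` = total number of alleles): the pixel is a
#' significant boundary element iff the exact upper-tail probability
#' `P(X >= c)` is at most `alpha`.  No multiple-testing correction is
#' applied across pixels.
#'
#' @param surface A `systemic_surface`.
#' @param params A `womble_params` (defaults to the ones stored in
#'   `surface`).
#' @return `surface` augmented with `candidate_counts` (per pixel),
#'   `significance_mask` (logical per pixel) and `min_significant_count`.
#' @export
boundary_test <- function(surface, params = surface$params) {
  stopifnot(inherits(surface, "systemic_surface"))
  n <- surface$n_alleles
  if (n == 0) stop("no alleles", call. = FALSE)
  p <- params$percentile
  gn <- surface$gradient_norms
  thr <- apply(gn, 2, quantile, probs = 1 - p, names = FALSE)
  cand <- sweep(gn, 2, thr, ">")
  counts <- rowSums(cand)
  # smallest count with upper-tail P(X >= c) <= alpha
  cmin <- suppressWarnings(min(which(
    pbinom(seq_len(n) - 1, n, p, lower.tail = FALSE) <= params$alpha)))
  surface$candidate_counts <- counts
  surface$significance_mask <- counts >= cmin
  surface$min_significant_count <- cmin
  surface
}

#' Individual-based wombling in one call
#'
#' Frequency-surface estimation, systemic function and binomial boundary
#' test, chained.
#'
#' @inheritParams estimate_frequency_surfaces
#' @return A `systemic_surface` with the significance mask attached.
#' @export
womble <- function(sample, params = womble_params(), extent = NULL) {
  boundary_test(systemic_function(
    estimate_frequency_surfaces(sample, params, extent)), params)
}

#' Coordinates of significant boundary elements
#'
#' @param surface A tested `systemic_surface`.
#' @return Matrix with columns `x`, `y` (map units), one row per
#'   significant pixel.
#' @export
significant_pixels <- function(surface) {
  stopifnot(inherits(surface, "systemic_surface"))
  if (is.null(surface$significance_mask))
    stop("run boundary_test() first", call. = FALSE)
  cbind(x = surface$px[surface$significance_mask],
        y = surface$py[surface$significance_mask])
}

#' @export
print.systemic_surface <- function(x, ...) {
  cat(sprintf("Systemic surface: %d x %d pixels, %d alleles\n",
              x$nx, x$ny, x$n_alleles))
  if (!is.null(x$significance_mask))
    cat(sprintf("  significant boundary elements: %d (count threshold %d)\n",
                sum(x$significance_mask), x$min_significant_count))
  invisible(x)
}

#' @export
plot.systemic_surface <- function(x, what = c("systemic", "significance",
                                              "counts"), ...) {
  what <- match.arg(what)
  z <- switch(what,
              systemic = x$systemic,
              counts = x$candidate_counts,
              significance = as.numeric(x$significance_mask))
  image(x$gx, x$gy, matrix(z, x$nx, x$ny), asp = 1,
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Write wombling rasters to CSV
#'
#' Writes the systemic function, candidate counts and significance mask as
#' three CSV matrices (rows = raster rows, bottom row first).
#'
#' @param surface A tested `systemic_surface`.
#' @param prefix Output path prefix; files `<prefix>_systemic.csv`,
#'   `<prefix>_counts.csv`, `<prefix>_significant.csv` are written.
#' @return The three paths, invisibly.
#' @export
write_wombling <- function(surface, prefix) {
  stopifnot(inherits(surface, "systemic_surface"))
  as_mat <- function(v) t(matrix(v, surface$nx, surface$ny))
  paths <- paste0(prefix, c("_systemic.csv", "_counts.csv",
                            "_significant.csv"))
  write.table(as_mat(surface$systemic), paths[1], sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(as_mat(surface$candidate_counts), paths[2], sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(as_mat(as.integer(surface$significance_mask)), paths[3],
              sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
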