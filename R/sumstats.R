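#' Expected number of alleles under the infinite-alleles model
#'
#' Ewens sampling formula expectation for the number of distinct alleles in
#' a sample of `n_genes` gene copies at mutation-drift equilibrium:
#' `sum_{i=0}^{n_genes-1} theta / (theta + i)`, with `theta = 4 N mu` for a
#' diploid population of size `N`.
#'
#' @param theta Scaled mutation rate `4 N mu`, `> 0`.
#' @param n_genes Number of gene copies sampled, `>= 1`.
#' @return Expected number of distinct alleles.
#' @examples
#' ewens_expected_alleles(4, 20000)   # 34.59 for N = 10000, mu = 1e-4
#' ewens_expected_alleles(1, 20000)   # 10.48 for N = 10000, mu = 2.5e-5
#' @export
ewens_expected_alleles <- function(theta, n_genes) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  sum(theta / (theta + 0:(as.integer(n_genes) - 1L)))
}

# Ewens variance of the number of distinct alleles
ewens_allele_variance <- function(theta, n_genes) {
  i <- 0:(as.integer(n_genes) - 1L)
  sum(theta * i / (theta + i)^2)
}

#' Expected gene diversity at mutation-drift equilibrium
#'
#' `theta / (1 + theta)` (Kimura-Crow), the equilibrium expected
#' heterozygosity under the infinite-alleles model.
#'
#' @param theta Scaled mutation rate `4 N mu`, `>= 0`.
#' @return Expected gene diversity in `[0, 1)`.
#' @examples
#' expected_heterozygosity(4)   # 0.8
#' expected_heterozygosity(1)   # 0.5
#' @export
expected_heterozygosity <- function(theta) {
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  theta / (1 + theta)
}

# split a genotype matrix (n x 2L) into a list of per-locus n x 2 matrices
per_locus <- function(genotypes, n_loci) {
  lapply(seq_len(n_loci), function(l) genotypes[, c(2 * l - 1, 2 * l),
                                                drop = FALSE])
}

#' Diversity descriptors of a sample
#'
#' Per-locus number of distinct alleles and Nei's unbiased gene diversity
#' `(2n / (2n - 1)) * (1 - sum p^2)`, plus their means over loci.
#'
#' @param sample A `sample_set`, or a genotype matrix (`n` x `2 * n_loci`).
#' @param n_loci Required when `sample` is a bare matrix.
#' @return An object of class `diversity_stats`: `na_per_locus`,
#'   `h_per_locus`, `mean_na`, `mean_h`, `n`.
#' @examples
#' g <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
#' diversity(g, n_loci = 1)
#' @export
diversity <- function(sample, n_loci = NULL) {
  if (inherits(sample, "sample_set")) {
    genotypes <- sample$genotypes; n_loci <- sample$n_loci
  } else {
    genotypes <- sample
    if (is.null(n_loci)) stop("n_loci required for a bare matrix",
                              call. = FALSE)
  }
  if (nrow(genotypes) < 1) stop("empty sample", call. = FALSE)
  loci <- per_locus(genotypes, n_loci)
  keep <- vapply(loci, function(m) any(!is.na(m)), logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " locus/loci entirely missing; excluded",
            call. = FALSE)
    loci <- loci[keep]
  }
  na <- vapply(loci, function(m) length(unique(as.vector(m[!is.na(m)]))),
               numeric(1))
  h <- vapply(loci, function(m) {
    al <- as.vector(m[!is.na(m)])
    n2 <- length(al)
    p <- tabulate(match(al, unique(al))) / n2
    (n2 / (n2 - 1)) * (1 - sum(p^2))
  }, numeric(1))
  structure(list(na_per_locus = na, h_per_locus = h,
                 mean_na = mean(na), mean_h = mean(h),
                 n = nrow(genotypes)),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("Diversity over %d loci (n = %d): mean Na = %.2f, mean H = %.4f\n",
              length(x$na_per_locus), x$n, x$mean_na, x$mean_h))
  invisible(x)
}

#' Weir-Cockerham FST among groups
#'
#' Multi-allelic Weir-Cockerham variance-components estimator of the
#' fixation index among groups (here typically the four landscape
#' quadrants).  Per-locus estimates are ratios of summed per-allele
#' components; the global multilocus estimate is the ratio of components
#' summed over loci and alleles.  Negative per-locus estimates are retained
#' in the global ratio (no truncation).
#'
#' @param sample A `sample_set`, or a genotype matrix.
#' @param groups Group label per individual; defaults to the sample's
#'   quadrant labels.
#' @param n_loci Required when `sample` is a bare matrix.
#' @return An object of class `fst_result`: `theta_per_locus`,
#'   `theta_global`, `groups_used`.
#' @examples
#' g <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 2L))
#' wc_fst(g, groups = c(1, 1, 2, 2), n_loci = 1)$theta_global  # 1
#' @export
wc_fst <- function(sample, groups = NULL, n_loci = NULL) {
  if (inherits(sample, "sample_set")) {
    genotypes <- sample$genotypes; n_loci <- sample$n_loci
    if (is.null(groups)) groups <- sample$coords$quadrant
  } else {
    genotypes <- sample
    if (is.null(n_loci) || is.null(groups))
      stop("groups and n_loci required for a bare matrix", call. = FALSE)
  }
  groups <- as.factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 individuals: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    genotypes <- genotypes[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  r <- nlevels(groups)
  if (r < 2) stop("need at least two groups with >= 2 individuals",
                  call. = FALSE)
  ni <- as.numeric(table(groups))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  loci <- per_locus(genotypes, n_loci)
  comp <- lapply(loci, function(m) {
    alleles <- sort(unique(as.vector(m)))
    a_sum <- b_sum <- c_sum <- 0
    for (al in alleles) {
      # per-group allele frequency and observed heterozygote frequency
      cnt <- (m[, 1] == al) + (m[, 2] == al)
      p_i <- tapply(cnt, groups, mean) / 2
      h_i <- tapply((m[, 1] == al) != (m[, 2] == al), groups, mean)
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) /
           (4 * nbar) * hbar)
      cc <- hbar / 2
      a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
    }
    c(a = a_sum, b = b_sum, c = c_sum)
  })
  comp <- do.call(rbind, comp)
  tot <- rowSums(comp)
  theta_per_locus <- ifelse(tot != 0, comp[, "a"] / tot, NA_real_)
  theta_global <- sum(comp[, "a"]) / sum(tot)
  structure(list(theta_per_locus = theta_per_locus,
                 theta_global = theta_global,
                 groups_used = levels(groups),
                 components = comp),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST among %d groups: theta = %.4f (%d loci)\n",
              length(x$groups_used), x$theta_global,
              length(x$theta_per_locus)))
  invisible(x)
}

#' Pairwise genetic distances between individuals
#'
#' Two individual-level metrics: `"rousset"`, an identity-based analogue of
#' `FST / (1 - FST)` for pairs of individuals (the a-hat statistic
#' recommended for individual-based isolation-by-distance regressions),
#' computed as `(Qw - Qij) / (1 - Qw)` with `Qw` the mean within-individual
#' allele identity and `Qij` the mean between-individual identity over the
#' four allele comparisons per locus; and `"dps"`, one minus the proportion
#' of shared alleles averaged over loci.
#'
#' @param sample A `sample_set` or genotype matrix.
#' @param metric `"rousset"` or `"dps"`.
#' @param n_loci Required when `sample` is a bare matrix.
#' @return A symmetric `n` x `n` distance matrix (zero diagonal).
#' @examples
#' g <- rbind(c(1L, 2L), c(1L, 2L), c(3L, 4L))
#' genetic_distance(g, "dps", n_loci = 1)
#' @export
genetic_distance <- function(sample, metric = c("rousset", "dps"),
                             n_loci = NULL) {
  metric <- match.arg(metric)
  if (inherits(sample, "sample_set")) {
    genotypes <- sample$genotypes; n_loci <- sample$n_loci
  } else {
    genotypes <- sample
    if (is.null(n_loci)) stop("n_loci required for a bare matrix",
                              call. = FALSE)
  }
  .bb_pairwise_dist(genotypes, as.integer(n_loci), metric)
}

#' Isolation-by-distance regression
#'
#' Least-squares regression of pairwise genetic distance on the natural log
#' of pairwise Euclidean geographic distance between individuals, with
#' significance assessed by a one-sided (positive slope) Mantel permutation
#' test over individuals.
#'
#' @param sample A `sample_set`.
#' @param n_permutations Mantel permutations (default 999).
#' @param metric Genetic distance metric, see [genetic_distance()].
#' @param seed Seed for the permutation stream.
#' @return An object of class `ibd_result`: `slope`, `intercept`,
#'   `mantel_p`, `n_pairs`, `metric`.
#' @examples
#' \donttest{
#' p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 5, mu = 1e-2,
#'                 delta = 1, burn_in_generations = 200, sample_size = 30)
#' s <- run_replicate(p)$samples[[1]]
#' ibd_regression(s, n_permutations = 99)
#' }
#' @export
ibd_regression <- function(sample, n_permutations = 999,
                           metric = c("rousset", "dps"), seed = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(sample, "sample_set"))
  n <- nrow(sample$coords)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  xy <- as.matrix(sample$coords[, c("x", "y")])
  if (nrow(unique(xy)) < 2)
    stop("need at least 2 distinct locations", call. = FALSE)
  G <- genetic_distance(sample, metric)
  D <- as.matrix(stats::dist(xy))
  ut <- upper.tri(D)
  keep <- D[ut] > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " coincident-coordinate pair(s)",
            call. = FALSE)
  logd <- log(D[ut][keep])
  g <- G[ut][keep]
  vx <- sum((logd - mean(logd))^2)
  slope <- sum((logd - mean(logd)) * (g - mean(g))) / vx
  intercept <- mean(g) - slope * mean(logd)
  set.seed(derive_seed31(seed, 17))
  cnt <- 0L
  for (i in seq_len(n_permutations)) {
    p <- sample.int(n)
    gp <- G[p, p][ut][keep]
    sl <- sum((logd - mean(logd)) * (gp - mean(gp))) / vx
    if (sl >= slope) cnt <- cnt + 1L
  }
  structure(list(slope = slope, intercept = intercept,
                 mantel_p = (cnt + 1) / (n_permutations + 1),
                 n_pairs = sum(keep), metric = metric),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(paste0("IBD regression (%s): slope = %.4f, intercept = %.4f, ",
                     "Mantel p = %.4g (%d pairs)\n"),
              x$metric, x$slope, x$intercept, x$mantel_p, x$n_pairs))
  invisible(x)
}

#' Descriptor table for a set of replicate samples
#'
#' Aggregates mean number of alleles, mean gene diversity (over loci, time
#' points and replicates) and the generation-0 isolation-by-distance slope
#' (over replicates) for one parameter combination, in the shape of a
#' descriptor-table row.
#'
#' @param replicates A list of replicate results from [run_replicate()].
#' @param n_permutations Mantel permutations for the IBD test.
#' @param metric IBD genetic-distance metric.
#' @param alpha Significance level for counting significant slopes.
#' @param seed Seed for the Mantel streams.
#' @return A one-row data.frame: `mean_na`, `sd_na`, `mean_h`, `sd_h`,
#'   `mean_ibd_slope`, `sd_ibd_slope`, `pct_significant`.
#' @export
descriptor_row <- function(replicates, n_permutations = 999,
                           metric = "rousset", alpha = 0.05, seed = 1) {
  per_ds <- lapply(replicates, function(r)
    vapply(r$samples, function(s) {
      d <- diversity(s); c(d$mean_na, d$mean_h)
    }, numeric(2)))
  na_all <- unlist(lapply(per_ds, function(m) m[1, ]))
  h_all <- unlist(lapply(per_ds, function(m) m[2, ]))
  ibd <- lapply(seq_along(replicates), function(i)
    ibd_regression(replicates[[i]]$samples[[1]], n_permutations,
                   metric = metric, seed = derive_seed(seed, i)))
  slopes <- vapply(ibd, `[[`, numeric(1), "slope")
  pvals <- vapply(ibd, `[[`, numeric(1), "mantel_p")
  data.frame(mean_na = mean(na_all), sd_na = sd(na_all),
             mean_h = mean(h_all), sd_h = sd(h_all),
             mean_ibd_slope = mean(slopes), sd_ibd_slope = sd(slopes),
             pct_significant = 100 * mean(pvals <= alpha))
}
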