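# Shared fixture builders and independent oracles.

# Minimal sample_set from raw pieces (coords 0-based)
make_sample <- function(xy, genotypes, n_loci, generation = 0L,
                        grid_width = max(xy[, 1]) + 1L,
                        grid_height = max(xy[, 2]) + 1L,
                        barrier = NULL) {
  q <- if (is.null(barrier)) rep(0L, nrow(xy)) else
    quadrant_of(xy[, 1], xy[, 2], barrier)
  structure(list(
    coords = data.frame(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
                        quadrant = q),
    genotypes = genotypes, n_loci = as.integer(n_loci),
    generation = as.integer(generation), replicate_id = 1L,
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height)),
    class = "sample_set")
}

# random diploid genotype matrix: n individuals, L loci, k alleles per locus
random_genotypes <- function(n, L, k) {
  m <- matrix(0L, n, 2 * L)
  for (l in seq_len(L)) {
    m[, 2 * l - 1] <- sample.int(k, n, replace = TRUE)
    m[, 2 * l] <- sample.int(k, n, replace = TRUE)
  }
  m
}

# Independent brute-force Weir & Cockerham (1984) variance components,
# written as plain loops straight from the component definitions.
wc_fst_bruteforce <- function(genotypes, groups, n_loci) {
  groups <- as.integer(factor(groups))
  r <- length(unique(groups))
  ni <- as.numeric(table(groups))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  A <- B <- C <- 0
  for (l in seq_len(n_loci)) {
    g <- genotypes[, c(2 * l - 1, 2 * l)]
    for (al in unique(as.vector(g))) {
      p_i <- h_i <- numeric(r)
      for (i in seq_len(r)) {
        rows <- which(groups == i)
        p_i[i] <- mean(c(g[rows, 1] == al, g[rows, 2] == al))
        h_i[i] <- mean((g[rows, 1] == al) != (g[rows, 2] == al))
      }
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                            (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                               hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                    ((r - 1) / r) * s2 -
                                    ((2 * nbar - 1) / (4 * nbar)) * hbar)
      A <- A + a
      B <- B + b
      C <- C + hbar / 2
    }
  }
  A / (A + B + C)
}

# two compact clusters with maximal between-cluster genetic distance:
# within-cluster distance 0, between-cluster distance 1
two_cluster_fixture <- function() {
  set.seed(99)
  xy1 <- cbind(runif(8, 0, 2.5), runif(8, 0, 6))
  xy2 <- cbind(runif(8, 7.5, 10), runif(8, 0, 6))
  xy <- rbind(xy1, xy2)
  g <- matrix(0L, 16, 4)
  g[1:8, ] <- 1L
  g[9:16, ] <- 2L
  list(xy = xy, genotypes = g, n_loci = 2L,
       cluster = rep(1:2, each = 8))
}
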