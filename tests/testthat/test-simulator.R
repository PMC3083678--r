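tiny_params <- function(...) {
  args <- list(grid_width = 10, grid_height = 10, n_loci = 5, mu = 1e-3,
               delta = 2, burn_in_generations = 0, sample_size = 10,
               export_generations = 0L, seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# whole-lattice genotypes as a matrix, for diversity checks
extract_lat_sample <- function(lat) {
  cells <- cbind(rep(0:(lat$grid_width - 1), times = lat$grid_height),
                 rep(0:(lat$grid_height - 1), each = lat$grid_width))
  barrierbench:::extract_genotypes(lat, cells)
}

test_that("initial lattice is monomorphic with the documented layout", {
  lat <- init_lattice(tiny_params())
  expect_equal(dim(lat$alleles), c(2L, 5L, 10L, 10L))
  expect_true(all(lat$alleles == 0L))
  expect_equal(lat$next_allele_id, rep(1L, 5))
  expect_equal(lat$generation, 0L)
  d <- diversity(extract_lat_sample(lat), n_loci = 5)
  expect_equal(d$mean_na, 1)
  expect_equal(d$mean_h, 0)
})

test_that("degenerate dispersal kernel returns the focal cell", {
  d <- draw_parent_cell(3, 7, sigma = 0, grid_width = 10, grid_height = 10,
                        n = 20, seed = 4)
  expect_true(all(d[, "x"] == 3L))
  expect_true(all(d[, "y"] == 7L))
})

test_that("an impermeable barrier confines parent draws to the quadrant", {
  b <- barrier_spec(split_x = 5, split_y = 5, b = 0)
  d <- draw_parent_cell(4, 4, sigma = 4, grid_width = 10, grid_height = 10,
                        barrier = b, n = 500, seed = 9)
  expect_true(all(quadrant_of(d[, 1], d[, 2], b) == 0L))
  d2 <- draw_parent_cell(5, 5, sigma = 4, grid_width = 10, grid_height = 10,
                         barrier = b, n = 500, seed = 9)
  expect_true(all(quadrant_of(d2[, 1], d2[, 2], b) == 3L))
})

test_that("draws always land inside the landscape", {
  d <- draw_parent_cell(0, 0, sigma = 10, grid_width = 8, grid_height = 8,
                        n = 2000, seed = 2)
  expect_true(all(d >= 0 & d < 8))
})

test_that("mean Euclidean parent-offspring distance matches delta", {
  # delta = sigma * sqrt(pi/2): the Rayleigh mean of the bivariate kernel
  for (delta in c(4, 11)) {
    sigma <- delta / sqrt(pi / 2)
    d <- draw_parent_cell(500, 500, sigma, 1000, 1000, n = 2e5,
                          seed = 42 + delta)
    disp <- sqrt((d[, 1] - 500)^2 + (d[, 2] - 500)^2)
    se <- sd(disp) / sqrt(length(disp))
    expect_lt(abs(mean(disp) - delta), 4 * se + 0.01 * delta)
  }
})

test_that("a fully permeable barrier crosses like no barrier at all", {
  b1 <- barrier_spec(split_x = 50, split_y = 50, b = 1)
  d_open <- draw_parent_cell(48, 48, sigma = 8, 100, 100, n = 4000,
                             seed = 5)
  d_b1 <- draw_parent_cell(48, 48, sigma = 8, 100, 100, barrier = b1,
                           n = 4000, seed = 6)
  f_open <- mean(quadrant_of(d_open[, 1], d_open[, 2], b1) != 0L)
  f_b1 <- mean(quadrant_of(d_b1[, 1], d_b1[, 2], b1) != 0L)
  expect_lt(abs(f_open - f_b1), 0.05)
})

test_that("without mutation a monomorphic lattice stays monomorphic", {
  p <- tiny_params(mu = 0)
  lat <- step_generation(init_lattice(p), p, n_generations = 10, seed = 3)
  expect_true(all(lat$alleles == 0L))
  expect_equal(lat$next_allele_id, rep(1L, 5))
  expect_equal(lat$generation, 10L)
})

test_that("mu = 1 forces every transmitted allele to be brand new", {
  p <- tiny_params(mu = 1)
  lat <- step_generation(init_lattice(p), p, n_generations = 1, seed = 3)
  expect_equal(dim(lat$alleles), c(2L, 5L, 10L, 10L))   # conservation
  for (l in 1:5) {
    copies <- as.vector(lat$alleles[, l, , ])
    expect_equal(length(unique(copies)), 200L)   # all unique
    expect_true(all(lat$alleles[1, l, , ] != lat$alleles[2, l, , ]))
  }
  expect_equal(lat$next_allele_id, rep(201L, 5))
})

test_that("allele IDs are always below the per-locus freshness counter", {
  p <- tiny_params(mu = 0.05)
  lat <- step_generation(init_lattice(p), p, n_generations = 20, seed = 8)
  for (l in 1:5)
    expect_true(all(lat$alleles[, l, , ] < lat$next_allele_id[l]))
})

test_that("drift is neutral: common allele frequency is unbiased", {
  p <- tiny_params(mu = 0)
  lat0 <- init_lattice(p)
  # half the landscape carries allele 1 on both chromosomes
  lat0$alleles[, , 1:5, ] <- 1L
  lat0$next_allele_id <- rep(2L, 5)
  freqs <- vapply(1:150, function(r) {
    lat <- step_generation(lat0, p, n_generations = 1, seed = 1000 + r)
    mean(lat$alleles[, 1, , ] == 1L)
  }, numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 4 * se)
})

test_that("small panmictic-like lattices reach Ewens/Nei equilibrium", {
  # 10x10, mu = 1e-3: theta = 0.4, expected H = 0.2857, expected allele
  # count in 200 gene copies from the Ewens sum
  p <- sim_params(grid_width = 10, grid_height = 10, n_loci = 20,
                  mu = 1e-3, delta = 8, burn_in_generations = 3000,
                  sample_size = 100, export_generations = 0L, seed = 77)
  hs <- nas <- numeric(0)
  for (r in 1:10) {
    res <- suppressWarnings(run_replicate(p, r))
    d <- diversity(res$samples[[1]])
    hs <- c(hs, d$mean_h)
    nas <- c(nas, d$mean_na)
  }
  theta <- 0.4
  exp_h <- expected_heterozygosity(theta)
  exp_k <- ewens_expected_alleles(theta, 200)
  expect_lt(abs(mean(hs) - exp_h), 3 * sd(hs) / sqrt(10))
  expect_lt(abs(mean(nas) - exp_k), 3 * sd(nas) / sqrt(10))
})

test_that("post-barrier snapshots are stamped and gen 0 is the input", {
  p <- tiny_params(mu = 1e-2, burn_in_generations = 30,
                   export_generations = c(0L, 5L, 10L))
  lat <- run_burn_in(p, equilibrium_warn = FALSE)
  snaps <- run_post_barrier(lat, p)
  expect_named(snaps, c("gen0", "gen5", "gen10"))
  expect_identical(snaps$gen0$alleles, lat$alleles)
  expect_equal(snaps$gen5$generation, 5L)
  expect_equal(snaps$gen10$generation, 10L)
  only0 <- run_post_barrier(lat, sim_params(grid_width = 10,
                                            grid_height = 10, n_loci = 5,
                                            mu = 1e-2, delta = 2,
                                            burn_in_generations = 30,
                                            sample_size = 10,
                                            export_generations = 0L))
  expect_length(only0, 1)
  expect_identical(only0$gen0$alleles, lat$alleles)
})

test_that("with b = 0 post-barrier mutations never escape their quadrant", {
  p <- sim_params(grid_width = 12, grid_height = 12, n_loci = 4, mu = 5e-3,
                  delta = 3, burn_in_generations = 40, sample_size = 10,
                  export_generations = c(0L, 15L, 30L), seed = 12)
  lat <- run_burn_in(p, equilibrium_warn = FALSE)
  bar <- barrier_spec(params = p)   # b = 0
  snaps <- run_post_barrier(lat, p, bar)
  born_after <- lat$next_allele_id  # IDs >= these are post-barrier mutants
  for (s in snaps[-1]) {
    for (l in seq_len(s$n_loci)) {
      al <- s$alleles[, l, , ]      # dim 2 x W x H
      new_ids <- unique(al[al >= born_after[l]])
      for (id in new_ids) {
        hits <- which(al == id, arr.ind = TRUE)  # (copy, x, y)
        q <- quadrant_of(hits[, 2] - 1L, hits[, 3] - 1L, bar)
        expect_length(unique(q), 1)
      }
    }
  }
})

test_that("sampling reuses one coordinate set across snapshots", {
  p <- tiny_params(mu = 1e-2, burn_in_generations = 20,
                   export_generations = c(0L, 5L))
  r <- run_replicate(p, 1)
  expect_identical(r$samples[[1]]$coords, r$samples[[2]]$coords)
  expect_false(any(duplicated(r$samples[[1]]$coords[, c("x", "y")])))
  # different replicates draw different coordinates
  r2 <- run_replicate(p, 2)
  expect_false(identical(r$samples[[1]]$coords$x, r2$samples[[1]]$coords$x))
  # sample_size = N returns the whole lattice
  b <- barrier_spec(params = p)
  s_all <- sample_individuals(init_lattice(p), 100, b, seed = 1)[[1]]
  expect_equal(nrow(s_all$coords), 100)
  expect_error(sample_individuals(init_lattice(p), 101, b, seed = 1),
               "sample_size")
})

test_that("identical seeds reproduce the simulation bit for bit", {
  p <- tiny_params(mu = 1e-2, burn_in_generations = 25,
                   export_generations = c(0L, 10L))
  r1 <- run_replicate(p, 1)
  r2 <- run_replicate(p, 1)
  expect_identical(r1$samples[[2]]$genotypes, r2$samples[[2]]$genotypes)
  expect_identical(r1$samples[[1]]$coords, r2$samples[[1]]$coords)
})

test_that("burn-in records equilibrium diagnostics", {
  p <- tiny_params(mu = 1e-2, burn_in_generations = 40)
  lat <- run_burn_in(p, diag_every = 10, equilibrium_warn = FALSE)
  dg <- attr(lat, "diagnostics")
  expect_equal(dg[, "generation"], c(10, 20, 30, 40))
  expect_true(all(dg[, "mean_na"] >= 1))
  expect_true(all(dg[, "mean_h"] >= 0 & dg[, "mean_h"] <= 1))
})
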