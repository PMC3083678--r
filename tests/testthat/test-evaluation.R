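truth_sample <- function(q, generation = 100L) {
  structure(list(coords = data.frame(quadrant = q),
                 generation = as.integer(generation)),
            class = "sample_set")
}

test_that("clustering verdicts follow the K-and-assignment rule", {
  q <- rep(0:3, each = 5)
  tr <- truth_sample(q)
  expect_true(score_clustering(cluster_result(4, rep(1:4, each = 5)), tr))
  # one misassigned individual is enough to fail
  bad <- rep(1:4, each = 5); bad[1] <- 2L
  expect_false(score_clustering(cluster_result(4, bad), tr))
  # wrong K fails even with a perfect spatial split
  expect_false(score_clustering(cluster_result(5, rep(1:4, each = 5)), tr))
  m5 <- rep(1:4, each = 5); m5[20] <- 5L
  expect_false(score_clustering(cluster_result(5, m5), tr))
  # generation 0: a single cluster is the correct answer
  tr0 <- truth_sample(q, 0L)
  expect_true(score_clustering(cluster_result(1, rep(1L, 20)), tr0))
  expect_false(score_clustering(cluster_result(4, rep(1:4, each = 5)),
                                tr0))
  expect_error(score_clustering(cluster_result(2, c(1L, 2L)), tr),
               "length")
})

test_that("clustering verdicts are invariant to label permutation", {
  set.seed(21)
  q <- rep(0:3, each = 6)
  tr <- truth_sample(q)
  base <- rep(1:4, each = 6)
  for (i in 1:10) {
    perm <- sample(4)
    expect_true(score_clustering(cluster_result(4, perm[base]), tr))
  }
  bad <- base; bad[3] <- 3L
  for (i in 1:5) {
    perm <- sample(4)
    expect_false(score_clustering(cluster_result(4, perm[bad]), tr))
  }
})

test_that("edge scoring accepts exact midlines and rejects fragments", {
  b <- barrier_spec(split_x = 50, split_y = 50)
  exact <- rbind(cbind(49.5, seq(0, 99, 0.5)), cbind(seq(0, 99, 0.5), 49.5))
  ok <- score_edges(exact, b, 500, 100, 100)
  expect_true(as.logical(ok))
  expect_equal(unname(attr(ok, "line_coverage")), c(1, 1))
  # a single fragment far from both midlines
  frag <- cbind(seq(5, 15, 0.5), 5)
  expect_false(as.logical(score_edges(frag, b, 500, 100, 100)))
  # empty output: correct at generation 0, incorrect later
  none <- matrix(numeric(0), 0, 2)
  expect_true(as.logical(score_edges(none, b, 0, 100, 100)))
  expect_false(as.logical(score_edges(none, b, 500, 100, 100)))
  # any detection at generation 0 is a false positive
  expect_false(as.logical(score_edges(exact, b, 0, 100, 100)))
})

test_that("edge scoring enforces two-sided coverage", {
  b <- barrier_spec(split_x = 50, split_y = 50)
  # only half of the vertical midline covered
  half <- rbind(cbind(49.5, seq(0, 49, 0.5)), cbind(seq(0, 99, 0.5), 49.5))
  ok <- score_edges(half, b, 500, 100, 100)
  expect_false(as.logical(ok))
  expect_lt(attr(ok, "line_coverage")["vertical"], 0.8)
  # full midlines plus a large remote blob fails the precision side
  blob <- cbind(rep(seq(5, 25, 0.5), each = 41), rep(seq(5, 25, 0.5), 41))
  exact <- rbind(cbind(49.5, seq(0, 99, 0.5)), cbind(seq(0, 99, 0.5), 49.5))
  ok2 <- score_edges(rbind(exact, blob), b, 500, 100, 100)
  expect_false(as.logical(ok2))
  expect_lt(attr(ok2, "element_precision"), 0.8)
})

test_that("benchmark aggregation is empty-safe and reproducible", {
  empty <- benchmark_table(data.frame(method = character(0),
                                      combo = character(0),
                                      generation = integer(0),
                                      replicate = integer(0),
                                      correct = logical(0),
                                      k_estimated = numeric(0)))
  expect_equal(nrow(empty), 0)
  cfg <- list(seed = 7, replicates = 2,
              combos = list(list(name = "tiny", grid_width = 16,
                                 grid_height = 16, n_loci = 4, mu = 5e-3,
                                 delta = 2, burn_in_generations = 150,
                                 export_generations = c(0L, 40L),
                                 sample_size = 40)),
              methods = list(monmonier = list(n_barriers = 2),
                             wombling = list(grid_nx = 16, grid_ny = 16,
                                             bandwidth = 3)),
              scoring = list(tolerance = 2, min_edges = 3))
  r1 <- run_benchmark(cfg, progress = FALSE)
  expect_s3_class(r1, "benchmark_result")
  expect_equal(nrow(r1$records), 2 * 2 * 2)   # 2 methods x 2 gens x 2 reps
  expect_true(all(c("combo", "generation", "monmonier_pct_correct",
                    "wombling_pct_correct") %in% names(r1$table)))
  expect_true(all(r1$table$monmonier_pct_correct >= 0 &
                    r1$table$monmonier_pct_correct <= 100))
  # bit-for-bit reproducibility under the same master seed
  r2 <- run_benchmark(cfg, progress = FALSE)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$table, r2$table)
})

test_that("external membership files are scored through the benchmark", {
  ext <- tempfile("ext")
  dir.create(ext)
  cfg <- list(seed = 3, replicates = 1,
              combos = list(list(name = "t", grid_width = 12,
                                 grid_height = 12, n_loci = 3, mu = 5e-3,
                                 delta = 2, burn_in_generations = 60,
                                 export_generations = 0L,
                                 sample_size = 20)),
              methods = list(), external = ext)
  # correct generation-0 answer: everyone in one cluster
  write.csv(data.frame(id = 1:20, cluster = rep(1, 20)),
            file.path(ext, "t_gen0_rep1.csv"), row.names = FALSE)
  r <- run_benchmark(cfg, progress = FALSE)
  expect_equal(nrow(r$records), 1)
  expect_true(r$records$correct[1])
  # missing file warns and is skipped
  unlink(file.path(ext, "t_gen0_rep1.csv"))
  expect_warning(r2 <- run_benchmark(cfg, progress = FALSE), "missing")
  expect_equal(nrow(r2$records), 0)
})

test_that("Monmonier detection improves with time since barrier imposition", {
  bat <- acceptance_battery()
  barrier <- barrier_spec(params = bat$pA)
  pct <- vapply(seq_len(6), function(g) {
    mean(vapply(bat$repsA[1:3], function(r) {
      s <- r$samples[[g]]
      mm <- monmonier(s, n_barriers = 4, distance = "residual")
      as.logical(score_edges(mm$barriers, barrier, s$generation, 100, 100))
    }, logical(1)))
  }, numeric(1))
  # nondecreasing up to one-replicate sampling slack, and a clear rise
  expect_true(all(diff(pct) >= -1 / 3))
  expect_equal(pct[1], 0)          # generation 0: no empty output possible
  expect_gt(pct[6], pct[1])
})

test_that("ranked barrier output is judged on its covering prefix", {
  b <- barrier_spec(split_x = 50, split_y = 50)
  seg_along <- function(x1, y1, x2, y2, n = 30) {
    t0 <- seq(0, 1, length.out = n + 1)
    cbind(x1 + head(t0, -1) * (x2 - x1), y1 + head(t0, -1) * (y2 - y1),
          x1 + tail(t0, -1) * (x2 - x1), y1 + tail(t0, -1) * (y2 - y1))
  }
  path <- function(segs, rank) structure(
    list(edges = seq_len(nrow(segs)), segments = segs, rank = rank),
    class = "boundary_path")
  vert <- path(seg_along(49.5, 0, 49.5, 99), 1)
  horiz <- path(seg_along(0, 49.5, 99, 49.5), 2)
  blob <- path(seg_along(5, 5, 25, 25), 3)
  # the two main barriers cover the cross; the trailing fragment is the
  # padding an inspector ignores
  expect_true(as.logical(score_edges(list(vert, horiz, blob), b, 500,
                                     100, 100)))
  # if a large spurious barrier ranks ahead of a midline, the covering
  # prefix includes it and precision fails
  blob1 <- path(seg_along(5, 5, 42, 42, n = 120), 1)
  vert2 <- path(seg_along(49.5, 0, 49.5, 99), 2)
  horiz3 <- path(seg_along(0, 49.5, 99, 49.5), 3)
  ok <- score_edges(list(blob1, vert2, horiz3), b, 500, 100, 100)
  expect_false(as.logical(ok))
  expect_lt(attr(ok, "element_precision"), 0.8)
  # coverage that never materializes is incorrect regardless of ranks
  expect_false(as.logical(score_edges(list(vert, blob), b, 500, 100, 100)))
})
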