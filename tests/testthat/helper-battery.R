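# Shared full-scale simulation battery for the acceptance checks.
# Computed lazily once per test run and cached; every consumer reads from
# the cache.  Master seed fixed once; all per-replicate and per-phase
# streams derive from it.
#
# Contents (100 x 100 landscape, 20 loci, samples of 200):
#   repsA: delta = 11, mu = 1e-4,   b = 0,    5 replicates, 6 time points
#   repsB: delta = 1,  mu = 1e-4,   b = 0,    5 replicates, 6 time points
#   repsC: delta = 1,  mu = 2.5e-5, b = 0,    3 replicates, generation 0
#          (20,000-generation burn-in: the isolation-by-distance ordering
#          is established long before full mutation-drift equilibrium)
#   repsD: delta = 11, mu = 1e-4,   b = 0.03, 3 replicates, 6 time points,
#          reusing repsA's burn-ins so pre-barrier histories are matched

.acc_env <- new.env(parent = emptyenv())

acceptance_battery <- function() {
  if (!exists("bat", envir = .acc_env)) {
    seed <- 11
    pA <- sim_preset("d11-mu1e4", seed = seed)
    pB <- sim_preset("d1-mu1e4", seed = seed)
    pC <- sim_preset("d1-mu2.5e5", seed = seed,
                     burn_in_generations = 20000L,
                     export_generations = 0L)
    pD <- sim_preset("d11-mu1e4-b03", seed = seed)
    repsA <- lapply(1:5, function(r) suppressWarnings(run_replicate(pA, r)))
    repsB <- lapply(1:5, function(r) suppressWarnings(run_replicate(pB, r)))
    repsC <- lapply(1:3, function(r) suppressWarnings(run_replicate(pC, r)))
    repsD <- lapply(1:3, function(r)
      run_replicate(pD, r, burned_in = repsA[[r]]$burned_in))
    slim <- function(reps) lapply(reps, function(r) list(samples = r$samples))
    assign("bat", list(seed = seed, pA = pA, pB = pB, pC = pC, pD = pD,
                       repsA = slim(repsA), repsB = slim(repsB),
                       repsC = slim(repsC), repsD = slim(repsD)),
           envir = .acc_env)
  }
  get("bat", envir = .acc_env)
}

# mean over loci, time points and replicates of a per-sample diversity stat
battery_diversity <- function(reps, stat, n_reps = length(reps)) {
  vals <- unlist(lapply(reps[seq_len(n_reps)], function(r)
    vapply(r$samples, function(s) diversity(s)[[stat]], numeric(1))))
  mean(vals)
}
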