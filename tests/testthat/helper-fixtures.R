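## Shared fixtures, memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

## small null table for unit tests (fast; p-value floor 2e-5)
small_null_table <- function() {
  memo("small_tab", build_null_table(n_range = 5:60, n_samples = 5e4,
                                     seed = 424242))
}

## modest simulated dataset shared across unit tests
small_sim <- function() {
  memo("small_sim", {
    grid <- motif_grid(n_occupied = 40, n_decoy = 40, seed = 7)
    cfg <- simulation_config(grid$motifs, grid$chromsizes,
                             pairs_per_motif = 400, seed = 7)
    sim <- simulate_pairs(cfg)
    sim$contacts <- reconstruct_fragments(sim$records)
    sim$chromsizes <- grid$chromsizes
    sim
  })
}

## exact multinomial tail probabilities of log2(alpha) on a grid, by
## enumeration of all quadrant splits of n (independent oracle)
enumerate_null_tail <- function(n, grid = seq(0, 5, by = 0.01), cap = 32) {
  parts <- as.matrix(expand.grid(n1 = 0:n, n2 = 0:n, n3 = 0:n))
  parts <- parts[rowSums(parts) <= n, , drop = FALSE]
  n4 <- n - rowSums(parts)
  pmf <- apply(cbind(parts, n4), 1, function(x) {
    dmultinom(x, prob = rep(0.25, 4))
  })
  alpha <- camel_statistic(parts[, 1], parts[, 2], parts[, 3], n4, cap = cap)
  la <- ifelse(alpha > 0, log2(alpha), -Inf)
  vapply(grid, function(g) sum(pmf[la >= g]), numeric(1))
}

## full-resolution null table shared by the acceptance-grade tests
full_null_table <- function() {
  memo("full_tab", build_null_table(n_range = 5:500, n_samples = 1e6,
                                    seed = 20240801))
}

## the detection benchmark at study-condition scale
acceptance_bench <- function() {
  memo("bench", detection_benchmark(seed = 101,
                                    null_table = full_null_table()))
}

## extrusion-focused simulation with an injected convergent-capture spike
extrusion_sim <- function() {
  memo("extrusion_sim", {
    grid <- motif_grid(n_occupied = 440, n_decoy = 0, spacing = 20000L,
                       occupancy = 1, seed = 55)
    cfg <- simulation_config(
      grid$motifs, grid$chromsizes, pairs_per_motif = 160L,
      class_probs_bound = c(tf_core = 0, tf_full = 0, tf_cohesin = 1),
      interaction = list(loop_weight = 0.35, spike_prob = 0.12),
      partner = list(short_prob = 1), seed = 55
    )
    sim <- simulate_pairs(cfg)
    sim$contacts <- reconstruct_fragments(sim$records)
    sim$config <- cfg
    sim
  })
}
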