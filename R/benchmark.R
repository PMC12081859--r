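## Synthetic detection benchmark: occupied motifs vs decoys, scored
## end-to-end through the simulator, the empirical null, scanning and
## peak calling.

#' Binding-site detection benchmark on synthetic pairs
#'
#' Simulates a chromosome with occupied CTCF motifs (occupancy 0.5,
#' boundary jitter sd 2 bp) and never-bound decoy motifs, builds the
#' multinomial null table, scans every bp within 150 bp of any motif, calls
#' peaks at the nominal threshold, and scores the calls against the known
#' occupied motif centers.
#'
#' @param seed RNG seed driving the simulation and the null table.
#' @param n_occupied,n_decoy numbers of occupied and decoy motifs.
#' @param pairs_per_motif simulated pairs anchored at each motif (800
#'   yields well over 200 observed-ligation fragments per occupied site).
#' @param occupancy per-molecule binding probability at occupied motifs.
#' @param null_samples Monte Carlo samples per total count for the null
#'   table (at least 1e6 so p-values resolve below the threshold).
#' @param null_table optional pre-built `camel_null_table` to reuse.
#' @param p_threshold nominal p-value threshold for peak calls.
#' @param match_radius bp radius for matching a peak to an occupied motif.
#' @return List with `precision`, `recall`, `frac_within_20bp`,
#'   `median_center_error`, `fdr` (all proportions except the median, in
#'   bp), `n_peaks`, `n_true`, plus the `peaks` table and `motifs`.
#' @export
detection_benchmark <- function(seed = 1L, n_occupied = 1000L,
                                n_decoy = 1000L, pairs_per_motif = 800L,
                                occupancy = 0.5, null_samples = 1e6,
                                null_table = NULL, p_threshold = 1e-5,
                                match_radius = 30L) {
  grid <- motif_grid(n_occupied = n_occupied, n_decoy = n_decoy,
                     occupancy = occupancy, seed = seed)
  cfg <- simulation_config(grid$motifs, grid$chromsizes,
                           pairs_per_motif = pairs_per_motif,
                           jitter_sd = 2, seed = seed + 1L)
  sim <- simulate_pairs(cfg)
  contacts <- reconstruct_fragments(sim$records)
  events <- fragment_events(contacts)
  if (is.null(null_table)) {
    null_table <- build_null_table(n_samples = null_samples,
                                   seed = seed + 2L)
  }
  scores <- camel_scan(events,
                       candidate_positions(sim$motifs, flank = 150L),
                       null_table)
  peaks <- call_peaks(scores, p_threshold = p_threshold)
  occ <- sim$motifs[sim$motifs$occupied == TRUE]
  ctr <- motif_center(occ)
  dist <- .nearest_dist(peaks$center, ctr)
  tp <- sum(dist <= match_radius)
  fp <- nrow(peaks) - tp
  detected <- .nearest_dist(ctr, peaks$center) <= match_radius
  list(
    precision = if (nrow(peaks)) tp / nrow(peaks) else NA_real_,
    recall = mean(detected),
    frac_within_20bp = if (nrow(peaks)) mean(dist <= 20) else NA_real_,
    median_center_error = if (nrow(peaks)) median(dist) else NA_real_,
    fdr = if (nrow(peaks)) fp / nrow(peaks) else NA_real_,
    n_peaks = nrow(peaks), n_true = length(ctr),
    peaks = peaks, motifs = sim$motifs, null_table = null_table
  )
}
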