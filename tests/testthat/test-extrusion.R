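test_that("the four qualifying filters match their printed thresholds", {
  sim <- extrusion_sim()
  q <- select_tf_protected_long_range(sim$contacts, sim$motifs)
  expect_gt(nrow(q), 0)
  expect_true(all(q$frag_len < 120))
  expect_true(all(q$rel_start <= -5))
  expect_true(all(q$rel_end >= 48))
  expect_true(all(q$interaction_length > 10000))
  ## brute-force application of the predicates on the same overlap set
  ov <- rbind(
    motif_overlaps(sim$contacts, sim$motifs[sim$motifs$strand == "+"],
                   side = 1L),
    motif_overlaps(sim$contacts, sim$motifs[sim$motifs$strand == "-"],
                   side = 2L)
  )
  keep <- ov$frag_len < 120 & ov$rel_start <= -5 & ov$rel_end >= 40 &
    ov$rel_end >= 48 & !ov$trans & ov$interaction_length > 10000
  expect_equal(nrow(q), sum(keep))
  ## individual exclusions
  expect_false(any(q$frag_len == 130))
  expect_false(any(q$interaction_length == 8000))
})

test_that("fully-extruded arithmetic follows the printed rule", {
  ## 50 fragments, 5 convergent -> raw 0.10, adjusted 0.05
  motifs <- data.table::data.table(
    chrom = "chrE", start = c(1000L, 60000L), end = c(1035L, 60035L),
    strand = c("+", "-"), motif_id = c("cbs", "conv"), occupancy = 1
  )
  mk_qual <- function(n, n_conv) {
    data.table::data.table(
      contact_row = seq_len(n), side = 1L, chrom = "chrE",
      start = 990L, end = 1045L, strand = "+", frag_len = 55L,
      censored = FALSE, partner_chrom = "chrE",
      partner_start = c(rep(60000L, n_conv), rep(30000L, n - n_conv)),
      partner_end = c(rep(60040L, n_conv), rep(30040L, n - n_conv)),
      trans = FALSE, interaction_length = 50000,
      motif_id = "cbs", motif_start = 1000L, motif_end = 1035L,
      motif_strand = "+", rel_start = -10L, rel_end = 45L
    )
  }
  est <- fully_extruded_fraction(mk_qual(50L, 5L), motifs)
  expect_equal(est$raw_fraction, 0.10)
  expect_equal(est$adjusted_fraction, 0.05)
  ## 49 fragments -> below the minimum, no estimate
  expect_equal(nrow(fully_extruded_fraction(mk_qual(49L, 5L), motifs)), 0L)
  ## upstream convergent motifs never count
  up <- mk_qual(50L, 5L)
  up$partner_start <- rep(200L, 50L)
  up$partner_end <- rep(240L, 50L)
  motifs_up <- data.table::copy(motifs)
  motifs_up$start[2] <- 190L
  motifs_up$end[2] <- 225L
  expect_equal(fully_extruded_fraction(up, motifs_up)$raw_fraction, 0)
})

test_that("convergent flags match a brute-force interval oracle", {
  sim <- extrusion_sim()
  q <- select_tf_protected_long_range(sim$contacts, sim$motifs)
  est <- fully_extruded_fraction(q, sim$motifs, min_n = 1L)
  m <- sim$motifs
  oracle <- vapply(seq_len(nrow(q)), function(i) {
    s <- q$motif_strand[i]
    conv <- m[m$strand == (if (s == "+") "-" else "+")]
    ctr <- motif_center(conv)
    cbs_ctr <- q$motif_start[i] + 18L
    down <- if (s == "+") ctr > cbs_ctr else ctr < cbs_ctr
    any(down & conv$chrom == q$partner_chrom[i] &
          q$partner_start[i] < conv$end & q$partner_end[i] > conv$start)
  }, logical(1))
  agg <- data.table::data.table(motif_id = q$motif_id, conv = oracle)[
    , .(n = .N, nc = sum(conv)), by = motif_id]
  got <- merge(est, agg, by = "motif_id")
  expect_equal(got$n_fragments, got$n)
  expect_equal(got$n_convergent, got$nc)
})

test_that("the estimator recovers the injected fully-extruded probability", {
  sim <- extrusion_sim()
  ## canonical analysis: + strand CBS with left fragments; partners are
  ## tested against the full (both-strand) motif set
  q <- select_tf_protected_long_range(
    sim$contacts, sim$motifs[sim$motifs$strand == "+"])
  est <- fully_extruded_fraction(q, sim$motifs, min_n = 50L)
  expect_gte(nrow(est), 200L)
  expect_true(all(est$adjusted_fraction >= 0 & est$adjusted_fraction <= 0.5))
  f <- sim$config$interaction$spike_prob
  summ <- genomewide_extrusion_summary(est)
  n_tot <- sum(est$n_fragments)
  se <- sqrt(f * (1 - f) / n_tot) / 2
  ## allowance for chance overlap of non-loop partners with motifs
  accidental <- (35 + 100) / (2 * 20000) / 2
  expect_lt(abs(summ$pooled - f / 2), 3 * se + accidental)
  expect_lt(abs(summ$mean - f / 2), 0.01)
})

test_that("genome-wide summary quantiles follow the nearest-rank oracle", {
  est <- data.table::data.table(
    motif_id = paste0("m", 1:9), n_fragments = 100L, n_convergent = 1:9,
    raw_fraction = (1:9) / 100, adjusted_fraction = (1:9) / 200,
    occupancy = 0.5
  )
  s <- genomewide_extrusion_summary(est, probs = c(0.25, 0.75))
  x <- sort(est$adjusted_fraction)
  expect_equal(s$q_lo, x[ceiling(0.25 * 9)])
  expect_equal(s$q_hi, x[ceiling(0.75 * 9)])
  expect_equal(s$mean, mean(est$adjusted_fraction))
  ## single estimate: mean equals it, zero-width range
  s1 <- genomewide_extrusion_summary(est[3])
  expect_equal(s1$mean, est$adjusted_fraction[3])
  expect_equal(s1$q_lo, s1$q_hi)
})

test_that("trans partners give the geometric background overlap rate", {
  ## uniform partner fragments on a second chromosome
  set.seed(19)
  n <- 20000L
  gsize <- 2e6L
  frag_len <- 40L
  contacts <- data.table::data.table(
    read_id = paste0("t", 1:n), pair_type = "UU",
    chrom1 = "chrA", start1 = 1000L, end1 = 1060L, strand1 = "+",
    chrom2 = "chrB",
    start2 = sample.int(gsize - frag_len, n, replace = TRUE),
    strand2 = "-", length1 = 60L,
    censored1 = FALSE, censored2 = FALSE,
    degenerate = FALSE, trans = TRUE, interaction_length = NA_real_
  )
  contacts[, end2 := start2 + frag_len]
  contacts[, length2 := frag_len]
  motifs <- data.table::data.table(
    chrom = "chrB", start = seq(50000L, 1950000L, by = 100000L))
  motifs[, `:=`(end = start + 35L, strand = "-",
                motif_id = paste0("c", seq_len(.N)))]
  got <- trans_background_fraction(contacts, motifs)
  p_exp <- nrow(motifs) * (35 + frag_len - 1) / gsize
  expect_lt(abs(got$fraction - p_exp), 3 * sqrt(p_exp / n))
  ## no overlaps -> 0
  none <- trans_background_fraction(
    contacts[1:10], motifs[, .(chrom = "chrC", start, end, strand, motif_id)])
  expect_equal(none$fraction, 0)
})

test_that("downstream context fractions match interval arithmetic", {
  cbs <- data.table::data.table(
    chrom = "chrZ", start = c(10000L, 40000L), end = c(10035L, 40035L),
    strand = c("+", "-"), motif_id = c("p", "q")
  )
  seg <- data.table::data.table(
    chrom = "chrZ",
    start = c(0L, 12000L, 20000L, 30000L, 36000L),
    end = c(12000L, 20000L, 30000L, 36000L, 60000L),
    state = c("E1", "E2", "E3", "E1", "E4")
  )
  map <- c(E1 = "active", E2 = "active", E3 = "polycomb_bivalent",
           E4 = "quiescent")
  cx <- annotate_downstream_context(cbs, seg, map, window = 10000)
  ## + CBS "p": window [10035, 20035): E1 tail 1965bp, E2 8000bp, E3 35bp
  p <- cx[cx$motif_id == "p"]
  expect_equal(p$fraction[p$category == "active"], (1965 + 8000) / 10000)
  expect_equal(p$fraction[p$category == "polycomb_bivalent"], 35 / 10000)
  expect_equal(p$fraction[p$category == "quiescent"], 0)
  ## - CBS "q": oriented downstream is decreasing: window [30000, 40000):
  ## E1 6000bp in [30000,36000), E4 4000bp in [36000,40000)
  qq <- cx[cx$motif_id == "q"]
  expect_equal(qq$fraction[qq$category == "active"], 0.6)
  expect_equal(qq$fraction[qq$category == "quiescent"], 0.4)
  ## fractions sum to at most 1 with unannotated remainder allowed
  expect_true(all(cx[, .(s = sum(fraction)), by = motif_id]$s <= 1 + 1e-9))
  ## window fully inside one state -> fraction 1
  one <- annotate_downstream_context(cbs[1], seg, map, window = 1000)
  expect_equal(one$fraction[one$category == "active"], 1)
  ## unmapped state label is an error naming the label
  expect_error(annotate_downstream_context(cbs, seg, map[-4], 1000), "E4")
  ## empty segmentation -> all-zero fractions
  empty <- annotate_downstream_context(
    cbs, seg[0], map, window = 1000)
  expect_true(all(empty$fraction == 0))
})

test_that("top-context-quantile selection is deterministic", {
  cx <- data.table::data.table(
    motif_id = sprintf("m%02d", 1:10), category = "active",
    fraction = c(0.9, 0.8, rep(0.5, 8))
  )
  sel <- select_top_context_quantile(cx, "active", q = 0.2)
  expect_equal(sel, c("m01", "m02"))
  ## all-equal fractions: ties broken by motif id, still ceiling(qN) picks
  cx$fraction <- 0.5
  expect_equal(select_top_context_quantile(cx, "active", 0.2),
               c("m01", "m02"))
})

test_that("loop length summary is the mean log10 interaction length", {
  s <- loop_length_summary(c(1e4, 1e6))
  expect_equal(s$mean_log10_length, 5)
  expect_equal(s$geometric_mean_bp, 1e5)
  s1 <- loop_length_summary(31623)
  expect_equal(s1$geometric_mean_bp, 31623, tolerance = 1e-6)
  set.seed(4)
  x <- 10^runif(500, 4, 6)
  expect_equal(loop_length_summary(x)$mean_log10_length, mean(log10(x)))
})

test_that("P(s) masses are normalized and refinement-consistent", {
  x <- c(1500, 2500, 2500, 40000)
  ps <- ps_curve(x, breaks = c(1e3, 1e4, 1e5))
  expect_equal(ps$mass, c(0.75, 0.25))
  expect_equal(sum(ps$mass), 1)
  ## all in one bin
  ps1 <- ps_curve(rep(5000, 10), breaks = c(1e3, 1e4, 1e5))
  expect_equal(ps1$mass, c(1, 0))
  ## histogram oracle + merging adjacent bins sums their masses
  set.seed(6)
  y <- 10^runif(2000, 3.01, 6.99)
  br <- 10^seq(3, 7, by = 0.5)
  ps2 <- ps_curve(y, breaks = br)
  h <- hist(y, breaks = br, plot = FALSE)
  expect_equal(ps2$count, h$counts)
  br2 <- br[seq(1, length(br), by = 2)]
  ps3 <- ps_curve(y, breaks = br2)
  merged <- ps2$mass[seq(1, 8, 2)] + ps2$mass[seq(2, 8, 2)]
  expect_equal(ps3$mass, merged)
})

test_that("mixed model recovers a known cohesin effect", {
  set.seed(23)
  n_cbs <- 200L
  per <- 20L
  beta <- 0.3
  u <- rnorm(n_cbs, 0, 0.2)
  dat <- data.table::CJ(cbs = seq_len(n_cbs), rep = seq_len(2L * per))
  dat[, class_label := rep(c("nucleosome", "cohesin_tf"),
                           each = per, times = n_cbs)]
  dat[, log10_length := 4.5 + u[cbs] + beta * (class_label == "cohesin_tf") +
        rnorm(.N, 0, 0.3)]
  data.table::setnames(dat, "cbs", "cbs_id")
  fit <- cohesin_effect_mixed_model(dat)
  expect_lt(abs(fit$beta - beta), 3 * fit$se)
  ## balanced design: beta-hat equals the mean within-CBS difference
  within <- dat[, .(d = mean(log10_length[class_label == "cohesin_tf"]) -
                      mean(log10_length[class_label == "nucleosome"])),
                by = cbs_id]
  expect_equal(fit$beta, mean(within$d), tolerance = 1e-6)
  ## no between-CBS variance: estimate equals the plain group difference
  dat0 <- data.table::copy(dat)
  dat0[, log10_length := 4.5 + beta * (class_label == "cohesin_tf") +
         rnorm(.N, 0, 0.3)]
  fit0 <- cohesin_effect_mixed_model(dat0)
  diff0 <- dat0[class_label == "cohesin_tf", mean(log10_length)] -
    dat0[class_label == "nucleosome", mean(log10_length)]
  expect_equal(fit0$beta, diff0, tolerance = 1e-6)
  ## single class is an error
  expect_error(cohesin_effect_mixed_model(dat[class_label == "nucleosome"]),
               "two fragment classes")
})

test_that("excluding convergent contacts complements the convergent flag", {
  sim <- extrusion_sim()
  q <- select_tf_protected_long_range(sim$contacts, sim$motifs)
  q[, rid := .I]
  kept <- exclude_convergent_contacts(q, sim$motifs)
  est <- fully_extruded_fraction(q, sim$motifs, min_n = 1L)
  expect_equal(nrow(kept), sum(est$n_fragments) - sum(est$n_convergent))
  ## none convergent -> identity
  expect_equal(nrow(exclude_convergent_contacts(kept, sim$motifs)),
               nrow(kept))
  ## all convergent -> empty
  conv_rows <- q[!rid %in% kept$rid]
  expect_gt(nrow(conv_rows), 0L)
  expect_equal(nrow(exclude_convergent_contacts(conv_rows, sim$motifs)), 0L)
})
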