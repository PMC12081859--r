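## Loop-extrusion estimators: the fully-extruded (CTCF-CTCF) loop fraction,
## chromatin-context-stratified extruded loop sizes, P(s) curves, and a
## mixed-model estimate of the cohesin effect on interaction length.
##
## "Downstream" is always motif-oriented: increasing coordinates for +
## strand binding sites, decreasing for - strand, with all convergence and
## window logic mirrored.

#' Select long-range TF-protected fragments at CTCF binding sites
#'
#' Applies the four fragment filters used for extrusion estimates: TF-scale
#' length (`< short_threshold`), boundary margins relative to the motif
#' ([tf_margin_filter()]), a cohesin-extended fragment end
#' (`rel_end >= extended_end_min`), and a long-range interaction partner
#' (`interaction_length > min_interaction`). For + strand sites the left
#' fragment of each pair is used; for - strand sites, the right fragment.
#'
#' @param contacts contacts `data.table` from [reconstruct_fragments()].
#' @param cbs motif `data.table` of binding sites (strand required).
#' @param min_interaction minimum partner distance, bp (default 10000).
#' @param short_threshold TF-scale length cutoff (default 120 bp).
#' @param extended_end_min extended-end cutoff (default 48 bp from the
#'   oriented motif start).
#' @param margin boundary margin in bp (default 5).
#' @param margin_mode margin interpretation, see [tf_margin_filter()].
#' @param observed_only restrict anchors to observed-ligation pairs.
#' @return `data.table` of qualifying (fragment, CBS) rows as from
#'   [motif_overlaps()].
#' @export
select_tf_protected_long_range <- function(contacts, cbs,
                                           min_interaction = 10000L,
                                           short_threshold = 120L,
                                           extended_end_min = 48L,
                                           margin = 5L,
                                           margin_mode = c("outside",
                                                           "distance"),
                                           observed_only = TRUE) {
  margin_mode <- match.arg(margin_mode)
  cbs <- as.data.table(cbs)
  ov <- rbind(
    motif_overlaps(contacts, cbs[strand == "+"], side = 1L,
                   observed_only = observed_only),
    motif_overlaps(contacts, cbs[strand == "-"], side = 2L,
                   observed_only = observed_only)
  )
  keep <- ov$frag_len < short_threshold &
    tf_margin_filter(ov, margin = margin,
                     motif_len = ov$motif_end - ov$motif_start,
                     mode = margin_mode) &
    ov$rel_end >= extended_end_min &
    !ov$trans & !is.na(ov$interaction_length) &
    ov$interaction_length > min_interaction
  ov[keep]
}

## flag qualifying rows whose partner fragment overlaps a downstream
## convergent (opposite-strand) motif
.flag_convergent <- function(qualifying, motifs, slack = 0L,
                             nearest_only = FALSE) {
  q <- as.data.table(qualifying)
  if (!nrow(q)) return(logical(0))
  m <- as.data.table(motifs)
  flag <- logical(nrow(q))
  for (s in c("+", "-")) {
    qi <- which(q$motif_strand == s)
    if (!length(qi)) next
    conv <- m[strand == (if (s == "+") "-" else "+")]
    if (!nrow(conv)) next
    pgr <- GRanges(q$partner_chrom[qi],
                   IRanges(q$partner_start[qi] + 1L - slack,
                           q$partner_end[qi] + slack))
    hits <- findOverlaps(pgr, .motif_granges(conv), ignore.strand = TRUE)
    if (!length(hits)) next
    hq <- qi[queryHits(hits)]
    hm <- subjectHits(hits)
    conv_ctr <- motif_center(conv)
    cbs_ctr <- q$motif_start[hq] +
      ((q$motif_end[hq] - q$motif_start[hq] + 1L) %/% 2L)
    downstream <- q$partner_chrom[hq] == conv$chrom[hm] &
      (if (s == "+") conv_ctr[hm] > cbs_ctr else conv_ctr[hm] < cbs_ctr)
    if (nearest_only) {
      ## keep only hits on the nearest downstream convergent motif per CBS
      dd <- abs(conv_ctr[hm] - cbs_ctr)
      hit_dt <- data.table(hq = hq, dd = dd, down = downstream)
      near <- hit_dt[down == TRUE, .(dmin = min(dd)), by = hq]
      hit_dt <- merge(hit_dt, near, by = "hq", all.x = TRUE)
      downstream <- hit_dt$down & !is.na(hit_dt$dmin) & hit_dt$dd == hit_dt$dmin
      hq <- hit_dt$hq
    }
    flag[unique(hq[downstream])] <- TRUE
  }
  flag
}

#' Per-CBS fully-extruded (CTCF-CTCF) loop fraction
#'
#' For each binding site with at least `min_n` qualifying long-range
#' TF-protected fragments, the raw fraction is the share of interaction
#' partners overlapping a downstream convergent (opposite-strand) motif.
#' Because the estimate conditions on CTCF being bound at the anchor, the
#' adjusted fraction multiplies by the assumed occupancy (default 0.5,
#' i.e. division by two).
#'
#' @param qualifying output of [select_tf_protected_long_range()].
#' @param motifs motif `data.table` supplying convergent-partner motifs
#'   (typically all motifs, both strands).
#' @param min_n minimum qualifying fragments per CBS (default 50).
#' @param occupancy assumed probability that the anchor motif is bound
#'   (default 0.5).
#' @param slack bp added around the partner fragment when testing motif
#'   overlap (default 0).
#' @param nearest_only count only partners overlapping the nearest
#'   downstream convergent motif (default FALSE: any downstream motif).
#' @return `data.table` per retained CBS: `motif_id`, `n_fragments`,
#'   `n_convergent`, `raw_fraction`, `adjusted_fraction`, `occupancy`.
#' @export
fully_extruded_fraction <- function(qualifying, motifs, min_n = 50L,
                                    occupancy = 0.5, slack = 0L,
                                    nearest_only = FALSE) {
  q <- as.data.table(qualifying)
  if (!nrow(q)) {
    return(data.table(motif_id = character(), n_fragments = integer(),
                      n_convergent = integer(), raw_fraction = numeric(),
                      adjusted_fraction = numeric(), occupancy = numeric()))
  }
  q[, convergent := .flag_convergent(q, motifs, slack = slack,
                                     nearest_only = nearest_only)]
  est <- q[, .(n_fragments = .N, n_convergent = sum(convergent)),
           by = motif_id]
  est <- est[n_fragments >= min_n]
  est[, raw_fraction := n_convergent / n_fragments]
  est[, adjusted_fraction := raw_fraction * occupancy]
  est[, occupancy := occupancy]
  est[]
}

#' Genome-wide summary of fully-extruded fractions
#'
#' @param estimates per-CBS table from [fully_extruded_fraction()].
#' @param probs percentile pair for the reported range (default 1st and
#'   99th), computed by the nearest-rank method.
#' @return List: `mean` (mean CBS-level adjusted fraction), `pooled`
#'   (total convergent / total fragments, occupancy-adjusted), `q_lo`,
#'   `q_hi`, `n_cbs`.
#' @export
genomewide_extrusion_summary <- function(estimates, probs = c(0.01, 0.99)) {
  stopifnot(nrow(estimates) >= 1L)
  qs <- quantile(estimates$adjusted_fraction, probs = probs, type = 1,
                 names = FALSE)
  list(
    mean = mean(estimates$adjusted_fraction),
    pooled = sum(estimates$n_convergent) / sum(estimates$n_fragments) *
      estimates$occupancy[1L],
    q_lo = qs[1L], q_hi = qs[2L],
    n_cbs = nrow(estimates)
  )
}

#' Convergent-overlap rate among trans contacts
#'
#' Trans (inter-chromosomal) partners cannot be linked by extrusion, so the
#' rate at which they happen to overlap convergent motifs is a
#' random-ligation background for the convergent fraction.
#'
#' @param contacts contacts `data.table`.
#' @param convergent_motifs motif `data.table` of the motif set partners
#'   are tested against.
#' @param slack bp slack around partner fragments (default 0).
#' @return List: `fraction`, `n_overlapping`, `n_trans`.
#' @export
trans_background_fraction <- function(contacts, convergent_motifs,
                                      slack = 0L) {
  tr <- as.data.table(contacts)[trans == TRUE & degenerate == FALSE]
  if (!nrow(tr)) return(list(fraction = 0, n_overlapping = 0L, n_trans = 0L))
  pgr <- GRanges(tr$chrom2, IRanges(tr$start2 + 1L - slack, tr$end2 + slack))
  hit <- suppressWarnings(
    overlapsAny(pgr, .motif_granges(convergent_motifs),
                ignore.strand = TRUE))
  list(fraction = mean(hit), n_overlapping = sum(hit), n_trans = nrow(tr))
}

#' Chromatin-category composition downstream of binding sites
#'
#' Annotates the motif-oriented downstream window of each CBS with the
#' fraction of bp per chromatin category, collapsing segmentation states
#' through `category_map`. Windows are clipped at chromosome ends and
#' fractions use the clipped width, so they sum to at most 1 (an
#' unannotated remainder is allowed).
#'
#' @param cbs motif `data.table` (strand required).
#' @param segmentation `data.table` from [read_segmentation_bed()];
#'   intervals must not overlap.
#' @param category_map named character vector state -> category; every
#'   state present in `segmentation` must be mapped.
#' @param window downstream window size, bp (default 1e6).
#' @param chromsizes named vector for clipping (optional).
#' @return `data.table` per (CBS, category): `motif_id`, `category`,
#'   `fraction`, plus window coordinates.
#' @export
annotate_downstream_context <- function(cbs, segmentation, category_map,
                                        window = 1e6, chromsizes = NULL) {
  seg <- as.data.table(segmentation)
  unmapped <- setdiff(unique(seg$state), names(category_map))
  if (length(unmapped)) {
    stop("segmentation states missing from category map: ",
         paste(unmapped, collapse = ", "))
  }
  seg_gr <- GRanges(seg$chrom, IRanges(seg$start + 1L, seg$end))
  ov_self <- findOverlaps(seg_gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov_self)) stop("segmentation intervals overlap")
  m <- as.data.table(cbs)
  win_start <- ifelse(m$strand == "+", m$end, pmax(0L, m$start - as.integer(window)))
  win_end <- ifelse(m$strand == "+", m$end + as.integer(window), m$start)
  win_start <- pmax(win_start, 0L)
  if (!is.null(chromsizes)) {
    win_end <- pmin(win_end, as.integer(chromsizes[m$chrom]))
  }
  win_gr <- GRanges(m$chrom, IRanges(win_start + 1L, pmax(win_end, win_start + 1L)))
  hits <- findOverlaps(win_gr, seg_gr)
  cats <- sort(unique(unname(category_map)))
  base <- CJ(motif_id = m$motif_id, category = cats, unique = TRUE)
  if (length(hits)) {
    inter <- pintersect(win_gr[queryHits(hits)], seg_gr[subjectHits(hits)])
    bp <- data.table(
      motif_id = m$motif_id[queryHits(hits)],
      category = unname(category_map[seg$state[subjectHits(hits)]]),
      bp = width(inter)
    )[, .(bp = sum(bp)), by = .(motif_id, category)]
  } else {
    bp <- data.table(motif_id = character(), category = character(),
                     bp = integer())
  }
  out <- merge(base, bp, by = c("motif_id", "category"), all.x = TRUE)
  out[is.na(bp), bp := 0L]
  wdt <- data.table(motif_id = m$motif_id, win_start = win_start,
                    win_end = win_end,
                    win_width = pmax(win_end - win_start, 1L))
  out <- merge(out, wdt, by = "motif_id")
  out[, fraction := bp / win_width]
  setorder(out, motif_id, category)
  out[]
}

#' Select the CBS with the highest fraction of a chromatin category
#'
#' @param contexts long table from [annotate_downstream_context()].
#' @param category category label to rank by.
#' @param q top quantile to keep (default 0.20); the top `ceiling(q * N)`
#'   sites are selected, ties broken by motif id.
#' @return Character vector of selected `motif_id`s.
#' @export
select_top_context_quantile <- function(contexts, category, q = 0.20) {
  cat_sel <- category
  cx <- as.data.table(contexts)[category == cat_sel]
  if (!nrow(cx)) stop("category not present: ", category)
  setorder(cx, -fraction, motif_id)
  k <- ceiling(q * nrow(cx))
  cx$motif_id[seq_len(k)]
}

#' Extruded loop size as mean log10 interaction length
#'
#' @param interaction_lengths numeric vector of partner distances (bp).
#' @param group label for the summarized set.
#' @return `data.table`: `group`, `n`, `mean_log10_length`,
#'   `geometric_mean_bp`.
#' @export
loop_length_summary <- function(interaction_lengths, group = "all") {
  x <- interaction_lengths[!is.na(interaction_lengths)]
  stopifnot(length(x) >= 1L, all(x > 0))
  m <- mean(log10(x))
  data.table(group = group, n = length(x), mean_log10_length = m,
             geometric_mean_bp = 10^m)
}

#' Contact probability as a function of genomic separation
#'
#' @param interaction_lengths cis partner distances (bp).
#' @param breaks ascending bin boundaries; default 40 log-spaced bins
#'   spanning the data.
#' @param n_bins number of default bins.
#' @return `data.table` per bin: `bin_lo`, `bin_hi`, `mid` (geometric
#'   midpoint), `count`, `mass` (normalized to sum 1 over in-range pairs),
#'   `density_per_bp` (mass / bin width).
#' @export
ps_curve <- function(interaction_lengths, breaks = NULL, n_bins = 40L) {
  x <- interaction_lengths[!is.na(interaction_lengths) &
                             interaction_lengths > 0]
  stopifnot(length(x) >= 1L)
  if (is.null(breaks)) {
    breaks <- 10^seq(log10(min(x)) - 1e-9, log10(max(x)) + 1e-9,
                     length.out = n_bins + 1L)
  }
  if (any(diff(breaks) <= 0)) stop("breaks must be ascending")
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  inb <- idx >= 1L & idx <= length(breaks) - 1L
  cnt <- tabulate(idx[inb], nbins = length(breaks) - 1L)
  out <- data.table(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
    mid = sqrt(breaks[-length(breaks)] * breaks[-1L]),
    count = cnt, mass = cnt / sum(cnt)
  )
  out[, density_per_bp := mass / (bin_hi - bin_lo)]
  out[]
}

#' Mixed-model estimate of the cohesin effect on interaction length
#'
#' Fits `log10(length) ~ class + (1 | cbs)` by REML (via lme4), estimating
#' the average increase in log10 interaction length for cohesin-extended TF
#' fragments relative to nucleosome fragments while absorbing
#' locus-to-locus baseline variability in a per-CBS random intercept.
#'
#' @param data `data.table` with columns `log10_length`, `class_label`
#'   (two levels; the reference is the first after factoring, by default
#'   `"nucleosome"` when present) and `cbs_id`.
#' @param reference reference class level (default `"nucleosome"`).
#' @return List: `beta` (fixed class effect, log10 bp), `se`, `t`,
#'   `sigma_cbs`, `sigma_resid`, `n`, `n_cbs`, and the fitted `model`.
#' @export
cohesin_effect_mixed_model <- function(data, reference = "nucleosome") {
  dt <- as.data.table(data)
  stopifnot(all(c("log10_length", "class_label", "cbs_id") %in% names(dt)))
  lv <- unique(dt$class_label)
  if (length(lv) < 2L) stop("need two fragment classes, got: ",
                            paste(lv, collapse = ", "))
  if (length(unique(dt$cbs_id)) < 2L) stop("need fragments from >= 2 CBS")
  if (reference %in% lv) lv <- c(reference, setdiff(lv, reference))
  dt[, class_label := factor(class_label, levels = lv)]
  fit <- lme4::lmer(log10_length ~ class_label + (1 | cbs_id), data = dt,
                    REML = TRUE)
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    beta = unname(co[2L, "Estimate"]),
    se = unname(co[2L, "Std. Error"]),
    t = unname(co[2L, "t value"]),
    sigma_cbs = vc$sdcor[vc$grp == "cbs_id"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    n = nrow(dt), n_cbs = length(unique(dt$cbs_id)),
    model = fit
  )
}

#' Drop qualifying fragments with convergent-motif partners
#'
#' Used to re-run loop-size analyses after excluding contacts between
#' convergent CTCF motifs (candidate fully-extruded loops).
#'
#' @inheritParams fully_extruded_fraction
#' @return The non-convergent subset of `qualifying`.
#' @export
exclude_convergent_contacts <- function(qualifying, motifs, slack = 0L,
                                        nearest_only = FALSE) {
  q <- as.data.table(qualifying)
  if (!nrow(q)) return(q)
  q[!.flag_convergent(q, motifs, slack = slack, nearest_only = nearest_only)]
}
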