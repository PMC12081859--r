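## Genome scanning, peak calling and precision/recall evaluation.

#' Candidate positions around motifs
#'
#' By default scanning is motif-guided: every bp within `flank` of a motif
#' interval is scored. Peak centers are then comparable to a per-bp
#' genome-wide scan restricted to motif neighbourhoods.
#'
#' @param motifs `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_motif_bed()].
#' @param flank bp added on each side of the motif interval (default 150).
#' @param chromsizes optional named vector used to clip positions.
#' @return `data.table` of unique `chrom`, `position` (1-based), sorted.
#' @export
candidate_positions <- function(motifs, flank = 150L, chromsizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(motifs)))
  m <- as.data.table(motifs)
  pos <- m[, .(position = seq.int(start + 1L - flank, end + flank)),
           by = .(chrom, idx = seq_len(nrow(m)))][, idx := NULL]
  pos <- unique(pos[position >= 1L])
  if (!is.null(chromsizes)) {
    pos <- pos[position <= chromsizes[chrom]]
  }
  setorder(pos, chrom, position)
  pos[]
}

#' Genome-wide per-bp candidate positions
#'
#' The dense alternative to motif-guided scanning: every `step`-th bp of
#' every chromosome.
#'
#' @param chromsizes named integer vector.
#' @param step spacing between positions (default 1, i.e. every bp).
#' @return `data.table` of `chrom`, `position` (1-based).
#' @export
genome_positions <- function(chromsizes, step = 1L) {
  rbindlist(lapply(names(chromsizes), function(ch) {
    data.table(chrom = ch,
               position = seq.int(1L, chromsizes[[ch]], by = step))
  }))
}

#' Score candidate positions with the CAMEL statistic
#'
#' @param events read 5' events from [fragment_events()] (observed-ligation
#'   pairs only).
#' @param positions `data.table` with `chrom` and `position` (1-based), e.g.
#'   from [candidate_positions()]; or an integer vector when `events` covers
#'   a single chromosome.
#' @param table `camel_null_table` for p-value lookup.
#' @param window quadrant half-window (default 75 bp).
#' @param min_total totals below this are flagged untested (default: table
#'   minimum).
#' @return `data.table` with `chrom`, `position`, `n1`..`n4`, `n_total`,
#'   `alpha_hat`, `log2_alpha`, `p_value`, `tested`.
#' @export
camel_scan <- function(events, positions, table, window = 75L,
                       min_total = min(table$n_range)) {
  stopifnot(inherits(table, "camel_null_table"))
  if (!is.data.frame(positions)) {
    chroms <- unique(events$chrom)
    if (length(chroms) != 1L) {
      stop("plain position vector requires single-chromosome events")
    }
    positions <- data.table(chrom = chroms, position = as.integer(positions))
  }
  positions <- as.data.table(positions)
  res <- positions[, count_quadrants(events, position, window = window,
                                     chrom = .BY$chrom),
                   by = chrom]
  res[, alpha_hat := camel_statistic(n1, n2, n3, n4, cap = table$cap)]
  res[, log2_alpha := ifelse(alpha_hat > 0, log2(alpha_hat), -Inf)]
  res[, tested := n_total >= min_total]
  res[, p_value := NA_real_]
  res[tested == TRUE,
      p_value := camel_pvalue(log2_alpha, n_total, table)]
  res[]
}

#' Merge significant positions into peaks
#'
#' Positions with `p_value < p_threshold` are merged into one peak while
#' consecutive significant positions are at most `merge_dist` bp apart. The
#' peak center is the position with maximal alpha-hat; ties go to the larger
#' total count, then the smaller coordinate.
#'
#' @param scores scan results from [camel_scan()].
#' @param p_threshold nominal p-value cutoff (default 1e-5).
#' @param merge_dist maximum gap between significant positions merged into
#'   one peak (default 20 bp).
#' @return `data.table` with one row per peak: `chrom`, `span_start`
#'   (0-based), `span_end`, `center` (1-based bp), `best_alpha`, `best_p`,
#'   `n_total` (at center), `n_positions`.
#' @export
call_peaks <- function(scores, p_threshold = 1e-5, merge_dist = 20L) {
  sig <- as.data.table(scores)[tested & !is.na(p_value) & p_value < p_threshold]
  if (!nrow(sig)) {
    return(data.table(chrom = character(), span_start = integer(),
                      span_end = integer(), center = integer(),
                      best_alpha = numeric(), best_p = numeric(),
                      n_total = integer(), n_positions = integer()))
  }
  setorder(sig, chrom, position)
  sig[, peak_id := cumsum(c(1L, (diff(position) > merge_dist) |
                                 (chrom[-1L] != chrom[-.N]))), ]
  peaks <- sig[, {
    o <- order(-alpha_hat, -n_total, position)
    ctr <- o[1L]
    .(chrom = chrom[1L],
      span_start = min(position) - 1L,
      span_end = max(position),
      center = position[ctr],
      best_alpha = alpha_hat[ctr],
      best_p = min(p_value),
      n_total = n_total[ctr],
      n_positions = .N)
  }, by = peak_id][, peak_id := NULL]
  setorder(peaks, chrom, center)
  peaks[]
}

#' Write peaks as narrowPeak-style BED6+
#'
#' @param peaks peak table from [call_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  np <- data.table(
    chrom = peaks$chrom, start = peaks$span_start, end = peaks$span_end,
    name = sprintf("camel_peak_%d", seq_len(nrow(peaks))),
    score = pmin(1000L, as.integer(round(100 * log2(pmax(peaks$best_alpha, 1))))),
    strand = ".",
    signalValue = peaks$best_alpha,
    pValue = -log10(peaks$best_p),
    qValue = -1,
    summit = peaks$center - 1L - peaks$span_start
  )
  fwrite(np, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

.nearest_dist <- function(x, centers) {
  ## distance from each x to the nearest value in centers
  if (!length(centers)) return(rep(Inf, length(x)))
  s <- sort(centers)
  i <- findInterval(x, s)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(s))
  pmin(abs(x - s[lo]), abs(x - s[hi]))
}

#' Precision/recall of peak calls against known binding sites
#'
#' A truth motif counts as detected (TP) when a called peak center lies
#' within `match_radius` of its center; false positives are peaks whose
#' center falls in the negative space. With no peaks called at a threshold,
#' recall is 0 and precision is reported as 1 with `no_calls = TRUE`.
#'
#' @param peaks peak table from [call_peaks()] (called at the loosest
#'   threshold of interest).
#' @param truth_positives `data.table` of true-site intervals (`chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param truth_negative_space `data.table` of negative intervals; must not
#'   overlap the positives.
#' @param match_radius bp tolerance on peak-center-to-motif-center distance
#'   (default 30).
#' @param thresholds p-value thresholds to sweep.
#' @return `data.table` per threshold: `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `no_calls`.
#' @export
evaluate_precision_recall <- function(peaks, truth_positives,
                                      truth_negative_space,
                                      match_radius = 30L,
                                      thresholds = 10^seq(-10, -2)) {
  tp_dt <- as.data.table(truth_positives)
  neg_dt <- as.data.table(truth_negative_space)
  gr_pos <- GRanges(tp_dt$chrom, IRanges(tp_dt$start + 1L, tp_dt$end))
  gr_neg <- GRanges(neg_dt$chrom, IRanges(neg_dt$start + 1L, neg_dt$end))
  if (length(findOverlaps(gr_pos, gr_neg))) {
    stop("truth positives overlap the negative space")
  }
  tp_dt[, center := start + ((end - start + 1L) %/% 2L)]
  pk <- as.data.table(peaks)
  out <- rbindlist(lapply(thresholds, function(t) {
    sel <- pk[best_p < t]
    if (!nrow(sel)) {
      return(data.table(threshold = t, tp = 0L, fp = 0L, fn = nrow(tp_dt),
                        precision = 1, recall = 0, no_calls = TRUE))
    }
    tp_n <- 0L
    for (ch in unique(tp_dt$chrom)) {
      d <- .nearest_dist(tp_dt[chrom == ch, center],
                         sel[chrom == ch, center])
      tp_n <- tp_n + sum(d <= match_radius)
    }
    in_neg <- overlapsAny(GRanges(sel$chrom, IRanges(sel$center, sel$center)),
                          gr_neg)
    fp_n <- sum(in_neg)
    data.table(threshold = t, tp = tp_n, fp = fp_n, fn = nrow(tp_dt) - tp_n,
               precision = if (tp_n + fp_n > 0) tp_n / (tp_n + fp_n) else 1,
               recall = tp_n / nrow(tp_dt), no_calls = FALSE)
  }))
  out[]
}
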