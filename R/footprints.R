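## Single-molecule footprint classification at CTCF binding sites.
##
## Fragment boundaries are expressed in motif-oriented coordinates: 0 is the
## oriented start of the 35 bp motif, increasing through the motif. The
## motif contains a 19 bp core module preceded by a 10 bp upstream module;
## cohesin adds protection extending past the motif end (an "extended
## fragment end").

#' Orient fragment boundaries relative to a motif
#'
#' For + strand motifs `rel_start = frag_start - motif_start`; for - strand
#' motifs coordinates are reflected about the motif's oriented start (its
#' genomic end), so a fragment and its mirror image on an opposite-strand
#' motif receive identical oriented coordinates.
#'
#' @param frag_start,frag_end fragment interval (0-based half-open).
#' @param motif_start,motif_end motif interval (0-based half-open).
#' @param motif_strand `"+"` or `"-"` (vectors recycle).
#' @return `data.table` with `rel_start`, `rel_end` (oriented bp offsets,
#'   `rel_start < rel_end`).
#' @export
orient_fragment <- function(frag_start, frag_end, motif_start, motif_end,
                            motif_strand) {
  k <- max(length(frag_start), length(frag_end), length(motif_start),
           length(motif_end), length(motif_strand))
  frag_start <- rep_len(frag_start, k); frag_end <- rep_len(frag_end, k)
  motif_start <- rep_len(motif_start, k); motif_end <- rep_len(motif_end, k)
  plus <- rep_len(motif_strand == "+", k)
  data.table(
    rel_start = ifelse(plus, frag_start - motif_start, motif_end - frag_end),
    rel_end   = ifelse(plus, frag_end - motif_start, motif_end - frag_start)
  )
}

#' Pair contact-side fragments with overlapping motifs
#'
#' @param contacts contacts `data.table` from [reconstruct_fragments()].
#' @param motifs motif `data.table`.
#' @param side which fragment of each pair to match (`1` = left, `2` =
#'   right, `"both"`).
#' @param observed_only restrict to observed-ligation, non-degenerate pairs.
#' @param max_len observed-ligation proxy threshold (bp).
#' @return `data.table`, one row per (fragment, overlapping motif):
#'   fragment fields (`chrom`, `start`, `end`, `strand`, `frag_len`,
#'   `censored`), oriented `rel_start`/`rel_end`, motif fields
#'   (`motif_id`, `motif_start`, `motif_end`, `motif_strand`), the partner
#'   fragment (`partner_start`, `partner_end`, `partner_chrom`), plus
#'   `contact_row`, `side`, `trans` and `interaction_length`.
#' @export
motif_overlaps <- function(contacts, motifs, side = 1L,
                           observed_only = TRUE, max_len = 125L) {
  stopifnot(side %in% list(1L, 2L, 1, 2, "both"))
  keep <- !contacts$degenerate
  if (observed_only) keep <- keep & is_observed_ligation(contacts, max_len)
  idx <- which(keep)
  one <- function(s) {
    o <- 3L - s
    frag <- GRanges(contacts[[paste0("chrom", s)]][idx],
                    IRanges(contacts[[paste0("start", s)]][idx] + 1L,
                            contacts[[paste0("end", s)]][idx]))
    hits <- findOverlaps(frag, .motif_granges(motifs), ignore.strand = TRUE)
    qi <- idx[queryHits(hits)]
    mi <- subjectHits(hits)
    out <- data.table(
      contact_row = qi, side = s,
      chrom = contacts[[paste0("chrom", s)]][qi],
      start = contacts[[paste0("start", s)]][qi],
      end = contacts[[paste0("end", s)]][qi],
      strand = contacts[[paste0("strand", s)]][qi],
      frag_len = contacts[[paste0("length", s)]][qi],
      censored = contacts[[paste0("censored", s)]][qi],
      partner_chrom = contacts[[paste0("chrom", o)]][qi],
      partner_start = contacts[[paste0("start", o)]][qi],
      partner_end = contacts[[paste0("end", o)]][qi],
      trans = contacts$trans[qi],
      interaction_length = contacts$interaction_length[qi],
      motif_id = motifs$motif_id[mi],
      motif_start = motifs$start[mi],
      motif_end = motifs$end[mi],
      motif_strand = motifs$strand[mi]
    )
    cbind(out, orient_fragment(out$start, out$end, out$motif_start,
                               out$motif_end, out$motif_strand))
  }
  if (identical(side, "both")) rbind(one(1L), one(2L)) else one(as.integer(side))
}

#' Classify fragments by footprint geometry
#'
#' Nucleosome-length fragments (>= `short_threshold`) are called
#' `nucleosome`; shorter ones are transcription-factor footprints (`tf`)
#' whose oriented start distinguishes protection of the 19 bp core alone
#' (`core_only`) from the full core-plus-upstream motif
#' (`core_plus_upstream`), and whose oriented end at or beyond
#' `extended_end_min` marks additional cohesin protection.
#'
#' @param oriented `data.table` from [motif_overlaps()] (needs `frag_len`,
#'   `rel_start`, `rel_end`).
#' @param short_threshold fragment length below which a fragment is
#'   TF-scale (default 120 bp).
#' @param extended_end_min minimum oriented fragment end, in bp from the
#'   motif start, for a cohesin-extended call (default 48).
#' @param span_boundary oriented-start cutoff separating
#'   `core_plus_upstream` (`rel_start <= span_boundary`) from `core_only`;
#'   default 5, the midpoint of the 10 bp upstream module.
#' @return Input with added columns `protein_class`
#'   (`nucleosome`/`tf`/`unclassified`), `motif_span`
#'   (`core_plus_upstream`/`core_only`/`NA`) and `cohesin_extended`.
#' @export
classify_fragments <- function(oriented, short_threshold = 120L,
                               extended_end_min = 48L, span_boundary = 5L) {
  out <- as.data.table(oriented)
  overlaps <- out$rel_end > 0 & out$rel_start < 35L
  if ("motif_end" %in% names(out) && "motif_start" %in% names(out)) {
    overlaps <- out$rel_end > 0 & out$rel_start < (out$motif_end - out$motif_start)
  }
  out[, protein_class := fifelse(!overlaps, "unclassified",
                          fifelse(frag_len >= short_threshold,
                                  "nucleosome", "tf"))]
  out[, motif_span := fifelse(protein_class == "tf",
                       fifelse(rel_start <= span_boundary,
                               "core_plus_upstream", "core_only"),
                       NA_character_)]
  out[, cohesin_extended := protein_class == "tf" & rel_end >= extended_end_min]
  out[]
}

#' Boundary-margin filter for TF-protected fragments
#'
#' Keeps fragments whose boundaries sit at least `margin` bp away from the
#' motif's oriented start and end. Two readings of "at least `margin` bp
#' from the motif start" are supported: `"outside"` (default) requires the
#' fragment to begin at least `margin` bp before the motif
#' (`rel_start <= -margin`); `"distance"` requires only
#' `|rel_start| >= margin`. Both require
#' `rel_end >= motif_len + margin`.
#'
#' @param oriented `data.table` with `rel_start`, `rel_end`.
#' @param margin bp margin (default 5).
#' @param motif_len motif length (default 35 bp).
#' @param mode `"outside"` or `"distance"`.
#' @return Logical vector.
#' @export
tf_margin_filter <- function(oriented, margin = 5L, motif_len = 35L,
                             mode = c("outside", "distance")) {
  mode <- match.arg(mode)
  start_ok <- switch(mode,
    outside = oriented$rel_start <= -margin,
    distance = abs(oriented$rel_start) >= margin
  )
  start_ok & oriented$rel_end >= motif_len + margin
}

#' 2D footprint density over (oriented start, oriented end)
#'
#' Bivariate normal kernel density of fragment boundary positions in motif
#' coordinates, the aggregate single-molecule "footprint plot": modes
#' correspond to distinct protected intervals (core, core+upstream, cohesin
#' extension).
#'
#' @param oriented `data.table` with `rel_start`, `rel_end`.
#' @param bandwidth kernel standard deviation per axis, bp (default 2;
#'   floored at `min_bandwidth`).
#' @param min_bandwidth lower bound protecting against degenerate input.
#' @param xlim,ylim grid extent (oriented bp); defaults cover the data.
#' @param gridsize points per axis (default 151).
#' @return List with `x`, `y`, and matrix `z`, normalized so the grid
#'   integral is 1 (class `camel_footprint_density`).
#' @export
footprint_density <- function(oriented, bandwidth = 2, min_bandwidth = 0.5,
                              xlim = NULL, ylim = NULL, gridsize = 151L) {
  stopifnot(nrow(oriented) >= 2L)
  bw <- max(bandwidth, min_bandwidth)
  x <- oriented$rel_start
  y <- oriented$rel_end
  if (is.null(xlim)) xlim <- range(x) + c(-4, 4) * bw
  if (is.null(ylim)) ylim <- range(y) + c(-4, 4) * bw
  ## MASS::kde2d uses h/4 as the normal-kernel standard deviation
  kd <- MASS::kde2d(x, y, h = 4 * bw, n = gridsize, lims = c(xlim, ylim))
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  kd$z <- kd$z / (sum(kd$z) * cell)
  structure(kd, class = c("camel_footprint_density", "list"))
}

#' Export a footprint density as a long-format TSV grid
#'
#' @param density result of [footprint_density()].
#' @param path output TSV.
#' @export
write_footprint_density <- function(density, path) {
  dt <- data.table(
    rel_start = rep(density$x, times = length(density$y)),
    rel_end = rep(density$y, each = length(density$x)),
    density = as.vector(density$z)
  )
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Fragment coverage metaplot around oriented motif centers
#'
#' Mean per-bp fragment coverage at each oriented offset in
#' `[-flank, flank]` from the motif center, stratified by fragment length
#' class and, optionally, by a caller-supplied role label (e.g. left/right
#' fragment of a long-range pair). Stratum profiles sum to the
#' unstratified profile.
#'
#' @param fragments `data.table` with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `role`.
#' @param motifs motif `data.table`.
#' @param flank half-window (default 500 bp).
#' @param short_threshold length cutoff separating `short` from `long`
#'   fragments (default 120 bp).
#' @return `data.table` with `offset` (oriented bp from motif center),
#'   `len_class`, `role`, `coverage` (mean fragments per bp per motif).
#' @export
coverage_metaplot <- function(fragments, motifs, flank = 500L,
                              short_threshold = 120L) {
  fr <- as.data.table(fragments)
  if (!"role" %in% names(fr)) fr[, role := "all"]
  fr[, len_class := fifelse(end - start < short_threshold, "short", "long")]
  m <- as.data.table(motifs)
  ctr <- motif_center(m)
  win <- GRanges(m$chrom, IRanges(ctr - flank, ctr + flank))
  fgr <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  hits <- findOverlaps(fgr, win)
  if (!length(hits)) {
    return(data.table(offset = integer(), len_class = character(),
                      role = character(), coverage = numeric()))
  }
  fi <- queryHits(hits); mi <- subjectHits(hits)
  ## covered 1-based positions clipped to the window
  lo <- pmax(fr$start[fi] + 1L, ctr[mi] - flank)
  hi <- pmin(fr$end[fi], ctr[mi] + flank)
  plus <- m$strand[mi] == "+"
  off_lo <- ifelse(plus, lo - ctr[mi], ctr[mi] - hi)
  off_hi <- ifelse(plus, hi - ctr[mi], ctr[mi] - lo)
  dt <- data.table(off_lo = off_lo, off_hi = off_hi,
                   len_class = fr$len_class[fi], role = fr$role[fi])
  width <- 2L * flank + 1L
  prof <- dt[, {
    delta <- tabulate(off_lo + flank + 1L, nbins = width + 1L) -
      tabulate(off_hi + flank + 2L, nbins = width + 1L)
    .(offset = seq(-flank, flank), coverage = cumsum(delta[-(width + 1L)]))
  }, by = .(len_class, role)]
  prof[, coverage := coverage / nrow(m)]
  prof[]
}

#' Per-motif fraction of short overlapping fragments
#'
#' @param fragments `data.table` with `chrom`, `start`, `end`.
#' @param motifs motif `data.table`.
#' @param short_threshold bp cutoff (default 120).
#' @return `data.table` per motif: `motif_id`, `n_fragments`, `n_short`,
#'   `short_fraction` (`NA` with `no_coverage = TRUE` for motifs without
#'   overlapping fragments).
#' @export
short_fraction_per_site <- function(fragments, motifs,
                                    short_threshold = 120L) {
  fr <- as.data.table(fragments)
  fgr <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  hits <- findOverlaps(fgr, .motif_granges(motifs), ignore.strand = TRUE)
  cnt <- data.table(mi = subjectHits(hits),
                    short = (fr$end - fr$start)[queryHits(hits)] <
                      short_threshold)
  agg <- cnt[, .(n_fragments = .N, n_short = sum(short)), by = mi]
  out <- data.table(motif_id = motifs$motif_id,
                    n_fragments = 0L, n_short = 0L)
  out[agg$mi, `:=`(n_fragments = agg$n_fragments, n_short = agg$n_short)]
  out[, short_fraction := ifelse(n_fragments > 0, n_short / n_fragments,
                                 NA_real_)]
  out[, no_coverage := n_fragments == 0L]
  out[]
}
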