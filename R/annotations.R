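## BED / segmentation / category-map input. All intervals are handled
## internally as 0-based half-open, the BED convention.

#' Read a motif BED file (BED6 with strand)
#'
#' @param path BED file; column 4 is used as the motif id, column 5 as a
#'   score when present.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `motif_id`, `score`.
#' @export
read_motif_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    motif_id = if (!is.null(gr$name)) gr$name else
      sprintf("motif_%d", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  )
  if (any(!dt$strand %in% c("+", "-"))) {
    stop("motif BED must carry +/- strands")
  }
  dt[]
}

#' Write motifs as BED6
#'
#' @param motifs motif `data.table` as from [read_motif_bed()].
#' @param path output path.
#' @export
write_motif_bed <- function(motifs, path) {
  dt <- as.data.table(motifs)
  out <- data.table(dt$chrom, dt$start, dt$end,
                    if ("motif_id" %in% names(dt)) dt$motif_id else ".",
                    if ("score" %in% names(dt) && !all(is.na(dt$score)))
                      dt$score else 0,
                    dt$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation (ChromHMM-style BED4)
#'
#' @param path BED file whose 4th column is the state label.
#' @return `data.table` with `chrom`, `start`, `end`, `state`.
#' @export
read_segmentation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("segmentation BED needs a 4th (state) column")
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    state = as.character(gr$name)
  )[]
}

#' Read a state-to-category mapping (YAML)
#'
#' The file maps each segmentation state label to one of the chromatin
#' categories (typically `active`, `polycomb_bivalent`, `quiescent`),
#' either as `state: category` pairs or as `category: [states...]` lists.
#'
#' @param path YAML file.
#' @return Named character vector: `names` are state labels, values are
#'   categories.
#' @export
read_category_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) stop("empty category map")
  if (all(lengths(y) == 1L) && !any(vapply(y, is.list, logical(1)))) {
    map <- unlist(y)
  } else {
    map <- unlist(lapply(names(y), function(cat) {
      setNames(rep(cat, length(y[[cat]])), unlist(y[[cat]]))
    }))
  }
  map
}

.motif_granges <- function(motifs) {
  GRanges(motifs$chrom, IRanges(motifs$start + 1L, motifs$end),
          strand = motifs$strand)
}

#' Oriented motif center (1-based bp)
#'
#' @param motifs motif `data.table`.
#' @return Integer vector of center positions.
#' @export
motif_center <- function(motifs) {
  motifs$start + ((motifs$end - motifs$start + 1L) %/% 2L)
}
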