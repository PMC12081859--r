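## Synthetic MNase proximity-ligation pairs with known ground truth.
##
## Each emitted pair has an anchor fragment drawn at a motif (or at a
## nearby background position) and a partner fragment placed by an
## interaction-length model. Protein occupancy shapes the anchor fragment:
## bound molecules yield TF-scale footprints (core, core+upstream, or
## cohesin-extended), unbound molecules yield positioned nucleosomes or
## unstructured background cuts. Read 5' ends follow from fragment
## boundaries and read strand, and fragments longer than the read length
## are censored exactly as in real 150 bp data.

#' Regular grid of occupied and decoy motifs on a synthetic chromosome
#'
#' @param n_occupied motifs with binding (occupancy probability
#'   `occupancy`).
#' @param n_decoy motifs with occupancy 0 (never bound).
#' @param spacing center-to-center distance, bp.
#' @param motif_len motif width (default 35 bp).
#' @param chrom chromosome name.
#' @param occupancy per-molecule binding probability at occupied motifs
#'   (default 0.5).
#' @param margin bp kept free at both chromosome ends.
#' @param seed RNG seed for the occupied/decoy assignment and strand
#'   shuffle.
#' @return List: `motifs` (`data.table` with `chrom`, `start`, `end`,
#'   `strand`, `motif_id`, `occupancy`, `occupied`), `chromsizes`.
#' @export
motif_grid <- function(n_occupied = 1000L, n_decoy = 1000L, spacing = 3000L,
                       motif_len = 35L, chrom = "chrS", occupancy = 0.5,
                       margin = 50000L, seed = 1L) {
  n <- n_occupied + n_decoy
  starts <- margin + (seq_len(n) - 1L) * spacing
  .with_seed(seed, {
    strands <- sample(rep(c("+", "-"), length.out = n))
    occ_idx <- sort(sample.int(n, n_occupied))
  })
  occupied <- seq_len(n) %in% occ_idx
  motifs <- data.table(
    chrom = chrom, start = starts, end = starts + motif_len,
    strand = strands,
    motif_id = sprintf("m%05d", seq_len(n)),
    occupancy = ifelse(occupied, occupancy, 0),
    occupied = occupied
  )
  list(motifs = motifs,
       chromsizes = setNames(2L * margin + n * spacing, chrom))
}

#' Simulation configuration
#'
#' Defaults emulate deeply sequenced 150 bp MNase HiChIP around CTCF sites:
#' TF footprints protect the 19 bp core (`[10, 29)`), the full 35 bp motif
#' (`[0, 35)`), or the motif plus cohesin (`[-8, 52)`, an extended end
#' reaching ~17 bp past the motif); unbound molecules carry a positioned
#' 147 bp nucleosome or unstructured cuts. Boundary jitter is Gaussian
#' (sd 2 bp) with optional one-sided geometric over-trimming. Interaction
#' lengths mix a truncated power-law background with a log-normal loop
#' component; `spike_prob` is the probability that a long-range pair is
#' captured at a downstream convergent motif (the injected fully-extruded
#' probability).
#'
#' @param motifs motif `data.table` (see [motif_grid()]); needs an
#'   `occupancy` column.
#' @param chromsizes named integer vector.
#' @param pairs_per_motif pairs anchored at each motif (scalar or
#'   per-motif vector).
#' @param class_probs_bound probabilities of (tf_core, tf_full,
#'   tf_cohesin) given a bound molecule; must sum to 1.
#' @param unbound_probs probabilities of (nucleosome, background) given an
#'   unbound molecule; must sum to 1.
#' @param footprints list of oriented protected intervals (bp offsets from
#'   the motif's oriented start, `[lo, hi)`).
#' @param nucleosome_shift list with `offsets` and `probs`: oriented shift
#'   of the nucleosome footprint per unbound molecule, emulating the phased
#'   nucleosome array around binding sites (flanking nucleosomes at
#'   +/- ~145 bp alongside motif-resident ones).
#' @param jitter_sd boundary noise sd, bp.
#' @param overtrim_prob probability of extra exonuclease trimming at the
#'   fragment start; trim length is geometric with parameter
#'   `overtrim_geom_p`.
#' @param overtrim_geom_p geometric parameter for over-trim length.
#' @param interaction list: `loop_weight`, `loop_meanlog10`,
#'   `loop_sdlog10`, `bg_exponent`, `bg_min`, `bg_max`, `spike_prob`,
#'   `min_loop_dist`.
#' @param partner list: `short_prob`, `short_range`, `nucleosome_len`.
#' @param background list: `len_range`, `halfwin` (anchor scatter around
#'   the motif for unstructured cuts).
#' @param read_len read length, bp (censoring; default 150).
#' @param trans_prob probability a pair is inter-chromosomal (needs >= 2
#'   chromosomes).
#' @param seed RNG seed.
#' @return A `camel_sim_config` list.
#' @export
simulation_config <- function(motifs, chromsizes,
                              pairs_per_motif = 800L,
                              class_probs_bound = c(tf_core = 0.3,
                                                    tf_full = 0.4,
                                                    tf_cohesin = 0.3),
                              unbound_probs = c(nucleosome = 0.6,
                                                background = 0.4),
                              footprints = list(tf_core = c(10L, 29L),
                                                tf_full = c(0L, 35L),
                                                tf_cohesin = c(-8L, 52L),
                                                nucleosome = c(-56L, 91L)),
                              nucleosome_shift = list(
                                offsets = c(-145L, 0L, 145L),
                                probs = c(0.4, 0.2, 0.4)),
                              jitter_sd = 2,
                              overtrim_prob = 0,
                              overtrim_geom_p = 0.5,
                              interaction = list(),
                              partner = list(),
                              background = list(),
                              read_len = 150L,
                              trans_prob = 0,
                              seed = 1L) {
  motifs <- as.data.table(motifs)
  stopifnot("occupancy" %in% names(motifs),
            all(motifs$occupancy >= 0 & motifs$occupancy <= 1),
            all(motifs$chrom %in% names(chromsizes)),
            all(motifs$end <= chromsizes[motifs$chrom]),
            abs(sum(class_probs_bound) - 1) < 1e-8,
            abs(sum(unbound_probs) - 1) < 1e-8,
            length(nucleosome_shift$offsets) ==
              length(nucleosome_shift$probs),
            abs(sum(nucleosome_shift$probs) - 1) < 1e-8,
            jitter_sd >= 0, read_len > 0)
  inter <- utils::modifyList(list(
    loop_weight = 0.3, loop_meanlog10 = 5.2, loop_sdlog10 = 0.35,
    bg_exponent = -1, bg_min = 500, bg_max = 1e6,
    spike_prob = 0, min_loop_dist = 1e4), interaction)
  prt <- utils::modifyList(list(
    short_prob = 0.6, short_range = c(60L, 120L), nucleosome_len = 147L),
    partner)
  bg <- utils::modifyList(list(len_range = c(60L, 140L), halfwin = 250L),
                          background)
  pairs_per_motif <- rep_len(as.integer(pairs_per_motif), nrow(motifs))
  structure(list(
    motifs = motifs, chromsizes = chromsizes,
    pairs_per_motif = pairs_per_motif,
    class_probs_bound = class_probs_bound, unbound_probs = unbound_probs,
    footprints = footprints, nucleosome_shift = nucleosome_shift,
    jitter_sd = jitter_sd,
    overtrim_prob = overtrim_prob, overtrim_geom_p = overtrim_geom_p,
    interaction = inter, partner = prt, background = bg,
    read_len = as.integer(read_len), trans_prob = trans_prob,
    seed = as.integer(seed)
  ), class = "camel_sim_config")
}

.rpowerlaw <- function(n, exponent, lo, hi) {
  u <- runif(n)
  if (abs(exponent + 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a <- exponent + 1
    ((hi^a - lo^a) * u + lo^a)^(1 / a)
  }
}

## censor a true fragment to the read and emit 1-based pos5/pos3
.read_ends <- function(start, end, strand, read_len) {
  len_obs <- pmin(end - start, read_len)
  pos5 <- ifelse(strand == "+", start + 1L, end)
  pos3 <- ifelse(strand == "+", start + len_obs, end - len_obs + 1L)
  list(pos5 = as.integer(pos5), pos3 = as.integer(pos3))
}

#' Simulate pairs records with ground truth
#'
#' @param config a `camel_sim_config` from [simulation_config()].
#' @return List: `records` (pairs `data.table` as from [read_pairs()],
#'   chromsizes attached), `truth` (per-pair `data.table` with `pair_id`,
#'   `motif_id`, `bound`, `class`, `loop_status`, true fragment intervals
#'   and the partner placement), `motifs`.
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "camel_sim_config"))
  m <- config$motifs
  fp <- config$footprints
  inter <- config$interaction
  .with_seed(config$seed, {
    site <- rep(seq_len(nrow(m)), times = config$pairs_per_motif)
    n <- length(site)
    if (!n) stop("config emits zero pairs")
    mstart <- m$start[site]; mend <- m$end[site]
    mstrand <- m$strand[site]; mchrom <- m$chrom[site]
    mcenter <- motif_center(m)[site]
    csize <- unname(config$chromsizes[mchrom])

    bound <- runif(n) < m$occupancy[site]
    cls <- character(n)
    nb <- sum(bound)
    if (nb) cls[bound] <- sample(names(config$class_probs_bound), nb,
                                 replace = TRUE,
                                 prob = config$class_probs_bound)
    nu <- n - nb
    if (nu) cls[!bound] <- sample(names(config$unbound_probs), nu,
                                  replace = TRUE,
                                  prob = config$unbound_probs)

    ## anchor fragment (0-based half-open, genomic)
    a_start <- integer(n); a_end <- integer(n)
    has_fp <- cls %in% names(fp)
    if (any(has_fp)) {
      lo <- vapply(fp, function(v) as.numeric(v[1L]), numeric(1))[cls[has_fp]]
      hi <- vapply(fp, function(v) as.numeric(v[2L]), numeric(1))[cls[has_fp]]
      rel_a <- round(lo + rnorm(sum(has_fp), 0, config$jitter_sd))
      rel_b <- round(hi + rnorm(sum(has_fp), 0, config$jitter_sd))
      nuc <- cls[has_fp] == "nucleosome"
      if (any(nuc)) {
        shift <- sample(config$nucleosome_shift$offsets, sum(nuc),
                        replace = TRUE, prob = config$nucleosome_shift$probs)
        rel_a[nuc] <- rel_a[nuc] + shift
        rel_b[nuc] <- rel_b[nuc] + shift
      }
      if (config$overtrim_prob > 0) {
        trim <- (runif(sum(has_fp)) < config$overtrim_prob) *
          (rgeom(sum(has_fp), config$overtrim_geom_p) + 1L)
        rel_a <- rel_a + trim
      }
      rel_b <- pmax(rel_b, rel_a + 5L)
      plus <- mstrand[has_fp] == "+"
      a_start[has_fp] <- as.integer(ifelse(plus, mstart[has_fp] + rel_a,
                                           mend[has_fp] - rel_b))
      a_end[has_fp] <- as.integer(ifelse(plus, mstart[has_fp] + rel_b,
                                         mend[has_fp] - rel_a))
    }
    is_bg <- cls == "background"
    if (any(is_bg)) {
      k <- sum(is_bg)
      len <- sample(seq(config$background$len_range[1L],
                        config$background$len_range[2L]), k, replace = TRUE)
      ctr <- mcenter[is_bg] +
        round(runif(k, -config$background$halfwin, config$background$halfwin))
      a_start[is_bg] <- as.integer(ctr - len %/% 2L)
      a_end[is_bg] <- a_start[is_bg] + len
    }
    a_start <- pmax(a_start, 0L)
    a_end <- pmin(a_end, csize)
    a_strand <- sample(c("+", "-"), n, replace = TRUE)

    ## interaction length and partner placement
    comp_loop <- runif(n) < inter$loop_weight
    dist <- numeric(n)
    dist[comp_loop] <- 10^rnorm(sum(comp_loop), inter$loop_meanlog10,
                                inter$loop_sdlog10)
    dist[!comp_loop] <- .rpowerlaw(sum(!comp_loop), inter$bg_exponent,
                                   inter$bg_min, inter$bg_max)
    dirn <- ifelse(comp_loop, ifelse(mstrand == "+", 1L, -1L),
                   sample(c(-1L, 1L), n, replace = TRUE))
    ## a contact can be captured at a convergent motif only when extrusion
    ## proceeds downstream of the oriented anchor past the loop-distance
    ## threshold; spike_prob is the convergent-capture probability among
    ## such long-range downstream contacts
    downstream_dir <- dirn == ifelse(mstrand == "+", 1L, -1L)
    long <- dist > inter$min_loop_dist
    snap <- long & downstream_dir & runif(n) < inter$spike_prob

    ## snap partners onto a downstream convergent (opposite-strand) motif
    snap_motif <- rep(NA_integer_, n)
    for (s in c("+", "-")) {
      idx <- which(snap & mstrand == s)
      if (!length(idx)) next
      conv <- which(m$strand == (if (s == "+") "-" else "+"))
      for (ch in unique(mchrom[idx])) {
        ii <- idx[mchrom[idx] == ch]
        cm <- conv[m$chrom[conv] == ch]
        if (!length(cm)) next
        ctrs <- motif_center(m)[cm]
        o <- order(ctrs); cm <- cm[o]; ctrs <- ctrs[o]
        d <- if (s == "+") 1 else -1
        lo <- mcenter[ii] + d * inter$min_loop_dist
        hi <- mcenter[ii] + d * inter$bg_max
        rng_lo <- pmin(lo, hi); rng_hi <- pmax(lo, hi)
        i_lo <- findInterval(rng_lo, ctrs)
        i_hi <- findInterval(rng_hi, ctrs)
        nc <- i_hi - i_lo
        ok <- nc > 0L
        pick <- i_lo + pmax(1L, ceiling(runif(length(ii)) * nc))
        snap_motif[ii[ok]] <- cm[pick[ok]]
      }
    }
    snapped <- !is.na(snap_motif)

    p_start <- integer(n); p_end <- integer(n)
    p_chrom <- mchrom
    ## non-snapped partner: length model at the drawn distance
    ns <- which(!snapped)
    if (length(ns)) {
      k <- length(ns)
      short <- runif(k) < config$partner$short_prob
      len <- integer(k)
      len[short] <- sample(seq(config$partner$short_range[1L],
                               config$partner$short_range[2L]),
                           sum(short), replace = TRUE)
      len[!short] <- config$partner$nucleosome_len +
        round(rnorm(sum(!short), 0, config$jitter_sd))
      a_mid <- (a_start[ns] + a_end[ns]) %/% 2L
      ctr <- a_mid + dirn[ns] * round(dist[ns])
      st <- as.integer(ctr - len %/% 2L)
      st <- pmin(pmax(st, 0L), csize[ns] - len)
      p_start[ns] <- st
      p_end[ns] <- st + len
    }
    ## snapped partner: CTCF-protected footprint on the convergent motif
    ## (the cohesin-extended end belongs to the extruding anchor; the
    ## captured side shows plain motif protection)
    sp <- which(snapped)
    if (length(sp)) {
      k <- length(sp)
      sm <- snap_motif[sp]
      rel_a <- round(fp$tf_full[1L] + rnorm(k, 0, config$jitter_sd))
      rel_b <- round(fp$tf_full[2L] + rnorm(k, 0, config$jitter_sd))
      rel_b <- pmax(rel_b, rel_a + 5L)
      plus <- m$strand[sm] == "+"
      p_start[sp] <- as.integer(ifelse(plus, m$start[sm] + rel_a,
                                       m$end[sm] - rel_b))
      p_end[sp] <- as.integer(ifelse(plus, m$start[sm] + rel_b,
                                     m$end[sm] - rel_a))
      p_chrom[sp] <- m$chrom[sm]
    }
    p_start <- pmax(p_start, 0L)
    p_end <- pmin(p_end, unname(config$chromsizes[p_chrom]))
    p_strand <- sample(c("+", "-"), n, replace = TRUE)

    ## optional trans pairs (re-home the partner on another chromosome)
    loop_status <- ifelse(snapped, "fully_extruded",
                          ifelse(comp_loop, "partial", "background"))
    if (config$trans_prob > 0 && length(config$chromsizes) > 1L) {
      tr <- which(runif(n) < config$trans_prob & !snapped)
      if (length(tr)) {
        others <- vapply(mchrom[tr], function(ch) {
          sample(setdiff(names(config$chromsizes), ch), 1L)
        }, character(1))
        p_chrom[tr] <- others
        len <- p_end[tr] - p_start[tr]
        st <- as.integer(floor(runif(length(tr)) *
                                 (unname(config$chromsizes[others]) - len)))
        p_start[tr] <- st
        p_end[tr] <- st + len
        loop_status[tr] <- "trans"
      }
    }

    e1 <- .read_ends(a_start, a_end, a_strand, config$read_len)
    e2 <- .read_ends(p_start, p_end, p_strand, config$read_len)
    records <- data.table(
      read_id = sprintf("sim_%07d", seq_len(n)),
      chrom1 = mchrom, pos1 = e1$pos5, chrom2 = p_chrom, pos2 = e2$pos5,
      strand1 = a_strand, strand2 = p_strand, pair_type = "UU",
      pos5_1 = e1$pos5, pos5_2 = e2$pos5, pos3_1 = e1$pos3,
      pos3_2 = e2$pos3,
      read_len1 = config$read_len, read_len2 = config$read_len
    )
    truth <- data.table(
      pair_id = seq_len(n), read_id = records$read_id,
      motif_id = m$motif_id[site], bound = bound, class = cls,
      loop_status = loop_status,
      anchor_start = a_start, anchor_end = a_end, anchor_strand = a_strand,
      partner_chrom = p_chrom, partner_start = p_start, partner_end = p_end,
      drawn_dist = dist, snap_motif = ifelse(snapped,
                                             m$motif_id[snap_motif], NA)
    )
  })
  setattr(records, "chromsizes", config$chromsizes)
  list(records = records, truth = truth, motifs = m)
}

#' Protein-free null pairs (uniform MNase cuts)
#'
#' Fragments with uniformly random positions and lengths, no footprint
#' structure; the calibration null for the CAMEL statistic.
#'
#' @param chromsizes named integer vector.
#' @param n_pairs number of pairs.
#' @param len_range fragment length range, bp.
#' @param dist_range partner distance range, bp (log-uniform).
#' @param read_len read length (censoring).
#' @param seed RNG seed.
#' @return Pairs records `data.table` (chromsizes attached).
#' @export
null_pairs <- function(chromsizes, n_pairs, len_range = c(50L, 130L),
                       dist_range = c(1e3, 1e5), read_len = 150L,
                       seed = 1L) {
  if (n_pairs == 0L) {
    out <- parse_pairs(character(0))
    setattr(out, "chromsizes", chromsizes)
    return(out)
  }
  .with_seed(seed, {
    chrom <- sample(names(chromsizes), n_pairs, replace = TRUE,
                    prob = chromsizes / sum(chromsizes))
    csize <- unname(chromsizes[chrom])
    len1 <- sample(seq(len_range[1L], len_range[2L]), n_pairs, replace = TRUE)
    len2 <- sample(seq(len_range[1L], len_range[2L]), n_pairs, replace = TRUE)
    s1 <- as.integer(floor(runif(n_pairs) * (csize - len1)))
    d <- .rpowerlaw(n_pairs, -1, dist_range[1L], dist_range[2L]) *
      sample(c(-1, 1), n_pairs, replace = TRUE)
    s2 <- as.integer(round(s1 + d))
    s2 <- pmin(pmax(s2, 0L), csize - len2)
    st1 <- sample(c("+", "-"), n_pairs, replace = TRUE)
    st2 <- sample(c("+", "-"), n_pairs, replace = TRUE)
    e1 <- .read_ends(s1, s1 + len1, st1, read_len)
    e2 <- .read_ends(s2, s2 + len2, st2, read_len)
    out <- data.table(
      read_id = sprintf("null_%07d", seq_len(n_pairs)),
      chrom1 = chrom, pos1 = e1$pos5, chrom2 = chrom, pos2 = e2$pos5,
      strand1 = st1, strand2 = st2, pair_type = "UU",
      pos5_1 = e1$pos5, pos5_2 = e2$pos5, pos3_1 = e1$pos3,
      pos3_2 = e2$pos3, read_len1 = read_len, read_len2 = read_len
    )
  })
  setattr(out, "chromsizes", chromsizes)
  out[]
}
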