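## Reading, writing and fragment reconstruction for 4DN .pairs files that
## carry the per-side 5'/3' mapped-end columns produced by
## `pairtools parse --add-columns pos5,pos3,read_len`.

#' Canonical pairs columns used by this package
#'
#' Maps internal field names to the column labels used in a pairs file
#' header. The default matches the pairtools convention of appending the
#' side index directly to the column name (`pos51`, `pos52`, ...).
#'
#' @param ... named overrides, e.g. `pos5_1 = "pos5_side1"`.
#' @return Named character vector mapping internal names to file columns.
#' @export
pairs_dialect <- function(...) {
  d <- c(
    read_id   = "readID",
    chrom1    = "chrom1",  pos1     = "pos1",
    chrom2    = "chrom2",  pos2     = "pos2",
    strand1   = "strand1", strand2  = "strand2",
    pair_type = "pair_type",
    pos5_1    = "pos51",   pos5_2   = "pos52",
    pos3_1    = "pos31",   pos3_2   = "pos32",
    read_len1 = "read_len1", read_len2 = "read_len2"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

.pairs_mandatory <- c(
  "read_id", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2",
  "pos5_1", "pos5_2", "pos3_1", "pos3_2"
)

#' Read a 4DN pairs file
#'
#' Header lines (starting with `#`) are scanned for `#chromsize:` entries and
#' a `#columns:` declaration; when present, `#columns:` takes precedence over
#' `dialect` for locating fields. The body is read as tab-separated text.
#'
#' @param path path to a `.pairs` file (plain or gzip).
#' @param dialect column map from [pairs_dialect()]; used when the file has
#'   no `#columns:` line.
#' @return A `data.table` of read-pair records with canonical column names
#'   (`read_id`, `chrom1`, `pos1`, ..., `pos5_1`, `pos3_1`, ...), carrying
#'   the chromosome sizes as attribute `chromsizes` (named integer vector)
#'   and the raw header as attribute `pairs_header`.
#' @export
read_pairs <- function(path, dialect = pairs_dialect()) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  body_first <- if (length(line) && !startsWith(line, "#")) line else character()
  body_rest <- readLines(con)
  body <- c(body_first, body_rest)
  parse_pairs(c(header, body), dialect = dialect)
}

#' Parse pairs records from text lines
#'
#' @param lines character vector: `#`-prefixed header lines followed by
#'   tab-separated body lines.
#' @inheritParams read_pairs
#' @return See [read_pairs()].
#' @export
parse_pairs <- function(lines, dialect = pairs_dialect()) {
  is_hdr <- startsWith(lines, "#")
  n_hdr <- if (all(is_hdr)) length(lines) else which(!is_hdr)[1L] - 1L
  header <- lines[seq_len(n_hdr)]
  body <- lines[-seq_len(n_hdr)]
  body <- body[nzchar(body)]

  cs_lines <- grep("^#chromsize:", header, value = TRUE)
  chromsizes <- integer()
  if (length(cs_lines)) {
    parts <- strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+")
    chromsizes <- setNames(
      vapply(parts, function(p) as.integer(p[2L]), integer(1)),
      vapply(parts, `[`, character(1), 1L)
    )
  }

  col_line <- grep("^#columns:", header, value = TRUE)
  if (length(col_line)) {
    file_cols <- strsplit(sub("^#columns:\\s*", "", col_line[1L]), "\\s+")[[1L]]
  } else {
    file_cols <- NULL
  }

  empty <- data.table(
    read_id = character(), chrom1 = character(), pos1 = integer(),
    chrom2 = character(), pos2 = integer(), strand1 = character(),
    strand2 = character(), pair_type = character(),
    pos5_1 = integer(), pos5_2 = integer(), pos3_1 = integer(),
    pos3_2 = integer(), read_len1 = integer(), read_len2 = integer()
  )
  if (!length(body)) {
    setattr(empty, "chromsizes", chromsizes)
    setattr(empty, "pairs_header", header)
    return(empty[])
  }

  dt <- fread(text = body, sep = "\t", header = FALSE, fill = TRUE,
              colClasses = "character")
  if (is.null(file_cols)) file_cols <- unname(dialect)
  if (ncol(dt) < length(.pairs_mandatory)) {
    stop("pairs body has ", ncol(dt), " columns; at least ",
         length(.pairs_mandatory), " are required")
  }
  setnames(dt, seq_len(min(ncol(dt), length(file_cols))),
           file_cols[seq_len(min(ncol(dt), length(file_cols)))])

  ## map file columns -> canonical names; accept canonical names directly
  out <- data.table(row_id = seq_len(nrow(dt)))
  for (field in names(pairs_dialect())) {
    src <- if (dialect[[field]] %in% names(dt)) dialect[[field]]
           else if (field %in% names(dt)) field
           else NA_character_
    if (is.na(src)) {
      if (field %in% .pairs_mandatory) {
        stop("mandatory pairs column missing: ", field,
             " (looked for '", dialect[[field]], "')")
      }
      out[[field]] <- if (field == "pair_type") NA_character_ else NA_integer_
    } else {
      out[[field]] <- dt[[src]]
    }
  }
  out[, row_id := NULL]

  int_fields <- c("pos1", "pos2", "pos5_1", "pos5_2", "pos3_1", "pos3_2",
                  "read_len1", "read_len2")
  for (f in int_fields) {
    v <- suppressWarnings(as.integer(out[[f]]))
    bad <- which(is.na(v) & !is.na(out[[f]]))
    if (length(bad)) {
      stop("non-integer value in column '", f, "' at body line(s) ",
           paste(head(bad + n_hdr, 5L), collapse = ", "),
           " (line numbers include the header)")
    }
    out[[f]] <- v
  }
  bad_strand <- which(!(out$strand1 %in% c("+", "-")) |
                      !(out$strand2 %in% c("+", "-")))
  if (length(bad_strand)) {
    stop("invalid strand at body line(s) ",
         paste(head(bad_strand + n_hdr, 5L), collapse = ", "))
  }
  setattr(out, "chromsizes", chromsizes)
  setattr(out, "pairs_header", header)
  out[]
}

#' Write records to a 4DN pairs file
#'
#' @param records a records `data.table` as returned by [read_pairs()].
#' @param path output path (`.gz` suffix writes gzip).
#' @param chromsizes named integer vector; defaults to the `chromsizes`
#'   attribute of `records`.
#' @param dialect column map giving the file column labels.
#' @param sort sort body by (chrom1, chrom2, pos1, pos2) before writing.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(records, path, chromsizes = attr(records, "chromsizes"),
                        dialect = pairs_dialect(), sort = FALSE) {
  stopifnot(is.data.frame(records))
  dt <- as.data.table(records)
  if (sort) setorder(dt, chrom1, chrom2, pos1, pos2)
  fields <- names(pairs_dialect())
  fields <- fields[fields %in% names(dt)]
  hdr <- c("## pairs format v1.0")
  if (length(chromsizes)) {
    hdr <- c(hdr, sprintf("#chromsize: %s %d", names(chromsizes),
                          as.integer(chromsizes)))
  }
  hdr <- c(hdr, paste("#columns:", paste(dialect[fields], collapse = " ")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(hdr, con)
  close(con)
  fwrite(dt[, fields, with = FALSE], path, sep = "\t", append = TRUE,
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct digestion fragments and contact pairs from pairs records
#'
#' Each side of a record is an MNase digestion fragment whose boundaries are
#' the extreme mapped ends of the read: start = min(pos5, pos3) - 1 (0-based),
#' end = max(pos5, pos3), so the fragment interval is 0-based half-open and
#' its length equals |pos3 - pos5| + 1. Fragments whose observed length
#' reaches the read length are censored: the true fragment extends past the
#' read and only a lower length bound is known.
#'
#' @param records records `data.table` from [read_pairs()].
#' @param read_len_censor observed lengths at or above this value are flagged
#'   censored (default 150, for 150 bp reads).
#' @param reorder order the two sides of cis pairs so side 1 is the left
#'   (smaller-start) fragment (default TRUE). Trans pairs keep input order.
#' @return A contacts `data.table`, one row per ligation event, with per-side
#'   columns `chrom*, start*, end*, strand*, length*, censored*`, plus
#'   `trans` (inter-chromosomal flag), `degenerate` (zero-extent fragment on
#'   either side, excluded downstream), and `interaction_length` (absolute
#'   distance between fragment midpoints; `NA` for trans pairs).
#'   Chromsizes are carried through as an attribute.
#' @export
reconstruct_fragments <- function(records, read_len_censor = 150L,
                                  reorder = TRUE) {
  stopifnot(is.data.frame(records), read_len_censor > 0)
  r <- as.data.table(records)
  ct <- data.table(
    read_id = r$read_id,
    pair_type = if ("pair_type" %in% names(r)) r$pair_type else NA_character_,
    chrom1 = r$chrom1,
    start1 = pmin(r$pos5_1, r$pos3_1) - 1L,
    end1   = pmax(r$pos5_1, r$pos3_1),
    strand1 = r$strand1,
    chrom2 = r$chrom2,
    start2 = pmin(r$pos5_2, r$pos3_2) - 1L,
    end2   = pmax(r$pos5_2, r$pos3_2),
    strand2 = r$strand2
  )
  ct[, `:=`(length1 = end1 - start1, length2 = end2 - start2)]
  ct[, `:=`(censored1 = length1 >= read_len_censor,
            censored2 = length2 >= read_len_censor)]
  ct[, degenerate := length1 <= 1L | length2 <= 1L]
  ct[, trans := chrom1 != chrom2]
  if (reorder) {
    swap <- which(!ct$trans & ct$start2 < ct$start1)
    if (length(swap)) {
      side1 <- c("chrom1", "start1", "end1", "strand1", "length1", "censored1")
      side2 <- c("chrom2", "start2", "end2", "strand2", "length2", "censored2")
      tmp <- ct[swap, side1, with = FALSE]
      for (i in seq_along(side1)) {
        set(ct, swap, side1[i], ct[[side2[i]]][swap])
        set(ct, swap, side2[i], tmp[[i]])
      }
    }
  }
  ct[, interaction_length := ifelse(
    trans, NA_real_,
    abs((start2 + end2) / 2 - (start1 + end1) / 2))]
  setattr(ct, "chromsizes", attr(records, "chromsizes"))
  ct[]
}

#' Observed-ligation filter
#'
#' A ligation event is "observed" when the junction falls inside the read on
#' both sides, so that both fragment lengths are known exactly. Because a
#' read must retain roughly 25 aligned bp on each side of the junction, this
#' is proxied by requiring the longer fragment to be at most `max_len` bp
#' (default 125 for 150 bp reads).
#'
#' @param contacts contacts `data.table` from [reconstruct_fragments()].
#' @param max_len maximum length of the longer fragment (bp).
#' @return Logical vector, one element per contact.
#' @export
is_observed_ligation <- function(contacts, max_len = 125L) {
  pmax(contacts$length1, contacts$length2) <= max_len
}

#' Read 5'-end events from contact fragments
#'
#' Each fragment contributes one read 5' event: on the + strand the 5' end is
#' the fragment start, on the - strand the fragment end (1-based bp).
#'
#' @param contacts contacts `data.table`.
#' @param sides which fragment sides to emit (`"both"`, `"left"`, `"right"`).
#' @param observed_only keep only observed-ligation, non-degenerate pairs
#'   (default TRUE), matching the read set used for binding-site scanning.
#' @param max_len observed-ligation length proxy passed to
#'   [is_observed_ligation()].
#' @return `data.table` with columns `chrom`, `fivep` (1-based read 5'
#'   position), `strand`, `contact_row` (row index into `contacts`), `side`.
#' @export
fragment_events <- function(contacts, sides = c("both", "left", "right"),
                            observed_only = TRUE, max_len = 125L) {
  sides <- match.arg(sides)
  keep <- !contacts$degenerate
  if (observed_only) keep <- keep & is_observed_ligation(contacts, max_len)
  idx <- which(keep)
  one_side <- function(s) {
    data.table(
      chrom = contacts[[paste0("chrom", s)]][idx],
      fivep = ifelse(contacts[[paste0("strand", s)]][idx] == "+",
                     contacts[[paste0("start", s)]][idx] + 1L,
                     contacts[[paste0("end", s)]][idx]),
      strand = contacts[[paste0("strand", s)]][idx],
      contact_row = idx,
      side = s
    )
  }
  ev <- switch(sides,
    both = rbind(one_side(1L), one_side(2L)),
    left = one_side(1L),
    right = one_side(2L)
  )
  setorder(ev, chrom, fivep)
  ev[]
}
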