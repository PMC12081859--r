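## Empirical multinomial null for the CAMEL statistic.
##
## Under no binding each read falls in any of the four quadrants with
## probability 1/4, independently. For each total count N the tail
## distribution of log2(alpha-hat) is estimated by Monte Carlo on a fixed
## log2 grid; an observed statistic is then converted to a nominal p-value
## by table lookup, which needs only the four quadrant counts.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Build the empirical null table for the CAMEL statistic
#'
#' For every total read count in `n_range`, draws `n_samples` multinomial
#' samples with equal quadrant probabilities, computes the capped
#' log2(alpha-hat), and tabulates the empirical tail probability
#' \eqn{P(\log_2\hat\alpha \ge g)} at each grid point \eqn{g}.
#'
#' @param n_range contiguous integer vector of total counts (default 5:500;
#'   observed totals above the maximum are binned at the maximum).
#' @param n_samples Monte Carlo draws per total count (default 1e6).
#' @param grid ascending log2-alpha evaluation grid (default 0 to 5 by 0.01,
#'   i.e. alpha in `[1, 32]`; the top grid point sets the alpha cap).
#' @param seed RNG seed; builds with the same seed are identical.
#' @return An object of class `camel_null_table`: list with `n_range`,
#'   `grid`, `tail_prob` (length(n_range) x length(grid) matrix),
#'   `n_samples`, `seed`, `cap`.
#' @export
build_null_table <- function(n_range = 5:500, n_samples = 1e6,
                             grid = seq(0, 5, by = 0.01), seed = 1L) {
  stopifnot(length(n_range) >= 1, all(diff(n_range) == 1L),
            n_samples >= 1e4, length(grid) >= 2)
  if (any(diff(grid) <= 0)) stop("grid must be strictly ascending")
  cap <- 2^max(grid)
  ng <- length(grid)
  tail_prob <- matrix(NA_real_, nrow = length(n_range), ncol = ng)
  .with_seed(seed, {
    for (i in seq_along(n_range)) {
      x <- rmultinom(n_samples, n_range[i], rep(0.25, 4))
      alpha <- camel_statistic(x[1L, ], x[2L, ], x[3L, ], x[4L, ], cap = cap)
      la <- ifelse(alpha > 0, log2(alpha), -Inf)
      bin <- findInterval(la, grid)           # 0 = below grid[1]
      cnt <- tabulate(bin + 1L, nbins = ng + 1L)
      tail_prob[i, ] <- rev(cumsum(rev(cnt[-1L]))) / n_samples
    }
  })
  structure(
    list(n_range = as.integer(n_range), grid = grid, tail_prob = tail_prob,
         n_samples = n_samples, seed = seed, cap = cap),
    class = "camel_null_table"
  )
}

#' @export
print.camel_null_table <- function(x, ...) {
  cat("CAMEL empirical null table\n",
      "  total counts: ", min(x$n_range), "-", max(x$n_range), "\n",
      "  grid: log2(alpha) in [", min(x$grid), ", ", max(x$grid),
      "] (", length(x$grid), " points)\n",
      "  samples per count: ", format(x$n_samples, big.mark = ","),
      "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Nominal p-value for observed quadrant counts
#'
#' Looks up the empirical tail probability at the grid point at or below
#' the observed log2(alpha-hat); totals above the table range use the top
#' bin, and alpha below 1 is never significant (p = 1). P-values are
#' floored at `1 / n_samples`, the table's resolution.
#'
#' @param log2_alpha observed log2 statistic (vector; `-Inf` allowed).
#' @param n_total observed total counts (vector, recycled).
#' @param table a `camel_null_table`.
#' @return Numeric p-values in `(0, 1]`; `NA` where `n_total` is below the
#'   table minimum (too few reads to test).
#' @export
camel_pvalue <- function(log2_alpha, n_total, table) {
  stopifnot(inherits(table, "camel_null_table"))
  k <- max(length(log2_alpha), length(n_total))
  log2_alpha <- rep_len(log2_alpha, k)
  n_total <- rep_len(n_total, k)
  n_eff <- pmin(n_total, max(table$n_range))
  p <- rep(NA_real_, k)
  ok <- n_eff >= min(table$n_range)
  if (any(ok)) {
    ridx <- n_eff[ok] - min(table$n_range) + 1L
    gidx <- findInterval(log2_alpha[ok], table$grid)
    pv <- numeric(sum(ok))
    pv[gidx == 0L] <- 1
    nz <- gidx > 0L
    pv[nz] <- table$tail_prob[cbind(ridx[nz], gidx[nz])]
    p[ok] <- pmax(pv, 1 / table$n_samples)
  }
  p
}

#' Save / load a null table as plain TSV with metadata
#'
#' @param table a `camel_null_table`.
#' @param path output TSV path (long format with a metadata comment header).
#' @return `path` (write) or the reconstructed table (read).
#' @export
write_null_table <- function(table, path) {
  stopifnot(inherits(table, "camel_null_table"))
  hdr <- sprintf("# camel_null_table n_samples=%d seed=%d grid_min=%g grid_max=%g grid_step=%g",
                 as.integer(table$n_samples), as.integer(table$seed),
                 min(table$grid), max(table$grid), table$grid[2] - table$grid[1])
  writeLines(hdr, path)
  dt <- data.table(n_total = rep(table$n_range, each = length(table$grid)),
                   grid = rep(table$grid, length(table$n_range)),
                   tail_prob = as.vector(t(table$tail_prob)))
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_null_table
#' @param path TSV path written by [write_null_table()].
#' @export
read_null_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# camel_null_table ", "", hdr),
                                             " ")[[1]]))
  names(meta) <- sub("=.*", "", strsplit(sub("^# camel_null_table ", "", hdr),
                                         " ")[[1]])
  dt <- fread(path, skip = 1L)
  n_range <- sort(unique(dt$n_total))
  grid <- sort(unique(dt$grid))
  setorder(dt, n_total, grid)
  structure(
    list(n_range = as.integer(n_range), grid = grid,
         tail_prob = matrix(dt$tail_prob, nrow = length(n_range),
                            ncol = length(grid), byrow = TRUE),
         n_samples = unname(meta["n_samples"]), seed = unname(meta["seed"]),
         cap = 2^max(grid)),
    class = "camel_null_table"
  )
}
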