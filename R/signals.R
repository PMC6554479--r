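#' Tile a chromosome into non-overlapping windows
#'
#' Builds the fixed window grid on which every density signal is computed.
#' Windows are 0-based half-open `[start, end)` intervals of `window_size` bp
#' that tile `[0, chrom_length)` without overlap or gap; the last window may be
#' shorter.
#'
#' @param chrom_length Chromosome length in bp (>= 1).
#' @param window_size Window size in bp (default 10 kb, the standard bin for
#'   chromosome-scale density profiles).
#' @param chrom Chromosome identifier carried through to outputs.
#' @return A `window_grid` object with fields `chrom`, `chrom_length`,
#'   `window_size`, and 0-based `starts`/`ends` vectors.
#' @examples
#' make_windows(25000, 10000)
#' @export
make_windows <- function(chrom_length, window_size = 10000L, chrom = "chr") {
  if (!is.numeric(chrom_length) || length(chrom_length) != 1L ||
      is.na(chrom_length) || chrom_length < 1) {
    stop("`chrom_length` must be a single value >= 1")
  }
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size < 1) {
    stop("`window_size` must be a single value >= 1")
  }
  chrom_length <- as.numeric(chrom_length)
  window_size <- as.numeric(window_size)
  starts <- seq(0, chrom_length - 1, by = window_size)
  ends <- pmin(starts + window_size, chrom_length)
  structure(
    list(chrom = as.character(chrom), chrom_length = chrom_length,
         window_size = window_size, starts = starts, ends = ends),
    class = "window_grid"
  )
}

#' Number of windows in a grid
#' @param grid A `window_grid`.
#' @return Integer window count.
#' @export
n_windows <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  length(grid$starts)
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %s: %g bp in %d windows of %g bp\n",
              x$chrom, x$chrom_length, n_windows(x), x$window_size))
  invisible(x)
}

#' @export
as.data.frame.window_grid <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$starts, end = x$ends)
}

#' Construct a set of genomic intervals
#'
#' Plain carrier for gene bodies, mapped reads or BLAST hits: 0-based
#' half-open `[start, end)` intervals on one chromosome.
#'
#' @param start,end Numeric vectors of equal length, `start < end` pairwise.
#' @param chrom Optional chromosome identifier.
#' @return An `interval_set` (a data frame with columns `start`, `end`).
#' @export
interval_set <- function(start, end, chrom = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("`start` and `end` lengths differ")
  if (any(is.na(start)) || any(is.na(end))) stop("intervals must be non-NA")
  if (any(start >= end)) stop("every interval needs start < end")
  if (any(start < 0)) stop("intervals must have start >= 0")
  out <- data.frame(start = start, end = end)
  attr(out, "chrom") <- chrom
  class(out) <- c("interval_set", "data.frame")
  out
}

new_density_profile <- function(grid, kind, values) {
  stopifnot(inherits(grid, "window_grid"), length(values) == n_windows(grid))
  if (any(values < 0)) stop("density values must be non-negative")
  structure(list(grid = grid, kind = kind, values = as.numeric(values)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> kind=%s, %s, %d windows, total=%g\n",
              x$kind, x$grid$chrom, n_windows(x$grid), sum(x$values)))
  invisible(x)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  cbind(as.data.frame(x$grid), count = x$values)
}

# window index (1-based) of a bp position on a uniform grid; NA if out of range
window_of <- function(pos, grid) {
  idx <- floor(pos / grid$window_size) + 1
  idx[pos < 0 | pos >= grid$chrom_length] <- NA_real_
  idx
}

#' Windowed count of point features
#'
#' Counts point features (typically SNP positions) per window, the signal
#' underlying SNP-density profiles.
#'
#' @param positions bp coordinates (0-based).
#' @param grid A `window_grid`.
#' @param out_of_range `"drop"` (default; drops with a warning giving the
#'   count) or `"error"`.
#' @return A `density_profile` of kind `"snp"`.
#' @export
point_density <- function(positions, grid, out_of_range = c("drop", "error")) {
  out_of_range <- match.arg(out_of_range)
  positions <- as.numeric(positions)
  idx <- window_of(positions, grid)
  n_bad <- sum(is.na(idx))
  if (n_bad > 0) {
    if (out_of_range == "error") {
      stop(sprintf("%d position(s) outside [0, %g)", n_bad, grid$chrom_length))
    }
    warning(sprintf("dropped %d out-of-range position(s)", n_bad))
    idx <- idx[!is.na(idx)]
  }
  values <- tabulate(idx, nbins = n_windows(grid))
  new_density_profile(grid, "snp", values)
}

#' Windowed read count (any-overlap)
#'
#' Counts intervals (mapped reads) per window; a boundary-spanning read
#' increments every window it overlaps by at least 1 bp, matching
#' bedtools-intersect count semantics. `method = "midpoint"` instead assigns
#' each read to the single window containing its midpoint.
#'
#' @param reads An `interval_set`.
#' @param grid A `window_grid`.
#' @param method `"overlap"` (default) or `"midpoint"`.
#' @return A `density_profile` of kind `"reads"`.
#' @export
read_count_density <- function(reads, grid, method = c("overlap", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(reads, "interval_set"))
  if (nrow(reads) == 0L) {
    return(new_density_profile(grid, "reads", numeric(n_windows(grid))))
  }
  if (method == "midpoint") {
    mid <- floor((reads$start + reads$end - 1) / 2)
    idx <- window_of(mid, grid)
    values <- tabulate(idx[!is.na(idx)], nbins = n_windows(grid))
    return(new_density_profile(grid, "reads", values))
  }
  win <- IRanges::IRanges(start = grid$starts + 1, end = grid$ends)
  ir <- IRanges::IRanges(start = reads$start + 1, end = reads$end)
  values <- IRanges::countOverlaps(win, ir)
  new_density_profile(grid, "reads", values)
}

#' Windowed positional coverage of intervals
#'
#' Number of bp in each window covered by the union of the intervals: a
#' position inside two overlapping features counts once. Used for gene-body
#' coverage (gene density) and BLAST-hit coverage (repeat density).
#'
#' @param features An `interval_set` (gene bodies, BLAST hits, ...).
#' @param grid A `window_grid`.
#' @param kind Profile kind label (default `"coverage"`; use `"blast_hits"`
#'   for repeat-hit tracks).
#' @return A `density_profile`; values are bounded by each window's length.
#' @export
positional_coverage_density <- function(features, grid, kind = "coverage") {
  stopifnot(inherits(features, "interval_set"))
  values <- numeric(n_windows(grid))
  if (nrow(features) > 0L) {
    red <- IRanges::reduce(IRanges::IRanges(start = features$start + 1,
                                            end = pmin(features$end, grid$chrom_length)))
    win <- IRanges::IRanges(start = grid$starts + 1, end = grid$ends)
    hits <- IRanges::findOverlaps(red, win)
    if (length(hits) > 0L) {
      ov <- IRanges::pintersect(red[S4Vectors::queryHits(hits)],
                                win[S4Vectors::subjectHits(hits)])
      w <- IRanges::width(ov)
      agg <- rowsum(w, group = S4Vectors::subjectHits(hits))
      values[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  new_density_profile(grid, kind, values)
}

#' Windowed assembly-gap density
#'
#' Counts ambiguous bases (`N`/`n`) per window of the assembled sequence,
#' the assembly-gap signal used to rule out gap-driven artefacts.
#'
#' @param sequence Character string or `Biostrings` XString of length equal to
#'   the grid's `chrom_length`.
#' @param grid A `window_grid`.
#' @return A `density_profile` of kind `"gap"`.
#' @export
gap_density <- function(sequence, grid) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) != grid$chrom_length) {
    stop(sprintf("sequence length %d does not match chrom_length %g",
                 nchar(sequence), grid$chrom_length))
  }
  bytes <- charToRaw(sequence)
  is_n <- bytes == charToRaw("N") | bytes == charToRaw("n")
  idx <- floor((seq_along(bytes) - 1) / grid$window_size) + 1
  values <- numeric(n_windows(grid))
  agg <- rowsum(as.numeric(is_n), group = idx)
  values[as.integer(rownames(agg))] <- agg[, 1]
  new_density_profile(grid, "gap", values)
}
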