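#' Standardize a vector to mean 0, sd 1
#'
#' Population standard deviation (n denominator), the scaling applied to the
#' pericentromeric and centromeric scale vectors before their difference is
#' maximized.
#'
#' @param v Numeric vector, length >= 2, non-constant.
#' @return Standardized vector.
#' @export
standardize <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("need at least 2 values to standardize")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) stop("cannot standardize a zero-variance vector")
  (v - m) / s
}

# 1-based row index splitting the scale axis: rows > this are the "upper
# third" (largest scales), rows <= this the "lower two thirds"
upper_third_cut <- function(n_scales) as.integer(ceiling(2 * n_scales / 3))

#' Pericentromeric scale: maximum in the upper third of the methylation landscape
#'
#' Finds the largest wavelet coefficient among the top third of scales
#' (largest scales) of the methylation landscape `M`. The row is the
#' pericentromeric scale `p`; the column is the position of the broad
#' methylation peak. Ties are broken to the smallest scale, then smallest
#' window, with a message.
#'
#' @param M A `wavelet_landscape` (methylation), >= 3 scales.
#' @return List with `p` (scale row index), `x_peak` (window index),
#'   `p_scale` (scale value) and `value` (the coefficient).
#' @export
find_pericentromeric_scale <- function(M) {
  stopifnot(inherits(M, "wavelet_landscape"))
  ns <- length(M$scales)
  if (ns < 3L) stop("need at least 3 scales to take an upper third")
  cut <- upper_third_cut(ns)
  rows <- seq.int(cut + 1L, ns)
  sub <- M$coeffs[rows, , drop = FALSE]
  mx <- max(sub)
  hits <- which(sub == mx, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    message("tie in pericentromeric-scale maximum; taking smallest scale/window")
  }
  p <- rows[hits[1, 1]]
  list(p = p, x_peak = as.integer(hits[1, 2]),
       p_scale = M$scales[p], value = mx)
}

#' Pericentromere borders: zeroes of the scale-p methylation vector
#'
#' Walks outward from the methylation peak along the pericentromeric scale
#' vector and reports the nearest window on each side where the coefficient
#' is zero or changes sign. A side with no crossing falls back to the
#' chromosome end and is flagged.
#'
#' @param M_p Coefficient vector at scale `p`.
#' @param x_peak Window index of the peak (must have `M_p[x_peak] > 0`).
#' @return List with `b1`, `b2` (window indices, `b1 <= x_peak <= b2`) and
#'   `qc_flags` (character vector, possibly empty).
#' @export
find_pericentromere_borders <- function(M_p, x_peak) {
  n <- length(M_p)
  if (x_peak < 1L || x_peak > n) stop("`x_peak` out of range")
  if (M_p[x_peak] <= 0) {
    stop(structure(class = c("centwave_degenerate", "error", "condition"),
                   list(message = "no positive methylation peak at the pericentromeric scale",
                        call = sys.call())))
  }
  qc <- character(0)
  left <- which(M_p[seq_len(x_peak)] <= 0)
  if (length(left) > 0L) {
    b1 <- max(left)
  } else {
    b1 <- 1L
    qc <- c(qc, "no_left_zero")
  }
  right_rel <- which(M_p[x_peak:n] <= 0)
  if (length(right_rel) > 0L) {
    b2 <- x_peak + min(right_rel) - 1L
  } else {
    b2 <- n
    qc <- c(qc, "no_right_zero")
  }
  list(b1 = as.integer(b1), b2 = as.integer(b2), qc_flags = qc)
}

#' Centromeric scale: minimum in the lower two-thirds of the SNP landscape
#'
#' Finds the smallest wavelet coefficient among the lower two-thirds of scales
#' of the SNP landscape, restricted to columns between the pericentromere
#' borders. The row is the centromeric scale `c`; the column is the centre of
#' the narrow SNP valley.
#'
#' @param S A `wavelet_landscape` (SNP density).
#' @param b1,b2 Pericentromere border window indices, `b1 < b2`.
#' @return List with `c` (scale row index), `x_min` (window index),
#'   `c_scale` (scale value) and `value` (the coefficient).
#' @export
find_centromeric_scale <- function(S, b1, b2) {
  stopifnot(inherits(S, "wavelet_landscape"))
  if (b1 >= b2) stop("need b1 < b2")
  ns <- length(S$scales)
  cut <- upper_third_cut(ns)
  cols <- seq.int(max(1L, b1), min(ncol(S$coeffs), b2))
  if (length(cols) == 0L) stop("empty column range between borders")
  sub <- S$coeffs[seq_len(cut), cols, drop = FALSE]
  mn <- min(sub)
  hits <- which(sub == mn, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(c = as.integer(hits[1, 1]), x_min = as.integer(cols[hits[1, 2]]),
       c_scale = S$scales[hits[1, 1]], value = mn)
}

# first window at-or-beyond which `d` is <= 0, walking outward from `center`
# within [lo, hi]; NA if no crossing
walk_to_crossing <- function(d, center, lo, hi, step) {
  i <- center + step
  while (i >= lo && i <= hi) {
    if (d[i] <= 0) return(i)
    i <- i + step
  }
  NA_integer_
}

#' Locate the centromere from methylation and SNP wavelet landscapes
#'
#' Implements the "tooth-X-ray" signature call. The pericentromeric scale `p`
#' and peak are found in the upper third of the methylation landscape `M`, the
#' pericentromere borders `b1`/`b2` as the zeroes of the scale-`p` vector, and
#' the centromeric scale `c` as the minimum of the SNP landscape `S` in the
#' lower two-thirds of scales between those borders. Both scale vectors are
#' standardized (mean 0, sd 1) and the centre is the position maximizing their
#' difference `M*_p - S*_c`; by default the search is restricted to
#' `[b1, b2]` (`search = "global"` lifts the restriction). The general
#' centromeric-region borders are the nearest intersections of the two
#' standardized curves on either side of the centre (falling back to `b1`/`b2`
#' with a flag), and the difference statistic `D` is taken on the unscaled
#' vectors at the called centre.
#'
#' Degenerate chromosomes (no positive upper-third methylation peak) yield a
#' structured no-call (`NA` fields, `qc_flags` containing `"no_call"`) rather
#' than an error.
#'
#' @param M Methylation `wavelet_landscape`.
#' @param S SNP `wavelet_landscape`, same window grid and scale grid.
#' @param search `"borders"` (default) or `"global"`.
#' @return A `centromere_call`: list with window indices (`center_window`,
#'   `region_start_win`, `region_end_win`, `b1_win`, `b2_win`), their bp
#'   equivalents when a grid is attached, the scale rows/values `p`/`c`, the
#'   unscaled difference `D`, and `qc_flags`.
#' @export
locate_centromere <- function(M, S, search = c("borders", "global")) {
  search <- match.arg(search)
  stopifnot(inherits(M, "wavelet_landscape"), inherits(S, "wavelet_landscape"))
  if (ncol(M$coeffs) != ncol(S$coeffs)) {
    stop("methylation and SNP landscapes cover different window counts")
  }
  nw <- ncol(M$coeffs)
  no_call <- function(flags) {
    structure(list(chrom = if (!is.null(M$grid)) M$grid$chrom else NA_character_,
                   center_window = NA_integer_, center_bp = NA_real_,
                   region_start_win = NA_integer_, region_end_win = NA_integer_,
                   region_start_bp = NA_real_, region_end_bp = NA_real_,
                   b1_win = NA_integer_, b2_win = NA_integer_,
                   b1_bp = NA_real_, b2_bp = NA_real_,
                   p = NA_integer_, c = NA_integer_,
                   p_scale = NA_real_, c_scale = NA_real_,
                   D = NA_real_, qc_flags = c("no_call", flags)),
              class = "centromere_call")
  }
  peri <- tryCatch(find_pericentromeric_scale(M), error = function(e) e)
  if (inherits(peri, "error")) return(no_call(conditionMessage(peri)))
  M_p <- scale_vector(M, peri$p)
  borders <- tryCatch(find_pericentromere_borders(M_p, peri$x_peak),
                      error = function(e) e)
  if (inherits(borders, "error")) return(no_call(conditionMessage(borders)))
  qc <- borders$qc_flags
  b1 <- borders$b1; b2 <- borders$b2
  cen <- tryCatch(find_centromeric_scale(S, b1, b2), error = function(e) e)
  if (inherits(cen, "error")) return(no_call(conditionMessage(cen)))
  S_c <- scale_vector(S, cen$c)

  Mst <- standardize(M_p)
  Sst <- standardize(S_c)
  d <- Mst - Sst
  dom <- if (search == "borders") seq.int(b1, b2) else seq_len(nw)
  mx <- max(d[dom])
  cand <- dom[d[dom] == mx]
  if (length(cand) > 1L) message("tie in centromere argmax; taking smallest window")
  center <- as.integer(min(cand))

  rs <- walk_to_crossing(d, center, b1, b2, -1L)
  if (is.na(rs)) { rs <- b1; qc <- c(qc, "region_start_at_b1") }
  re <- walk_to_crossing(d, center, b1, b2, +1L)
  if (is.na(re)) { re <- b2; qc <- c(qc, "region_end_at_b2") }

  if (!(peri$p_scale > cen$c_scale)) qc <- c(qc, "p_scale_not_above_c_scale")
  D <- M_p[center] - S_c[center]

  grid <- M$grid
  to_bp <- function(w) {
    if (is.null(grid) || is.na(w)) return(NA_real_)
    (grid$starts[w] + grid$ends[w]) / 2
  }
  structure(list(chrom = if (!is.null(grid)) grid$chrom else NA_character_,
                 center_window = center, center_bp = to_bp(center),
                 region_start_win = as.integer(rs), region_end_win = as.integer(re),
                 region_start_bp = to_bp(rs), region_end_bp = to_bp(re),
                 b1_win = b1, b2_win = b2, b1_bp = to_bp(b1), b2_bp = to_bp(b2),
                 p = peri$p, c = cen$c,
                 p_scale = peri$p_scale, c_scale = cen$c_scale,
                 D = D, qc_flags = qc),
            class = "centromere_call")
}

#' @export
print.centromere_call <- function(x, ...) {
  if ("no_call" %in% x$qc_flags) {
    cat(sprintf("<centromere_call> %s: NO CALL (%s)\n", x$chrom,
                paste(x$qc_flags[-1], collapse = "; ")))
  } else {
    cat(sprintf("<centromere_call> %s: center window %d (bp %g), region [%d, %d], b=[%d, %d], p_scale=%.1f, c_scale=%.1f, D=%.3f%s\n",
                x$chrom, x$center_window, x$center_bp,
                x$region_start_win, x$region_end_win, x$b1_win, x$b2_win,
                x$p_scale, x$c_scale, x$D,
                if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.centromere_call <- function(x, ...) {
  data.frame(chrom = x$chrom, center_bp = x$center_bp,
             region_start = x$region_start_bp, region_end = x$region_end_bp,
             b1 = x$b1_bp, b2 = x$b2_bp,
             p_scale = x$p_scale, c_scale = x$c_scale, D = x$D,
             qc_flags = paste(x$qc_flags, collapse = ","))
}

#' Call a centromere from raw methylation and SNP density profiles
#'
#' Convenience pipeline: standardizes both profiles (mean 0, sd 1), computes
#' their Ricker CWT landscapes on a shared scale grid, and runs
#' [locate_centromere()].
#'
#' @param meth A methylation `density_profile`.
#' @param snp A SNP-density `density_profile` on the same grid.
#' @param voices,norm,boundary CWT options, see [cwt()].
#' @param search Argmax search domain, see [locate_centromere()].
#' @return A `centromere_call`.
#' @export
call_centromere <- function(meth, snp, voices = 8, norm = "l2",
                            boundary = "reflect", search = "borders") {
  stopifnot(inherits(meth, "density_profile"), inherits(snp, "density_profile"))
  if (n_windows(meth$grid) != n_windows(snp$grid)) {
    stop("profiles are on different window grids")
  }
  scales <- scale_grid(n_windows(meth$grid), voices = voices)
  M <- cwt(meth, scales = scales, norm = norm, boundary = boundary,
           standardize = TRUE)
  S <- cwt(snp, scales = scales, norm = norm, boundary = boundary,
           standardize = TRUE)
  locate_centromere(M, S, search = search)
}
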