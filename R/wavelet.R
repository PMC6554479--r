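#' Ricker (Mexican-hat) wavelet
#'
#' Second derivative of a Gaussian, the mother wavelet used for peak/valley
#' detection: zero-mean, symmetric, maximal at `t = 0`, with roots at
#' `t = +/- s`. The amplitude constant `A = 2 / (sqrt(3) * pi^(1/4))` gives the
#' mother wavelet (s = 1) unit L2 norm in the continuum.
#'
#' @param t Offset from the wavelet centre, in window units.
#' @param s Scale (> 0), in window units.
#' @return Wavelet values, same length as `t`.
#' @examples
#' ricker(0, 5)          # positive maximum
#' ricker(c(-5, 5), 5)   # zeros at +/- s
#' @export
ricker <- function(t, s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    stop("scale `s` must be a single positive number")
  }
  A <- 2 / (sqrt(3) * pi^0.25)
  u <- t / s
  A * (1 - u^2) * exp(-u^2 / 2)
}

#' Dyadic scale grid for the CWT
#'
#' Scales in window units, dyadically spaced with `voices` scales per octave,
#' from `s_min` up to `s_max` (default `n_windows / 4`, the largest scale whose
#' support fits the signal comfortably).
#'
#' @param n_windows Signal length in windows (used for the default `s_max`).
#' @param s_min Smallest scale (default 2 windows).
#' @param s_max Largest scale (default `n_windows / 4`).
#' @param voices Scales per octave (default 8).
#' @return Strictly increasing numeric vector of scales.
#' @export
scale_grid <- function(n_windows = NULL, s_min = 2, s_max = NULL, voices = 8) {
  if (is.null(s_max)) {
    if (is.null(n_windows)) stop("give `n_windows` or `s_max`")
    s_max <- n_windows / 4
  }
  if (s_min < 1) stop("smallest scale must be >= 1 window")
  if (s_max < s_min) stop("`s_max` must be >= `s_min`")
  k <- seq(0, floor(voices * log2(s_max / s_min)))
  s_min * 2^(k / voices)
}

# reflection (mirror-without-repeat) index into 1..n for any integer j;
# period 2n-2 handles pads wider than the signal
fold_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  p <- 2L * n - 2L
  m <- ((j - 1L) %% p)
  m <- ifelse(m < 0, m + p, m)
  as.integer(ifelse(m < n, m + 1L, p - m + 1L))
}

pad_signal <- function(x, pad, boundary) {
  n <- length(x)
  if (pad == 0L) return(x)
  if (boundary == "zero") {
    c(numeric(pad), x, numeric(pad))
  } else {
    x[fold_index(seq.int(1L - pad, n + pad), n)]
  }
}

#' Continuous wavelet transform of a density signal
#'
#' Computes the coefficient landscape `W(s, tau)`: for every scale `s` and
#' window position `tau`, the correlation of the signal with the scaled,
#' translated Ricker wavelet,
#' `W(s, tau) = s^(-1/2) * sum_t f(t) * psi((t - tau) / s)` (L2 normalization;
#' `norm = "l1"` uses a `1/s` prefactor instead). Positive coefficients mark
#' peaks and negative ones valleys of width comparable to `s`.
#'
#' The signal is padded on both sides by `4 * max(scales)` windows (reflection
#' by default, zeros with `boundary = "zero"`) before the transform and the
#' result is cropped back, so telomere ends do not produce spurious valleys.
#' The wavelet is truncated at `|t| <= 8 s`, where its tail is below 1e-13 of
#' the peak; consequently coefficients within `4 s` of either end still feel
#' a small boundary contribution, while positions at least `4 s` from both
#' ends are boundary-free to ~1e-13. Scales larger than a quarter of the
#' signal length are dropped with a warning.
#'
#' @param x A `density_profile` or numeric vector.
#' @param scales Scale vector (window units); default `scale_grid(length(x),
#'   voices = voices)`.
#' @param voices Scales per octave for the default grid.
#' @param norm `"l2"` (default, `1/sqrt(s)`) or `"l1"` (`1/s`).
#' @param boundary `"reflect"` (default) or `"zero"`.
#' @param standardize If `TRUE`, centre and scale the signal to mean 0, sd 1
#'   (population sd) before transforming, as the centromere caller does.
#' @return A `wavelet_landscape`: list with `scales` (ascending), `coeffs`
#'   (matrix, one row per scale, one column per window), `norm`, `boundary`,
#'   and the source `grid`/`kind` when `x` is a profile.
#' @export
cwt <- function(x, scales = NULL, voices = 8, norm = c("l2", "l1"),
                boundary = c("reflect", "zero"), standardize = FALSE) {
  norm <- match.arg(norm)
  boundary <- match.arg(boundary)
  grid <- NULL; kind <- NULL
  if (inherits(x, "density_profile")) {
    grid <- x$grid; kind <- x$kind; x <- x$values
  }
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal must be finite")
  n <- length(x)
  if (n < 8L) stop("signal too short for a wavelet transform")
  if (is.null(scales)) scales <- scale_grid(n, voices = voices)
  scales <- sort(unique(as.numeric(scales)))
  if (any(scales <= 0)) stop("scales must be positive")
  keep <- scales <= n / 4
  if (!all(keep)) {
    warning(sprintf("dropped %d scale(s) larger than n/4 = %g windows",
                    sum(!keep), n / 4))
    scales <- scales[keep]
    if (length(scales) == 0L) stop("no usable scales for this signal length")
  }
  if (standardize) x <- standardize(x)

  pad <- as.integer(ceiling(4 * max(scales)))
  xp <- pad_signal(x, pad, boundary)
  np <- length(xp)
  t_max <- as.integer(ceiling(8 * max(scales)))
  L <- stats::nextn(np + 2L * t_max + 1L)
  fx <- stats::fft(c(xp, numeric(L - np)))

  coeffs <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    T_ <- as.integer(ceiling(8 * s))
    k <- ricker(seq.int(-T_, T_), s) * if (norm == "l2") 1 / sqrt(s) else 1 / s
    kv <- numeric(L)
    kv[1L] <- k[T_ + 1L]                    # offset 0
    kv[2L:(T_ + 1L)] <- k[(T_ + 2L):(2L * T_ + 1L)]   # offsets 1..T
    kv[(L - T_ + 1L):L] <- k[1L:T_]         # offsets -T..-1
    z <- Re(stats::fft(fx * stats::fft(kv), inverse = TRUE)) / L
    coeffs[si, ] <- z[(pad + 1L):(pad + n)]
  }
  structure(list(scales = scales, coeffs = coeffs, norm = norm,
                 boundary = boundary, grid = grid, kind = kind),
            class = "wavelet_landscape")
}

#' @export
print.wavelet_landscape <- function(x, ...) {
  cat(sprintf("<wavelet_landscape> %d scales [%g..%g windows] x %d positions (norm=%s, boundary=%s)\n",
              length(x$scales), min(x$scales), max(x$scales),
              ncol(x$coeffs), x$norm, x$boundary))
  invisible(x)
}

#' Extract one scale's coefficient vector
#'
#' Row `s_index` of the landscape: the signal's peaks and troughs smoothed at
#' that scale.
#'
#' @param landscape A `wavelet_landscape`.
#' @param s_index Scale row index (1-based, ascending scale).
#' @return Numeric vector of coefficients, one per window.
#' @export
scale_vector <- function(landscape, s_index) {
  stopifnot(inherits(landscape, "wavelet_landscape"))
  if (s_index < 1L || s_index > length(landscape$scales)) {
    stop(sprintf("scale index %d out of range 1..%d",
                 s_index, length(landscape$scales)))
  }
  landscape$coeffs[s_index, ]
}
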