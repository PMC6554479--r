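# hand-built landscapes for the scale/border finders
fake_landscape <- function(coeffs, scales = seq_len(nrow(coeffs))) {
  structure(list(scales = scales, coeffs = coeffs, norm = "l2",
                 boundary = "reflect", grid = NULL, kind = NULL),
            class = "wavelet_landscape")
}

test_that("standardize gives mean 0, population sd 1, and affine invariance", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  set.seed(3); v <- rnorm(50)
  expect_equal(standardize(3 * v + 7), standardize(v), tolerance = 1e-10)
  expect_equal(standardize(-2 * v + 1), -standardize(v), tolerance = 1e-10)
  expect_error(standardize(rep(4, 10)), "zero-variance")
  expect_error(standardize(1), "at least 2")
})

test_that("pericentromeric scale search is restricted to the upper third", {
  m <- matrix(0, nrow = 9, ncol = 20)
  m[8, 13] <- 5          # planted max in the top third (rows 7..9)
  m[2, 4] <- 50          # larger global max in the bottom third: ignored
  got <- find_pericentromeric_scale(fake_landscape(m))
  expect_equal(got$p, 8L)
  expect_equal(got$x_peak, 13L)
  expect_equal(got$value, 5)
  # all-equal upper third: tie broken to smallest scale then window
  m2 <- matrix(1, nrow = 9, ncol = 10)
  suppressMessages(got2 <- find_pericentromeric_scale(fake_landscape(m2)))
  expect_equal(got2$p, 7L)
  expect_equal(got2$x_peak, 1L)
  expect_error(find_pericentromeric_scale(fake_landscape(matrix(1, 2, 5))),
               "at least 3 scales")
})

test_that("pericentromere borders are the nearest sign changes, with end fallback", {
  got <- find_pericentromere_borders(c(-1, 2, 3, 2, -1), 3)
  expect_equal(c(got$b1, got$b2), c(1L, 5L))
  expect_length(got$qc_flags, 0)
  # exact zeros count as crossings
  got0 <- find_pericentromere_borders(c(1, 0, 2, 5, 2, 0, 1), 4)
  expect_equal(c(got0$b1, got0$b2), c(2L, 6L))
  # all-positive vector falls back to the chromosome ends with flags
  gotp <- find_pericentromere_borders(rep(2, 7), 4)
  expect_equal(c(gotp$b1, gotp$b2), c(1L, 7L))
  expect_setequal(gotp$qc_flags, c("no_left_zero", "no_right_zero"))
  expect_error(find_pericentromere_borders(c(1, -2, 1), 2), "no positive")
})

test_that("centromeric scale search is restricted to the lower two-thirds between borders", {
  s <- matrix(0, nrow = 9, ncol = 20)
  s[3, 10] <- -4         # planted min in the lower two-thirds inside [b1,b2]
  s[2, 2] <- -50         # smaller min outside [b1,b2]: ignored
  s[8, 12] <- -60        # and in the upper third: ignored
  got <- find_centromeric_scale(fake_landscape(s), b1 = 5, b2 = 15)
  expect_equal(got$c, 3L)
  expect_equal(got$x_min, 10L)
  expect_error(find_centromeric_scale(fake_landscape(s), 10, 10), "b1 < b2")
})

test_that("the full caller recovers planted centromeres on synthetic chromosomes", {
  for (seed in 1:3) {
    sig <- simulate_signals(centromere_scenario(seed = seed))
    cl <- call_centromere(sig$methylation, sig$snp)
    expect_lte(abs(cl$center_window - 800), 2)
    # containment invariants
    expect_lte(cl$b1_win, cl$region_start_win)
    expect_lte(cl$region_start_win, cl$center_window)
    expect_lte(cl$center_window, cl$region_end_win)
    expect_lte(cl$region_end_win, cl$b2_win)
    expect_true(is.finite(cl$D))
    expect_gt(cl$p_scale, cl$c_scale)
    # centre in bp sits inside the called region
    expect_true(cl$region_start_bp <= cl$center_bp &&
                  cl$center_bp <= cl$region_end_bp)
  }
})

test_that("pericentromere borders bracket the planted pericentromere width", {
  sig <- simulate_signals(centromere_scenario(seed = 4))
  M <- cwt(sig$methylation, standardize = TRUE)
  peri <- find_pericentromeric_scale(M)
  expect_lte(abs(peri$x_peak - 800), 5)
  bor <- find_pericentromere_borders(scale_vector(M, peri$p), peri$x_peak)
  width <- bor$b2 - bor$b1
  expect_gte(width, 2 * 150)
  expect_lte(width, 6 * 150)
})

test_that("calls are invariant to positive rescaling of either profile", {
  sig <- simulate_signals(centromere_scenario(seed = 6))
  base <- call_centromere(sig$methylation, sig$snp)
  m2 <- sig$methylation; m2$values <- m2$values * 37
  s2 <- sig$snp; s2$values <- s2$values * 0.01
  scaled <- call_centromere(m2, s2)
  expect_equal(scaled$center_window, base$center_window)
  expect_equal(scaled$b1_win, base$b1_win)
  expect_equal(scaled$b2_win, base$b2_win)
})

test_that("reversing both profiles mirrors the call", {
  sig <- simulate_signals(centromere_scenario(seed = 8))
  fwd <- call_centromere(sig$methylation, sig$snp)
  rev_ <- call_centromere(reverse_profile(sig$methylation),
                          reverse_profile(sig$snp))
  n <- 2000
  expect_equal(rev_$center_window, n + 1 - fwd$center_window)
  expect_equal(rev_$b1_win, n + 1 - fwd$b2_win)
  expect_equal(rev_$b2_win, n + 1 - fwd$b1_win)
})

test_that("degenerate chromosomes give a structured no-call", {
  # methylation landscape with a non-positive upper third: no tooth-X-ray
  m <- matrix(-1, nrow = 9, ncol = 50)
  s <- matrix(rnorm(9 * 50), nrow = 9)
  cl <- locate_centromere(fake_landscape(m), fake_landscape(s))
  expect_s3_class(cl, "centromere_call")
  expect_true("no_call" %in% cl$qc_flags)
  expect_true(is.na(cl$center_window))
  expect_true(is.na(cl$D))
})

test_that("global search mode can look outside the pericentromere borders", {
  sig <- simulate_signals(centromere_scenario(seed = 9))
  cb <- call_centromere(sig$methylation, sig$snp, search = "borders")
  cg <- call_centromere(sig$methylation, sig$snp, search = "global")
  # on clean synthetic data both find the same centre
  expect_lte(abs(cg$center_window - cb$center_window), 2)
})
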