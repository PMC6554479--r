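# Independent brute-force oracles: explicit per-position / per-pair /
# per-individual loops, deliberately naive and written without reusing any
# package internals.

oracle_point_density <- function(positions, grid) {
  counts <- numeric(n_windows(grid))
  for (p in positions) {
    for (w in seq_along(grid$starts)) {
      if (p >= grid$starts[w] && p < grid$ends[w]) counts[w] <- counts[w] + 1
    }
  }
  counts
}

oracle_read_count <- function(reads, grid) {
  counts <- numeric(n_windows(grid))
  for (r in seq_len(nrow(reads))) {
    for (w in seq_along(grid$starts)) {
      if (reads$start[r] < grid$ends[w] && reads$end[r] > grid$starts[w]) {
        counts[w] <- counts[w] + 1
      }
    }
  }
  counts
}

oracle_coverage <- function(features, grid) {
  covered <- rep(FALSE, grid$chrom_length)
  for (r in seq_len(nrow(features))) {
    lo <- max(0, features$start[r]); hi <- min(grid$chrom_length, features$end[r])
    if (hi > lo) covered[(lo + 1):hi] <- TRUE
  }
  counts <- numeric(n_windows(grid))
  for (w in seq_along(grid$starts)) {
    counts[w] <- sum(covered[(grid$starts[w] + 1):grid$ends[w]])
  }
  counts
}

oracle_gap <- function(sequence, grid) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- numeric(n_windows(grid))
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("N", "n")) {
      w <- floor((i - 1) / grid$window_size) + 1
      counts[w] <- counts[w] + 1
    }
  }
  counts
}

# Quadrature of the CWT definition at one (scale, translation): explicit sum
# over t on a reflection-padded copy built by simple vector reversal (valid
# for pad <= length(x) - 1, which the calling tests respect).
oracle_cwt_at <- function(x, s, tau, pad, norm = "l2") {
  n <- length(x)
  stopifnot(pad <= n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  taup <- tau + pad
  A <- 2 / (sqrt(3) * pi^0.25)
  acc <- 0
  T_ <- ceiling(8 * s)
  for (t in -T_:T_) {
    idx <- taup + t
    if (idx >= 1 && idx <= length(xp)) {
      u <- t / s
      acc <- acc + xp[idx] * A * (1 - u^2) * exp(-u^2 / 2)
    }
  }
  acc * if (norm == "l2") 1 / sqrt(s) else 1 / s
}

# per-individual loop evaluation of R and CCC for one allele pair
oracle_ccc_pair <- function(gm, i, j, x, y, pairing, reading) {
  n_ov <- 0L; co_min <- 0; co_car <- 0L; cx <- 0; cy <- 0
  for (k in seq_len(nrow(gm$dosage))) {
    di <- unname(gm$dosage[k, i]); dj <- unname(gm$dosage[k, j])
    if (is.na(di) || is.na(dj)) next
    dx <- if (x == "alt") di else 2 - di
    dy <- if (y == "alt") dj else 2 - dj
    n_ov <- n_ov + 1L
    co_min <- co_min + min(dx, dy)
    if (dx > 0 && dy > 0) co_car <- co_car + 1L
    cx <- cx + dx; cy <- cy + dy
  }
  if (n_ov == 0L) return(list(R = NA, n_overlap = 0L, ccc = NA))
  R <- if (pairing == "carrier") co_car / n_ov else co_min / (2 * n_ov)
  fx <- cx / (2 * n_ov); fy <- cy / (2 * n_ov)
  ccc <- if (fx <= 0 || fy <= 0) NA_real_
         else if (reading == "freq_penalty") 4.5 * R * (1 - fx) * (1 - fy)
         else 4.5 * R * (1 - 1 / fx) * (1 - 1 / fy)
  list(R = R, n_overlap = n_ov, f_ix = fx, f_jy = fy, ccc = ccc)
}

# exhaustive all-pairs scan using the loop oracle
oracle_ccc_scan <- function(gm, threshold, min_overlap, pairing, reading) {
  out <- list()
  ns <- ncol(gm$dosage)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    for (x in c("ref", "alt")) for (y in c("ref", "alt")) {
      o <- oracle_ccc_pair(gm, i, j, x, y, pairing, reading)
      if (o$n_overlap >= min_overlap && !is.na(o$ccc) && o$ccc >= threshold) {
        out[[length(out) + 1]] <- data.frame(site_i = i, allele_x = x,
                                             site_j = j, allele_y = y,
                                             R = o$R, n_overlap = o$n_overlap,
                                             ccc = o$ccc)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site_i = integer(), allele_x = character(),
               site_j = integer(), allele_y = character(),
               R = numeric(), n_overlap = integer(), ccc = numeric())
}

random_genotype_matrix <- function(n_ind, n_sites, missing_rate = 0.1) {
  d <- matrix(sample(c(0L, 1L, 2L), n_ind * n_sites, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)), nrow = n_ind)
  d[matrix(runif(length(d)) < missing_rate, nrow = n_ind)] <- NA_integer_
  genotype_matrix(d, data.frame(chrom = "chrT", pos = seq_len(n_sites) * 100,
                                ref = "A", alt = "C"))
}

reverse_profile <- function(p) { p$values <- rev(p$values); p }
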