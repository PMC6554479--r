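toy_gm <- function(dosage_cols, chrom = "chr1") {
  d <- do.call(cbind, dosage_cols)
  genotype_matrix(d, data.frame(chrom = chrom,
                                pos = seq_len(ncol(d)) * 1000,
                                ref = "A", alt = "G"))
}

test_that("site statistics: call rate, allele frequencies, MAF", {
  gm <- toy_gm(list(c(0L, 1L, 2L, NA)))
  st <- site_stats(gm)
  expect_equal(st$call_rate, 0.75)
  expect_equal(st$f_alt, 0.5)
  expect_equal(st$maf, 0.5)
  gm0 <- toy_gm(list(c(0L, 0L, 0L, 0L)))
  expect_equal(site_stats(gm0)$maf, 0)
  gmm <- toy_gm(list(rep(NA_integer_, 4)))
  expect_equal(site_stats(gmm)$call_rate, 0)
  expect_true(is.na(site_stats(gmm)$maf))

  set.seed(21)
  gm <- random_genotype_matrix(40, 15)
  st <- site_stats(gm)
  for (s in c(1, 7, 15)) {
    d <- gm$dosage[, s]
    nc <- sum(!is.na(d))
    expect_equal(st$call_rate[s], nc / 40)
    expect_equal(st$f_alt[s], sum(d, na.rm = TRUE) / (2 * nc))
  }
})

test_that("site filter removes MAF and call-rate boundary cases strictly", {
  n <- 100
  make_col <- function(n1, n2, nmiss) {
    c(rep(1L, n1), rep(2L, n2), rep(NA_integer_, nmiss),
      rep(0L, n - n1 - n2 - nmiss))
  }
  gm <- toy_gm(list(
    make_col(2, 0, 0),    # maf = 0.01 exactly -> removed
    make_col(3, 0, 0),    # maf = 0.015 -> kept
    make_col(40, 10, 50), # call rate = 0.5 exactly -> removed
    make_col(40, 10, 48), # call rate = 0.52 -> kept
    make_col(0, 0, 0)     # monomorphic -> removed
  ))
  kept <- filter_sites(gm)
  expect_equal(kept$sites$pos, c(2000, 4000))
  # survivor set equals an explicit oracle filter on a random matrix
  set.seed(33)
  gm2 <- random_genotype_matrix(60, 25, missing_rate = 0.4)
  st <- site_stats(gm2)
  expect_equal(filter_sites(gm2)$sites$pos,
               gm2$sites$pos[!is.na(st$maf) & st$maf > 0.01 & st$call_rate > 0.5])
})

test_that("relative co-occurrence matches per-individual loops under both pairings", {
  # all homozygous for both alleles -> R = 1 under both rules
  gm <- toy_gm(list(rep(2L, 10), rep(2L, 10)))
  expect_equal(relative_cooccurrence(gm, 1, 2, pairing = "min")$R, 1)
  expect_equal(relative_cooccurrence(gm, 1, 2, pairing = "carrier")$R, 1)
  # alleles never carried together -> R = 0
  gm2 <- toy_gm(list(c(2L, 2L, 0L, 0L), c(0L, 0L, 2L, 2L)))
  expect_equal(relative_cooccurrence(gm2, 1, 2, pairing = "min")$R, 0)
  expect_equal(relative_cooccurrence(gm2, 1, 2, pairing = "carrier")$R, 0)

  set.seed(55)
  gm3 <- random_genotype_matrix(50, 6)
  for (rep in 1:20) {
    ij <- sample(6, 2)
    x <- sample(c("ref", "alt"), 1); y <- sample(c("ref", "alt"), 1)
    for (pr in c("carrier", "min")) {
      got <- relative_cooccurrence(gm3, ij[1], ij[2], x, y, pairing = pr)
      want <- oracle_ccc_pair(gm3, ij[1], ij[2], x, y, pr, "freq_penalty")
      expect_equal(got$R, want$R)
      expect_equal(got$n_overlap, want$n_overlap)
      expect_equal(got$f_ix, want$f_ix)
      expect_true(got$R >= 0 && got$R <= 1)
    }
  }
})

test_that("ccc_value implements both formula readings", {
  expect_equal(ccc_value(0, 0.5, 0.5), 0)
  expect_equal(ccc_value(0.5, 1, 0.3), 0)         # monomorphic allele -> 0
  expect_equal(ccc_value(0.3, 0.5, 0.5), 4.5 * 0.3 * 0.25)
  expect_equal(ccc_value(0.3, 0.5, 0.5), 0.3375)
  expect_true(is.na(ccc_value(0.3, 0, 0.5)))      # frequency 0 -> undefined
  expect_equal(ccc_value(0.2, 0.5, 0.25, reading = "inverse_freq"),
               4.5 * 0.2 * (1 - 2) * (1 - 4))
})

test_that("ccc_scan equals the exhaustive brute-force scan and is symmetric", {
  # planted perfectly co-segregating pair, f = 0.3, no missing
  set.seed(77)
  lat <- rbinom(60, 2, 0.3)
  gm <- toy_gm(list(as.integer(lat), as.integer(lat),
                    as.integer(rbinom(60, 2, 0.4))))
  ed <- ccc_scan(gm, threshold = 0.7, min_overlap = 10)
  pair12 <- ed[ed$site_i == 1 & ed$site_j == 2 & ed$allele_x == "alt" &
                 ed$allele_y == "alt", ]
  expect_equal(nrow(pair12), 1)
  o <- oracle_ccc_pair(gm, 1, 2, "alt", "alt", "carrier", "freq_penalty")
  expect_equal(pair12$R, o$R)
  expect_equal(pair12$ccc, o$ccc)
  expect_gte(pair12$ccc, 0.7)

  # impossible threshold -> empty
  expect_equal(nrow(ccc_scan(gm, threshold = 1.2, min_overlap = 10)), 0)

  # full equality with the oracle on a random matrix, all rule combinations
  set.seed(88)
  gmr <- random_genotype_matrix(50, 12)
  for (pr in c("carrier", "min")) for (rd in c("freq_penalty", "inverse_freq")) {
    got <- ccc_scan(gmr, threshold = 0.5, min_overlap = 20,
                    pairing = pr, reading = rd)
    want <- oracle_ccc_scan(gmr, 0.5, 20, pr, rd)
    expect_equal(got[, c("site_i", "allele_x", "site_j", "allele_y")],
                 want[, c("site_i", "allele_x", "site_j", "allele_y")],
                 ignore_attr = TRUE)
    expect_equal(got$ccc, want$ccc)
    expect_equal(got$R, want$R)
  }

  # symmetry: reversing site order relabels but keeps the same edge set
  rev_idx <- rev(seq_len(ncol(gmr$dosage)))
  gm_rev <- genotype_matrix(gmr$dosage[, rev_idx], gmr$sites[rev_idx, ],
                            gmr$individuals)
  e1 <- ccc_scan(gmr, threshold = 0.5, min_overlap = 20)
  e2 <- ccc_scan(gm_rev, threshold = 0.5, min_overlap = 20)
  key <- function(e) sort(paste(pmin(e$pos_i, e$pos_j), pmax(e$pos_i, e$pos_j),
                                ifelse(e$pos_i < e$pos_j, e$allele_x, e$allele_y),
                                ifelse(e$pos_i < e$pos_j, e$allele_y, e$allele_x)))
  expect_equal(key(e1), key(e2))
})

test_that("edges below the overlap floor are suppressed", {
  lat <- as.integer(rbinom(30, 2, 0.4))
  d1 <- lat; d1[1:25] <- NA_integer_  # only 5 overlapping individuals
  gm <- toy_gm(list(d1, lat))
  expect_equal(nrow(ccc_scan(gm, threshold = 0, min_overlap = 10)), 0)
})

test_that("block schedule covers every site pair exactly once", {
  s20 <- block_schedule(200, 20)
  expect_equal(nrow(s20), 210)
  expect_equal(sum(s20$block_a == s20$block_b), 20)
  expect_equal(nrow(block_schedule(10, 1)), 1)
  expect_equal(nrow(block_schedule(30, 3)), 6)
  expect_error(block_schedule(5, 6), "n_blocks")

  for (nb in 1:10) {
    n <- 23
    sched <- block_schedule(n, nb)
    blocks <- attr(sched, "blocks")
    expect_equal(sort(unlist(blocks)), 1:n)  # partition
    seen <- character(0)
    for (j in seq_len(nrow(sched))) {
      a <- blocks[[sched$block_a[j]]]; b <- blocks[[sched$block_b[j]]]
      pairs <- if (sched$block_a[j] == sched$block_b[j]) {
        if (length(a) < 2) character(0)
        else apply(utils::combn(a, 2), 2, paste, collapse = "-")
      } else {
        as.vector(outer(a, b, paste, sep = "-"))
      }
      seen <- c(seen, pairs)
    }
    norm_pair <- function(p) {
      xy <- as.integer(strsplit(p, "-")[[1]])
      paste(min(xy), max(xy), sep = "-")
    }
    seen <- vapply(seen, norm_pair, character(1))
    all_pairs <- apply(utils::combn(n, 2), 2, paste, collapse = "-")
    expect_equal(sort(unname(seen)), sort(all_pairs))  # each exactly once
  }
})

test_that("co-evolution profiles count distinct anchor-linked SNPs outside the anchor", {
  grid <- make_windows(50000, 10000, chrom = "chr1")
  edges <- data.frame(
    site_i = c(1, 2, 3), allele_x = "alt",
    site_j = c(4, 4, 5), allele_y = "alt",
    chrom_i = "chr1", pos_i = c(500, 700, 900),       # anchor SNPs
    chrom_j = "chr1", pos_j = c(25000, 25000, 44000), # distal partners
    R = 1, f_ix = 0.3, f_jy = 0.3, n_overlap = 200, ccc = 0.9)
  prof <- coevolution_profile(edges, "chr1", 0, 1000, grid)
  # SNP at 25000 linked to two anchor SNPs counts once
  expect_equal(prof$values, c(0, 0, 1, 0, 1))
  expect_equal(prof$kind, "corr_snp")
  # anchor on the other side of the edge is handled symmetrically
  edges2 <- edges
  names(edges2)[c(5, 6, 7, 8)] <- c("chrom_j", "pos_j", "chrom_i", "pos_i")
  prof2 <- coevolution_profile(edges2, "chr1", 0, 1000, grid)
  expect_equal(prof2$values, prof$values)
  expect_warning(coevolution_profile(edges, "chr9", 0, 1000, grid), "anchor")
})
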