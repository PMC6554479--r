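#' Construct a genotype matrix
#'
#' Individuals x sites table of ALT-allele dosages (0, 1, 2 or `NA` for a
#' missing call) for biallelic SNPs, with per-site metadata.
#'
#' @param dosage Integer matrix, individuals in rows, sites in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param sites Data frame with one row per site: columns `chrom`, `pos`
#'   (bp, 0-based), `ref`, `alt`.
#' @param individuals Character vector of individual identifiers (default
#'   rownames or `ind1..indN`).
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, individuals = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(sites) != ncol(dosage)) stop("`sites` rows must match dosage columns")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("`sites` needs columns chrom, pos, ref, alt")
  }
  if (is.null(individuals)) {
    individuals <- rownames(dosage)
    if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(dosage)))
  }
  rownames(dosage) <- individuals
  structure(list(dosage = dosage, sites = as.data.frame(sites),
                 individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-site call rate, allele frequencies and MAF
#'
#' Call rate is the fraction of individuals with a non-missing genotype;
#' allele frequencies are taken over the `2 x` non-missing allele slots;
#' MAF is the smaller of the two. All-missing sites get call rate 0 and
#' `NA` frequencies.
#'
#' @param gm A `genotype_matrix`.
#' @param sites Site indices (default all).
#' @return Data frame with columns `site`, `call_rate`, `f_ref`, `f_alt`,
#'   `maf`.
#' @export
site_stats <- function(gm, sites = seq_len(ncol(gm$dosage))) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage[, sites, drop = FALSE]
  n_called <- colSums(!is.na(d))
  call_rate <- n_called / nrow(d)
  f_alt <- ifelse(n_called > 0, colSums(d, na.rm = TRUE) / (2 * n_called), NA_real_)
  f_ref <- 1 - f_alt
  data.frame(site = sites, call_rate = call_rate, f_ref = f_ref,
             f_alt = f_alt, maf = pmin(f_ref, f_alt))
}

#' Filter sites on MAF and call rate
#'
#' Removes sites with MAF <= `maf_min` or call rate <= `callrate_min`
#' (strict retention: a site at exactly the boundary is removed).
#'
#' @param gm A `genotype_matrix`.
#' @param maf_min MAF boundary (default 0.01).
#' @param callrate_min Call-rate boundary (default 0.5).
#' @return Filtered `genotype_matrix` (possibly with zero sites, warned).
#' @export
filter_sites <- function(gm, maf_min = 0.01, callrate_min = 0.5) {
  st <- site_stats(gm)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$call_rate > callrate_min
  if (!any(keep)) warning("no sites survive the MAF/call-rate filter")
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$sites[keep, , drop = FALSE], gm$individuals)
}

# dosage of a named allele ("ref"/"alt") from ALT dosage
allele_dosage <- function(d, allele) {
  if (allele == "alt") d else 2L - d
}

#' Relative co-occurrence of two alleles at two sites
#'
#' Over the individuals with non-missing calls at both sites, measures how
#' often allele `x` at site `i` and allele `y` at site `j` occur together.
#' Two pairing rules for unphased diploids are offered: `"carrier"` (default)
#' counts an individual once if it carries at least one copy of each allele,
#' divided by the overlap count; `"min"` sums `min(d_x, d_y)` per individual
#' (maximal within-individual pairing without phase), divided by twice the
#' overlap count. Either way `R` lies in `[0, 1]`.
#'
#' @param gm A `genotype_matrix`.
#' @param i,j Site indices, `i != j`.
#' @param x,y `"ref"` or `"alt"`: the allele considered at each site.
#' @param pairing `"carrier"` (default) or `"min"`.
#' @return List with `R`, `n_overlap`, and the allele frequencies `f_ix`,
#'   `f_jy` computed over the overlap individuals.
#' @export
relative_cooccurrence <- function(gm, i, j, x = "alt", y = "alt",
                                  pairing = c("carrier", "min")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (i == j) stop("need two distinct sites")
  x <- match.arg(x, c("ref", "alt")); y <- match.arg(y, c("ref", "alt"))
  di <- gm$dosage[, i]; dj <- gm$dosage[, j]
  ok <- !is.na(di) & !is.na(dj)
  n <- sum(ok)
  if (n == 0L) {
    return(list(R = NA_real_, n_overlap = 0L, f_ix = NA_real_, f_jy = NA_real_))
  }
  dx <- allele_dosage(di[ok], x)
  dy <- allele_dosage(dj[ok], y)
  R <- if (pairing == "carrier") {
    mean(dx > 0L & dy > 0L)
  } else {
    sum(pmin(dx, dy)) / (2 * n)
  }
  list(R = R, n_overlap = n, f_ix = sum(dx) / (2 * n), f_jy = sum(dy) / (2 * n))
}

#' Custom Correlation Coefficient of an allele pair
#'
#' `CCC = (9/2) * R * (1 - f_ix) * (1 - f_jy)` under the default
#' frequency-penalty reading: common alleles are down-weighted and a
#' monomorphic allele (frequency 1) gets CCC 0. The alternative reading
#' `"inverse_freq"` uses `(1 - 1/f)` factors instead.
#'
#' @param R Relative co-occurrence in `[0, 1]`.
#' @param f_ix,f_jy Allele frequencies in `(0, 1]`.
#' @param reading `"freq_penalty"` (default) or `"inverse_freq"`.
#' @return The CCC value (`NA` if a frequency is 0 or inputs are `NA`).
#' @export
ccc_value <- function(R, f_ix, f_jy, reading = c("freq_penalty", "inverse_freq")) {
  reading <- match.arg(reading)
  out <- rep(NA_real_, length(R))
  ok <- !is.na(R) & !is.na(f_ix) & !is.na(f_jy) & f_ix > 0 & f_jy > 0
  if (reading == "freq_penalty") {
    out[ok] <- 4.5 * R[ok] * (1 - f_ix[ok]) * (1 - f_jy[ok])
  } else {
    out[ok] <- 4.5 * R[ok] * (1 - 1 / f_ix[ok]) * (1 - 1 / f_jy[ok])
  }
  out
}

#' All-pairs CCC scan
#'
#' Evaluates the CCC for every unordered site pair and all four allele pairs
#' (ref/alt at each site), keeping edges with `ccc >= threshold` and an
#' overlap of at least `min_overlap` doubly non-missing individuals. Each
#' unordered (site, allele) pair is reported once.
#'
#' @param gm A (filtered) `genotype_matrix`.
#' @param threshold CCC retention threshold (default 0.7).
#' @param min_overlap Minimum doubly non-missing individuals (default 100).
#' @param pairing,reading See [relative_cooccurrence()] and [ccc_value()].
#' @return Data frame of edges: `site_i`, `allele_x`, `site_j`, `allele_y`,
#'   `chrom_i`, `pos_i`, `chrom_j`, `pos_j`, `R`, `f_ix`, `f_jy`,
#'   `n_overlap`, `ccc`.
#' @export
ccc_scan <- function(gm, threshold = 0.7, min_overlap = 100,
                     pairing = c("carrier", "min"),
                     reading = c("freq_penalty", "inverse_freq")) {
  pairing <- match.arg(pairing); reading <- match.arg(reading)
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- ncol(gm$dosage)
  rows <- vector("list", 0L)
  alleles <- c("ref", "alt")
  if (ns >= 2L) {
    for (i in seq_len(ns - 1L)) {
      for (j in seq.int(i + 1L, ns)) {
        for (x in alleles) for (y in alleles) {
          rc <- relative_cooccurrence(gm, i, j, x, y, pairing = pairing)
          if (rc$n_overlap < min_overlap) next
          cc <- ccc_value(rc$R, rc$f_ix, rc$f_jy, reading = reading)
          if (!is.na(cc) && cc >= threshold) {
            rows[[length(rows) + 1L]] <- data.frame(
              site_i = i, allele_x = x, site_j = j, allele_y = y,
              chrom_i = gm$sites$chrom[i], pos_i = gm$sites$pos[i],
              chrom_j = gm$sites$chrom[j], pos_j = gm$sites$pos[j],
              R = rc$R, f_ix = rc$f_ix, f_jy = rc$f_jy,
              n_overlap = rc$n_overlap, ccc = cc)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(site_i = integer(), allele_x = character(),
                      site_j = integer(), allele_y = character(),
                      chrom_i = character(), pos_i = numeric(),
                      chrom_j = character(), pos_j = numeric(),
                      R = numeric(), f_ix = numeric(), f_jy = numeric(),
                      n_overlap = integer(), ccc = numeric())
  } else {
    out <- do.call(rbind, rows)
  }
  attr(out, "pairing") <- pairing
  attr(out, "reading") <- reading
  out
}

#' Block-pair job schedule for an all-pairs computation
#'
#' Splits `n_items` sites into `n_blocks` near-equal contiguous blocks and
#' lists every within-block job plus every unordered cross-block pair:
#' `n_blocks + choose(n_blocks, 2)` jobs that together cover each site pair
#' exactly once (20 blocks give 210 jobs).
#'
#' @param n_items Number of sites.
#' @param n_blocks Number of blocks, `1 <= n_blocks <= n_items`.
#' @return Data frame `job_id`, `block_a`, `block_b` (`block_a == block_b`
#'   for within-block jobs), with the block membership as attribute
#'   `"blocks"` (a list of index vectors).
#' @export
block_schedule <- function(n_items, n_blocks) {
  if (n_blocks < 1L || n_items < 1L || n_blocks > n_items) {
    stop("need 1 <= n_blocks <= n_items")
  }
  cuts <- floor(seq(0, n_items, length.out = n_blocks + 1))
  blocks <- lapply(seq_len(n_blocks), function(b) seq.int(cuts[b] + 1L, cuts[b + 1L]))
  pairs <- which(upper.tri(diag(n_blocks), diag = TRUE), arr.ind = TRUE)
  out <- data.frame(job_id = seq_len(nrow(pairs)),
                    block_a = pairs[, "row"], block_b = pairs[, "col"])
  attr(out, "blocks") <- blocks
  out
}

#' Gene-anchored co-evolution density profile
#'
#' From a CCC edge table, collects the distinct SNP positions outside an
#' anchor interval (e.g. a candidate CENH3 gene body) that are linked by at
#' least one retained edge to a SNP inside the anchor, and bins them on a
#' window grid. A distal SNP correlated with several anchor SNPs counts once.
#'
#' @param edges Edge data frame from [ccc_scan()].
#' @param anchor_chrom,anchor_start,anchor_end Anchor interval (0-based
#'   half-open bp).
#' @param grid A `window_grid` for the chromosome being profiled.
#' @return A `density_profile` of kind `"corr_snp"` over `grid` (zero, with a
#'   warning, if no edge touches the anchor).
#' @export
coevolution_profile <- function(edges, anchor_chrom, anchor_start, anchor_end,
                                grid) {
  stopifnot(inherits(grid, "window_grid"))
  in_anchor <- function(chrom, pos) {
    chrom == anchor_chrom & pos >= anchor_start & pos < anchor_end
  }
  ai <- in_anchor(edges$chrom_i, edges$pos_i)
  aj <- in_anchor(edges$chrom_j, edges$pos_j)
  partners <- rbind(
    data.frame(chrom = edges$chrom_j[ai & !aj], pos = edges$pos_j[ai & !aj]),
    data.frame(chrom = edges$chrom_i[aj & !ai], pos = edges$pos_i[aj & !ai])
  )
  partners <- unique(partners)
  partners <- partners[partners$chrom == grid$chrom, , drop = FALSE]
  if (!any(ai | aj)) warning("no edges touch the anchor interval")
  point_profile <- point_density(partners$pos, grid)
  new_density_profile(grid, "corr_snp", point_profile$values)
}
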