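#' Scenario for a chromosome with a planted centromere signature
#'
#' Parameterizes the expected per-window count signals: methylation is a
#' baseline plus a broad pericentromeric Gaussian peak minus a narrower
#' central dip (hypomethylated active centromere); the SNP signal carries a
#' coincident narrow centromeric valley (same sd as the methylation dip, with
#' an optional broad pericentromeric shoulder) and gene coverage a broad
#' valley. Realized counts are Poisson draws
#' around these expectations, and optional gap runs force windows to zero
#' (assembly gaps).
#'
#' Defaults emulate a mid-sized plant chromosome at 10 kb windows: 20 Mb
#' (2000 windows), centromere at window 800, pericentromere sd 150 windows
#' (1.5 Mb), central dip sd 25 windows, methylation read counts of order 100
#' per window with a 200-count pericentromeric peak and 120-count dip, SNP
#' counts of order 80 with a 60-count valley, and gene coverage around
#' 5000 bp/window collapsing to near zero across the centromere.
#'
#' @param n_windows Number of 10 kb windows (default 2000).
#' @param center Planted centromere centre, window units (default 800).
#' @param peri_sd,dip_sd Pericentromere and dip Gaussian sds in windows
#'   (defaults 150 and 25; `dip_sd < peri_sd` required).
#' @param meth_baseline,peri_amp,dip_amp Methylation baseline and amplitudes
#'   (defaults 100, 200, 120; `dip_amp < peri_amp` required).
#' @param snp_baseline,snp_valley SNP-density baseline and depth of the
#'   narrow centromeric valley, sd `dip_sd` (defaults 80, 60).
#' @param snp_shoulder Amplitude of an optional broad pericentromeric SNP
#'   elevation (sd `peri_sd`) around the narrow valley, reproducing the full
#'   tooth-X-ray shape in the SNP landscape (default 0: valley only).
#' @param gene_baseline,gene_valley Gene-coverage baseline and valley depth
#'   in bp/window (defaults 5000, 4500).
#' @param gap_runs List of `c(start_window, width)` runs forced to zero.
#' @param window_size Window size in bp (default 10000).
#' @param seed RNG seed used by [simulate_signals()].
#' @return A `centromere_scenario` list.
#' @export
centromere_scenario <- function(n_windows = 2000, center = 800,
                                peri_sd = 150, dip_sd = 25,
                                meth_baseline = 100, peri_amp = 200,
                                dip_amp = 120,
                                snp_baseline = 80, snp_valley = 60,
                                snp_shoulder = 0,
                                gene_baseline = 5000, gene_valley = 4500,
                                gap_runs = list(), window_size = 10000,
                                seed = 1) {
  if (!(dip_sd < peri_sd)) stop("need dip_sd < peri_sd")
  if (!(dip_amp < peri_amp)) stop("need dip_amp < peri_amp")
  if (!(center > 0 && center < n_windows)) stop("center must lie inside (0, n_windows)")
  for (g in gap_runs) {
    if (length(g) != 2L || g[1] < 1 || g[2] < 1 || g[1] + g[2] - 1 > n_windows) {
      stop("each gap run must be c(start_window, width) inside the chromosome")
    }
  }
  structure(list(n_windows = n_windows, center = center, peri_sd = peri_sd,
                 dip_sd = dip_sd, meth_baseline = meth_baseline,
                 peri_amp = peri_amp, dip_amp = dip_amp,
                 snp_baseline = snp_baseline, snp_valley = snp_valley,
                 snp_shoulder = snp_shoulder,
                 gene_baseline = gene_baseline, gene_valley = gene_valley,
                 gap_runs = gap_runs, window_size = window_size, seed = seed),
            class = "centromere_scenario")
}

unit_gauss <- function(w, mu, sd) exp(-((w - mu)^2) / (2 * sd^2))

#' Closed-form expected signals of a scenario
#'
#' The noise-free per-window expectations that [simulate_signals()] draws
#' Poisson counts around (before gap-run zeroing).
#'
#' @param scenario A `centromere_scenario`.
#' @return List of numeric vectors `methylation`, `snp`, `gene`.
#' @export
expected_signals <- function(scenario) {
  w <- seq_len(scenario$n_windows)
  gp <- unit_gauss(w, scenario$center, scenario$peri_sd)
  gc <- unit_gauss(w, scenario$center, scenario$dip_sd)
  list(
    methylation = pmax(0, scenario$meth_baseline + scenario$peri_amp * gp -
                         scenario$dip_amp * gc),
    snp = pmax(0, scenario$snp_baseline + scenario$snp_shoulder * gp -
                 scenario$snp_valley * gc),
    gene = pmax(0, pmin(scenario$window_size,
                        scenario$gene_baseline - scenario$gene_valley * gp))
  )
}

#' Simulate chromosome density profiles with a planted centromere
#'
#' Draws Poisson counts around the scenario's expected signals, zeroes the
#' gap-run windows, and returns methylation, SNP, gene and gap profiles on a
#' shared window grid. Calls with the same scenario (including seed) are
#' bit-identical.
#'
#' @param scenario A `centromere_scenario`.
#' @return List of `density_profile`s: `methylation`, `snp`, `gene`, `gap`.
#' @export
simulate_signals <- function(scenario) {
  stopifnot(inherits(scenario, "centromere_scenario"))
  set.seed(scenario$seed)
  ex <- expected_signals(scenario)
  nw <- scenario$n_windows
  grid <- make_windows(nw * scenario$window_size, scenario$window_size,
                       chrom = "chrSim")
  meth <- stats::rpois(nw, ex$methylation)
  snp <- stats::rpois(nw, ex$snp)
  gene <- pmin(scenario$window_size, stats::rpois(nw, ex$gene))
  gap <- numeric(nw)
  for (g in scenario$gap_runs) {
    idx <- seq.int(g[1], g[1] + g[2] - 1L)
    meth[idx] <- 0; snp[idx] <- 0; gene[idx] <- 0
    gap[idx] <- scenario$window_size
  }
  list(methylation = new_density_profile(grid, "reads", meth),
       snp = new_density_profile(grid, "snp", snp),
       gene = new_density_profile(grid, "coverage", gene),
       gap = new_density_profile(grid, "gap", gap))
}

#' Scenario for a genotype matrix with planted LD blocks
#'
#' Each block has one latent biallelic genotype drawn per individual under
#' Hardy-Weinberg at the block's minor allele frequency; every SNP in the
#' block copies the latent dosage with an independent per-allele flip
#' probability `eps`. Latents of different blocks are independent, so
#' within-block pairs are in strong LD and cross-block pairs are unlinked.
#' Cells are masked missing at `missing_rate`.
#'
#' Defaults: 200 individuals, three blocks of 8 SNPs at intermediate MAFs
#' 0.15 / 0.25 / 0.35, flip noise 0.02, 10% missing calls.
#'
#' @param n_individuals Number of diploid individuals (default 200).
#' @param blocks List of blocks, each `list(n_snps =, maf =, eps =)`.
#' @param anchor_block Index of the block used as co-evolution anchor
#'   (default 1).
#' @param missing_rate Per-cell missing probability in `[0, 0.5)`.
#' @param seed RNG seed used by [simulate_genotypes()].
#' @return An `ld_scenario` list.
#' @export
ld_scenario <- function(n_individuals = 200,
                        blocks = list(list(n_snps = 8, maf = 0.15, eps = 0.02),
                                      list(n_snps = 8, maf = 0.25, eps = 0.02),
                                      list(n_snps = 8, maf = 0.35, eps = 0.02)),
                        anchor_block = 1, missing_rate = 0.1, seed = 1) {
  for (b in blocks) {
    if (!all(c("n_snps", "maf", "eps") %in% names(b))) {
      stop("each block needs n_snps, maf, eps")
    }
    if (b$maf <= 0.01 || b$maf > 0.5) stop("block MAF must be in (0.01, 0.5]")
    if (b$eps < 0 || b$eps >= 0.5) stop("flip noise must be in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop("missing_rate must be in [0, 0.5)")
  }
  if (anchor_block < 1 || anchor_block > length(blocks)) {
    stop("anchor_block out of range")
  }
  structure(list(n_individuals = n_individuals, blocks = blocks,
                 anchor_block = anchor_block, missing_rate = missing_rate,
                 seed = seed),
            class = "ld_scenario")
}

#' Simulate a genotype matrix with planted LD blocks
#'
#' See [ld_scenario()] for the generative model. Sites are laid out with
#' block `b` occupying positions `(b-1)*1e6 + (0, 1000, 2000, ...)` on a
#' single synthetic chromosome, so block membership is recoverable from
#' coordinates. Same scenario (including seed) gives identical output.
#'
#' @param scenario An `ld_scenario`.
#' @return A `genotype_matrix`; site metadata carries a `block` column.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "ld_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_individuals
  cols <- list(); meta <- list()
  for (b in seq_along(scenario$blocks)) {
    blk <- scenario$blocks[[b]]
    latent <- stats::rbinom(n, 2L, blk$maf)
    for (k in seq_len(blk$n_snps)) {
      kept <- stats::rbinom(n, latent, 1 - blk$eps)
      gained <- stats::rbinom(n, 2L - latent, blk$eps)
      d <- kept + gained
      cols[[length(cols) + 1L]] <- as.integer(d)
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = "chrSim", pos = (b - 1) * 1e6 + (k - 1) * 1000,
        ref = "A", alt = "G", block = b)
    }
  }
  dosage <- do.call(cbind, cols)
  if (scenario$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dosage)) < scenario$missing_rate,
                   nrow = nrow(dosage))
    dosage[mask] <- NA_integer_
  }
  genotype_matrix(dosage, do.call(rbind, meta))
}
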