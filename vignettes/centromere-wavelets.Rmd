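---
title: "Locating centromeres with wavelet landscapes of chromosome density signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating centromeres with wavelet landscapes of chromosome density signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centwave)
```

## The problem

Plant centromeres are megabase-scale, repeat-rich, gene-poor regions that are
hard to place from sequence alone, especially in assemblies where the
centromeric repeats are collapsed or gapped. They do, however, leave a
characteristic multi-scale fingerprint in cheap, genome-wide summary signals:
the pericentromere is broadly hypermethylated and depleted of genes and
segregating SNPs, while the active centromere core inside it is *less*
methylated than its flanks and locally depleted of SNP calls. `centwave`
detects that fingerprint.

All signals are per-window counts on a fixed grid of non-overlapping 10 kb
windows (`make_windows()`): SNPs per window from a VCF (`point_density()`),
MeDIP-seq read counts per window from mapped-read intervals
(`read_count_density()`, any-overlap semantics as in `bedtools intersect -c`),
gene-body or BLAST-hit coverage in bp per window
(`positional_coverage_density()`, union of intervals so overlapping features
count once), and assembly-gap bases per window (`gap_density()`).

## The wavelet landscape

A peak or valley "of width w" is a scale-space notion, so the signals are
analysed with a continuous wavelet transform using the Ricker (Mexican-hat)
wavelet, the standard zero-mean kernel for peak detection:

$$W(s, \tau) = \frac{1}{\sqrt{s}} \sum_t f(t)\, \psi\!\left(\frac{t - \tau}{s}\right),
\qquad \psi(u) = \frac{2}{\sqrt{3}\,\pi^{1/4}} (1 - u^2)\, e^{-u^2/2}.$$

`cwt()` evaluates this for every window position $\tau$ and a dyadic grid of
scales $s$ (default 2 to $n/4$ windows, 8 voices per octave), producing a
coefficient matrix — the *landscape*. Positive coefficients mark peaks of
width comparable to $s$, negative coefficients valleys; a constant signal is
annihilated exactly because $\psi$ has zero mean.

Numerical choices, each of which is a configuration knob:

* **Normalization.** The prefactor is $1/\sqrt{s}$ (L2) by default, with
  $1/s$ (L1) selectable (`norm = "l1"`). Within a scale the two differ by a
  positive constant, so every within-scale decision (argmax, argmin, zero
  crossings) is identical under both; only the cross-scale selection of the
  pericentromeric and centromeric scales can differ, which is why the choice
  is recorded in all output metadata and the caller is tested for stability
  across it.
* **Boundary.** The signal is reflection-padded by $4\,s_{\max}$ windows
  before transforming (`boundary = "zero"` gives zero padding). Reflection
  avoids spurious negative lobes at the telomeres that would mimic a
  centromeric valley. The wavelet is truncated at $|t| \le 8s$ where its tail
  is below $10^{-13}$ of the peak; positions at least $4s$ from both
  chromosome ends are therefore boundary-free to machine precision, while the
  outermost $4s$ windows at each end carry a small, documented boundary
  contribution.
* **Implementation.** Each scale's row is a single FFT-based circular
  convolution on a zero-extended buffer, with the signal's FFT computed once
  and reused across scales; the transform is validated in the test suite
  against an independent brute-force quadrature at random $(s, \tau)$ pairs
  to a relative $10^{-6}$ (observed agreement is ~$10^{-14}$).

## The centromere caller

Let $M$ be the methylation landscape and $S$ the SNP landscape of one
chromosome, both computed from signals standardized to mean 0, sd 1
(population sd). `locate_centromere()` proceeds exactly as:

1. **Pericentromeric scale** $p$: row and column of the maximum coefficient
   in the *upper third* of $M$'s scale rows (largest scales). The split index
   is $\lceil 2 n_s / 3 \rceil$ over the ascending scale grid; ties break to
   the smallest scale, then smallest window.
2. **Pericentromere borders** $b_1, b_2$: nearest windows on either side of
   the peak where the scale-$p$ vector $M_p$ reaches zero or changes sign
   (exact zeros count as crossings; crossings are reported at window
   resolution, no sub-window interpolation). A side with no crossing falls
   back to the chromosome end with a QC flag.
3. **Centromeric scale** $c$: row and column of the minimum coefficient in
   the *lower two-thirds* of $S$'s rows, columns restricted to $[b_1, b_2]$.
4. **Centre**: both scale vectors are standardized and the centre is
   $\arg\max_x (M^{*}_{p,x} - S^{*}_{c,x})$, searched within $[b_1, b_2]$ by
   default. The construction of the borders implies the signature lives
   between them; `search = "global"` lifts the restriction for comparison.
5. **Region borders**: nearest intersections of the two standardized curves
   on either side of the centre (first sign change of their difference),
   falling back to $b_1$/$b_2$ with a QC flag.
6. **Difference statistic** $D$: computed at the called centre from the
   *unscaled* vectors, $D = M_{p,\hat{x}} - S_{c,\hat{x}}$, so that $D$
   remains comparable across chromosomes whose landscapes were standardized
   separately.

A chromosome with no positive upper-third methylation peak has no signature;
the caller returns a structured no-call with QC flags rather than an error.
`p_scale > c_scale` is checked and flagged, not enforced: a legitimate call
has the broad methylation peak at a larger scale than the narrow SNP valley,
and a violation marks a suspicious chromosome without suppressing the record.

## Allele co-segregation: the CCC

For population-scale evidence (e.g. whether SNPs inside a candidate
centromeric-histone gene co-segregate with centromeric sequence elsewhere),
the package implements the allele-specific Custom Correlation Coefficient

$$\mathrm{CCC}_{ixjy} = \tfrac{9}{2}\, R_{ixjy}\, (1 - f_{ix})(1 - f_{jy}),$$

where $R_{ixjy}$ is the relative co-occurrence of allele $x$ at site $i$ with
allele $y$ at site $j$, and $f$ are the allele frequencies, computed over the
individuals non-missing at *both* sites so that missingness cannot inflate a
correlation.

Two genuinely open conventions are implemented, with explicit defaults:

* **Pairing rule for unphased diploids.** The default, `pairing =
  "carrier"`, takes $R$ as the fraction of overlap individuals carrying at
  least one copy of each allele. The alternative, `pairing = "min"`, sums
  $\min(d_x, d_y)$ over individuals divided by $2n$. The carrier rule is the
  default because under the min rule $R \le \min(f_{ix}, f_{jy})$, which
  bounds the CCC by $\tfrac92 f (1-f)^2 \le \tfrac23$ for every possible
  pair — the conventional operating threshold of 0.7 could then never retain
  an edge, whereas under the carrier rule perfectly co-segregating
  intermediate-frequency alleles score well above 0.7 (up to the CCC's
  supremum of 9/8).
* **Frequency factors.** The default reading $(1 - f)$ keeps the CCC
  non-negative and sends monomorphic alleles to zero; `reading =
  "inverse_freq"` gives the $(1 - 1/f)$ variant.

Both knobs are stamped into edge-table metadata. Filtering follows the
standard population-genetics screen: sites with MAF $\le$ 0.01 or call rate
$\le$ 0.5 are removed (strict boundaries), and edges need at least 100
doubly non-missing individuals (`min_overlap`; a per-allele-slot reading
would halve this — the stricter per-individual reading is used).
`block_schedule()` reproduces the classic all-pairs decomposition into
near-equal contiguous blocks (20 blocks → 20 within-block + 190 cross-block
= 210 jobs) for batch execution; `ccc_scan()` itself is a serial engine
suited to the package's desk scale. `coevolution_profile()` bins the distinct
partner SNPs of an anchor interval into windows, de-duplicated, anchor-side
SNPs excluded.

## The synthetic generator, and what passing means

`simulate_signals()` plants the signature with known truth: expected
methylation is a baseline plus a broad pericentromeric Gaussian (sd
$\sigma_p$, default 150 windows = 1.5 Mb) minus a narrower central dip (sd
$\sigma_c$, default 25 windows); the expected SNP signal carries a narrow
valley of sd $\sigma_c$ coincident with the methylation dip (with an optional
broad "shoulder" elevation reproducing the full SNP tooth-X-ray, off by
default); gene coverage has a broad valley. Realized counts are Poisson draws
around the expectations — appropriate because every signal is a window
count — and gap runs force windows to zero. Defaults (2000 windows, centre
800, methylation 100 baseline / 200 peak / 120 dip, SNP 80 baseline / 60
valley, gene 5000/4500 bp) give count magnitudes typical of a 20 Mb plant
chromosome with ~40× MeDIP coverage and GWAS-density SNP calls. The narrow
SNP valley is what makes the centromeric scale a *narrow* scale; it is the
feature the caller's precision relies on, and it is the package's reading of
the signature's SNP component.

`simulate_genotypes()` plants LD blocks: one latent Hardy–Weinberg genotype
per block per individual, copied to each block SNP with per-allele flip
probability $\varepsilon$, plus uniform missingness. Defaults are 200
individuals, three 8-SNP blocks at MAFs 0.15/0.25/0.35, $\varepsilon = 0.02$,
10% missing. The MAFs were fixed analytically before any testing: they are
intermediate frequencies at which perfectly co-segregating pairs score
expected CCC ≈ 0.86–1.1 (comfortably above 0.7) while the *largest*
cross-block expected CCC (the 0.25/0.35 pair, ≈ 0.55) sits more than two
standard errors below 0.7 at $n = 200$. Frequencies near 0.42 were avoided
because there the cross-block expectation approaches its theoretical
supremum of 2/3 and sampling noise would cross the threshold.

What the generator does *not* emulate: overdispersed coverage (a
negative-binomial option exists for robustness experiments but Poisson is the
tested default), population structure or relatedness in the genotypes,
recombination gradients, repeat-driven mapping artefacts, and multi-tissue
methylation variation. Passing the planted-recovery suite therefore
demonstrates that the *algorithm* recovers the signature it defines under
count noise — not that every real chromosome carries a recoverable
signature; on real data, chromosomes may legitimately end in no-calls or
flagged calls.

## Validation surface and problem sizes

The test suite runs entirely on generated data, at sizes chosen to keep the
whole suite around a minute: counting operators are checked against naive
per-position/per-pair loops on >100 randomized instances; the CWT against
direct quadrature; the caller on 20 default-scenario seeds (±2-window
recovery) and a 27-scenario × 10-seed sweep of centre position,
pericentromere width and dip width (median error ≤ 2 windows, ≥90% within
±5), plus stability across normalization, boundary rule and distal gap runs;
the CCC scan against an exhaustive brute-force evaluation on a 30-site ×
50-individual matrix under all four rule combinations; and LD recovery at
the 0.7 threshold. `scripts/acceptance.R` recomputes the same quantities
from scratch under a caller-supplied seed.

## Known limitations

* Window-resolution output: centres and borders are reported at 10 kb
  resolution by construction; no sub-window refinement is attempted.
* A gap run or mapping desert *inside* the pericentromere borders that is
  deeper and sharper than the true SNP valley could capture the centromeric
  minimum; the gap profile exists precisely so users can flag such calls.
* Holocentric chromosomes and multi-tissue consensus calling are out of
  scope; the caller takes one methylation profile at a time.
* The CCC engine is serial and meant for thousands of sites, not genome-wide
  tens of millions; the block schedule exists to organise larger runs
  externally.
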