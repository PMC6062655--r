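---
title: "Pooled-heterozygosity sweep scans with poolhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-heterozygosity sweep scans with poolhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolhet)
```

## The statistic and the model behind it

A hard selective sweep drives one haplotype toward fixation and strips
heterozygosity from the surrounding region. The pooled-heterozygosity scan
detects this as a local deficit of minor alleles. For each genomic window,
allele counts are pooled across all samples of a population and the window
statistic is

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

where $\Sigma n_{MAJ}$ and $\Sigma n_{MIN}$ are the window sums of per-site
major- and minor-allele counts. Writing $p = \Sigma n_{MAJ} / (\Sigma n_{MAJ}
+ \Sigma n_{MIN})$ gives the closed form $H_p = 2p(1-p)$, so $0 \le H_p \le
0.5$ with the maximum reached exactly when the two sums are equal and zero
exactly when no minor alleles remain — the signature of a completed sweep.
`hp_statistic()` implements this identity directly and the test suite asserts
it on random count pairs.

Window values are then standardized genome-wide:

$$Z(H_p) = \frac{H_p - \bar{H_p}}{\sigma(H_p)},$$

with $\bar{H_p}$ and $\sigma(H_p)$ the mean and sample standard deviation
(n − 1 denominator) over all analyzed windows, pooled across chromosomes but
always within a single population. Windows at $Z(H_p) \le -4$ (inclusive) are
called significant. The threshold is a conventional fixed cut-off for this
statistic, not an error-rate guarantee; no multiple-testing correction is
applied, which is why downstream results are described as *candidate* sweep
regions.

### Major and minor alleles

Major/minor status is decided per site *within* each population's pooled
counts, not across the cohort: the statistic asks whether this population has
lost variation. Ties (equal counts) assign the reference allele as major; the
choice cannot affect $H_p$, which is symmetric in the two counts. Missing
alleles are simply absent from both counts, so the denominator is the number
of observed alleles at the site. Sites monomorphic within a population are
retained by default — a site fixed in one population while variable in the
joint call set is exactly the signal the scan exists to find — but
`drop_monomorphic = TRUE` is available for sensitivity analysis, since
upstream variant callers differ in whether such sites reach the per-population
VCF at all.

## Windows, filtering, and order of operations

Chromosomes are tiled with 20-kb windows sliding by 10 kb (`scan_config()`
defaults), anchored at position 1. A terminal window truncated by the
chromosome end is kept only if it is longer than one step; this avoids
emitting a trailing stub that duplicates the previous window's second half,
while still covering short chromosomes with a single truncated window.

Windows with fewer than 50 SNPs are excluded before anything else: the
statistic is noisy when built from few sites, and the exclusion count is
reported per scan. The genome-wide mean and SD are computed *after* this
filter (`filter_before_z = TRUE`), so excluded windows influence neither the
centre nor the scale of the Z transform; the alternative order is available
as a configuration switch for sensitivity analysis because upstream
descriptions of this procedure do not pin it down. With ~10^5 windows the two
orders differ negligibly unless many windows are sparse.

The choice of sample SD (n − 1) over population SD is likewise immaterial at
genome scale but is fixed and documented so that runs are reproducible to the
last digit.

## Region calling and cross-population classification

Significant windows that overlap or abut on a chromosome merge into one
candidate region spanning their union; with full windows of width $w$ sliding
by $s$ a run of $k$ windows spans $w + (k-1)s$, so region sizes fall on a
10-kb lattice (20, 30, 40, ... kb). Merging is idempotent and conserves the
window count. A `max_merge_gap` option (default 0) can bridge isolated failed
windows inside an otherwise significant run — useful because a single window
dropped by the 50-SNP rule would otherwise split a long sweep in two.

Region SNP density is reported as the SNP count divided by the *nominal*
region length — the span rounded to the nearest 10 kb — rounded half-up to an
integer SNPs/kb. Real region spans come out a few bp short of the lattice
(a single-window region is 19,988 bp when the last SNP sits before the window
edge), and the nominal-length convention keeps densities comparable across
regions.

Sharing across populations is decided at the *window* level, not by region
overlap: a shared region is a maximal interval covered by significant windows
in every member population. `intersect_populations()` partitions the genome
into maximal segments with a constant covering set (via
`GenomicRanges::disjoin`) and classifies each segment by that exact set,
optionally distinguishing a wild/outgroup population (`all-domestic+wild`,
`all-domestic`, `domestic+wild`, `domestic-pair`, `unique`). Each region
appears in exactly one class, and the result is invariant to population
order. Venn-style shared/unique SNP counts (`shared_snp_counts()`) key sites
by (chromosome, position, ref, alt) and return the exact membership
partition, from which any union or intersection follows by
inclusion–exclusion.

## The synthetic-data generator

`sim_config()` describes a genome the scan can be validated on without any
external data. The defaults are the package's reference study conditions:

| parameter | default | why |
|---|---|---|
| chromosome lengths | 2 × 5 Mb | ~1,000 windows; enough for a stable Z transform, small enough to run in seconds |
| diploid samples / population | 10 | the scale of a village-chicken-style resequencing panel |
| SNP density | 14 /kb | per-population densities of such panels fall around 9–19 /kb |
| background MAF | Uniform(0.05, 0.5) | simple folded spectrum; guarantees well-populated windows at modest sample sizes |
| planted sweeps | 40, 100, 200 kb at MAF ≤ 0.02 | spans the size range the region caller must recover |
| missing rate | 0.02 | occasional missing genotypes exercise the called-alleles-only denominator |

Site frequencies are drawn i.i.d. — there is no linkage or coalescent
structure — because the scan consumes only per-site pooled counts; LD would
change the correlation between neighbouring windows but not the per-window
statistic this package computes. For the same reason the generator makes no
attempt at demographic realism, and ref/alt bases are uniform labels without
transition bias. Consequently, passing the recovery tests shows the
*machinery* is correct (counting, windowing, standardization, merging,
intersection), not that the statistic separates sweeps from, say, background
selection or bottlenecks in real genomes — that judgement belongs to the
study design, not the software.

Inside a planted sweep the minor-allele frequency is capped (uniform on
\[0, ceiling\]); the configuration requires the ceiling to sit below the
background MAF support, since otherwise the "sweep" would not depress
heterozygosity and planted truth would be meaningless. With the default
background, windowed $H_p$ centres near 0.37: the analytic per-site mean of
$2f(1-f)$ under Uniform(0.05, 0.5) is 0.365, and folding finite-sample
counts (20 alleles) pulls the pooled major fraction slightly above the
unfolded expectation. The calibration test asserts the genome mean lies in
\[0.25, 0.40\] over ≥ 1,000 windows, and that windows fully inside planted
sweeps fall more than four background SDs below the background mean.

Each population draws from its own RNG stream, derived from the master seed
as `seed + 11113 * population_index` (genotype draws use the index offset by
1000). Adding a population therefore never perturbs the sites or genotypes
of existing ones, and identical configurations reproduce byte-identical
VCFs.

## Numerical and degenerate-input choices

- An empty window has undefined $H_p$ (no alleles); it can never pass the
  min-SNP filter, so it never reaches the Z transform.
- A scan in which no window passes the filter, or in which all passing
  windows have identical $H_p$ (zero variance), stops with an error rather
  than emitting NaN Z scores.
- `genotype_samples()` rejects `missing_rate = 1` (no callable genotypes)
  and non-positive sample counts.
- Coordinates are 1-based inclusive internally (VCF convention); BED exports
  convert to 0-based half-open.
- Rounding of SNP densities is half-*up*, not banker's rounding: a density
  of 6.5 prints as 7.

## Problem sizes

The bundled tests and the reproduction script run the full pipeline —
simulate, write VCF, re-read, scan, call, intersect — on the 2 × 5 Mb
reference genome (≈ 140,000 SNPs per population, ~1,000 windows), which
completes in well under a minute. Scaling to a real ~1-Gb genome is linear in
sites and windows; the windowed sums use prefix sums over sorted sites, so
the scan itself is not the bottleneck (VCF parsing is).

## Known limitations

- The fixed $Z \le -4$ threshold has no attached false-discovery rate; on
  Gaussian-like background roughly 3 in 10^5 windows exceed it by chance,
  but real window distributions are heavy-tailed.
- Window-level intersection reports only intervals where significance
  coincides across populations; sweeps at slightly offset positions in two
  populations appear as two `unique` regions, not one shared region.
- The generator's i.i.d. sites make neighbouring windows independent,
  which understates the run lengths of false positives relative to real,
  LD-structured genomes.
- Gene annotation of candidate regions is a join against a user-supplied
  interval file; no database is bundled.
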