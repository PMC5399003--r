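---
title: "Windowed selection scans on genetic-map coordinates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed selection scans on genetic-map coordinates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Crop germplasm panels frequently split into diverged subgene pools — for
example a grain-type and a vegetable-type pool in an inbred legume
collection. Domestication or improvement of one pool leaves selective
sweeps: regions where that pool has lost diversity and the two pools have
drifted apart more than the genome-wide background. `sweepscan` detects
such regions from a diploid genotype matrix (high residual homozygosity,
some heterozygous and missing calls), a genetic map in centimorgans, and a
subpopulation assignment, and then asks whether the detected regions
coincide with a catalog of known trait loci.

All window arithmetic is on genetic-map (cM) coordinates, not base pairs:
for array-genotyped panels without a finished reference assembly the
linkage map is the coordinate system in which marker order is trustworthy.
An average physical scale can be attached afterwards with `cm_to_kb()`
(e.g. a 0.15 cM window on a 630 Mb / 837.11 cM genome is roughly 113 Kb).

## Per-site statistics

At a biallelic site with allele counts $n_i$ ($n = \sum_i n_i$; every
non-missing diploid call contributes two allele observations, a
heterozygote one of each), nucleotide diversity is

$$\pi = 1 - \sum_i n_i^2 / n^2,$$

the probability that two allele observations drawn with replacement
differ. Differentiation between subpopulations $j$ with allele totals
$n_j$ and within-subpopulation diversities $\pi_j$ is

$$F_{ST} = 1 - \frac{\sum_j n_j^2 \pi_j}{\pi \sum_j n_j^2},$$

an estimator whose squared-size weights keep a large subpopulation from
being swamped by a small one. Two deliberate choices:

* **No clamping.** The estimator can be negative when subpopulation
  diversity exceeds pooled diversity. Clamping at zero would bias window
  means upward and distort the bootstrap null, so raw values are kept.
* **Genomic-mean substitution.** When the pooled sample is monomorphic the
  denominator is zero and the site's $F_{ST}$ is undefined. Such sites
  arise when the scan contrast uses a subset of the samples that passed
  the MAF filter. Each undefined value is replaced by the arithmetic mean
  of all defined per-site values genome-wide (one pool per contrast, not
  per linkage group), and flagged. The substitution sentence applies to
  $F_{ST}$ only: windowed $\pi$ ratios with a zero denominator are instead
  marked undefined and excluded from outlier ranking, because inventing a
  ratio there has no defensible value.

The diversity ratio $\pi_1/\pi_2$ is formed per window from the two
smoothed window diversities (subpopulation 1 in the numerator); large
values indicate diversity loss in subpopulation 2.

## The window scan

Windows of `window_cm = 0.15` advance in `step_cm = 0.03` steps from the
first to beyond the last marker of each linkage group; spans are half-open
$[c - w/2,\, c + w/2)$ so that a site on a boundary belongs to exactly one
abutting window. The default kernel is uniform (the unweighted mean of
in-span per-site values); a truncated Gaussian ($\sigma = w/3$) is
available for closer agreement with kernel-smoothing traditions, but the
uniform mean is the default because averaging is the operation the
downstream bootstrap replicates reproduce exactly.

Significance uses bootstrap resampling: for each SNP count $k$ occurring
among windows, `n_boot` replicates are drawn, each the mean of $k$ per-site
values resampled with replacement from the genome-wide pool ($(\pi_1,
\pi_2)$ pairs for the ratio, with the ratio of means formed per replicate).
Stratifying by $k$ matches each window against a null of its own precision.
Replicate banks are drawn once per $k$ in ascending order under a single
seed, then shared by every window of that count — p-values are therefore
reproducible bit-for-bit and invariant to window order. The upper-tail
p-value uses the add-one estimator $p = (1 + \#\{\text{rep} \ge
\text{obs}\})/(1 + n_\text{boot})$, which can never return zero. The
default `n_boot` is $10^6$; tests, the bundled analysis scripts and the
acceptance script use $10^4$, which stabilises the 0.05 tail amply at desk
scale. Only the upper tail is tested for both statistics, because sweeps in
subpopulation 2 push both divergence and $\pi_1/\pi_2$ upward.

Windows with $p \le \alpha$ are merged (overlapping or abutting, per
statistic and linkage group) into regions; spans are clipped to the mapped
extent of the group. Because neighbouring windows overlap 5-fold, a run of
significant windows is wider than the distance between its centers, so the
summed region length is reported two ways: the span union (used as the
headline length) and the center-to-center extent. At $\alpha$-level calling
on a null genome the span union covers noticeably more of the map than
$\alpha$ — an accounting effect worth remembering when comparing scans.

## Coincidence with trait loci

Catalog loci carry a detection mode. A *qualitative* locus (a gene or QTL
tagged by a specific linked marker) must lie inside a region (point in
half-open span). A *GWAS* locus is widened to its LD block — 2 cM down- and
upstream by default — and the closed block coincides when it overlaps or
touches a region. Associated SNPs are chained into LD-block clusters by
single linkage with a strict `< 2` cM rule: a gap of exactly 2 cM starts a
new cluster. Enlarging the block half-width can only add coincidences
(monotonicity), which the tests verify.

## The synthetic panel generator

No genotype matrix is distributed with the package, so validation rests on
a generator that emulates the statistical structure the scan assumes:

* SNP positions uniform per linkage group; 11 groups of 76.1 cM and
  25 873 SNPs by default.
* Ancestral allele frequencies uniform on $(0.10, 0.90)$. Array SNPs are
  ascertained to be polymorphic in diverse material, which depletes extreme
  frequencies; the truncated range reflects that.
* Subpopulation frequencies follow the Balding–Nichols model: Beta with
  mean $p$ and variance $F p (1 - p)$. `background_F` accepts one value
  per subpopulation, default $F = (0.20, 0.70)$. A single shared $F$
  cannot produce unequal subpopulation diversities, whereas real panels
  routinely show them (a bottlenecked improvement pool is far less diverse
  than the landrace pool), so the asymmetric default is the realistic
  choice. With these defaults the realized panel shows mean $\pi \approx
  0.316$ and $0.130$ in the two pools, mean per-site $F_{ST} \approx
  0.256$ and ~2% heterozygosity — the regime of a strongly structured
  inbred germplasm collection.
* Inbred-line genotypes are homozygous draws at the subpopulation
  frequency, then contaminated with heterozygous calls (2%) and missing
  calls (5%): residual outcrossing and assay failure, not Hardy–Weinberg
  sampling.
* Planted sweeps raise $F$ to `sweep_F` for both pools inside an interval
  and push subpopulation-2 frequencies toward the nearer boundary by
  `diversity_loss`, depressing $\pi_2$ there.

What the generator does **not** emulate: linkage disequilibrium between
sites (sites are drawn independently given the map position), an admixed
sample class, non-uniform marker density, genotyping-batch artefacts.
Consequently LD decay on synthetic panels collapses at the first distance
bin, and passing tests say nothing about LD-sensitive behaviour on real
data; the LD functions are validated on constructed fixtures instead.

## Two demes and what "recovering F" means

With only two subpopulations the realized differentiation of this
estimator is well below the nominal Balding–Nichols $F$: the pooled
diversity in the denominator is itself depressed by drift, and for two
demes of similar size the per-site mean lands near $F/(2 - F)$ (about 0.11
at $F = 0.25$), not at $F$. Parameter recovery is therefore checked
against the *realized* differentiation computed from the latent truth
frequencies by the same formula — the quantity the estimator actually
estimates — and the genotype-based estimate tracks that oracle to within
±0.03 at 5 000 SNPs. Matching nominal $F$ would require many demes or a
different estimator, neither of which is in scope.

## The recovery validation design

`recovery_design()` fixes the scenario used to validate end-to-end sweep
recovery: 6 000 SNPs on two 40 cM groups (about 11 SNPs per window), a low
background $F = 0.05$, and four planted sweeps totalling 11 cM with
`sweep_F = 0.85` and `diversity_loss = 0.95`. The low background is what
makes recovery statistically identifiable: under the bootstrap's
exchangeable null, about $\alpha$ of background windows are always called
(the p-values are uniform by construction — a property the tests assert),
so discrimination requires the planted signal both to dominate the pool's
upper tail and to stand clear of the background per-site noise. Under the
paper-like panel background ($F_2 = 0.7$, genome-wide bottleneck) the
per-site $F_{ST}$ standard deviation (~0.22) swamps the increment a small
planted sweep adds, and no windowed method can separate them at this
window size — a genuine limitation of sweep scanning in strongly diverged
panels, not of the implementation. On the reference design the scan
recovers 84–89% of sweep windows with 3–5% of called F_ST region length
outside the planted spans (seeds 1–3; `analysis/05_sweep_recovery.R`).

## Numerical choices and edge cases

* Window tiling uses an epsilon guard so a group whose span is an exact
  multiple of the step does not gain a duplicate end window.
* Sites exactly on `end_cm` fall into the next window (half-open spans);
  co-segregating bin markers (tied cM) all land in the same windows.
* Bootstrap ratio replicates with a zero denominator evaluate to `Inf`
  and count toward the tail (conservative); `0/0` replicates are treated
  the same way.
* `filter_snps` applies all three criteria in one pass, so it is
  idempotent and order-independent; an all-missing SNP fails both the
  heterozygosity and MAF criteria by convention (`NaN` rates).
* Pairwise distances score any pair involving a heterozygote 0.5 — also
  het–het pairs, where allele identity is ambiguous for unphased inbreds.
* Sample pairs with no jointly observed SNP get `NA` distance and are
  counted in an attribute rather than silently dropped.

## Problem sizes

The test suite and acceptance script run the full calibrated panel
(25 873 SNPs × 178 lines) for panel-level statistics, the 6 000-SNP
recovery design for end-to-end validation, $10^4$ bootstrap replicates,
and 500-window calibration experiments; the whole suite completes in well
under a minute of compute. These sizes were chosen so that Monte-Carlo
error is comfortably inside every asserted tolerance.
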