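# sweepscan

Selection scans for structured inbred germplasm panels, on genetic-map
coordinates.

A diversity panel that splits into two diverged subgene pools — say a
grain-type and a vegetable-type pool of an inbred crop — carries the
footprints of domestication as selective sweeps: regions where one pool has
lost diversity and the pools have drifted apart more than the genome-wide
background. `sweepscan` finds those regions from three inputs: a genotype
matrix of biallelic SNP calls (AA/AB/BB/missing, TSV or VCF), a linkage map
(SNP → linkage group + cM), and a subpopulation assignment. It then tests
whether the detected regions coincide with a catalog of trait-associated
loci.

The statistics at the core, computed at every mapped SNP:

- nucleotide diversity π = 1 − Σᵢ nᵢ²/n², from allele counts nᵢ
  (two observations per non-missing diploid call);
- a differentiation index that accounts for unbalanced subpopulation
  sizes, F_ST = 1 − (Σⱼ nⱼ² πⱼ) / (π · Σⱼ nⱼ²), left unclamped, with
  undefined (pooled-monomorphic) sites replaced by the genomic mean;
- the windowed diversity ratio π₁/π₂, large when subpopulation 2 has lost
  diversity.

Per-site values are averaged in 0.15 cM sliding windows advanced by
0.03 cM, and each window is assigned an upper-tail p-value from bootstrap
resampling of the genome-wide per-site pool (replicates stratified by the
window's SNP count and banked for reuse; one million replicates by default).
Windows with P ≤ 0.05 merge into candidate sweep regions. Trait loci
coincide with a region either by lying inside it (qualitative loci) or by
overlap of their ±2 cM LD block (GWAS loci); associated SNPs chain into
LD-block clusters at a strict < 2 cM rule.

Because panels of this kind rarely come with distributable genotypes, the
package includes a calibrated Balding–Nichols generator
(`simulate_panel()`) producing two-subpopulation inbred panels with planted
sweeps and full ground truth, used by the test suite and the analysis
scripts.

## Worked example

Simulate the reference validation panel (6 000 SNPs on two 40 cM linkage
groups, low background divergence, four planted sweeps totalling 11 cM),
scan it, and score the result against the planted truth:

```r
library(sweepscan)

panel <- simulate_panel(recovery_design(seed = 1))
scan <- run_scan(panel$genotypes, panel$map, panel$assignment,
                 scan_config(n_boot = 1e4), seed = 2)
scan
#> sweep_scan: 6000 SNPs, 178 samples, 2664 windows (0.15 cM / 0.03 cM)
#>   contrast pop1 vs pop2 | mean F_ST 0.075 | mean pi 0.332 / 0.329
#>   fst: 8 region(s), 11.25 cM
#>   pi_ratio: 27 region(s), 14.47 cM

subset(scan$regions, statistic == "fst" & length_cm > 1)
#>     lg  start_cm    end_cm statistic length_cm
#> 1 LG01  9.949257 12.709257       fst      2.76
#> 3 LG01 28.069257 30.529257       fst      2.46
#> 4 LG02  5.949533  7.299533       fst      1.35
#> 7 LG02 21.909533 23.409533       fst      1.50
#> 8 LG02 23.409533 25.089533       fst      1.68

perf <- evaluate_recovery(scan, panel$truth)
round(c(recall = perf$recall_fst, false = perf$false_length_fraction_fst), 3)
#> recall  false
#>  0.885  0.034
```

The four largest called regions sit on the planted sweeps
(LG1 10–13, LG1 28–30.5, LG2 6–8.5, LG2 22–25 cM): 88.5% of sweep windows
are recovered and 3.4% of the called F_ST length falls outside the planted
spans.

The numbered scripts under `analysis/` walk through the full workflow on
the calibrated 25 873-SNP panel — panel diversity (heterozygosity, IBS
distances, LD decay), per-site statistics, the genome scan, locus
coincidence, and sweep recovery — writing their tables under `results/`.

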