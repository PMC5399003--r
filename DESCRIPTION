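Package: sweepscan
Title: Selection Scans from Windowed F-ST and Nucleotide Diversity on Genetic-Map Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-SNP nucleotide diversity and an unbalanced-sample-size F-ST
    estimator for diploid genotype panels, kernel-smoothed sliding-window
    genome scans on genetic-map (centimorgan) coordinates, bootstrap
    resampling null distributions for window outlier significance, merging of
    significant windows into candidate selective-sweep regions, and
    coincidence testing of those regions against a catalog of trait-associated
    loci. Includes a two-subpopulation Balding-Nichols genotype simulator with
    planted sweeps for end-to-end validation, plus panel diversity utilities
    (heterozygosity, identity-by-state distances, linkage-disequilibrium decay).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
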