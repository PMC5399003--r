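test_that("chaining splits clusters at gaps of 2 cM or more", {
  snps <- data.frame(snp_id = c("a", "b", "c"), lg = "LG3",
                     cm = c(10.0, 11.5, 14.0))
  cl <- cluster_snps(snps, gap_cm = 2)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_snps, c(2L, 1L))
  expect_equal(cl$start_cm, c(10.0, 14.0))
  # a gap of exactly 2 cM starts a new cluster (strict < joins)
  snps2 <- data.frame(snp_id = c("a", "b"), lg = "LG1", cm = c(0, 2))
  expect_equal(nrow(cluster_snps(snps2, 2)), 2L)
  expect_equal(nrow(cluster_snps(snps2, 2.001)), 1L)
  # single SNP: one cluster
  expect_equal(nrow(cluster_snps(snps[1, ], 2)), 1L)
})

test_that("cluster count ignores input order; infinite gap gives one per group", {
  set.seed(21)
  snps <- data.frame(snp_id = sprintf("s%02d", 1:40),
                     lg = sample(c("LG1", "LG2", "LG3"), 40, TRUE),
                     cm = round(runif(40, 0, 60), 2))
  base <- cluster_snps(snps, 2)
  for (i in 1:5) {
    sh <- cluster_snps(snps[sample(40), ], 2)
    expect_equal(nrow(sh), nrow(base))
    expect_equal(sh$start_cm, base$start_cm)
  }
  huge <- cluster_snps(snps, Inf)
  expect_equal(nrow(huge), length(unique(snps$lg)))
  # unmapped SNPs are excluded with a warning
  snps$cm[3] <- NA
  expect_warning(cl <- cluster_snps(snps, 2), "unmapped")
  expect_equal(attr(cl, "n_unmapped"), 1L)
})

test_that("coincidence rules differ between GWAS and qualitative loci", {
  regions <- data.frame(lg = "LG1", start_cm = 31, end_cm = 33,
                        statistic = "fst", length_cm = 2)
  cat_ <- data.frame(locus_id = c("q1", "g1"), trait = "pod length",
                     lg = "LG1", cm = 30, mode = c("qualitative", "gwas"))
  out <- coincide_loci(cat_, regions, ld_halfwidth_cm = 2)
  expect_equal(out$coincident, c(FALSE, TRUE))   # block [28, 32] overlaps
  # empty region set: nothing coincides
  out0 <- coincide_loci(cat_, regions[0, ])
  expect_false(any(out0$coincident))
  # qualitative point-in-interval is half-open on the region
  cat2 <- data.frame(locus_id = c("lo", "hi"), trait = "t", lg = "LG1",
                     cm = c(31, 33), mode = "qualitative")
  expect_equal(coincide_loci(cat2, regions)$coincident, c(TRUE, FALSE))
})

test_that("widening the LD block never removes a coincidence", {
  set.seed(14)
  regions <- data.frame(lg = "LG1", start_cm = c(5, 40), end_cm = c(9, 44),
                        statistic = "fst", length_cm = 4)
  cat_ <- data.frame(locus_id = sprintf("g%02d", 1:30), trait = "t",
                     lg = "LG1", cm = runif(30, 0, 60), mode = "gwas")
  prev <- rep(FALSE, 30)
  for (hw in c(0.5, 1, 2, 4, 8)) {
    cur <- coincide_loci(cat_, regions, ld_halfwidth_cm = hw)$coincident
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("report counts per scan are consistent and flag scan-specific regions", {
  regions_a <- data.frame(lg = c("LG1", "LG2"), start_cm = c(10, 5),
                          end_cm = c(12, 7), statistic = "fst",
                          length_cm = 2)
  regions_b <- data.frame(lg = "LG1", start_cm = 10.5, end_cm = 11.5,
                          statistic = "fst", length_cm = 1)
  cat_ <- data.frame(
    locus_id = c("pl1", "ot1", "far"),
    trait = c("pod length", "seed size", "pod length"),
    lg = c("LG1", "LG2", "LG1"), cm = c(11, 6, 50),
    mode = "qualitative")
  rep_ <- coincidence_report(cat_, list(dom = regions_a, imp = regions_b))
  rs <- rep_$region_summary
  expect_equal(rs$n_regions_focal_trait[rs$scan == "dom"], 1L)
  expect_equal(rs$n_regions_other_trait[rs$scan == "dom"], 1L)
  expect_equal(rs$n_loci_coincident[rs$scan == "dom"], 2L)
  # locus coincident in both scans appears in both per-locus blocks
  pl <- rep_$per_locus
  expect_true(all(pl$coincident[pl$locus_id == "pl1"]))
  expect_false(any(pl$coincident[pl$locus_id == "far"]))
  # LG2 region only exists in scan a
  ss <- rep_$scan_specific
  expect_equal(ss$lg[ss$scan == "dom"], "LG2")
  # identical region sets: nothing scan-specific
  rep2 <- coincidence_report(cat_, list(a = regions_a, b = regions_a))
  expect_equal(nrow(rep2$scan_specific), 0L)
  # per-trait coincidences sum to the total count
  expect_equal(sum(rs$n_loci_coincident[rs$scan == "dom"]),
               sum(pl$coincident[pl$scan == "dom"], na.rm = TRUE))
})

test_that("loci on unknown linkage groups are skipped with a warning", {
  regions <- data.frame(lg = "LG1", start_cm = 0, end_cm = 5,
                        statistic = "fst", length_cm = 5)
  cat_ <- data.frame(locus_id = c("ok", "odd"), trait = "t",
                     lg = c("LG1", "LG99"), cm = c(1, 1), mode = "qualitative")
  expect_warning(out <- coincide_loci(cat_, regions, known_lgs = "LG1"),
                 "unknown linkage group")
  expect_true(out$coincident[1])
  expect_true(is.na(out$coincident[2]))
})
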