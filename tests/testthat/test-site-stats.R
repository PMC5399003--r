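test_that("site diversity evaluates the count formula exactly", {
  expect_equal(site_pi(5, 5), 0.5)
  expect_equal(site_pi(10, 0), 0)
  expect_equal(site_pi(3, 1), 0.375)
  expect_true(is.na(site_pi(0, 0)))
  # invariant to allele-label permutation; zero iff monomorphic
  set.seed(2)
  for (i in 1:30) {
    cc <- sample(0:12, 2)
    if (sum(cc) == 0) next
    expect_equal(site_pi(cc[1], cc[2]), site_pi(cc[2], cc[1]))
    expect_equal(site_pi(cc[1], cc[2]) == 0, min(cc) == 0)
  }
})

test_that("F_ST hand cases: none, complete, and partial differentiation", {
  expect_equal(site_fst(c(2, 2), c(2, 2)), 0)
  expect_equal(site_fst(c(4, 0), c(0, 4)), 1)
  expect_equal(site_fst(c(3, 1), c(1, 3)), 0.25)
  # undefined when pooled monomorphic; error with a single subpopulation
  expect_true(is.na(site_fst(c(4, 4), c(0, 0))))
  expect_error(site_fst(matrix(2, 1, 1), matrix(2, 1, 1)), "2 subpopulations")
})

test_that("F_ST is 0 for proportional counts and 1 for fixed differences", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:10, 1); b <- sample(1:10, 1); s <- sample(1:4, 1)
    if (a == 0 && b == 0) next
    # second subpopulation is the first scaled by s
    expect_equal(site_fst(c(a, s * a), c(b, s * b)), 0, tolerance = 1e-12)
    expect_equal(site_fst(c(a + b, 0), c(0, a + b)), 1)
  }
})

test_that("vectorised pi and F_ST agree with the allele-looping oracle", {
  set.seed(1234)
  n_sites <- 200
  c1a <- sample(0:40, n_sites, TRUE); c1b <- sample(0:40, n_sites, TRUE)
  c2a <- sample(0:50, n_sites, TRUE); c2b <- sample(0:50, n_sites, TRUE)
  keep <- (c1a + c1b) > 0 & (c2a + c2b) > 0
  pi_pkg <- site_pi(c1a, c1b)
  fst_pkg <- site_fst(cbind(c1a, c2a)[keep, ], cbind(c1b, c2b)[keep, ])
  for (i in seq_len(n_sites)) {
    if ((c1a[i] + c1b[i]) > 0)
      expect_lt(abs(pi_pkg[i] - oracle_pi(c1a[i], c1b[i])), 1e-12)
  }
  oracle <- vapply(which(keep), function(i)
    oracle_fst(list(c(c1a[i], c1b[i]), c(c2a[i], c2b[i]))), numeric(1))
  expect_lt(max(abs(unname(fst_pkg[!is.na(oracle)]) - oracle[!is.na(oracle)])),
            1e-12)
  expect_identical(is.na(unname(fst_pkg)), is.na(oracle))
})

test_that("genomic-mean substitution fills only undefined sites", {
  sites <- data.frame(snp_id = c("a", "b", "c"), lg = "LG1", cm = 1:3,
                      pi_pooled = c(0.3, 0.2, 0), fst = c(0.2, 0.4, NA),
                      substituted = FALSE)
  out <- substitute_undefined_fst(sites)
  expect_equal(out$fst, c(0.2, 0.4, 0.3))
  expect_equal(out$substituted, c(FALSE, FALSE, TRUE))
  # no-op when nothing is undefined; multiset of defined values unchanged
  expect_identical(substitute_undefined_fst(out), out)
  expect_equal(sort(out$fst[!out$substituted]), c(0.2, 0.4))
  expect_equal(mean(out$fst[!out$substituted]), 0.3)
  all_na <- transform(sites, fst = NA_real_)
  expect_error(substitute_undefined_fst(all_na), "no defined")
})

test_that("site table wires counts, positions and contrast order correctly", {
  # pop1: 2 samples, pop2: 3 samples; snp m01 fixed difference, m02 shared
  g <- geno("00", "00", "20", "20", "20")
  map <- flat_map(g)
  asg <- two_pop_assignment(g, 2)
  sites <- site_stats(g, map, asg)
  expect_equal(sites$n_pop1, c(4, 4))
  expect_equal(sites$n_pop2, c(6, 6))
  expect_equal(sites$fst[1], 1)
  expect_true(is.na(sites$fst[2]))      # pooled monomorphic at m02
  expect_equal(sites$pi_pop1, c(0, 0))
  # excluded samples are dropped; unmapped SNPs reported and dropped
  asg$subpop[3] <- "excluded"
  sites2 <- site_stats(g, map, asg)
  expect_equal(sites2$n_pop2[1], 4)
  expect_message(site_stats(g, map[-1, ], asg), "not on the map")
  asg$subpop <- "pop1"
  expect_error(site_stats(g, map, asg), "two non-excluded")
})

test_that("genome-wide summary averages per-site records", {
  sites <- data.frame(snp_id = c("a", "b"), lg = "LG1", cm = 1:2,
                      n_pop1 = 10, n_pop2 = 10,
                      pi_pop1 = c(0.5, 0.1), pi_pop2 = c(0.2, 0.2),
                      pi_pooled = c(0.4, 0.25), fst = c(0.25, 0.25),
                      substituted = FALSE)
  s <- genomewide_summary(sites)
  expect_equal(s$mean_fst, 0.25)
  expect_equal(s$mean_pi_pop1, 0.3)
  expect_equal(s$n_sites, 2L)
  # single record: mean equals the record
  expect_equal(genomewide_summary(sites[1, ])$mean_fst, 0.25)
})
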