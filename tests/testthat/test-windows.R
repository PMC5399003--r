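test_that("window centers tile each linkage group from min to beyond max", {
  map <- data.frame(snp_id = c("a", "b", "c"), lg = "LG1", cm = c(0, 0.031, 0.06))
  w <- make_windows(map, scan_config())
  expect_equal(w$center_cm, c(0, 0.03, 0.06))
  expect_equal(w$start_cm, w$center_cm - 0.075)
  # a single-SNP group yields exactly one window centered on the SNP
  map1 <- data.frame(snp_id = "a", lg = "LG1", cm = 12.5)
  w1 <- make_windows(map1, scan_config())
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$center_cm, 12.5)
  # step = window gives a non-overlapping tiling
  cfg <- scan_config(window_cm = 1, step_cm = 1)
  map2 <- data.frame(snp_id = letters[1:3], lg = "LG1", cm = c(0, 1.2, 2.9))
  w2 <- make_windows(map2, cfg)
  expect_true(all(diff(w2$center_cm) == 1))
  expect_true(all(w2$start_cm[-1] == w2$end_cm[-nrow(w2)]))
})

test_that("uniform smoothing takes the unweighted mean of in-span sites", {
  sites <- data.frame(lg = "LG1", cm = c(0.10, 0.12, 0.20),
                      fst = c(0.1, 0.2, 0.6))
  win <- data.frame(lg = "LG1", center_cm = 0.15, start_cm = 0.075,
                    end_cm = 0.225)
  sm <- smooth_statistic(sites, win, "fst", scan_config())
  expect_equal(sm$fst, 0.3)
  expect_equal(sm$k, 3L)
  # one-site window returns that site's value; empty window is NA with k = 0
  win2 <- data.frame(lg = "LG1", center_cm = c(0.115, 0.9),
                     start_cm = c(0.11, 0.825), end_cm = c(0.125, 0.975))
  sm2 <- smooth_statistic(sites, win2, "fst", scan_config())
  expect_equal(sm2$fst, c(0.2, NA))
  expect_equal(sm2$k, c(1L, 0L))
  # the span is half-open: a site exactly at the end boundary is excluded
  win3 <- data.frame(lg = "LG1", center_cm = 0.125, start_cm = 0.05,
                     end_cm = 0.20)
  expect_equal(smooth_statistic(sites, win3, "fst", scan_config())$k, 2L)
})

test_that("a window covering a whole group returns the group mean", {
  set.seed(8)
  sites <- data.frame(lg = "LG1", cm = runif(50, 0, 2), fst = rnorm(50))
  win <- data.frame(lg = "LG1", center_cm = 1, start_cm = -1, end_cm = 3)
  expect_equal(smooth_statistic(sites, win, "fst", scan_config())$fst,
               mean(sites$fst))
  # gaussian kernel weights fall off with distance but keep the same support
  cfgg <- scan_config(kernel = "gaussian")
  smg <- smooth_statistic(sites, win, "fst", cfgg)
  expect_equal(smg$k, 50L)
  w <- exp(-((sites$cm - 1)^2) / (2 * (0.15 / 3)^2))
  expect_equal(smg$fst, sum(w * sites$fst) / sum(w))
})

test_that("window diversity ratio handles zero denominators", {
  w <- data.frame(pi_pop1 = c(0.3, 0.2, 0.1), pi_pop2 = c(0.1, 0.2, 0))
  out <- window_pi_ratio(w)
  expect_equal(out$pi_ratio, c(3, 1, NA))
})

test_that("bootstrap p-values use the add-one upper-tail estimator", {
  # observed above every replicate: p = 1/(n_boot + 1)
  sites <- data.frame(lg = "LG1", cm = seq(0, 9.9, 0.1),
                      fst = rep(c(0.1, 0.2), 50),
                      pi_pop1 = 0.3, pi_pop2 = 0.2)
  win <- data.frame(lg = "LG1", center_cm = 1, start_cm = 0.5, end_cm = 1.5,
                    k = 5L, fst = 0.9, pi_ratio = 1.5)
  cfg <- scan_config(n_boot = 999)
  out <- bootstrap_pvalues(win, sites, cfg, seed = 4)
  expect_equal(out$p_fst, 1 / 1000)
  expect_equal(out$p_ratio, 1 / 1000)
  # observed at the pool mean of a symmetric pool: p near 0.5
  win$fst <- 0.15
  out2 <- bootstrap_pvalues(win, sites, scan_config(n_boot = 10000), seed = 4)
  expect_lt(abs(out2$p_fst - 0.5), 0.03)
  # undefined observed values stay NA
  win$fst <- NA_real_
  win$pi_ratio <- NA_real_
  out3 <- bootstrap_pvalues(win, sites, cfg, seed = 4)
  expect_true(is.na(out3$p_fst) && is.na(out3$p_ratio))
})

test_that("bootstrap is reproducible and invariant to window order", {
  set.seed(99)
  sites <- data.frame(lg = "LG1", cm = runif(300, 0, 30),
                      fst = rbeta(300, 2, 5), pi_pop1 = runif(300, 0, 0.5),
                      pi_pop2 = runif(300, 0.01, 0.5))
  cfg <- scan_config(n_boot = 2000)
  win <- make_windows(data.frame(snp_id = 1:300, lg = "LG1", cm = sites$cm), cfg)
  win <- window_pi_ratio(smooth_statistic(sites, win,
                                          c("fst", "pi_pop1", "pi_pop2"), cfg))
  a <- bootstrap_pvalues(win, sites, cfg, seed = 7)
  b <- bootstrap_pvalues(win, sites, cfg, seed = 7)
  expect_identical(a, b)
  perm <- sample(nrow(win))
  c_ <- bootstrap_pvalues(win[perm, ], sites, cfg, seed = 7)
  expect_equal(c_[order(perm), ]$p_fst, a$p_fst)
})

test_that("p-values are approximately uniform under exchangeability", {
  set.seed(31)
  pool <- data.frame(lg = "LG1", cm = runif(2000, 0, 100),
                     fst = rbeta(2000, 2, 5))
  k <- 8L
  win <- data.frame(lg = "LG1", center_cm = seq_len(500), start_cm = 0,
                    end_cm = 0, k = k,
                    fst = colMeans(matrix(sample(pool$fst, 500 * k, TRUE), k)))
  out <- bootstrap_pvalues(win, cbind(pool, pi_pop1 = 0.1, pi_pop2 = 0.1),
                           scan_config(n_boot = 10000), seed = 13,
                           statistics = "fst")
  ks <- suppressWarnings(stats::ks.test(out$p_fst, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("significant windows merge into clipped, non-overlapping regions", {
  cfg <- scan_config(alpha = 0.05)
  map <- data.frame(snp_id = letters[1:4], lg = "LG1", cm = c(0, 0.05, 0.4, 1))
  win <- data.frame(lg = "LG1",
                    center_cm = c(0.03, 0.06, 0.60),
                    start_cm = c(-0.045, -0.015, 0.525),
                    end_cm = c(0.105, 0.135, 0.675),
                    k = 2L, fst = 0.5,
                    p_fst = c(0.01, 0.04, 0.5))
  out <- call_outlier_regions(win, cfg, map = map, statistics = "fst")
  expect_equal(nrow(out$regions), 1L)
  expect_equal(out$regions$start_cm, 0)       # clipped at the group minimum
  expect_equal(out$regions$end_cm, 0.135)
  expect_equal(out$regions$length_cm, 0.135)
  expect_equal(out$totals$total_length_cm, 0.135)
  expect_equal(out$totals$total_center_span_cm, 0.03)
  # a gap wider than a window keeps two regions apart
  win$p_fst <- c(0.01, 0.5, 0.01)
  out2 <- call_outlier_regions(win, cfg, map = map, statistics = "fst")
  expect_equal(nrow(out2$regions), 2L)
  expect_true(all(out2$regions$end_cm[-nrow(out2$regions)] <=
                    out2$regions$start_cm[-1]))
  # nothing significant: empty regions, zero totals
  win$p_fst <- 0.9
  out3 <- call_outlier_regions(win, cfg, map = map, statistics = "fst")
  expect_equal(nrow(out3$regions), 0L)
  expect_equal(out3$totals$total_length_cm, 0)
})

test_that("map-fraction and physical-distance conversions follow the ratios", {
  gs <- genome_spec(837.11, 630)
  expect_equal(genome_fraction(15.33, gs), 100 * 15.33 / 837.11)
  expect_equal(round(genome_fraction(15.33, gs), 1), 1.8)
  expect_equal(genome_fraction(0, gs), 0)
  expect_equal(cm_to_kb(0.15, gs), 0.15 * 630000 / 837.11)
  expect_equal(round(cm_to_kb(0.15, gs)), 113)
  expect_equal(round(cm_to_kb(0.03, gs), 1), 22.6)
  expect_equal(cm_to_kb(0, gs), 0)
})
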