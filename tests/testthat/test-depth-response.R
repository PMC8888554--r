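test_that("perfect monotone abundances get the exact classes", {
  depths <- seq(200, 1400, length.out = 10)
  mat <- rbind(up = depths / 2000, down = 1 - depths / 2000,
               flat = rep(0.3, 10))
  res <- classify_depth_trends(mat, depths)
  expect_equal(res$estimate[1], 1, tolerance = 1e-12)
  expect_equal(res$estimate[2], -1, tolerance = 1e-12)
  expect_identical(res$class, c("increasing", "decreasing", "none"))
  expect_true(is.na(res$estimate[3]))
  expect_true(all(res$p_fdr >= res$p, na.rm = TRUE))
  expect_error(classify_depth_trends(mat, depths[-1]), "depths")
})

test_that("correlation p matches a permutation oracle at small n", {
  # n = 5, r ~ 0.6: two-sided t-transform p should be > 0.05 ->
  # increasing-trend; an exhaustive permutation oracle agrees on the scale
  set.seed(42)
  x <- c(0.1, 0.35, 0.2, 0.5, 0.45)
  d <- c(300, 500, 700, 900, 1100)
  res <- classify_depth_trends(matrix(x, 1), d)
  expect_identical(res$class, "increasing-trend")
  expect_gt(res$p, 0.05)
  # oracle: all 120 permutations of the depths
  perms <- holodepth:::gtools_permutations(5)
  r_obs <- cor(x, d)
  r_all <- apply(perms, 1, function(idx) cor(x, d[idx]))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  expect_lt(abs(res$p - p_exact), 0.15)
  expect_gt(p_exact, 0.05)
})

test_that("Benjamini-Hochberg adjustment matches a brute-force step-up oracle", {
  set.seed(7)
  p <- runif(40)^2
  bh_brute <- function(p) {
    n <- length(p); o <- order(p); adj <- numeric(n)
    prev <- 1
    for (i in n:1) {
      val <- min(prev, p[o[i]] * n / i)
      adj[o[i]] <- val; prev <- val
    }
    adj
  }
  expect_equal(holodepth:::fdr_adjust(p), bh_brute(p), tolerance = 1e-12)
  # NA entries stay out of the family
  p2 <- c(p[1:5], NA, p[6:10])
  adj <- holodepth:::fdr_adjust(p2)
  expect_true(is.na(adj[6]))
  expect_equal(adj[-6], bh_brute(p2[-6]), tolerance = 1e-12)
})

test_that("water-mass t-test is calibrated under the null and powered for shifts", {
  depths <- c(rep(500, 7), rep(1200, 7))
  set.seed(11)
  reps <- 400
  pnull <- vapply(seq_len(reps), function(i) {
    water_mass_ttest(matrix(rnorm(14), 1), depths)$p
  }, numeric(1))
  expect_lt(abs(mean(pnull <= 0.05) - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps))
  # large shift at n = 7 + 7 is detected
  shifted <- matrix(c(rnorm(7), rnorm(7, 3)), 1)
  expect_lt(water_mass_ttest(shifted, depths)$p, 0.05)
  # constant variable flagged, excluded from the FDR family
  mixed <- rbind(rep(1, 14), c(rnorm(7), rnorm(7, 3)))
  res <- water_mass_ttest(mixed, depths)
  expect_true(is.na(res$p[1]))
  expect_equal(res$p_fdr[2], res$p[2])  # family of one
  expect_error(water_mass_ttest(matrix(rnorm(3), 1), c(500, 500, 1200)),
               "group")
})

test_that("common-ASV rule is a strict 0.25% threshold", {
  counts <- matrix(c(30, 25, 9945, 30, 25, 9945), 2, 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  res <- classify_common(asv_table(counts), threshold = 0.0025)
  expect_true("A" %in% res$common_ids)        # mean 0.30%
  expect_false("B" %in% res$common_ids)       # exactly 0.25%: excluded
  expect_equal(res$read_fraction,
               sum(counts[, c("A", "C")]) / sum(counts))
  # uniform community: everything common, read fraction 1
  u <- matrix(10, 2, 100, dimnames = list(c("S1", "S2"), sprintf("A%d", 1:100)))
  resu <- classify_common(asv_table(u))
  expect_equal(length(resu$common_ids), 100)
  expect_equal(resu$read_fraction, 1)
})

test_that("depth-response summary recovers planted responses on low-noise data", {
  nf <- make_noisefree_community(n_samples = 15, n_asvs = 40, n_sister_pairs = 0)
  res <- trend_of(nf$sim, nf$metadata)
  summ <- summarize_depth_response(res, nf$sim$table)
  truth <- nf$sim$truth$responsive_ids
  cls <- setNames(res$class, res$variable_id)[names(truth)]
  # every planted effect is recovered with the right direction; closure
  # can additionally drag unplanted taxa past the threshold, so the
  # summary counts bound the planted counts from above
  expect_true(all(cls[truth > 0] == "increasing"))
  expect_true(all(cls[truth < 0] == "decreasing"))
  expect_gte(summ$n_increasing, sum(truth > 0))
  expect_gte(summ$n_decreasing, sum(truth < 0))
  expect_gte(summ$fraction_responsive, length(truth) / 40)
  expect_gt(summ$mean_rel_abundance_responsive, 0)
  # zero responsive and all-responsive degenerate cases
  none <- res; none$class[] <- "none"
  s0 <- summarize_depth_response(none, nf$sim$table)
  expect_equal(c(s0$n_increasing, s0$n_decreasing, s0$fraction_responsive,
                 s0$mean_rel_abundance_responsive), c(0, 0, 0, 0))
  all_up <- res; all_up$class[] <- "increasing"
  expect_equal(summarize_depth_response(all_up, nf$sim$table)$mean_rel_abundance_responsive,
               1, tolerance = 1e-9)
})

test_that("no result ever pairs class 'increasing' with a negative coefficient", {
  for (s in 1:5) {
    md <- simulate_metadata(12, seed = 500 + s)
    sim <- simulate_asv_table(md, "HMA", n_asvs = 60, seed = 600 + s)
    res <- trend_of(sim, md)
    up <- res$class %in% c("increasing", "increasing-trend")
    dn <- res$class %in% c("decreasing", "decreasing-trend")
    expect_true(all(res$estimate[up] > 0))
    expect_true(all(res$estimate[dn] < 0))
    sig <- res$class %in% c("increasing", "decreasing")
    expect_true(all(res$p[sig] <= 0.05))
  }
})
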