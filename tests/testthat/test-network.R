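test_that("prevalence filter applies the three-sample rule and reports sparsity", {
  counts <- matrix(0, 10, 4, dimnames = list(sprintf("S%d", 1:10),
                                             c("A", "B", "C", "D")))
  counts[1:2, "A"] <- 5          # present in 2 samples -> removed
  counts[1:3, "B"] <- 5
  counts[, "C"] <- 2
  counts[1:6, "D"] <- 1
  res <- prevalence_filter(asv_table(counts), min_samples = 3)
  expect_setequal(colnames(res$table$counts), c("B", "C", "D"))
  expect_equal(unname(res$n_eff[c("B", "C", "D")]), c(3, 10, 6))
  expect_equal(res$sparsity, mean(res$table$counts == 0))
  expect_equal(res$sparsity, (7 + 0 + 4) / 30)
  expect_error(prevalence_filter(asv_table(counts), min_samples = 11),
               "threshold")
})

test_that("correlation associations: duplicates at the floor, ranks invariant", {
  set.seed(2)
  base <- matrix(rpois(80, 20), 20, 4,
                 dimnames = list(sprintf("S%d", 1:20), c("A", "B", "C", "D")))
  base[, "B"] <- base[, "A"]          # duplicated ASV
  tab <- asv_table(base)
  res <- correlation_assoc(tab, "pearson", n_perm = 49, seed = 1)
  expect_equal(res$stat["A", "B"], 1, tolerance = 1e-12)
  expect_equal(min(res$p, na.rm = TRUE), res$p["A", "B"])
  # Spearman invariant under a monotone transform of one variable, with
  # sample totals held fixed so closure does not reshuffle ranks
  tot <- 10000
  raw <- base[, c("C", "D")]
  filler <- tot - rowSums(raw)
  t1 <- asv_table(cbind(raw, filler = filler))
  raw2 <- raw; raw2[, "C"] <- round(raw2[, "C"]^1.5)
  t2 <- asv_table(cbind(raw2, filler = tot - rowSums(raw2)))
  r1 <- correlation_assoc(t1, "spearman", n_perm = 9, seed = 1)
  r2 <- correlation_assoc(t2, "spearman", n_perm = 9, seed = 1)
  expect_equal(r1$stat["C", "D"], r2$stat["C", "D"], tolerance = 1e-12)
})

test_that("pooled permutation p-values are roughly uniform under independence", {
  sim <- simulate_basis_associations(40, 30, n_pairs = 0, seed = 4)
  res <- correlation_assoc(sim$table, "spearman", n_perm = 99, seed = 5)
  p <- res$p[upper.tri(res$p)]
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
  expect_true(all(p > 0))
})

test_that("SparCC recovers planted basis correlations and is null-quiet", {
  sim <- simulate_basis_associations(200, 50, n_pairs = 1,
                                     basis_correlation = 0.8, seed = 11)
  tp <- sim$truth$planted_associations
  res <- sparcc_assoc(sim$table, n_bootstrap = 50, seed = 3)
  expect_lt(abs(res$stat[tp$asv_a, tp$asv_b] - 0.8), 0.15)
  expect_lt(res$p[tp$asv_a, tp$asv_b], 0.05)
  null <- simulate_basis_associations(200, 50, n_pairs = 0, seed = 12)
  r0 <- holodepth:::sparcc_rho(null$table$counts)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.1)
  # invariant to sample order
  idx <- sample(200)
  r1 <- holodepth:::sparcc_rho(sim$table$counts[idx, ])
  r2 <- holodepth:::sparcc_rho(sim$table$counts)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(sparcc_assoc(asv_table(matrix(1:9, 3, 3,
    dimnames = list(letters[1:3], LETTERS[1:3])))), "4 ASVs")
})

test_that("local similarity equals its definition and a brute-force oracle", {
  # y = x: the maximal run is the full series; score = mean of squared scores
  n <- 20
  z <- qnorm((seq_len(n) - 0.5) / n)
  counts <- matrix(rpois(n * 6, 50), n, 6,
                   dimnames = list(sprintf("S%d", 1:n), sprintf("A%d", 1:6)))
  counts[, 2] <- counts[, 1]
  tab <- asv_table(counts)
  res <- local_similarity_assoc(tab, order_by = seq_len(n), n_perm = 9, seed = 1)
  expect_equal(res$stat[1, 2], mean(z^2), tolerance = 1e-9)
  # monotone pair at zero delay reduces to the normalized inner product
  zz <- holodepth:::normal_scores(relative_abundance(tab)$counts)
  expect_equal(res$stat[1, 2], sum(zz[, 1] * zz[, 2]) / n, tolerance = 1e-9)
  # brute-force enumeration of all contiguous runs at n = 6
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6)
  dp <- holodepth:::cpp_lsa_matrix(cbind(x, y), 0L)$score[1, 2]
  runs <- c()
  for (i in 1:6) for (j in i:6) runs <- c(runs, sum(x[i:j] * y[i:j]))
  expect_equal(abs(dp), max(abs(runs)) / 6, tolerance = 1e-12)
  expect_equal(sign(dp), sign(runs[which.max(abs(runs))]))
  expect_error(local_similarity_assoc(tab, order_by = c(1, NA, 3:20)),
               "ordering")
})

test_that("MIC is 1 for exact functional relations, symmetric, and null-calibrated", {
  n <- 30
  counts <- matrix(rpois(n * 5, 40) + 1, n, 5,
                   dimnames = list(sprintf("S%d", 1:n), sprintf("A%d", 1:5)))
  counts[, 2] <- counts[, 1] * 2           # y = 2x exactly
  tab <- asv_table(counts)
  res <- mic_assoc(tab, n_perm = 19, seed = 2)
  expect_equal(res$stat[1, 2], 1, tolerance = 1e-9)
  expect_identical(res$stat, t(res$stat))
  expect_lt(res$p[1, 2], 0.05)
  # independent pairs: p not concentrated at small values
  sim <- simulate_basis_associations(30, 12, n_pairs = 0, seed = 3)
  r0 <- mic_assoc(sim$table, n_perm = 49, seed = 4)
  p <- r0$p[upper.tri(r0$p)]
  expect_gt(mean(p > 0.2), 0.5)
  expect_error(mic_assoc(asv_table(counts[1:3, ])), "4 samples")
})

test_that("consensus voting follows the 4-of-5 positive rule exactly", {
  ids <- c("X", "Y")
  mk <- function(p, sgn, adjustable = TRUE) {
    stat <- matrix(c(1, sgn, sgn, 1), 2, dimnames = list(ids, ids))
    pm <- matrix(c(NA, p, p, NA), 2, dimnames = list(ids, ids))
    holodepth:::new_assoc_result("m", stat, pm, sign(stat), list(),
                                 adjustable = adjustable)
  }
  five <- function(ps, sgns) {
    setNames(lapply(seq_along(ps), function(i) mk(ps[i], sgns[i])),
             c("pearson", "spearman", "sparcc", "local_similarity", "mic"))
  }
  # p = {0.01, 0.02, 0.03, 0.04, 0.9}, all positive -> edge with 4 votes
  net <- consensus_network(five(c(0.01, 0.02, 0.03, 0.04, 0.9), rep(1, 5)))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$votes, 4)
  # significant in only 3 methods -> no edge
  net3 <- consensus_network(five(c(0.01, 0.02, 0.03, 0.9, 0.9), rep(1, 5)))
  expect_equal(nrow(net3$edges), 0)
  # five significant but one negative voting method -> no edge
  netn <- consensus_network(five(c(0.01, 0.02, 0.03, 0.04, 0.05),
                                 c(1, 1, 1, 1, -1)))
  expect_equal(nrow(netn$edges), 0)
})

test_that("consensus is monotone in p_max and min_votes and order-invariant", {
  sim <- simulate_basis_associations(40, 15, n_pairs = 3, seed = 21)
  set.seed(99)
  depth <- runif(40, 244, 1476)
  results <- list(
    pearson = correlation_assoc(sim$table, "pearson", 49, 1),
    spearman = correlation_assoc(sim$table, "spearman", 49, 2),
    sparcc = sparcc_assoc(sim$table, n_bootstrap = 50, seed = 3),
    local_similarity = local_similarity_assoc(sim$table, depth, n_perm = 49, seed = 4),
    mic = mic_assoc(sim$table, n_perm = 49, seed = 5)
  )
  key <- function(net) paste(net$edges$asv_a, net$edges$asv_b)
  base <- consensus_network(results, p_max = 0.05, min_votes = 4)
  looser_p <- consensus_network(results, p_max = 0.2, min_votes = 4)
  looser_v <- consensus_network(results, p_max = 0.05, min_votes = 3)
  expect_true(all(key(base) %in% key(looser_p)))
  expect_true(all(key(base) %in% key(looser_v)))
  shuffled <- consensus_network(results[c(3, 1, 5, 2, 4)])
  expect_setequal(key(base), key(shuffled))
  # no self-edges, every edge meets the vote minimum
  expect_true(all(base$edges$asv_a != base$edges$asv_b))
  expect_true(all(base$edges$votes >= 4))
  g <- consensus_to_igraph(base)
  expect_equal(igraph::vcount(g), length(base$nodes))
})
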