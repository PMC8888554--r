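test_that("alpha diversity matches closed forms", {
  counts <- rbind(uniform = rep(5, 10), single = c(9, rep(0, 9)),
                  mixed = c(2, 1, 1, rep(0, 7)))
  colnames(counts) <- sprintf("A%d", 1:10)
  res <- alpha_diversity(asv_table(counts))
  expect_equal(res$richness, c(10, 1, 3))
  expect_equal(res$shannon[1], log(10), tolerance = 1e-9)
  expect_equal(res$inv_simpson[1], 10, tolerance = 1e-9)
  expect_equal(res$shannon[2], 0, tolerance = 1e-12)
  # (0.5, 0.25, 0.25): H = 1.5 * ln 2 = 1.0397...
  expect_equal(res$shannon[3], 1.5 * log(2), tolerance = 1e-9)
  empty <- rbind(counts, none = rep(0, 10))
  res2 <- suppressWarnings(alpha_diversity(asv_table(empty)))
  expect_true(is.na(res2$shannon[4]))
})

test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  m <- rbind(x = c(2, 1, 0), y = c(1, 1, 1), z = c(0, 0, 5))
  colnames(m) <- c("a", "b", "c")
  d <- as.matrix(bray_curtis(asv_table(m)))
  expect_equal(d["x", "y"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["x", "x"], 0)
  expect_equal(d["x", "z"], 1)            # disjoint supports
  set.seed(5)
  r <- matrix(rpois(60, 3), 6, 10,
              dimnames = list(sprintf("S%d", 1:6), sprintf("A%d", 1:10)))
  r[1, ] <- r[1, ] + 1   # keep non-empty
  dd <- as.matrix(bray_curtis(asv_table(r)))
  expect_true(all(dd >= 0 & dd <= 1))
  expect_equal(dd, t(dd))
  expect_equal(unname(diag(dd)), rep(0, 6))
})

test_that("PERMANOVA separates planted clusters and conserves sums of squares", {
  set.seed(3)
  g1 <- cbind(matrix(rpois(50, 50), 10), matrix(rpois(50, 2), 10))
  g2 <- cbind(matrix(rpois(50, 2), 10), matrix(rpois(50, 50), 10))
  m <- rbind(g1, g2)
  dimnames(m) <- list(sprintf("S%d", 1:20), sprintf("A%d", 1:10))
  d <- bray_curtis(asv_table(m))
  res <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)              # minimum attainable at 999 perms
  expect_gt(res$R2, 0.3)
  expect_equal(res$ss_among + res$ss_within, res$ss_total, tolerance = 1e-9)
  # cross-check F and R2 against vegan::adonis2
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = rep(c("a", "b"), each = 10)),
                       permutations = 99)
  expect_equal(res$F, ad$F[1], tolerance = 1e-8)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-8)
  expect_error(permanova(d, rep("a", 20)), "groups")
})

test_that("PERMANOVA permutation p is calibrated and matches exhaustive enumeration", {
  set.seed(8)
  reps <- 300
  hits <- vapply(seq_len(reps), function(i) {
    m <- matrix(rpois(48, 15), 8)
    dimnames(m) <- list(sprintf("S%d", 1:8), sprintf("A%d", 1:6))
    d <- bray_curtis(asv_table(m))
    permanova(d, rep(c("a", "b"), each = 4), n_perm = 59, seed = i)$p <= 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps) + 0.01)
  # exhaustive enumeration at n = 6 is the limit of the sampling estimate
  m <- matrix(rpois(36, 10), 6)
  dimnames(m) <- list(sprintf("S%d", 1:6), sprintf("A%d", 1:6))
  d <- bray_curtis(asv_table(m))
  grp <- rep(c("a", "b"), each = 3)
  pex <- permanova(d, grp, exact = TRUE)$p
  pbig <- permanova(d, grp, n_perm = 9999, seed = 2)$p
  expect_lt(abs(pex - pbig), 0.02)
})

test_that("metric ordination is exact on Euclidean geometries and sign-canonical", {
  # points on a line: 1-D scores reproduce the distances
  x <- c(0, 1, 3, 7, 12)
  d <- dist(x)
  attr(d, "Labels") <- sprintf("S%d", 1:5)
  sc <- ordinate(d, k = 1)
  expect_equal(as.vector(dist(sc[, 1])), as.vector(d), tolerance = 1e-9)
  expect_identical(sc, ordinate(d, k = 1))   # deterministic re-run
  expect_gt(sc[which(abs(sc[, 1]) > 1e-12)[1], 1], 0)  # canonical sign
  # unit square recovered up to rotation/reflection
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  scores <- ordinate(dist(sq), k = 2)
  m2 <- holodepth:::procrustes_m2(sq, scores)
  expect_lt(m2, 1e-12)
  expect_error(suppressWarnings(ordinate(dist(x), k = 4)), "eigenvalues")
})

test_that("environmental vector fitting recovers axes and matches vegan r2", {
  set.seed(12)
  scores <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("S%d", 1:20), NULL))
  env <- data.frame(axis = scores[, 1],
                    mix = 0.8 * scores[, 1] + 0.6 * scores[, 2] + rnorm(20, 0, 0.3),
                    noise = rnorm(20), flat = rep(1, 20))
  res <- envfit_vectors(scores, env, n_perm = 199, seed = 5)
  expect_equal(res$r2[1], 1, tolerance = 1e-9)
  expect_equal(abs(res$axis1[1]), 1, tolerance = 1e-6)
  expect_true(is.na(res$r2[4]))            # constant variable flagged
  expect_true(all(res$r2 <= 1, na.rm = TRUE))
  ef <- vegan::envfit(scores, env[, 1:3], permutations = 99)
  expect_equal(res$r2[1:3], unname(ef$vectors$r), tolerance = 1e-6)
  expect_lt(res$p[1], 0.01)
  expect_gt(res$p[3], 0.05)
})

test_that("VIF screening handles orthogonal, duplicated and constructed collinearity", {
  set.seed(21)
  n <- 50
  q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  ortho <- as.data.frame(q)
  names(ortho) <- c("v1", "v2", "v3")
  res <- vif_screen(ortho)
  expect_equal(unname(res$vif), rep(1, 3), tolerance = 1e-2)
  expect_setequal(res$retained, names(ortho))
  # duplicated variable: infinite VIF, one copy removed
  dup <- data.frame(a = rnorm(n), b = rnorm(n))
  dup$c <- dup$a
  res2 <- vif_screen(dup)
  expect_equal(length(res2$removed), 1)
  expect_true(res2$removed %in% c("a", "c"))
  # x2 = x1 + noise with R^2 = 0.95 -> VIF = 20, removed at threshold 10
  x1 <- rnorm(100000)
  x2 <- x1 + rnorm(100000, 0, sqrt(1 / 19))   # var ratio gives R2 ~ 0.95
  cc <- data.frame(x1 = x1, x2 = x2, z = rnorm(100000))
  v <- 1 / (1 - summary(lm(x2 ~ x1 + z, cc))$r.squared)
  expect_equal(v, 20, tolerance = 1)
  res3 <- vif_screen(cc, threshold = 10)
  expect_equal(length(res3$removed), 1)
  expect_true(all(res3$vif < 10))
})

test_that("transformation selection tracks the generating transformation", {
  md <- simulate_metadata(14, seed = 61)
  sim <- simulate_asv_table(md, "HMA", n_asvs = 80, frac_responsive = 0.5,
                            theta = 1e6, seed = 62)
  res <- select_transformation(sim$table, md$depth)
  expect_true(res$best %in% names(res$rank_correlation))
  expect_gt(max(res$rank_correlation), 0.5)
  # shuffled gradient: correlations collapse
  set.seed(9)
  res0 <- select_transformation(sim$table, sample(md$depth))
  expect_lt(max(abs(res0$rank_correlation)), 0.4)
  expect_identical(select_transformation(sim$table, md$depth,
                                         candidates = "sqrt")$best, "sqrt")
  expect_error(select_transformation(sim$table, rep(1, 14)), "constant")
})

test_that("UPGMA is exact on ultrametric input and recovers planted clusters", {
  # ultrametric distances: cophenetic distances reproduce the input
  dm <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  res <- upgma_cluster(dm, k = 2)
  expect_equal(as.matrix(stats::cophenetic(res$tree))[letters[1:4], letters[1:4]],
               dm, tolerance = 1e-12)
  expect_equal(unname(res$labels[c("a", "b")]), c(1, 1))
  expect_equal(unname(res$labels[c("c", "d")]), c(2, 2))
  # two tight simulated clusters
  set.seed(31)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 5, 0.1), 5))
  rownames(pts) <- sprintf("S%d", 1:10)
  cl <- upgma_cluster(dist(pts), k = 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_error(upgma_cluster(dist(1)), "samples")
})
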