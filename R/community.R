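#' Per-sample alpha diversity
#'
#' Observed richness, Shannon entropy (natural log) and inverse Simpson
#' index per sample. Empty (all-zero) samples get `NA` diversity.
#'
#' @param tab an [asv_table()].
#' @return data.frame with `sample_id`, `richness`, `shannon`,
#'   `inv_simpson`.
#' @export
alpha_diversity <- function(tab) {
  m <- tab$counts
  empty <- rowSums(m) == 0
  sh <- suppressWarnings(vegan::diversity(m, index = "shannon"))
  is <- suppressWarnings(vegan::diversity(m, index = "invsimpson"))
  sh[empty] <- NA_real_
  is[empty] <- NA_real_
  data.frame(
    sample_id = rownames(m),
    richness = rowSums(m > 0),
    shannon = sh,
    inv_simpson = is,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x - y| / sum (x + y); 0 for identical profiles, 1 for
#' disjoint supports. Pairs of all-zero samples are undefined and flagged.
#'
#' @param tab an [asv_table()] or abundance matrix (samples x taxa).
#' @return a `dist` object with metric label `"bray"`.
#' @export
bray_curtis <- function(tab) {
  m <- if (inherits(tab, "asv_table")) tab$counts else tab
  if (any(rowSums(m) == 0)) {
    warning("all-zero sample(s); their distances are undefined (NaN)")
  }
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray"
  d
}

# Seeded list of permutations of 1:n; exhaustive enumeration when
# exact = TRUE (for small n, identity permutation included in the count).
perm_indices <- function(n, n_perm, seed, exact = FALSE) {
  if (exact) {
    check_flag(factorial(n) <= 50000, "exhaustive enumeration infeasible for n = %d", n)
    all_p <- gtools_permutations(n)
    return(lapply(seq_len(nrow(all_p)), function(i) all_p[i, ]))
  }
  with_seed(seed, lapply(seq_len(n_perm), function(i) sample(n)))
}

# All permutations of 1:n (recursive; small n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

permanova_f <- function(d2, grouping) {
  n <- nrow(d2)
  groups <- split(seq_len(n), grouping)
  a <- length(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- sum(vapply(groups, function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ssa <- sst - ssw
  list(F = (ssa / (a - 1)) / (ssw / (n - a)),
       R2 = ssa / sst, ss_total = sst, ss_among = ssa, ss_within = ssw)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from among- vs within-group sums of squared distances, with a
#' seeded permutation p-value using the add-one estimator
#' p = (1 + #permuted F >= observed) / (1 + n_perm). `exact = TRUE`
#' enumerates all label permutations (small n) and reports
#' p = #(F >= observed) / n! (the observed arrangement counts itself).
#'
#' @param d a `dist` or square distance matrix.
#' @param grouping factor-like group labels, one per sample.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exact exhaustive enumeration instead of sampling.
#' @return list with `F`, `R2`, `p`, `n_perm`, and the sums of squares.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1L, exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  check_flag(length(grouping) == n, "grouping length must match samples")
  grouping <- as.factor(grouping)
  check_flag(nlevels(droplevels(grouping)) >= 2, "need >= 2 groups")
  check_flag(any(table(grouping) >= 2),
             "grouping with only singleton groups is untestable")
  d2 <- dm^2
  obs <- permanova_f(d2, grouping)
  perms <- perm_indices(n, n_perm, sub_seed(seed, 11L), exact)
  fperm <- vapply(perms, function(idx) permanova_f(d2, grouping[idx])$F,
                  numeric(1))
  p <- if (exact) mean(fperm >= obs$F - 1e-12)
       else perm_pvalue(sum(fperm >= obs$F - 1e-12), length(perms))
  c(obs, list(p = p, n_perm = length(perms), exact = exact))
}

#' Metric ordination (principal coordinates)
#'
#' Classical scaling of the double-centred squared-distance matrix. Axis
#' signs are canonicalized (first non-zero loading of each axis positive)
#' so repeated runs yield identical scores.
#'
#' @param d a `dist` or square distance matrix.
#' @param k number of dimensions (default 2).
#' @return samples x k score matrix; eigenvalues in attribute `"eig"`.
#' @export
ordinate <- function(d, k = 2) {
  dm <- as.matrix(d)
  full <- cmdscale(dm, k = min(nrow(dm) - 1, k), eig = TRUE)
  npos <- sum(full$eig > max(full$eig) * 1e-10)
  if (k > npos) {
    stopf("k = %d exceeds the %d positive eigenvalues (spectrum: %s)",
          k, npos, paste(signif(full$eig, 3), collapse = ", "))
  }
  scores <- full$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, j]) > 1e-12)
    if (length(nz) && scores[nz[1], j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PCo", seq_len(k))
  attr(scores, "eig") <- full$eig
  scores
}

#' Fit environmental vectors onto ordination scores
#'
#' For each environmental variable, the least-squares direction in the
#' 2-D score space that best predicts it: unit direction cosines, squared
#' multiple correlation r2, and a seeded permutation p-value (variable
#' permuted across samples, add-one estimator). Constant variables are
#' flagged undefined.
#'
#' @param scores samples x 2 score matrix from [ordinate()].
#' @param env data.frame/matrix of numeric environmental variables.
#' @param n_perm permutations per variable.
#' @param seed integer seed.
#' @return data.frame with `variable`, `axis1`, `axis2` (unit direction),
#'   `r2`, `p`.
#' @export
envfit_vectors <- function(scores, env, n_perm = 999, seed = 1L) {
  check_flag(ncol(scores) == 2, "envfit expects k = 2 scores")
  env <- as.data.frame(env)
  check_flag(nrow(env) == nrow(scores), "scores and env must share samples")
  sc <- scale(scores, scale = FALSE)
  r2_of <- function(v) {
    fit <- lm.fit(cbind(1, sc), v)
    1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  }
  out <- lapply(seq_along(env), function(j) {
    v <- env[[j]]
    if (!is.numeric(v) || sd(v) == 0) {
      return(data.frame(variable = names(env)[j], axis1 = NA_real_,
                        axis2 = NA_real_, r2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    b <- lm.fit(cbind(1, sc), v)$coefficients[2:3]
    dir <- b / sqrt(sum(b^2))
    r2 <- r2_of(v)
    perms <- perm_indices(length(v), n_perm, sub_seed(seed, 20L + j))
    hits <- sum(vapply(perms, function(idx) r2_of(v[idx]), numeric(1)) >= r2 - 1e-12)
    data.frame(variable = names(env)[j], axis1 = dir[1], axis2 = dir[2],
               r2 = r2, p = perm_pvalue(hits, length(perms)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variance-inflation-factor screening
#'
#' VIF_j = 1 / (1 - R2_j) from regressing variable j on the remaining
#' variables. Variables are removed iteratively (largest VIF first;
#' perfectly collinear variables, infinite VIF, go first) until all
#' remaining VIFs are below `threshold`.
#'
#' @param env data.frame/matrix of numeric variables.
#' @param threshold VIF cutoff (default 10).
#' @return list with `retained` (names), `vif` (final VIFs), `removed`
#'   (names in removal order).
#' @export
vif_screen <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  env <- env[vapply(env, is.numeric, logical(1))]
  check_flag(ncol(env) >= 2, "need >= 2 numeric variables")
  check_flag(nrow(env) > ncol(env), "need more samples than variables")
  vifs_of <- function(df) {
    vapply(seq_along(df), function(j) {
      y <- df[[j]]
      X <- as.matrix(df[-j])
      fit <- lm.fit(cbind(1, X), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- character(0)
  repeat {
    if (ncol(env) == 1) break
    v <- vifs_of(env)
    if (all(v < threshold)) break
    worst <- which.max(v)
    removed <- c(removed, names(env)[worst])
    env <- env[-worst]
  }
  final <- if (ncol(env) >= 2) setNames(vifs_of(env), names(env))
           else setNames(1, names(env))
  list(retained = names(env), vif = final, removed = removed)
}

.transformations <- list(
  identity = function(m) m,
  relative = function(m) m / ifelse(rowSums(m) == 0, 1, rowSums(m)),
  sqrt = function(m) sqrt(m),
  log1p = function(m) log1p(m),
  pa = function(m) (m > 0) * 1
)

#' Select the data transformation best separating a gradient
#'
#' For each candidate transformation, computes the Spearman rank
#' correlation between the Bray-Curtis dissimilarities of the transformed
#' table and the pairwise gradient separation (absolute depth difference),
#' and returns the argmax.
#'
#' @param tab an [asv_table()].
#' @param gradient numeric gradient (e.g. depth), one value per sample.
#' @param candidates subset of `c("identity", "relative", "sqrt", "log1p",
#'   "pa")`.
#' @return list with `best` (label) and `rank_correlation` (per candidate).
#' @export
select_transformation <- function(tab, gradient,
                                  candidates = names(.transformations)) {
  check_flag(length(candidates) >= 1, "candidates must be non-empty")
  check_flag(all(candidates %in% names(.transformations)),
             "unknown candidate transformation(s)")
  check_flag(sd(gradient) > 0, "gradient is constant; separation undefined")
  gdist <- as.vector(dist(gradient))
  rc <- vapply(candidates, function(cand) {
    m <- .transformations[[cand]](tab$counts)
    d <- as.vector(vegan::vegdist(m, method = "bray"))
    suppressWarnings(cor(d, gdist, method = "spearman"))
  }, numeric(1))
  list(best = candidates[which.max(rc)], rank_correlation = rc)
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' @param d a `dist` or square distance matrix.
#' @param k optional number of flat clusters to cut.
#' @param h optional cut height (alternative to `k`).
#' @return list with `tree` (an `hclust`) and `labels` (flat cluster
#'   vector, if `k` or `h` given).
#' @export
upgma_cluster <- function(d, k = NULL, h = NULL) {
  dm <- stats::as.dist(d)
  check_flag(attr(dm, "Size") >= 2, "need >= 2 samples to cluster")
  tree <- hclust(dm, method = "average")
  labels <- if (!is.null(k) || !is.null(h)) cutree(tree, k = k, h = h) else NULL
  list(tree = tree, labels = labels)
}
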