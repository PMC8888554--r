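#' Prevalence preflight for network inference
#'
#' Removes ASVs present (non-zero) in fewer than `min_samples` samples and
#' reports the sparsity (fraction of zero cells) of the retained table and
#' the effective sample number N_eff of each retained ASV (the number of
#' samples in which it is present).
#'
#' @param tab an [asv_table()] of counts.
#' @param min_samples presence threshold (default 3).
#' @return list with `table` (filtered [asv_table()]), `sparsity`, and
#'   `n_eff` (named vector).
#' @export
prevalence_filter <- function(tab, min_samples = 3) {
  present <- colSums(tab$counts > 0)
  keep <- present >= min_samples
  if (!any(keep)) {
    stopf("no ASV present in >= %d samples; lower the prevalence threshold",
          min_samples)
  }
  m <- tab$counts[, keep, drop = FALSE]
  list(table = asv_table(m, tab$taxonomy[keep]),
       sparsity = mean(m == 0),
       n_eff = present[keep])
}

new_assoc_result <- function(method, stat, p, sign, params,
                             adjustable = TRUE) {
  structure(list(method = method, stat = stat, p = p, sign = sign,
                 params = params, adjustable = adjustable),
            class = "assoc_result")
}

# Pooled-null permutation p-values: the null distribution is pooled over
# all pairs and all permutation rounds (valid under pair exchangeability
# of rank-based statistics; an approximation for Pearson), giving a p
# resolution of 1/(n_pairs * n_perm + 1) -- fine enough for FDR control
# across pairs at the consensus stage.
pooled_perm_p <- function(obs_abs, pool_sorted) {
  N <- length(pool_sorted)
  D <- nrow(obs_abs)
  hits <- N - findInterval(obs_abs - 1e-12, pool_sorted)
  p <- matrix(perm_pvalue(hits, N), D, D, dimnames = dimnames(obs_abs))
  diag(p) <- NA
  p
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result:%s> %d ASVs; %d pair(s) with p <= 0.05\n",
              x$method, nrow(x$stat),
              sum(x$p[upper.tri(x$p)] <= 0.05, na.rm = TRUE)))
  invisible(x)
}

# Column-wise independent permutation of a matrix (breaks all pairwise
# dependence while preserving marginals).
shuffle_cols <- function(m) {
  apply(m, 2, sample)
}

#' Pairwise correlation associations with permutation p-values
#'
#' Pearson or Spearman correlations between all ASV pairs on relative
#' abundances, with two-sided p-values from seeded permutations (each
#' ASV's values shuffled independently per round; add-one estimator).
#' Constant ASVs yield undefined (`NA`) entries.
#'
#' @param tab an [asv_table()].
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm permutation rounds.
#' @param seed integer seed.
#' @return an `assoc_result`.
#' @export
correlation_assoc <- function(tab, method = c("pearson", "spearman"),
                              n_perm = 99, seed = 1L) {
  method <- match.arg(method)
  rel <- relative_abundance(tab)$counts
  check_flag(nrow(rel) >= 4, "need >= 4 samples")
  obs <- suppressWarnings(cor(rel, method = method))
  pool <- with_seed(sub_seed(seed, 41L), {
    unlist(lapply(seq_len(n_perm), function(b) {
      rp <- suppressWarnings(cor(shuffle_cols(rel), method = method))
      abs(rp[upper.tri(rp)])
    }), use.names = FALSE)
  })
  p <- pooled_perm_p(abs(obs), sort(pool[!is.na(pool)]))
  p[is.na(obs)] <- NA
  new_assoc_result(method, obs, p, sign(obs),
                  list(n_perm = n_perm, seed = seed))
}

# SparCC basis correlations from a counts matrix (samples x ASVs):
# log-ratio variation matrix -> approximate basis variances -> basis
# correlations, with iterative exclusion of the most strongly correlated
# pair until none exceeds the exclusion threshold.
sparcc_rho <- function(counts, n_iterations = 20, exclusion_threshold = 0.1,
                       pseudocount = 1) {
  frac <- (counts + pseudocount) / rowSums(counts + pseudocount)
  L <- log(frac)
  C <- cov(L)
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C      # variation matrix t_ij
  D <- ncol(counts)
  M <- matrix(1, D, D); diag(M) <- 0   # pair inclusion indicator
  solve_rho <- function(M) {
    A <- diag(rowSums(M)) + M
    w <- tryCatch(solve(A, rowSums(M * Tm)), error = function(e) NULL)
    if (is.null(w)) return(NULL)
    w <- pmax(w, .Machine$double.eps)
    s <- sqrt(w)
    rho <- (outer(w, w, "+") - Tm) / (2 * outer(s, s))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho(M)
  for (it in seq_len(n_iterations)) {
    masked <- abs(rho) * M
    top <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    if (masked[top[1], top[2]] <= exclusion_threshold) break
    if (sum(M[top[1], ]) <= 2 || sum(M[top[2], ]) <= 2) break  # keep identifiable
    M[top[1], top[2]] <- M[top[2], top[1]] <- 0
    new_rho <- solve_rho(M)
    if (is.null(new_rho)) break
    rho <- new_rho
  }
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  rho
}

#' SparCC compositional associations with bootstrap p-values
#'
#' Basis correlations estimated from log-ratio variances under the sparse
#' -correlation assumption, with iterative exclusion of strongly
#' correlated pairs. A pseudocount of 1 is added before closure.
#' Two-sided pseudo p-values come from bootstrap resampling of samples:
#' an association whose bootstrap estimates do not concentrate on one
#' side of zero earns a large p (add-one corrected).
#'
#' @param tab an [asv_table()] of counts.
#' @param n_iterations maximum exclusion iterations (default 20).
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param n_bootstrap bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return an `assoc_result`.
#' @export
sparcc_assoc <- function(tab, n_iterations = 20, exclusion_threshold = 0.1,
                         n_bootstrap = 100, seed = 1L) {
  counts <- tab$counts
  check_flag(ncol(counts) >= 4,
             "SparCC needs >= 4 ASVs (the basis-variance system is underdetermined below that)")
  obs <- sparcc_rho(counts, n_iterations, exclusion_threshold)
  n <- nrow(counts)
  neg <- pos <- matrix(0, ncol(counts), ncol(counts))
  with_seed(sub_seed(seed, 42L), {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample(n, n, replace = TRUE)
      rb <- sparcc_rho(counts[idx, , drop = FALSE], n_iterations,
                       exclusion_threshold)
      neg <- neg + (rb <= 0)
      pos <- pos + (rb >= 0)
    }
  })
  p <- pmin(2 * (1 + pmin(neg, pos)) / (1 + n_bootstrap), 1)
  diag(p) <- NA
  dimnames(p) <- dimnames(obs)
  new_assoc_result("sparcc", obs, p, sign(obs),
                  list(n_iterations = n_iterations,
                       exclusion_threshold = exclusion_threshold,
                       n_bootstrap = n_bootstrap, seed = seed),
                  adjustable = FALSE)
}

normal_scores <- function(m) {
  apply(m, 2, function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x)))
}

#' Local similarity associations
#'
#' Local similarity analysis over samples ordered along a gradient
#' (depth by default; the study design has no time axis): per pair, the
#' maximal contiguous run of summed products of normal-score series,
#' normalized by the series length, carrying the run's sign. Alignment
#' delays up to `max_delay` are searched. p-values by seeded permutation
#' of the series (add-one).
#'
#' @param tab an [asv_table()].
#' @param order_by numeric vector ordering the samples (e.g. depth).
#' @param max_delay maximum alignment delay (default 0).
#' @param n_perm permutation rounds.
#' @param seed integer seed.
#' @return an `assoc_result` (stat = signed local-similarity score).
#' @export
local_similarity_assoc <- function(tab, order_by, max_delay = 0,
                                   n_perm = 99, seed = 1L) {
  check_flag(length(order_by) == nrow(tab$counts) && all(is.finite(order_by)),
             "ordering variable must be defined for every sample")
  rel <- relative_abundance(tab)$counts[order(order_by), , drop = FALSE]
  Z <- normal_scores(rel)
  obs <- cpp_lsa_matrix(Z, as.integer(max_delay))$score
  pool <- with_seed(sub_seed(seed, 43L), {
    unlist(lapply(seq_len(n_perm), function(b) {
      sp <- cpp_lsa_matrix(shuffle_cols(Z), as.integer(max_delay))$score
      abs(sp[upper.tri(sp)])
    }), use.names = FALSE)
  })
  dimnames(obs) <- list(colnames(rel), colnames(rel))
  p <- pooled_perm_p(abs(obs), sort(pool))
  new_assoc_result("local_similarity", obs, p, sign(obs),
                  list(max_delay = max_delay, n_perm = n_perm, seed = seed))
}

#' Maximal information coefficient associations
#'
#' MIC: the maximum, over grid partitions of the rank-rank plane with
#' `x * y <= B = n^grid_exponent` cells, of the normalized mutual
#' information (y axis equipartitioned, x axis optimized by dynamic
#' programming; both orientations searched, so the statistic is
#' symmetric). MIC is unsigned; the sign needed by the positive-edge
#' consensus vote is taken from the pair's Spearman correlation.
#' p-values by seeded permutation (add-one).
#'
#' @param tab an [asv_table()].
#' @param grid_exponent exponent of the grid-size bound (default 0.6).
#' @param n_perm permutation rounds.
#' @param seed integer seed.
#' @return an `assoc_result` (stat = MIC in `[0, 1]`).
#' @export
mic_assoc <- function(tab, grid_exponent = 0.6, n_perm = 99, seed = 1L) {
  rel <- relative_abundance(tab)$counts
  n <- nrow(rel)
  check_flag(n >= 4, "MIC needs >= 4 samples")
  if (n < 8) warning("MIC on fewer than 8 samples is weakly resolved")
  B <- max(4L, as.integer(floor(n^grid_exponent)))
  obs <- cpp_mic_matrix(rel, B, 30L)
  pool <- with_seed(sub_seed(seed, 44L), {
    unlist(lapply(seq_len(n_perm), function(b) {
      mp <- cpp_mic_matrix(shuffle_cols(rel), B, 30L)
      mp[upper.tri(mp)]
    }), use.names = FALSE)
  })
  dimnames(obs) <- list(colnames(rel), colnames(rel))
  p <- pooled_perm_p(obs, sort(pool))
  sgn <- sign(suppressWarnings(cor(rel, method = "spearman")))
  new_assoc_result("mic", obs, p, sgn,
                  list(grid_exponent = grid_exponent, B = B,
                       n_perm = n_perm, seed = seed))
}

#' Consensus positive co-occurrence network
#'
#' An edge joins two ASVs when at least `min_votes` of the association
#' estimators give p <= `p_max` AND every voting estimator's statistic is
#' positive. Isolated nodes are dropped. With `p_adjust = "BH"` (the
#' default, following the multiple-testing guidance for co-occurrence
#' networks), each permutation-based method's p matrix is
#' Benjamini-Hochberg adjusted across all pairs before the vote; SparCC's
#' bootstrap stability p is voted on raw (its resolution floor of
#' 2/(n_bootstrap+1) does not support FDR across thousands of pairs).
#'
#' @param results named list of `assoc_result`s over the same ASV set
#'   (typically pearson, spearman, sparcc, local_similarity, mic).
#' @param p_max per-method significance threshold (default 0.05).
#' @param min_votes minimum number of significant methods (default 4).
#' @param p_adjust `"BH"` (adjust permutation-based methods across pairs)
#'   or `"none"`.
#' @return list of class `consensus_network`: `edges` (data.frame
#'   `asv_a`, `asv_b`, `votes`, per-method `p_*`), `nodes`, and the input
#'   parameters.
#' @export
consensus_network <- function(results, p_max = 0.05, min_votes = 4,
                              p_adjust = c("BH", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (p_adjust == "BH") {
    results <- lapply(results, function(r) {
      if (!isTRUE(r$adjustable)) return(r)
      ut <- upper.tri(r$p)
      adj <- fdr_adjust(r$p[ut])
      q <- r$p
      q[ut] <- adj
      q[lower.tri(q)] <- t(q)[lower.tri(q)]
      r$p <- q
      r
    })
  }
  check_flag(length(results) >= 2, "need >= 2 association results")
  ids <- rownames(results[[1]]$stat)
  for (r in results) {
    check_flag(identical(rownames(r$stat), ids),
               "association results cover different ASV sets")
  }
  D <- length(ids)
  methods <- names(results)
  edges <- list()
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      pv <- vapply(results, function(r) r$p[i, j], numeric(1))
      sg <- vapply(results, function(r) r$sign[i, j], numeric(1))
      voting <- !is.na(pv) & pv <= p_max
      if (sum(voting) < min_votes) next
      if (any(sg[voting] <= 0)) next
      row <- data.frame(asv_a = ids[i], asv_b = ids[j],
                        votes = sum(voting), stringsAsFactors = FALSE)
      for (m in methods) row[[paste0("p_", m)]] <- pv[m]
      edges[[length(edges) + 1]] <- row
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else {
    out <- data.frame(asv_a = character(0), asv_b = character(0),
                      votes = integer(0), stringsAsFactors = FALSE)
    for (m in methods) out[[paste0("p_", m)]] <- numeric(0)
    out
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$asv_a, edges$asv_b))),
                 p_max = p_max, min_votes = min_votes, methods = methods),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d nodes, %d positive edges (>= %d/%d votes at p <= %g)\n",
              length(x$nodes), nrow(x$edges), x$min_votes, length(x$methods),
              x$p_max))
  invisible(x)
}

#' Convert a consensus network to an igraph object
#' @param net a `consensus_network`.
#' @return an `igraph` undirected graph.
#' @export
consensus_to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
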