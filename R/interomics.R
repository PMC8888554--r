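#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a permutation
#' p-value from seeded joint row/column permutations of the second matrix
#' (add-one estimator). Matrices are aligned by sample id when both carry
#' labels. `exact = TRUE` enumerates all permutations (small n) and counts
#' the observed arrangement itself.
#'
#' @param d1,d2 `dist` objects or square matrices over the same samples.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param exact exhaustive enumeration.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L, exact = FALSE) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    missing <- c(setdiff(rownames(m1), rownames(m2)),
                 setdiff(rownames(m2), rownames(m1)))
    check_flag(length(missing) == 0,
               "sample sets differ after alignment: %s",
               paste(unique(missing), collapse = ", "))
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  check_flag(all(dim(m1) == dim(m2)), "distance matrices differ in size")
  n <- nrow(m1)
  lower <- lower.tri(m1)
  r_of <- function(mm) cor(m1[lower], mm[lower])
  r_obs <- r_of(m2)
  perms <- perm_indices(n, n_perm, sub_seed(seed, 51L), exact)
  rp <- vapply(perms, function(idx) r_of(m2[idx, idx]), numeric(1))
  p <- if (exact) mean(rp >= r_obs - 1e-12)
       else perm_pvalue(sum(rp >= r_obs - 1e-12), length(perms))
  list(r = r_obs, p = p, n_perm = length(perms))
}

# Procrustes m^2: normalized residual after optimal translation,
# rotation (optionally reflection) and scaling of Y onto X.
procrustes_m2 <- function(X, Y, reflections = TRUE) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  d <- sv$d
  if (!reflections) {
    # constrain to proper rotations: flip the smallest singular value if
    # the optimal orthogonal map would be a reflection
    s <- sign(det(sv$u %*% t(sv$v)))
    d[length(d)] <- d[length(d)] * s
  }
  1 - sum(d)^2 / (sum(Xc^2) * sum(Yc^2))
}

#' Procrustes rotation test between two ordinations
#'
#' Superimposes `scores2` onto `scores1` by translation, orthogonal
#' rotation (reflections allowed by default) and scaling; the statistic is
#' the normalized residual m^2 in `[0, 1]` (0 = congruent). The p-value
#' permutes the sample rows of `scores2` (seeded, add-one); `exact = TRUE`
#' enumerates all permutations.
#'
#' @param scores1,scores2 samples x k score matrices (same k).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param reflections allow improper rotations (default TRUE).
#' @param exact exhaustive enumeration.
#' @return list with `m2`, `p`, `n_perm`.
#' @export
procrustes_test <- function(scores1, scores2, n_perm = 999, seed = 1L,
                            reflections = TRUE, exact = FALSE) {
  X <- as.matrix(scores1); Y <- as.matrix(scores2)
  check_flag(ncol(X) == ncol(Y),
             "dimension mismatch: k = %d vs %d", ncol(X), ncol(Y))
  check_flag(nrow(X) == nrow(Y), "sample mismatch between score sets")
  m2_obs <- procrustes_m2(X, Y, reflections)
  perms <- perm_indices(nrow(X), n_perm, sub_seed(seed, 52L), exact)
  mp <- vapply(perms, function(idx) procrustes_m2(X, Y[idx, , drop = FALSE],
                                                  reflections), numeric(1))
  p <- if (exact) mean(mp <= m2_obs + 1e-12)
       else perm_pvalue(sum(mp <= m2_obs + 1e-12), length(perms))
  list(m2 = m2_obs, p = p, n_perm = length(perms))
}

#' Link ASVs to compound signals by Spearman correlation
#'
#' Correlates every ASV's relative abundance with every compound's signal
#' (Spearman), ranks the positively correlated ASVs per compound, and for
#' each compound group reports how often each ASV appears among the top-k
#' lists of the group's compounds, plus the intersection of the groups'
#' top-ASV sets. Compounds with constant signal are flagged and excluded.
#'
#' @param tab an [asv_table()].
#' @param compound_signals compounds x samples matrix (shared samples,
#'   matching order or named columns).
#' @param compound_groups named list mapping group name -> compound ids,
#'   or `NULL` for one group of all compounds.
#' @param top_k list length per compound (default 10). Shorter lists are
#'   returned when fewer positive correlations exist.
#' @return list of class `compound_links`: `per_compound` (named list of
#'   data.frames `asv`, `rho`, `p`), `group_counts`, `group_top_sets`,
#'   `intersection`, `excluded` (constant compounds).
#' @export
link_asvs_to_compounds <- function(tab, compound_signals,
                                   compound_groups = NULL, top_k = 10) {
  rel <- relative_abundance(tab)$counts
  cs <- as.matrix(compound_signals)
  if (!is.null(colnames(cs)) && !is.null(rownames(rel))) {
    check_flag(setequal(colnames(cs), rownames(rel)),
               "ASV table and compound signals must share samples")
    cs <- cs[, rownames(rel), drop = FALSE]
  }
  check_flag(ncol(cs) == nrow(rel), "sample count mismatch")
  if (is.null(rownames(cs))) rownames(cs) <- sprintf("compound_%d", seq_len(nrow(cs)))
  if (is.null(compound_groups)) compound_groups <- list(all = rownames(cs))
  constant <- apply(cs, 1, sd) == 0
  excluded <- rownames(cs)[constant]

  n <- nrow(rel)
  per_compound <- list()
  for (cmp in rownames(cs)[!constant]) {
    rho <- suppressWarnings(cor(rel, cs[cmp, ], method = "spearman"))[, 1]
    ok <- !is.na(rho) & rho > 0
    ord <- order(rho[ok], decreasing = TRUE)
    sel <- head(ord, top_k)
    asvs <- names(rho[ok])[sel]
    r <- rho[ok][sel]
    p <- vapply(r, function(x) {
      if (abs(x) >= 1) return(0)
      tstat <- x * sqrt((n - 2) / (1 - x^2))
      2 * pt(-abs(tstat), df = n - 2)
    }, numeric(1))
    per_compound[[cmp]] <- data.frame(asv = asvs, rho = r, p = p,
                                      stringsAsFactors = FALSE, row.names = NULL)
  }
  group_counts <- lapply(compound_groups, function(members) {
    members <- setdiff(members, excluded)
    asvs <- unlist(lapply(per_compound[members], `[[`, "asv"))
    sort(table(asvs), decreasing = TRUE)
  })
  group_top_sets <- lapply(group_counts, names)
  inter <- if (length(group_top_sets) >= 2) {
    Reduce(intersect, group_top_sets)
  } else unlist(group_top_sets, use.names = FALSE)
  structure(list(per_compound = per_compound, group_counts = group_counts,
                 group_top_sets = group_top_sets, intersection = inter,
                 excluded = excluded, top_k = top_k),
            class = "compound_links")
}
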