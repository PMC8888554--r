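#' Classify variables by their monotone association with depth
#'
#' Correlates each variable (ASV relative abundance or metabolite feature
#' signal) with sample depth and assigns a trend class: `increasing` /
#' `decreasing` when the two-sided p-value is at or below `alpha`,
#' `increasing-trend` / `decreasing-trend` for same-signed but
#' non-significant correlations, `none` for zero or undefined (constant
#' variable) correlations. Benjamini-Hochberg adjusted p-values are
#' appended over the family of testable variables.
#'
#' @param mat numeric matrix, variables x samples.
#' @param depths numeric depth vector (m), one per sample.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level of the class rule (raw p).
#' @param mean_abundance optional per-variable mean relative abundance to
#'   carry through into the result.
#' @return data.frame with `variable_id`, `estimate`, `p`, `p_fdr`,
#'   `class`, `mean_abundance`.
#' @export
classify_depth_trends <- function(mat, depths, method = c("pearson", "spearman"),
                                  alpha = 0.05, mean_abundance = NULL) {
  method <- match.arg(method)
  check_flag(ncol(mat) == length(depths),
             "matrix has %d samples but %d depths given", ncol(mat), length(depths))
  check_flag(ncol(mat) >= 3, "need >= 3 samples")
  check_flag(all(is.finite(depths)), "depths must be finite")
  n <- length(depths)
  est <- p <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (sd(x) == 0 || sd(depths) == 0) next
    r <- suppressWarnings(cor(x, depths, method = method))
    if (is.na(r)) next
    est[i] <- r
    # two-sided p via the t transform of r on n-2 df (exact for Pearson
    # under normality; the standard large-sample approximation for rho)
    if (abs(r) >= 1) {
      p[i] <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p[i] <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  cls <- rep("none", nrow(mat))
  sig <- !is.na(p) & p <= alpha
  up <- !is.na(est) & est > 0
  dn <- !is.na(est) & est < 0
  cls[up & sig] <- "increasing"
  cls[dn & sig] <- "decreasing"
  cls[up & !sig] <- "increasing-trend"
  cls[dn & !sig] <- "decreasing-trend"
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(nrow(mat)))
  data.frame(
    variable_id = ids,
    estimate = est,
    p = p,
    p_fdr = fdr_adjust(p),
    class = cls,
    mean_abundance = if (is.null(mean_abundance)) rowMeans(mat) else mean_abundance,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Welch t-tests of abundance above vs below a water-mass split
#'
#' For each variable, compares values in samples at or above the split
#' depth ("shallow", depth <= split) with those below ("deep"), using
#' Welch's unequal-variance t-test, and adjusts p-values across the family
#' (Benjamini-Hochberg). Variables that are essentially constant are
#' flagged (`NA`) and excluded from the FDR family.
#'
#' @param mat numeric matrix, variables x samples.
#' @param depths numeric depth vector (m).
#' @param split split depth in metres (default 1000).
#' @return data.frame with `variable_id`, `mean_shallow`, `mean_deep`,
#'   `t`, `p`, `p_fdr`.
#' @export
water_mass_ttest <- function(mat, depths, split = 1000) {
  check_flag(ncol(mat) == length(depths),
             "matrix has %d samples but %d depths given", ncol(mat), length(depths))
  shallow <- depths <= split
  n1 <- sum(shallow); n2 <- sum(!shallow)
  check_flag(n1 >= 2 && n2 >= 2,
             "each depth group needs >= 2 samples (shallow=%d, deep=%d)", n1, n2)
  res <- t(apply(mat, 1, function(x) {
    a <- x[shallow]; b <- x[!shallow]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    c(mean(a), mean(b),
      if (is.null(tt)) c(NA_real_, NA_real_) else c(tt$statistic, tt$p.value))
  }))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(nrow(mat)))
  data.frame(
    variable_id = ids,
    mean_shallow = res[, 1], mean_deep = res[, 2],
    t = res[, 3], p = res[, 4], p_fdr = fdr_adjust(res[, 4]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify common ASVs by mean relative abundance
#'
#' An ASV is "common" when its average relative abundance across the
#' table's samples strictly exceeds `threshold` (default 0.25%). The
#' summary reports which fraction of all reads the common set represents.
#'
#' @param tab an [asv_table()] (counts or relative abundances).
#' @param threshold mean relative abundance cutoff (default 0.0025).
#' @return list with `common_ids`, `mean_rel_abundance` (per ASV), and
#'   `read_fraction` of the common set.
#' @export
classify_common <- function(tab, threshold = 0.0025) {
  rel <- relative_abundance(tab)$counts
  mean_rel <- colMeans(rel)
  common <- names(mean_rel)[mean_rel > threshold]
  total <- sum(tab$counts)
  list(
    common_ids = common,
    mean_rel_abundance = mean_rel,
    read_fraction = if (total > 0) sum(tab$counts[, common, drop = FALSE]) / total else NA_real_
  )
}

#' Summarize a depth-trend classification against its ASV table
#'
#' @param results data.frame from [classify_depth_trends()].
#' @param tab the [asv_table()] the results were computed on.
#' @return list with `n_increasing`, `n_decreasing`, `fraction_responsive`
#'   (of all ASVs) and `mean_rel_abundance_responsive` (average per-sample
#'   relative abundance represented by the responsive set).
#' @export
summarize_depth_response <- function(results, tab) {
  ids <- colnames(tab$counts)
  check_flag(all(results$variable_id %in% ids),
             "result ids do not match the ASV table")
  inc <- results$variable_id[results$class == "increasing"]
  dec <- results$variable_id[results$class == "decreasing"]
  resp <- c(inc, dec)
  rel <- relative_abundance(tab)$counts
  list(
    n_increasing = length(inc),
    n_decreasing = length(dec),
    fraction_responsive = length(resp) / ncol(rel),
    mean_rel_abundance_responsive =
      if (length(resp)) mean(rowSums(rel[, resp, drop = FALSE])) else 0
  )
}
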