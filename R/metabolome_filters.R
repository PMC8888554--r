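#' Per-feature QC coefficient of variation
#'
#' CV = sample standard deviation / mean over the pooled QC injections of
#' each feature (the metabolomics convention: n-1 denominator, raw
#' intensities). Features whose QC mean is zero get `NA` — the statistic is
#' undefined and the feature is treated as unreliable downstream.
#'
#' @param tab a [metabo_table()] with at least two QC columns.
#' @return named numeric vector of CVs (`NA` where undefined).
#' @export
qc_cv <- function(tab) {
  qc <- tab$intensity[, tab$is_qc, drop = FALSE]
  check_flag(ncol(qc) >= 2,
             "QC CV needs >= 2 QC columns (found %d)", ncol(qc))
  m <- rowMeans(qc)
  s <- apply(qc, 1, sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  setNames(cv, tab$features$feature_id)
}

new_filter_report <- function(rule, input_ids, surviving_ids, removed_by, cv = NULL) {
  structure(list(
    rule = rule,
    n_input = length(input_ids),
    n_surviving = length(surviving_ids),
    removed_by = removed_by,   # named integer vector, partitioned counts
    surviving_ids = surviving_ids,
    removed_ids = setdiff(input_ids, surviving_ids),
    qc_cv = cv
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report:%s> %d -> %d features (removed: %s)\n",
              x$rule, x$n_input, x$n_surviving,
              paste(sprintf("%s=%d", names(x$removed_by), x$removed_by),
                    collapse = ", ")))
  invisible(x)
}

#' "cleaned" filter: drop void-eluting and QC-unstable features
#'
#' Removes features eluting in the void (retention time strictly below
#' `void_rt_max`, default 40 s) and features whose QC coefficient of
#' variation exceeds `qc_cv_max` (default 0.30) or is undefined. A feature
#' at exactly 40 s is retained (the rule is "< 40 s").
#'
#' @param tab a [metabo_table()] with QC columns.
#' @param void_rt_max void retention-time cutoff, seconds.
#' @param qc_cv_max maximum tolerated QC CV.
#' @return list with `table` (filtered [metabo_table()], tagged as
#'   "cleaned") and `report` (a `filter_report`).
#' @export
filter_cleaned <- function(tab, void_rt_max = 40, qc_cv_max = 0.30) {
  cv <- qc_cv(tab)
  rt <- tab$features$rt
  is_void <- rt < void_rt_max
  bad_cv <- is.na(cv) | cv > qc_cv_max
  keep <- !is_void & !bad_cv
  ids <- tab$features$feature_id
  report <- new_filter_report(
    "cleaned", ids, ids[keep],
    removed_by = c(void = sum(is_void),
                   qc_cv = sum(bad_cv & !is_void)),
    cv = cv
  )
  out <- subset_features(tab, ids[keep], add_filter = "cleaned")
  list(table = out, report = report)
}

#' "pc_group" filter: one representative feature per adduct cluster
#'
#' From a "cleaned" table, retains only the feature with the greatest
#' cumulative signal (sum of intensities over the study samples, QC columns
#' excluded) within each pc_group. Ties are broken deterministically in
#' favour of the lexicographically smaller feature id and recorded in the
#' report.
#'
#' @param tab a "cleaned" [metabo_table()].
#' @return list with `table` and `report` (report's `ties` lists tied
#'   groups, if any).
#' @export
filter_pc_group <- function(tab) {
  check_flag("cleaned" %in% tab$filters,
             "filter_pc_group expects a \"cleaned\" table (run filter_cleaned first)")
  check_flag(!is.null(tab$features$pc_group), "pc_group column required")
  ids <- tab$features$feature_id
  signal <- rowSums(sample_intensity(tab))
  ties <- character(0)
  keep <- unlist(lapply(split(seq_along(ids), tab$features$pc_group), function(idx) {
    s <- signal[idx]
    best <- idx[s == max(s)]
    if (length(best) > 1) {
      best <- best[order(ids[best])]
      ties <<- c(ties, ids[best[1]])
    }
    best[1]
  }), use.names = FALSE)
  keep <- sort(keep)
  report <- new_filter_report(
    "pc_group", ids, ids[keep],
    removed_by = c(non_representative = length(ids) - length(keep))
  )
  report$ties <- ties
  list(table = subset_features(tab, ids[keep], add_filter = "pc_group"),
       report = report)
}

# Normalize an annotation string: strip whitespace, unify unicode
# minus/dash variants, so "[M + H]+" matches "[M+H]+".
normalize_annotation <- function(x) {
  x <- gsub("[−–—]", "-", x)
  gsub("[[:space:]]+", "", x)
}

#' "ion" filter: keep only explicit molecular-ion annotations
#'
#' From a "cleaned" table, retains only features annotated as the
#' protonated molecular ion `[M+H]+` (positive ESI mode) or the
#' deprotonated ion `[M-H]-` (negative mode), after whitespace/dash
#' normalization of the annotation string.
#'
#' @param tab a "cleaned" [metabo_table()] with known acquisition mode.
#' @return list with `table` and `report`.
#' @export
filter_ion <- function(tab) {
  check_flag("cleaned" %in% tab$filters,
             "filter_ion expects a \"cleaned\" table (run filter_cleaned first)")
  check_flag(!is.null(tab$mode) && tab$mode$polarity %in% c("positive", "negative"),
             "acquisition mode (polarity) must be known for the ion filter")
  target <- if (tab$mode$polarity == "positive") "[M+H]+" else "[M-H]-"
  ann <- normalize_annotation(tab$features$annotation)
  keep <- !is.na(ann) & ann == target
  ids <- tab$features$feature_id
  report <- new_filter_report(
    "ion", ids, ids[keep],
    removed_by = c(non_ion = sum(!keep))
  )
  list(table = subset_features(tab, ids[keep], add_filter = "ion"),
       report = report)
}

#' Apply a named filtering variant
#'
#' Convenience dispatcher for the three published feature-set variants:
#' `"cleaned"`, `"pc_group"` (cleaned, then one representative per
#' pc_group) and `"ion"` (cleaned, then molecular ions only).
#'
#' @param tab a raw [metabo_table()].
#' @param filter one of `"cleaned"`, `"pc_group"`, `"ion"`.
#' @param void_rt_max,qc_cv_max thresholds passed to [filter_cleaned()].
#' @return list with `table` and `reports` (list of per-step reports).
#' @export
apply_filter_variant <- function(tab, filter = c("cleaned", "pc_group", "ion"),
                                 void_rt_max = 40, qc_cv_max = 0.30) {
  filter <- match.arg(filter)
  cl <- filter_cleaned(tab, void_rt_max, qc_cv_max)
  if (filter == "cleaned") {
    return(list(table = cl$table, reports = list(cleaned = cl$report)))
  }
  second <- if (filter == "pc_group") filter_pc_group(cl$table) else filter_ion(cl$table)
  list(table = second$table,
       reports = setNames(list(cl$report, second$report), c("cleaned", filter)))
}
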