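#' ASV count/abundance table
#'
#' Light container for a samples x ASVs abundance matrix, the central
#' community object of the pipeline. Stores either non-negative integer
#' counts or relative abundances (rows summing to 1).
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns, with
#'   dimnames.
#' @param taxonomy optional character vector of per-ASV taxonomy strings.
#' @return an object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  check_flag(is.matrix(counts), "counts must be a matrix")
  check_flag(!is.null(rownames(counts)) && !is.null(colnames(counts)),
             "counts must have sample and ASV ids as dimnames")
  check_flag(!anyDuplicated(rownames(counts)), "duplicate sample ids")
  check_flag(!anyDuplicated(colnames(counts)), "duplicate ASV ids")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("negative abundance at sample '%s', ASV '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  if (!is.null(taxonomy)) {
    check_flag(length(taxonomy) == ncol(counts),
               "taxonomy length must equal number of ASVs")
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is_relative(x)) "relative abundances" else "counts"))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

is_relative <- function(tab) {
  rs <- rowSums(tab$counts)
  all(abs(rs[rs > 0] - 1) < 1e-6)
}

#' Convert an ASV table to relative abundances
#'
#' Total-sum scaling; rows of the result sum to 1 (within 1e-9) except
#' all-zero samples, which stay zero and are flagged with a warning.
#'
#' @param tab an [asv_table()].
#' @return an `asv_table` of relative abundances.
#' @export
relative_abundance <- function(tab) {
  rs <- rowSums(tab$counts)
  if (any(rs == 0)) warning("all-zero sample(s): ",
                            paste(rownames(tab$counts)[rs == 0], collapse = ", "))
  rel <- tab$counts / ifelse(rs == 0, 1, rs)
  asv_table(rel, tab$taxonomy)
}

#' LC-MS feature table
#'
#' Container for an untargeted metabolomics feature table: a features x
#' columns intensity matrix (study samples plus pooled QC injections),
#' per-feature retention time, m/z, annotation string and pc_group id, and
#' the acquisition mode.
#'
#' @param intensity non-negative numeric matrix, features x columns.
#' @param features data.frame with columns `feature_id`, `rt` (seconds),
#'   `mz`, `annotation`, `pc_group`.
#' @param is_qc logical vector flagging QC columns.
#' @param mode list with `chromatography` (`"HILIC"`/`"RP"`) and `polarity`
#'   (`"positive"`/`"negative"`), or `NULL` when unknown.
#' @param filters character vector of filter names already applied.
#' @return an object of class `metabo_table`.
#' @export
metabo_table <- function(intensity, features, is_qc, mode = NULL,
                         filters = character(0)) {
  check_flag(is.matrix(intensity), "intensity must be a matrix")
  check_flag(nrow(intensity) == nrow(features),
             "intensity rows must match feature metadata rows")
  check_flag(length(is_qc) == ncol(intensity),
             "is_qc must flag every intensity column")
  need <- c("feature_id", "rt", "mz", "annotation", "pc_group")
  miss <- setdiff(need, names(features))
  check_flag(length(miss) == 0, "feature metadata missing column(s): %s",
             paste(miss, collapse = ", "))
  check_flag(!anyDuplicated(features$feature_id), "duplicate feature ids")
  check_flag(all(features$rt >= 0), "retention_time must be >= 0")
  check_flag(all(intensity >= 0), "intensities must be non-negative")
  rownames(intensity) <- features$feature_id
  structure(list(intensity = intensity, features = features,
                 is_qc = as.logical(is_qc), mode = mode, filters = filters),
            class = "metabo_table")
}

#' @export
print.metabo_table <- function(x, ...) {
  cat(sprintf("<metabo_table> %d features x %d samples (+%d QC) [%s %s]%s\n",
              nrow(x$intensity), sum(!x$is_qc), sum(x$is_qc),
              if (is.null(x$mode)) "?" else x$mode$chromatography,
              if (is.null(x$mode)) "?" else x$mode$polarity,
              if (length(x$filters)) paste0(" filters: ",
                                            paste(x$filters, collapse = "+"))
              else ""))
  invisible(x)
}

# Study-sample intensity submatrix (QC columns dropped).
sample_intensity <- function(tab) tab$intensity[, !tab$is_qc, drop = FALSE]

# Subset a metabo_table to a set of feature ids (order preserved).
subset_features <- function(tab, keep_ids, add_filter = NULL) {
  idx <- match(keep_ids, tab$features$feature_id)
  metabo_table(tab$intensity[idx, , drop = FALSE],
               tab$features[idx, , drop = FALSE],
               tab$is_qc, tab$mode,
               filters = union(tab$filters, add_filter))
}
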