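#' Read an ASV table from TSV
#'
#' Accepts QIIME-style orientation in either direction: the header sentinel
#' of the first column decides. `sample_id` means samples in rows;
#' `asv_id` means ASVs in rows (the matrix is transposed on read).
#'
#' @param path TSV file path.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path) {
  check_flag(file.exists(path), "no such file: %s", path)
  check_flag(file.size(path) > 0, "empty file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  check_flag(length(unique(nf)) == 1,
             "ragged TSV: rows have %s fields", paste(unique(nf), collapse = "/"))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_flag(ncol(df) >= 2 && nrow(df) >= 1, "file has no abundance cells: %s", path)
  sentinel <- names(df)[1]
  check_flag(sentinel %in% c("sample_id", "asv_id"),
             "first header cell must be 'sample_id' or 'asv_id' (got '%s')",
             sentinel)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  check_flag(is.numeric(m), "non-numeric abundance cell(s) in %s", path)
  rownames(m) <- ids
  if (sentinel == "asv_id") m <- t(m)
  asv_table(m)
}

#' Write an ASV table to TSV (samples in rows)
#' @param tab an [asv_table()].
#' @param path output path.
#' @export
write_asv_table <- function(tab, path) {
  df <- data.frame(sample_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "depth")
  miss <- setdiff(need, names(df))
  check_flag(length(miss) == 0, "metadata missing column(s): %s",
             paste(miss, collapse = ", "))
  check_flag(!anyDuplicated(df$sample_id), "duplicate sample_id in metadata")
  df
}

#' @rdname read_metadata
#' @param metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LC-MS feature table from CSV
#'
#' Expects columns `feature_id`, `rt`, `mz`, `annotation`, `pc_group`
#' followed by intensity columns; columns whose name starts with `QC` are
#' treated as pooled QC injections (header convention).
#'
#' @param path CSV file path.
#' @param mode acquisition mode as `c(chromatography, polarity)`, or `NULL`.
#' @return a [metabo_table()].
#' @export
read_feature_table <- function(path, mode = NULL) {
  check_flag(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "rt", "mz", "annotation", "pc_group")
  for (col in need) {
    if (!col %in% names(df)) {
      stopf("%s required", if (col == "rt") "retention_time" else col)
    }
  }
  meta <- df[need]
  meta$annotation[is.na(meta$annotation)] <- ""
  sample_cols <- setdiff(names(df), need)
  check_flag(length(sample_cols) > 0, "no intensity columns in %s", path)
  m <- as.matrix(df[sample_cols])
  if (!is.null(mode)) mode <- list(chromatography = mode[[1]], polarity = mode[[2]])
  metabo_table(m, meta, is_qc = startsWith(sample_cols, "QC"), mode = mode)
}

#' Write an LC-MS feature table to CSV
#' @param tab a [metabo_table()].
#' @param path output path.
#' @export
write_feature_table <- function(tab, path) {
  df <- cbind(tab$features, as.data.frame(tab$intensity, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ASV sequences (FASTA)
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_sequences
#' @param seqs named character vector of DNA sequences.
#' @export
write_sequences <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read / write a planted-truth ledger (JSON)
#' @param path JSON path.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$sister_pairs) && length(x$sister_pairs)) {
    x$sister_pairs <- as.data.frame(x$sister_pairs, stringsAsFactors = FALSE)
  }
  x
}

#' @rdname read_truth
#' @param truth list as produced by the generators.
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors must become JSON objects, not bare arrays
  truth <- lapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a square distance/statistic matrix as TSV
#' @param m square matrix with dimnames (or a `dist`).
#' @param path output path.
#' @param id_col header label for the id column.
#' @export
write_square_tsv <- function(m, path, id_col = "id") {
  if (inherits(m, "dist")) m <- as.matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
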