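#' Pairwise ungapped sequence identity
#'
#' Positional identity (matching positions / length) between all pairs of
#' equal-length sequences — the natural similarity for fixed-length ASVs
#' built from concatenated trimmed reads. No alignment is attempted; for
#' variable-length inputs set `align = TRUE` to use a Needleman-Wunsch
#' global alignment identity instead.
#'
#' @param seqs named character vector of DNA sequences.
#' @param align use global-alignment identity (allows unequal lengths).
#' @return symmetric identity matrix with unit diagonal.
#' @export
pairwise_identity <- function(seqs, align = FALSE) {
  n <- length(seqs)
  check_flag(n >= 2, "need >= 2 sequences")
  check_flag(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
             "sequences must have unique names")
  if (align) {
    ss <- Biostrings::DNAStringSet(seqs)
    m <- diag(1, n)
    for (i in seq_len(n - 1)) {
      al <- Biostrings::pairwiseAlignment(ss[rep(i, n - i)], ss[(i + 1):n],
                                          type = "global")
      pid <- Biostrings::pid(al) / 100
      m[i, (i + 1):n] <- pid
      m[(i + 1):n, i] <- pid
    }
    dimnames(m) <- list(names(seqs), names(seqs))
    return(m)
  }
  lens <- nchar(seqs)
  check_flag(length(unique(lens)) == 1,
             "unequal sequence lengths (%s); use align = TRUE",
             paste(unique(lens), collapse = ", "))
  L <- lens[1]
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    x <- (chars == b) * 1
    matches <- matches + tcrossprod(x)
  }
  m <- matches / L
  diag(m) <- 1
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Detect sister-group ASV pairs (candidate water-mass ecotypes)
#'
#' A sister pair is an unordered pair of ASVs whose sequences are at least
#' `min_identity` identical (default 97%) and whose depth responses point
#' in strictly opposite directions. The depth response comes from either
#' the depth-correlation classification (`basis = "correlation"`) or the
#' above/below-split t-tests (`basis = "ttest"`); significance uses the
#' raw or the FDR-adjusted p-value (`stringency`). By default both members
#' must be individually significant; `require_both = FALSE` relaxes this
#' to one significant member plus an opposite-signed (possibly
#' non-significant) trend in the other.
#'
#' @param identity symmetric identity matrix from [pairwise_identity()].
#' @param response data.frame of per-ASV depth responses: either a
#'   [classify_depth_trends()] result (for `basis = "correlation"`) or a
#'   [water_mass_ttest()] result (for `basis = "ttest"`).
#' @param min_identity identity threshold (default 0.97).
#' @param basis `"correlation"` or `"ttest"`.
#' @param stringency `"raw_p"` or `"fdr_p"`.
#' @param alpha significance level.
#' @param require_both require both members significant (default TRUE).
#' @return data.frame of pairs: `asv_a`, `asv_b` (canonical order),
#'   `identity`, `class_a`, `class_b`, `basis`, `stringency`.
#' @export
find_sister_pairs <- function(identity, response, min_identity = 0.97,
                              basis = c("correlation", "ttest"),
                              stringency = c("raw_p", "fdr_p"),
                              alpha = 0.05, require_both = TRUE) {
  basis <- match.arg(basis)
  stringency <- match.arg(stringency)
  ids <- rownames(identity)
  check_flag(all(ids %in% response$variable_id),
             "trend results must cover every sequence in the identity matrix")
  r <- response[match(ids, response$variable_id), ]
  direction <- if (basis == "correlation") {
    sign(ifelse(is.na(r$estimate), 0, r$estimate))
  } else {
    # positive direction = more abundant in the deep group
    sign(ifelse(is.na(r$t), 0, r$mean_deep - r$mean_shallow))
  }
  p <- if (stringency == "raw_p") r$p else r$p_fdr
  sig <- !is.na(p) & p <= alpha & direction != 0
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (identity[i, j] < min_identity) next
      opposing <- direction[i] * direction[j] == -1
      if (!opposing) next
      ok <- if (require_both) sig[i] && sig[j] else sig[i] || sig[j]
      if (!ok) next
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      lab <- function(d, s) {
        base <- if (d > 0) "increasing" else "decreasing"
        if (s) base else paste0(base, "-trend")
      }
      ia <- if (a == ids[i]) i else j
      ib <- if (a == ids[i]) j else i
      out[[length(out) + 1]] <- data.frame(
        asv_a = a, asv_b = b, identity = identity[i, j],
        class_a = lab(direction[ia], sig[ia]),
        class_b = lab(direction[ib], sig[ib]),
        basis = basis, stringency = stringency,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(asv_a = character(0), asv_b = character(0),
                      identity = numeric(0), class_a = character(0),
                      class_b = character(0), basis = character(0),
                      stringency = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$asv_a, res$asv_b), , drop = FALSE]
}
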