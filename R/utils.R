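#' @useDynLib holodepth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cmdscale cutree dist hclust lm.fit p.adjust pt qnorm
#'   rgamma rlnorm rmultinom rnorm runif sd setNames t.test cov
#' @importFrom utils head read.delim write.table
NULL

# Derive a reproducible sub-stream seed from a master seed and a stream index.
# Kept strictly below 2^31 - 1 so set.seed() accepts it on all platforms.
sub_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 1048573) * 2039 + as.numeric(stream) * 97 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

# Add-one permutation / resampling p-value estimator: never returns 0.
perm_pvalue <- function(n_hits, n_perm) (1 + n_hits) / (1 + n_perm)

#' Benjamini-Hochberg adjustment over the defined members of a p-value family
#'
#' Wraps [stats::p.adjust()] but keeps `NA` entries (undefined tests, e.g.
#' constant variables) out of the family so they do not dilute the correction.
#'
#' @param p numeric vector of raw p-values, possibly with `NA`.
#' @return vector of the same length; `NA` where the input was `NA`.
#' @keywords internal
fdr_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
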