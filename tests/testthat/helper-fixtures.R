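# Shared fixtures, built in code.

# The five-feature filtering fixture: retention times and QC intensities
# chosen so the QC coefficients of variation are exactly
# 0.10, 0.35, 0.10, 0.20, 0.29 (two QC columns: mean 10, sd = cv * 10,
# i.e. values 10 +/- cv * 10 / sqrt(2)).
make_filter_fixture <- function() {
  rt <- c(30, 45, 100, 50, 41)
  cv <- c(0.10, 0.35, 0.10, 0.20, 0.29)
  delta <- cv * 10 / sqrt(2)
  qc <- cbind(10 - delta, 10 + delta)
  colnames(qc) <- c("QC_01", "QC_02")
  study <- matrix(rep(c(100, 250, 30, 80, 60), 3), nrow = 5,
                  dimnames = list(NULL, c("S1", "S2", "S3")))
  metabo_table(
    intensity = cbind(study, qc),
    features = data.frame(
      feature_id = sprintf("F%d", 1:5),
      rt = rt, mz = 100 + 1:5,
      annotation = c("[M+H]+", "adduct", "[M+H]+", "", "[M + H]+"),
      pc_group = c(1L, 1L, 2L, 2L, 3L),
      stringsAsFactors = FALSE
    ),
    is_qc = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    mode = list(chromatography = "HILIC", polarity = "positive")
  )
}

# A nearly noise-free planted community: very large Dirichlet mass makes
# depth responses essentially deterministic, so planted signals are
# individually significant.
make_noisefree_community <- function(n_samples = 15, n_asvs = 40,
                                     n_sister_pairs = 2, seed = 101) {
  md <- simulate_metadata(n_samples, seed = seed)
  sim <- simulate_asv_table(md, "HMA", n_asvs = n_asvs,
                            frac_responsive = 0.4,
                            n_sister_pairs = n_sister_pairs,
                            theta = 1e7, lib_meanlog = log(1e5),
                            lib_sdlog = 0.01, seed = seed + 1)
  list(metadata = md, sim = sim)
}

trend_of <- function(sim, md, method = "pearson") {
  rel <- relative_abundance(sim$table)$counts
  classify_depth_trends(t(rel), md$depth, method = method)
}

# Independent single-component PLS1 oracle: closed-form NIPALS step on
# autoscaled data, kept free of the package's OPLS code path.
pls1_oracle_predictions <- function(X, y) {
  Xs <- scale(X)
  ys <- y - mean(y)
  w <- drop(crossprod(Xs, ys))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  q <- sum(ys * t) / sum(t^2)
  t * q + mean(y)
}
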