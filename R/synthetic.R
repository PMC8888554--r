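#' Simulate sample metadata along a bathymetric gradient
#'
#' Generates a metadata table emulating deep-sea sponge collections across a
#' depth gradient spanning two water masses. Depths are uniform over
#' `depth_range`; temperature and salinity decrease linearly with depth (the
#' regional water-column structure) with a tunable degree of collinearity;
#' the categorical `water_mass` label splits at 1000 m, the approximate
#' midpoint between the shallow and deep water masses of the study region.
#'
#' @param n_samples number of specimens (>= 3).
#' @param depth_range numeric length-2, metres; default `c(244, 1476)`, the
#'   span of the sponge collections the generator emulates.
#' @param collinearity value in `[0, 1]`: target correlation magnitude between
#'   depth and the hydrographic variables. 1 gives a deterministic linear
#'   map, 0 gives independence.
#' @param species character label(s) recycled across samples.
#' @param years integer vector of candidate sampling years.
#' @param split_depth metres; boundary of the water-mass label (default 1000).
#' @param seed integer master seed.
#' @return a `data.frame` with columns `sample_id`, `species`, `depth`,
#'   `latitude`, `longitude`, `temperature`, `salinity`, `year`,
#'   `water_mass`.
#' @export
simulate_metadata <- function(n_samples, depth_range = c(244, 1476),
                              collinearity = 0.9,
                              species = "Geodia_barretti",
                              years = 2015:2017,
                              split_depth = 1000, seed = 1L) {
  check_flag(n_samples >= 3, "n_samples must be >= 3 (got %d)", n_samples)
  check_flag(length(depth_range) == 2 && diff(range(depth_range)) > 0,
             "depth_range must be a non-degenerate interval")
  check_flag(collinearity >= 0 && collinearity <= 1,
             "collinearity must lie in [0, 1]")
  with_seed(seed, {
    depth <- runif(n_samples, depth_range[1], depth_range[2])
    # Regional hydrography: ~4.5 C / 34.93 psu near 600 m falling to
    # ~3.7 C / 34.89 psu near 1200 m.
    z <- as.numeric(scale(depth))
    mix <- function(base, slope_per_m, noise_sd) {
      signal <- slope_per_m * (depth - mean(depth))
      base + collinearity * signal +
        sqrt(max(0, 1 - collinearity^2)) * noise_sd * rnorm(n_samples)
    }
    temperature <- mix(4.2, -0.00133, 0.00133 * sd(depth))
    salinity <- mix(34.91, -6.7e-05, 6.7e-05 * sd(depth))
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      species = rep_len(species, n_samples),
      depth = depth,
      latitude = runif(n_samples, 60.5, 66.5),
      longitude = runif(n_samples, -60.5, -54.5),
      temperature = temperature,
      salinity = salinity,
      year = sample(years, n_samples, replace = TRUE),
      water_mass = ifelse(depth <= split_depth, "shallow", "deep"),
      stringsAsFactors = FALSE
    )
  })
}

# Baseline log-abundance spread calibrated so default communities reproduce
# the observed per-sample richness means (about 190 ASVs for rich HMA-like
# communities of 420 ASVs, about 30 for poor LMA-like communities of 135).
.profile_defaults <- function(profile) {
  switch(profile,
    HMA = list(n_asvs = 420L, sd_base = 2.65),
    LMA = list(n_asvs = 135L, sd_base = 4.8),
    stopf("unknown profile '%s' (use \"HMA\" or \"LMA\")", profile)
  )
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute exactly k positions of a sequence, each to a different base.
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (i in pos) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate an ASV count table with planted depth structure
#'
#' Counts follow a Dirichlet-multinomial: per-ASV log-concentrations are a
#' log-normal baseline plus, for planted depth-responsive ASVs, a log-linear
#' slope in depth (km). Slope signs are balanced. Planted "sister" pairs
#' receive near-identical sequences (differing at exactly
#' `floor((1 - identity_target) * seq_length)` positions) and slopes of
#' opposite sign, emulating candidate water-mass ecotypes. The `"HMA"`
#' profile yields rich communities, `"LMA"` poor ones.
#'
#' @param metadata data.frame from [simulate_metadata()].
#' @param profile `"HMA"` or `"LMA"` community profile.
#' @param n_asvs number of ASVs (default: profile-specific, 420 or 135).
#' @param frac_responsive fraction of ASVs with a planted depth effect.
#' @param n_sister_pairs number of planted sister pairs (counted inside the
#'   responsive set).
#' @param effect_size log-linear slope magnitude, per km of depth.
#' @param identity_target sister-pair sequence identity in `(0, 1]`.
#' @param seq_length nucleotides per ASV sequence (default 140, two
#'   concatenated 70-nt reads).
#' @param theta Dirichlet concentration mass (overdispersion; smaller = more
#'   overdispersed).
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param seed integer master seed.
#' @return list with elements `table` (an [asv_table()]), `sequences` (named
#'   character vector), and `truth` (planted ground-truth ledger; see
#'   [validate_truth()]).
#' @export
simulate_asv_table <- function(metadata, profile = c("HMA", "LMA"),
                               n_asvs = NULL, frac_responsive = 0.3,
                               n_sister_pairs = 0, effect_size = 4,
                               identity_target = 0.97, seq_length = 140L,
                               theta = 2000, lib_meanlog = log(2e4),
                               lib_sdlog = 0.3, seed = 1L) {
  profile <- match.arg(profile)
  def <- .profile_defaults(profile)
  if (is.null(n_asvs)) n_asvs <- def$n_asvs
  check_flag(identity_target > 0 && identity_target <= 1,
             "identity_target must lie in (0, 1]")
  check_flag(frac_responsive >= 0 && frac_responsive <= 1,
             "frac_responsive must lie in [0, 1]")
  check_flag(n_asvs >= 2 * n_sister_pairs,
             "need n_asvs >= 2 * n_sister_pairs (%d < %d)",
             n_asvs, 2 * n_sister_pairs)
  n <- nrow(metadata)
  with_seed(sub_seed(seed, 1L), {
    ids <- sprintf("ASV_%04d", seq_len(n_asvs))
    base <- rnorm(n_asvs, 0, def$sd_base)
    slopes <- setNames(numeric(n_asvs), ids)

    n_resp <- round(frac_responsive * n_asvs)
    n_resp <- max(n_resp, 2 * n_sister_pairs)
    # Depth effects are planted on taxa above a detectability floor
    # (expected baseline relative abundance high enough to be observed at
    # the default library size); a trend on a never-observed taxon is not
    # defined in the resulting data.
    rel0 <- exp(base - max(base)); rel0 <- rel0 / sum(rel0)
    eligible <- which(rel0 >= 20 / exp(lib_meanlog))
    if (length(eligible) < n_resp) {
      eligible <- order(rel0, decreasing = TRUE)[seq_len(min(n_resp, n_asvs))]
    }
    resp_idx <- if (n_resp > 0) sample(eligible, n_resp) else integer(0)
    if (n_resp > 0) {
      signs <- rep(c(1, -1), length.out = n_resp)[sample(n_resp)]
      slopes[resp_idx] <- signs * effect_size
    }

    # Sister pairs: consecutive responsive indices with forced opposite signs.
    sister <- NULL
    # epsilon guards against binary-representation error in (1 - p) * L
    n_sub <- floor((1 - identity_target) * seq_length + 1e-9)
    seqs <- setNames(random_dna(n_asvs, seq_length), ids)
    if (n_sister_pairs > 0) {
      pair_idx <- resp_idx[seq_len(2 * n_sister_pairs)]
      for (p in seq_len(n_sister_pairs)) {
        a <- pair_idx[2 * p - 1]; b <- pair_idx[2 * p]
        slopes[a] <- effect_size
        slopes[b] <- -effect_size
        seqs[b] <- mutate_seq(seqs[a], n_sub)
      }
      sister <- data.frame(
        asv_a = pmin(ids[pair_idx[c(TRUE, FALSE)]], ids[pair_idx[c(FALSE, TRUE)]]),
        asv_b = pmax(ids[pair_idx[c(TRUE, FALSE)]], ids[pair_idx[c(FALSE, TRUE)]]),
        identity = (seq_length - n_sub) / seq_length,
        slope_a = NA_real_, slope_b = NA_real_,
        stringsAsFactors = FALSE
      )
      sister$slope_a <- slopes[sister$asv_a]
      sister$slope_b <- slopes[sister$asv_b]
    }

    depth_km <- metadata$depth / 1000
    counts <- matrix(0L, n, n_asvs, dimnames = list(metadata$sample_id, ids))
    for (s in seq_len(n)) {
      la <- base + slopes * (depth_km[s] - mean(depth_km))
      rel <- exp(la - max(la)); rel <- rel / sum(rel)
      g <- rgamma(n_asvs, shape = rel * theta, rate = 1)
      g[g == 0] <- .Machine$double.xmin   # guard ultra-small shapes
      p <- g / sum(g)
      N <- max(1000, round(rlnorm(1, lib_meanlog, lib_sdlog)))
      counts[s, ] <- rmultinom(1, N, p)[, 1]
    }

    truth <- list(
      responsive_ids = setNames(slopes[resp_idx], ids[resp_idx]),
      sister_pairs = sister,
      profile = profile,
      effect_size = effect_size,
      seed = seed
    )
    list(table = asv_table(counts), sequences = seqs, truth = truth)
  })
}

#' Simulate an untargeted LC-MS feature table with planted structure
#'
#' Features are grouped into `pc_groups` (adduct/isotope clusters of one
#' underlying compound); within a group, intensities are proportional up to
#' multiplicative noise, and the member with the largest response factor is
#' recorded in the truth ledger as the group's maximal-cumulative-signal
#' representative. Exactly `ceiling(frac_void * n_features)` features elute
#' in the void (retention time < 40 s). A planted subset carries high
#' technical variability on the pooled QC injections (target CV well above
#' the 0.30 threshold). One feature in a subset of groups is annotated as
#' the molecular ion (`"[M+H]+"` in positive mode, `"[M-H]-"` in negative),
#' others as `"adduct"`, `"isotope"` or left blank. Responsive compounds get
#' monotone log-linear depth trends.
#'
#' @param metadata data.frame from [simulate_metadata()].
#' @param n_features number of LC-MS features.
#' @param n_pc_groups number of compound (pc) groups.
#' @param frac_void fraction of features eluting before 40 s.
#' @param frac_high_cv fraction of features with planted high QC variability.
#' @param frac_responsive fraction of pc_groups with a planted depth trend.
#' @param n_qc number of pooled QC injections (>= 2).
#' @param mode acquisition mode: list/character of chromatography
#'   (`"HILIC"`/`"RP"`) and polarity (`"positive"`/`"negative"`).
#' @param effect_size log-linear slope magnitude per km for responsive
#'   compounds.
#' @param sample_effect_sd log-scale standard deviation of the per-sample
#'   technical factor (extraction/injection efficiency); this shared
#'   factor dominates the covariance of real LC-MS tables and is the
#'   archetypal response-orthogonal variation an OPLS model strips.
#' @param qc_cv_base,qc_cv_high target QC coefficients of variation for
#'   well-behaved and planted high-CV features.
#' @param seed integer master seed.
#' @return list with `table` (a [metabo_table()]) and `truth` ledger.
#' @export
simulate_metabolome <- function(metadata, n_features = 200, n_pc_groups = 40,
                                frac_void = 0.1, frac_high_cv = 0.1,
                                frac_responsive = 0.3, n_qc = 8,
                                mode = c("HILIC", "positive"),
                                effect_size = 1.5, sample_effect_sd = 0.4,
                                qc_cv_base = 0.08, qc_cv_high = 0.6,
                                seed = 1L) {
  check_flag(n_qc >= 2,
             "n_qc must be >= 2 (a coefficient of variation needs >= 2 QC injections)")
  check_flag(n_features >= n_pc_groups, "need n_features >= n_pc_groups")
  n <- nrow(metadata)
  with_seed(sub_seed(seed, 2L), {
    fid <- sprintf("FT_%04d", seq_len(n_features))
    # Assign features to groups: every group non-empty.
    grp <- c(seq_len(n_pc_groups),
             sample(n_pc_groups, n_features - n_pc_groups, replace = TRUE))
    grp <- grp[sample(n_features)]

    depth_km <- metadata$depth / 1000
    n_resp_grp <- round(frac_responsive * n_pc_groups)
    resp_grp <- if (n_resp_grp > 0) sample(n_pc_groups, n_resp_grp) else integer(0)
    grp_slope <- numeric(n_pc_groups)
    if (n_resp_grp > 0) {
      grp_slope[resp_grp] <- rep(c(1, -1), length.out = n_resp_grp) * effect_size
    }
    grp_mu <- rnorm(n_pc_groups, log(1e5), 1)

    # Per-sample compound log-intensity (biological noise sd 0.3).
    compound <- sapply(seq_len(n_pc_groups), function(g) {
      grp_mu[g] + grp_slope[g] * (depth_km - mean(depth_km)) + rnorm(n, 0, 0.3)
    })  # n x n_pc_groups

    factor_f <- rlnorm(n_features, 0, 0.8)   # per-feature response factor
    sample_eff <- rlnorm(n, 0, sample_effect_sd)  # shared technical factor
    intensity <- t(exp(compound[, grp, drop = FALSE]) * sample_eff *
                     matrix(rlnorm(n * n_features, 0, 0.05), n, n_features)) *
      factor_f
    dimnames(intensity) <- list(fid, metadata$sample_id)

    # QC injections: pooled material, multiplicative technical noise.
    n_high <- round(frac_high_cv * n_features)
    high_idx <- if (n_high > 0) sample(n_features, n_high) else integer(0)
    cv_target <- rep(qc_cv_base, n_features)
    cv_target[high_idx] <- qc_cv_high
    sdlog_qc <- sqrt(log(1 + cv_target^2))
    pooled <- rowMeans(intensity)
    qc <- matrix(0, n_features, n_qc,
                 dimnames = list(fid, sprintf("QC_%02d", seq_len(n_qc))))
    for (j in seq_len(n_qc)) qc[, j] <- pooled * rlnorm(n_features, 0, sdlog_qc)

    # Retention times: planted void features strictly below 40 s.
    n_void <- ceiling(frac_void * n_features)
    void_idx <- if (n_void > 0) sample(n_features, n_void) else integer(0)
    rt <- runif(n_features, 45, 600)
    rt[void_idx] <- runif(n_void, 5, 39.5)

    polarity <- mode[[2]]
    ion_label <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
    annotation <- sample(c("adduct", "isotope", ""), n_features,
                         replace = TRUE, prob = c(0.35, 0.25, 0.4))
    # The molecular ion of a subset of groups: the group's representative
    # feature (realized maximal cumulative study-sample signal) gets the
    # ion label.
    signal <- rowSums(intensity)
    rep_feature <- vapply(seq_len(n_pc_groups), function(g) {
      members <- which(grp == g)
      members[which.max(signal[members])]
    }, integer(1))
    ion_groups <- sample(n_pc_groups, ceiling(0.6 * n_pc_groups))
    annotation[rep_feature[ion_groups]] <- ion_label

    features <- data.frame(
      feature_id = fid,
      rt = rt,
      mz = runif(n_features, 80, 1200),
      annotation = annotation,
      pc_group = grp,
      stringsAsFactors = FALSE
    )
    tab <- metabo_table(
      intensity = cbind(intensity, qc),
      features = features,
      is_qc = c(rep(FALSE, n), rep(TRUE, n_qc)),
      mode = list(chromatography = mode[[1]], polarity = polarity)
    )
    resp_feat <- fid[grp %in% resp_grp]
    truth <- list(
      responsive_ids = setNames(grp_slope[grp][grp %in% resp_grp], resp_feat),
      void_ids = fid[void_idx],
      high_cv_ids = fid[high_idx],
      qc_cv_targets = setNames(cv_target, fid),
      pc_representatives = setNames(fid[rep_feature],
                                    as.character(seq_len(n_pc_groups))),
      ion_ids = fid[rep_feature[ion_groups]],
      seed = seed
    )
    list(table = tab, truth = truth)
  })
}

#' Simulate compositional counts with planted basis associations
#'
#' Generates an ASV count table from a log-normal basis model (the model
#' underlying SparCC): per-sample log basis abundances are independent
#' Gaussians except for planted pairs, whose log abundances are correlated
#' at `basis_correlation`. Counts are multinomial draws from the closed
#' (relative) basis. Used to test association estimators against known
#' ground truth.
#'
#' @param n_samples number of samples.
#' @param n_asvs number of ASVs (>= 2 * n_pairs).
#' @param n_pairs number of planted associated pairs (disjoint).
#' @param basis_correlation log-scale correlation of planted pairs.
#' @param mu_sd spread of mean log abundances across ASVs.
#' @param eps_sd per-sample log-abundance fluctuation scale.
#' @param lib_size multinomial library size per sample.
#' @param seed integer seed.
#' @return list with `table` (an [asv_table()]) and `truth` (with element
#'   `planted_associations`: data.frame `asv_a`, `asv_b`,
#'   `basis_correlation`).
#' @export
simulate_basis_associations <- function(n_samples, n_asvs, n_pairs = 0,
                                        basis_correlation = 0.8, mu_sd = 1,
                                        eps_sd = 1, lib_size = 2e4, seed = 1L) {
  check_flag(n_asvs >= 2 * n_pairs, "need n_asvs >= 2 * n_pairs")
  check_flag(abs(basis_correlation) <= 1, "basis_correlation must lie in [-1, 1]")
  with_seed(sub_seed(seed, 3L), {
    ids <- sprintf("ASV_%04d", seq_len(n_asvs))
    mu <- rnorm(n_asvs, 0, mu_sd)
    eps <- matrix(rnorm(n_samples * n_asvs), n_samples, n_asvs)
    pairs <- NULL
    if (n_pairs > 0) {
      idx <- sample(n_asvs, 2 * n_pairs)
      a <- idx[seq_len(n_pairs)]
      b <- idx[n_pairs + seq_len(n_pairs)]
      r <- basis_correlation
      eps[, b] <- r * eps[, a] + sqrt(1 - r^2) * eps[, b]
      pairs <- data.frame(asv_a = pmin(ids[a], ids[b]),
                          asv_b = pmax(ids[a], ids[b]),
                          basis_correlation = r, stringsAsFactors = FALSE)
      pairs <- pairs[order(pairs$asv_a), , drop = FALSE]
    }
    logw <- sweep(eps * eps_sd, 2, mu, "+")
    counts <- matrix(0L, n_samples, n_asvs,
                     dimnames = list(sprintf("S%03d", seq_len(n_samples)), ids))
    for (s in seq_len(n_samples)) {
      w <- exp(logw[s, ] - max(logw[s, ]))
      counts[s, ] <- rmultinom(1, lib_size, w / sum(w))[, 1]
    }
    list(table = asv_table(counts),
         truth = list(planted_associations = pairs, seed = seed))
  })
}

#' Check that a planted-truth ledger resolves against generated tables
#'
#' @param truth a truth ledger from one of the generators.
#' @param asv_tab optional [asv_table()] the ASV ids must resolve against.
#' @param sequences optional named sequence vector.
#' @param metabo optional [metabo_table()] the feature ids must resolve
#'   against.
#' @param min_identity sister pairs must be at least this identical.
#' @return invisibly `TRUE`; errors describe the first inconsistency.
#' @export
validate_truth <- function(truth, asv_tab = NULL, sequences = NULL,
                           metabo = NULL, min_identity = 0.97) {
  if (!is.null(asv_tab)) {
    ids <- colnames(asv_tab$counts)
    miss <- setdiff(names(truth$responsive_ids), ids)
    check_flag(length(miss) == 0, "truth ids missing from ASV table: %s",
               paste(head(miss), collapse = ", "))
    sp <- truth$sister_pairs
    if (!is.null(sp) && nrow(sp) > 0) {
      check_flag(all(c(sp$asv_a, sp$asv_b) %in% ids),
                 "sister pair ids missing from ASV table")
      check_flag(all(sign(sp$slope_a) * sign(sp$slope_b) == -1),
                 "sister pair slopes must have opposite signs")
      check_flag(all(sp$identity >= min_identity),
                 "sister pair identity below threshold")
      if (!is.null(sequences)) {
        obs <- mapply(function(a, b) {
          ca <- strsplit(sequences[[a]], "")[[1]]
          cb <- strsplit(sequences[[b]], "")[[1]]
          mean(ca == cb)
        }, sp$asv_a, sp$asv_b)
        check_flag(all(abs(obs - sp$identity) < 1e-12),
                   "sequence identity does not match truth ledger")
      }
    }
  }
  if (!is.null(metabo)) {
    fid <- metabo$features$feature_id
    for (field in c("responsive_ids", "void_ids", "high_cv_ids", "ion_ids")) {
      v <- truth[[field]]
      v <- if (is.null(names(v))) v else names(v)
      if (is.null(v)) next
      miss <- setdiff(v, fid)
      check_flag(length(miss) == 0, "truth %s missing from feature table: %s",
                 field, paste(head(miss), collapse = ", "))
    }
  }
  invisible(TRUE)
}
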