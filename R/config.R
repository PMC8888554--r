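#' Default run configuration
#'
#' Houses every threshold the pipeline applies, at its published default:
#' void retention-time cutoff 40 s, QC CV cutoff 0.30, common-ASV mean
#' relative abundance 0.25%, sister-pair identity 0.97, water-mass split
#' 1000 m, VIP importance 1, pQ2 rejection 0.05, good-model gates R2X > 0.9
#' and Q2 > 0.5, edge significance 0.05 with 4-of-5 consensus votes,
#' network prevalence 3 samples, top-10 compound links. All values can be
#' overridden via `...`.
#'
#' @param ... named overrides of any config entry.
#' @return a named list of class `holodepth_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    void_rt_max = 40,          # s
    qc_cv_max = 0.30,
    common_threshold = 0.0025, # mean relative abundance
    sister_identity = 0.97,
    split_depth = 1000,        # m
    vip_min = 1,
    pq2_max = 0.05,
    r2x_min = 0.9,
    q2_min = 0.5,
    edge_p_max = 0.05,
    consensus_votes = 4,
    prevalence_min = 3,        # samples
    top_k = 10,
    alpha = 0.05,
    n_perm = 999,              # permutation tests (PERMANOVA, envfit, Mantel, Procrustes)
    n_perm_assoc = 99,         # per-edge permutations in the network stage
    n_perm_pq2 = 99,           # response permutations for pQ2
    n_bootstrap = 100,         # SparCC bootstraps
    n_ortho = 1,
    cv_folds = 7,
    network_max_asvs = 60,     # most abundant ASVs entering the network stage
    seed = 1L,
    # synthetic-study layout: three species, two community profiles
    species = c("Geodia_barretti", "Stryphnus_fortis", "Weberella_bursa"),
    profiles = c("HMA", "HMA", "LMA"),
    n_samples = c(14L, 15L, 16L),
    n_asvs = c(300L, 300L, 135L),
    n_sister_pairs = c(3L, 2L, 0L),
    frac_responsive = 0.3,
    effect_size = 4,
    experiments = c("HILIC_positive", "HILIC_negative", "RP_positive", "RP_negative"),
    filters = c("cleaned", "pc_group", "ion"),
    n_features = 120L,
    n_qc = 8L,
    output_dir = "holodepth_out"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  check_flag(length(unknown) == 0, "unknown config entr%s: %s",
             if (length(unknown) == 1) "y" else "ies",
             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "holodepth_config"
  cfg
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changing any threshold changes
#' the hash, so outputs are auditable against the settings that made them.
#'
#' @param config a [default_config()] list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "output_dir")]  # location, not a setting
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @return a `holodepth_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @rdname read_config
#' @param config configuration to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
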