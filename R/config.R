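# Pipeline configuration: defaults, validation, YAML round-trip.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_samples = 20L, mean_depth_tumor = 104, mean_depth_normal = 107,
      depth_dispersion = 0.002, purity = 0.8, probe_count = 3000L,
      n_genes = 60L, hrd_fraction = 0.23
    ),
    cnv = list(
      alpha = 0.05, min_probes = 10L, stat_threshold = 5,
      min_normal_depth = 10, min_arm_fraction = 0.6, max_components = 3L
    ),
    sv = list(
      n_true = 20L, n_artifact = 40L, true_sr_rate = 20, true_pe_rate = 20,
      artifact_sr_rate = 1, artifact_pe_rate = 1, myc_min_separation = 1e5,
      annotation_window = 1e6
    ),
    snv = list(
      min_alt = 4, min_vaf = 0.05, fractions = seq(0.1, 1, by = 0.1),
      plateau_gain = 0.02
    ),
    stats = list(
      alpha = 0.05, hypermutator_k = 3, panel_mb = 3.3,
      hazard_ratio = 1.46, baseline_rate = 0.02, censor_rate = 0.01,
      aid_length = 5000L, aid_density = 0.01, aid_n_mutations = 40L,
      aid_fraction = 0.8
    ),
    log_level = "info"
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and applies overrides given as nested
#' lists (e.g. `cohort = list(n_samples = 30)`). Unknown keys at any level
#' are rejected; value constraints (significance levels in (0, 1), purity
#' in (0, 1], positive depths) are checked before any stage runs.
#'
#' @param ... Nested overrides of the default blocks (`seed`, `cohort`,
#'   `cnv`, `sv`, `snv`, `stats`, `log_level`).
#' @return A list of class `mm_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- merge_config(default_pipeline_config(), overrides, path = "")
  validate_pipeline_config(cfg)
}

merge_config <- function(base, overrides, path) {
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in ", path) else "",
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(overrides)) {
    if (is.list(base[[k]]) && is.list(overrides[[k]])) {
      base[[k]] <- merge_config(base[[k]], overrides[[k]],
                                paste0(path, if (nzchar(path)) "$" else "", k))
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  assert_scalar_in(cfg$cnv$alpha, 0, 1, "cnv$alpha",
                   open_lo = TRUE, open_hi = TRUE)
  assert_scalar_in(cfg$stats$alpha, 0, 1, "stats$alpha",
                   open_lo = TRUE, open_hi = TRUE)
  assert_scalar_in(cfg$cohort$purity, 0, 1, "cohort$purity", open_lo = TRUE)
  if (cfg$cohort$n_samples < 1) abort("cohort$n_samples must be >= 1")
  if (cfg$cohort$mean_depth_tumor <= 0 || cfg$cohort$mean_depth_normal <= 0) {
    abort("mean depths must be > 0")
  }
  structure(cfg, class = "mm_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the blocks of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return A validated `mm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), raw, path = "")
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config A pipeline configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
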