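# Top-level driver: synthesize a cohort (or load user inputs) and chain
# CNV -> SV -> SNV -> integrative statistics, writing every stage's
# outputs, a resolved-config snapshot, a structured log, and a checksum
# manifest into one run directory.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes synthesize -> cnv -> sv -> snv -> stats with the parameters of
#' a [pipeline_config()]. Re-running with the same configuration
#' reproduces identical outputs bit-for-bit (all randomness flows from the
#' config seed through named substreams).
#'
#' @param config An `mm_pipeline_config` (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir Run directory, created if needed.
#' @return Invisibly, a list of the in-memory stage results; files are the
#'   primary output.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "mm_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_event <- function(stage, event, ...) {
    line <- sprintf("%s\t%s\t%s", stage, event,
                    paste(sprintf("%s=%s", names(list(...)),
                                  unlist(list(...))), collapse = " "))
    log_lines <<- c(log_lines, line)
  }
  p <- function(...) file.path(out_dir, ...)
  cfg <- config

  ## ---- synthesize ----
  cc <- cohort_config(
    n_samples = cfg$cohort$n_samples,
    mean_depth_tumor = cfg$cohort$mean_depth_tumor,
    mean_depth_normal = cfg$cohort$mean_depth_normal,
    depth_dispersion = cfg$cohort$depth_dispersion,
    purity = cfg$cohort$purity,
    probe_count = cfg$cohort$probe_count,
    seed = cfg$seed
  )
  panel <- make_panel(cc, panel_spec(n_genes = cfg$cohort$n_genes))
  truth <- simulate_cnv_truth(panel, cc, hrd_fraction = cfg$cohort$hrd_fraction)
  depths <- simulate_depths(panel, truth, cc)
  write_bed(panel, p("panel.bed"))
  write_depths(depths$tumor, p("tumor_depths.tsv"))
  write_depths(depths$normal, p("normal_depths.tsv"))
  readr::write_tsv(truth, p("cnv_truth.tsv"))
  log_event("synth", "cohort", n_samples = cc$n_samples,
            probes = nrow(panel))

  sv_sim <- simulate_sv_candidates(
    n_true = cfg$sv$n_true, n_artifact = cfg$sv$n_artifact,
    true_sr_rate = cfg$sv$true_sr_rate, true_pe_rate = cfg$sv$true_pe_rate,
    artifact_sr_rate = cfg$sv$artifact_sr_rate,
    artifact_pe_rate = cfg$sv$artifact_pe_rate,
    n_samples = cc$n_samples, include_normals = TRUE,
    seed = substream_seed(cfg$seed, "sv_stage")
  )
  write_bedpe(sv_sim$candidates, p("sv_candidates.bedpe"))

  gene_feats <- intersect(
    c("NRAS", "KRAS", "FAM46C", "TP53", "DIS3", "BRAF", "IGLL5"),
    c(panel$gene, "IGLL5")
  )
  freqs <- setNames(
    c(0.24, 0.21, 0.17, 0.09, 0.09, 0.03, 0.18),
    c("NRAS", "KRAS", "FAM46C", "TP53", "DIS3", "BRAF", "IGLL5")
  )[gene_feats]
  interactions <- tibble(feature_a = "IGLL5", feature_b = "NRAS",
                         log_odds = -3)
  truth_matrix <- simulate_mutation_matrix(
    freqs, interactions, n_samples = cc$n_samples,
    seed = substream_seed(cfg$seed, "matrix_stage")
  )
  gene_panel <- if ("IGLL5" %in% panel$gene) panel else {
    igl <- panel[panel$region_class == "IGL", , drop = FALSE]
    if (nrow(igl) > 0) igl$gene <- "IGLL5"
    bind_rows(panel[panel$gene != "IGL", , drop = FALSE], igl)
  }
  variants <- simulate_variant_calls(
    truth_matrix, gene_panel, mean_depth = cc$mean_depth_tumor,
    purity = cc$purity, seed = substream_seed(cfg$seed, "variants_stage")
  )
  write_variants(variants, p("variants.tsv"))
  log_event("synth", "variants", n = nrow(variants))

  aid <- simulate_aid_sequence(
    length = cfg$stats$aid_length, target_wrcy_density = cfg$stats$aid_density,
    n_mutations = cfg$stats$aid_n_mutations,
    aid_fraction = cfg$stats$aid_fraction,
    seed = substream_seed(cfg$seed, "aid_stage")
  )
  writeLines(aid$sequence, p("aid_sequence.txt"))
  readr::write_tsv(aid$variants, p("aid_variants.tsv"))

  ## ---- cnv ----
  track <- compute_log2_ratios(depths$tumor, depths$normal,
                               min_normal_depth = cfg$cnv$min_normal_depth) |>
    annotate_track(panel)
  segments <- segment_track(track, min_probes = cfg$cnv$min_probes,
                            stat_threshold = cfg$cnv$stat_threshold)
  noise <- purrr::map(unique(track$sample_id), function(sid) {
    fit_noise_model(track, sample = sid,
                    max_components = cfg$cnv$max_components,
                    alpha = cfg$cnv$alpha,
                    seed = substream_seed(cfg$seed, paste0("noise_", sid)))
  })
  names(noise) <- unique(track$sample_id)
  calls <- filter_segments(segments, noise, alpha = cfg$cnv$alpha)
  arm_events <- call_arm_events(calls,
                                min_arm_fraction = cfg$cnv$min_arm_fraction)
  hrd <- detect_hyperdiploidy(arm_events)
  readr::write_tsv(segments, p("segments.tsv"))
  readr::write_tsv(calls, p("cnv_calls.tsv"))
  readr::write_tsv(arm_events, p("arm_events.tsv"))
  readr::write_tsv(hrd, p("hyperdiploidy.tsv"))
  log_event("cnv", "calls", n_segments = nrow(segments),
            n_events = sum(calls$state != "neutral"))

  ## ---- sv ----
  cand <- sv_sim$candidates
  tumor_cand <- cand[!cand$is_normal, , drop = FALSE]
  thresholds <- tune_thresholds(tumor_cand)
  somatic <- apply_thresholds(tumor_cand, thresholds)
  myc_thresholds <- tune_normal_panel(cand)
  somatic_np <- apply_thresholds(tumor_cand, myc_thresholds)
  classified <- classify_translocation(
    somatic, myc_min_separation = cfg$sv$myc_min_separation
  )
  annotation <- annotate_breakpoints(
    classified,
    gene_bed = panel |>
      group_by(.data$gene) |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), .groups = "drop") |>
      select("chrom", "start", "end", "gene"),
    window = cfg$sv$annotation_window
  )
  readr::write_tsv(tidy(thresholds), p("sv_thresholds.tsv"))
  readr::write_tsv(tidy(myc_thresholds), p("sv_normal_panel_thresholds.tsv"))
  write_bedpe(classified |> mutate(class = as.character(.data$class)) |>
                select(-dplyr::any_of(c("is_true", "class"))),
              p("sv_somatic.bedpe"))
  readr::write_tsv(classified |>
                     select("candidate_id", "sample_id", "class"),
                   p("sv_classes.tsv"))
  readr::write_tsv(annotation, p("sv_breakpoint_genes.tsv"))
  log_event("sv", "filtered", retained = nrow(somatic),
            normal_panel_retained = nrow(somatic_np),
            precision = thresholds$achieved_precision)

  ## ---- snv ----
  filtered <- filter_variants(variants)
  readr::write_tsv(filtered, p("variants_filtered.tsv"))
  readr::write_tsv(variant_drop_log(filtered) |>
                     dplyr::count(.data$drop_reason),
                   p("variant_filter_log.tsv"))
  # emulate a deep re-sequencing run: re-draw read counts at 10x depth
  # around each variant's underlying allele fraction
  deep <- with_seed(substream_seed(cfg$seed, "deep_rerun"), {
    depth10 <- 10L * (variants$ref_count + variants$alt_count)
    alt10 <- rbinom(nrow(variants), depth10, pmin(pmax(variants$vaf, 0), 1))
    variants |>
      mutate(ref_count = depth10 - alt10, alt_count = alt10,
             vaf = ifelse(depth10 > 0, alt10 / depth10, 0))
  })
  matched <- match_variants(filter_variants(variants), filter_variants(deep))
  concord <- vaf_concordance(matched)
  curve <- yield_curve(deep, fractions = cfg$snv$fractions,
                       min_alt = cfg$snv$min_alt, min_vaf = cfg$snv$min_vaf,
                       plateau_gain = cfg$snv$plateau_gain,
                       seed = substream_seed(cfg$seed, "yield"))
  clonality <- summarize_clonality(filtered, calls)
  readr::write_tsv(concord, p("vaf_concordance.tsv"))
  readr::write_tsv(
    curve |> mutate(r_squared = attr(curve, "r_squared"),
                    plateau_fraction = attr(curve, "plateau_fraction")),
    p("yield_curve.tsv")
  )
  readr::write_tsv(clonality, p("clonality.tsv"))
  log_event("snv", "filtering", kept = nrow(filtered),
            dropped = nrow(variant_drop_log(filtered)))

  ## ---- stats ----
  mat <- build_matrix(
    filtered, arm_events,
    classified |> select("sample_id", "class"),
    feature_spec = list(
      composites = list(RAS = c("KRAS", "NRAS")),
      hyperdiploidy = hrd
    ),
    sample_ids = sprintf("S%03d", seq_len(cc$n_samples)),
    panel_mb = cfg$stats$panel_mb
  )
  mat2 <- exclude_hypermutators(mat, k = cfg$stats$hypermutator_k)
  assoc <- pairwise_association(mat2, alpha = cfg$stats$alpha)
  aid_res <- aid_signature_test(aid$variants, aid$sequence)
  expr <- with_seed(substream_seed(cfg$seed, "expression"), {
    vals <- stats::rlnorm(cc$n_samples, meanlog = 1, sdlog = 0.3)
    vals[seq_len(max(1, round(0.05 * cc$n_samples)))] <-
      exp(1) * 6 # planted DERL3-style overexpression
    tibble(sample_id = mat$sample_id, value = vals)
  })
  outliers <- expression_outliers(expr)
  surv <- simulate_survival(
    truth_matrix, "IGLL5", hazard_ratio = cfg$stats$hazard_ratio,
    baseline_rate = cfg$stats$baseline_rate,
    censor_rate = cfg$stats$censor_rate,
    seed = substream_seed(cfg$seed, "survival_stage")
  )
  km <- km_curve(surv)
  if (length(unique(surv$group)) == 2) {
    lr <- logrank_test(surv)
    cox <- suppressWarnings(cox_hr(surv))
  } else {
    # degenerate tiny cohort: no mutant/WT contrast to test
    lr <- tibble(statistic = NA_real_, df = 1L, p_value = NA_real_,
                 group_1 = NA_character_, observed_1 = NA_real_,
                 expected_1 = NA_real_)
    cox <- new_mm_cox(NA, NA, NA, NA, NA, nrow(surv), sum(surv$event),
                      0.95, NA_character_, estimable = FALSE)
    log_event("stats", "survival_skipped", reason = "single_group")
  }
  readr::write_tsv(as_tibble(as.data.frame(unclass(mat))), p("matrix.tsv"))
  jsonlite::write_json(as.list(feature_types(mat)), p("matrix_features.json"),
                       auto_unbox = TRUE)
  readr::write_tsv(assoc, p("associations.tsv"))
  readr::write_tsv(aid_res, p("aid_test.tsv"))
  readr::write_tsv(outliers, p("expression_outliers.tsv"))
  write_survival(surv, p("survival.tsv"))
  readr::write_tsv(as_tibble(km), p("km_curve.tsv"))
  readr::write_tsv(lr, p("logrank.tsv"))
  readr::write_tsv(glance(cox), p("cox.tsv"))
  log_event("stats", "association", n_pairs = nrow(assoc),
            significant = sum(assoc$direction != "none"))

  ## ---- provenance ----
  write_pipeline_config(cfg, p("resolved_config.yaml"))
  writeLines(c("stage\tevent\tdetails", log_lines), p("run_log.tsv"))
  outputs <- setdiff(list.files(out_dir), c("manifest.tsv"))
  manifest <- tibble(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(out_dir, outputs)))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))

  invisible(list(
    panel = panel, truth = truth, track = track, segments = segments,
    calls = calls, arm_events = arm_events, hyperdiploidy = hrd,
    sv = list(thresholds = thresholds, normal_panel = myc_thresholds,
              somatic = classified, annotation = annotation),
    variants = filtered, concordance = concord, yield = curve,
    clonality = clonality, matrix = mat2, associations = assoc,
    aid = aid_res, outliers = outliers, survival = surv,
    km = km, logrank = lr, cox = cox
  ))
}
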