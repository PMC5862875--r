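# Noise-filtered CNV calls, arm-level events, and hyperdiploidy scoring.

CNV_STATES <- c("homozygous_loss", "loss", "neutral", "gain", "amplification")

#' Filter segments against the diploid noise model and assign CNV states
#'
#' A segment is retained (non-neutral) iff its mean log2 ratio lies outside
#' the noise band AND the two-sided tail probability of its mean under the
#' diploid component (sd scaled by `1/sqrt(n_probes)`) is below `alpha`.
#' Retained segments get a state from fixed cut-points bracketing the
#' clonal landmarks `log2(1/2) = -1` and `log2(3/2) = 0.58`:
#' `<= -1.6` homozygous_loss, `(-1.6, band_low)` loss, `(band_high, 1)`
#' gain, `>= 1` amplification.
#'
#' @param segments Segment tibble from [segment_track()].
#' @param noise An [fit_noise_model()] object, or a named list of them
#'   keyed by sample id for multi-sample segment tables.
#' @param alpha Significance level for the diploid tail test.
#' @param cut_homozygous,cut_amplification State cut-points on `mean_lr`.
#' @return The segments with `p_value` and `state` columns (a CNV call
#'   table).
#' @export
filter_segments <- function(segments, noise, alpha = 0.05,
                            cut_homozygous = -1.6, cut_amplification = 1.0) {
  assert_cols(segments, c("sample_id", "mean_lr", "n_probes"))
  get_model <- function(sid) {
    if (inherits(noise, "mm_noise_model")) return(noise)
    m <- noise[[sid]]
    if (is.null(m)) abort(sprintf("no noise model supplied for sample %s", sid))
    m
  }
  segments |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, g) {
      m <- get_model(g$sample_id)
      mu <- m$components$mean[m$diploid_index]
      sdv <- m$components$sd[m$diploid_index]
      se <- sdv / sqrt(d$n_probes)
      p <- pmin(1, 2 * pnorm(-abs(d$mean_lr - mu) / se))
      outside <- d$mean_lr < m$band_low | d$mean_lr > m$band_high
      keep <- outside & p < alpha
      state <- dplyr::case_when(
        !keep ~ "neutral",
        d$mean_lr <= cut_homozygous ~ "homozygous_loss",
        d$mean_lr < m$band_low ~ "loss",
        d$mean_lr >= cut_amplification ~ "amplification",
        d$mean_lr > m$band_high ~ "gain",
        TRUE ~ "neutral"
      )
      mutate(d, p_value = p, state = factor(state, levels = CNV_STATES))
    }) |>
    ungroup() |>
    dplyr::relocate("sample_id")
}

#' Call arm-level gains and losses from filtered segments
#'
#' An arm is called gained (lost) for a sample when its retained segments
#' of that sign jointly cover at least `min_arm_fraction` of the arm's
#' usable probes.
#'
#' @param calls CNV call tibble from [filter_segments()].
#' @param min_arm_fraction Minimum covered fraction of arm probes.
#' @return A tibble per (sample, arm): `chrom`, `arm`, `gain_fraction`,
#'   `loss_fraction`, `status` in `gain`/`loss`/`none`.
#' @export
call_arm_events <- function(calls, min_arm_fraction = 0.6) {
  assert_cols(calls, c("sample_id", "chrom", "arm", "n_probes",
                       "arm_n_probes", "state"))
  calls |>
    group_by(.data$sample_id, .data$chrom, .data$arm) |>
    summarise(
      gain_fraction = sum(.data$n_probes[.data$state %in%
                                           c("gain", "amplification")]) /
        .data$arm_n_probes[1],
      loss_fraction = sum(.data$n_probes[.data$state %in%
                                           c("loss", "homozygous_loss")]) /
        .data$arm_n_probes[1],
      .groups = "drop"
    ) |>
    mutate(status = dplyr::case_when(
      .data$gain_fraction >= min_arm_fraction ~ "gain",
      .data$loss_fraction >= min_arm_fraction ~ "loss",
      TRUE ~ "none"
    ))
}

#' Score hyperdiploidy from arm-level events
#'
#' Counts the odd chromosomes (3, 5, 7, 9, 11, 15, 19, 21) for which every
#' arm present in the table is gained (for acrocentric chromosomes only the
#' q arm exists, so a q gain suffices). Sex chromosomes never contribute.
#'
#' @param arm_events Arm-event tibble from [call_arm_events()] (all arms,
#'   not only events).
#' @param min_chromosomes Trisomy count required to flag hyperdiploidy.
#' @return A tibble per sample: `hrd_score`, `hyperdiploid`.
#' @export
detect_hyperdiploidy <- function(arm_events, min_chromosomes = 2) {
  assert_cols(arm_events, c("sample_id", "chrom", "arm", "status"))
  odd <- paste0("chr", c(3, 5, 7, 9, 11, 15, 19, 21))
  arm_events |>
    dplyr::filter(.data$chrom %in% odd) |>
    group_by(.data$sample_id, .data$chrom) |>
    summarise(whole_gain = all(.data$status == "gain"), .groups = "drop") |>
    group_by(.data$sample_id) |>
    summarise(hrd_score = sum(.data$whole_gain), .groups = "drop") |>
    mutate(hyperdiploid = .data$hrd_score >= min_chromosomes)
}
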