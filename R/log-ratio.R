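# Per-probe log2 tumor/normal depth ratios, median-normalized on autosomes.

#' Compute normalized log2 tumor/normal depth ratios
#'
#' For each probe, `log2_ratio = log2(max(tumor, eps) / max(normal, eps)) - m`,
#' where `m` is the per-sample autosomal median of the uncorrected ratios
#' over unmasked probes. The floor pseudo-count `eps` only matters for
#' zero tumor depths, so clonal landmarks stay exact: a single-copy gain
#' (3 vs 2 copies) sits at `log2(3/2) = 0.58` and a single-copy loss at
#' `log2(1/2) = -1`. Probes with normal depth below `min_normal_depth` are
#' masked (excluded from normalization, segmentation, and the noise model).
#'
#' @param tumor_depths,normal_depths Depth tibbles (`probe_id`, `chrom`,
#'   `start`, `end`, `sample_id`, `depth`) over an identical probe set.
#' @param min_normal_depth Mask probes whose normal depth falls below this.
#' @param eps Depth floor guarding `log2(0)`.
#' @return A tibble (one row per probe per sample): `probe_id`, `chrom`,
#'   `start`, `end`, `arm` (if present in inputs), `sample_id`,
#'   `log2_ratio`, `masked`; per-sample normalization factors are stored in
#'   the `normalization` attribute.
#' @export
compute_log2_ratios <- function(tumor_depths, normal_depths,
                                min_normal_depth = 10, eps = 0.5) {
  assert_cols(tumor_depths, c("probe_id", "chrom", "start", "sample_id", "depth"))
  assert_cols(normal_depths, c("probe_id", "sample_id", "depth"))

  key <- c("probe_id", "sample_id")
  a <- arrange(tumor_depths, .data$sample_id, chrom_rank(.data$chrom), .data$start)
  b <- normal_depths |>
    select(dplyr::all_of(key), normal_depth = "depth")
  merged <- left_join(a, b, by = key)
  if (nrow(merged) != nrow(a) || anyNA(merged$normal_depth)) {
    bad <- merged[which(is.na(merged$normal_depth))[1], ]
    abort(sprintf(
      "tumor and normal depth tables do not share an identical probe set (first mismatch: probe %s, sample %s)",
      bad$probe_id %||% "?", bad$sample_id %||% "?"
    ))
  }
  if (nrow(merged) != nrow(normal_depths)) {
    extra <- anti_join(normal_depths, tumor_depths, by = key)
    abort(sprintf(
      "tumor and normal depth tables do not share an identical probe set (first mismatch: probe %s, sample %s)",
      extra$probe_id[1], extra$sample_id[1]
    ))
  }

  track <- merged |>
    mutate(
      masked = .data$normal_depth < min_normal_depth,
      lr_raw = log2(pmax(.data$depth, eps) / pmax(.data$normal_depth, eps))
    ) |>
    group_by(.data$sample_id) |>
    mutate(
      norm_m = median(.data$lr_raw[!.data$masked & is_autosome(.data$chrom)]),
      log2_ratio = if_else(.data$masked, NA_real_, .data$lr_raw - .data$norm_m)
    ) |>
    ungroup()

  norm <- distinct(track, .data$sample_id, .data$norm_m)
  out <- track |>
    select(-"depth", -"normal_depth", -"lr_raw", -"norm_m")
  attr(out, "normalization") <- norm
  out
}
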