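# Recursive binary segmentation of log2-ratio tracks on mean shift.

#' Attach panel annotation (arm, gene, region class) to a track
#'
#' @param track A track or depth tibble carrying `probe_id`.
#' @param panel A probe panel from [make_panel()] or [read_bed()].
#' @return The track with `arm`, `gene`, `region_class` columns joined.
#' @export
annotate_track <- function(track, panel) {
  assert_cols(track, "probe_id")
  assert_cols(panel, c("probe_id", "arm"))
  cols <- intersect(c("arm", "gene", "region_class"), names(panel))
  track |>
    select(-dplyr::any_of(cols)) |>
    left_join(panel[c("probe_id", cols)], by = "probe_id")
}

#' Segment a log2-ratio track by recursive binary splitting
#'
#' Within each (sample, chromosome arm), the probe maximizing the
#' two-sample t-statistic between left and right means is proposed as a
#' breakpoint; the split is accepted when the statistic exceeds
#' `stat_threshold` and both sides keep at least `min_probes` probes, then
#' both sides are segmented recursively. Arms are contiguous within a
#' chromosome, so the segments partition each chromosome's unmasked probes
#' and each segment maps to exactly one arm. Masked probes are excluded.
#'
#' @param track A log2-ratio track from [compute_log2_ratios()], annotated
#'   with `arm` (see [annotate_track()]).
#' @param min_probes Minimum probes per segment.
#' @param stat_threshold t-statistic required to accept a split.
#' @return A tibble of segments: `sample_id`, `chrom`, `arm`, `start`,
#'   `end`, `first_probe`, `last_probe`, `n_probes`, `mean_lr`,
#'   `arm_n_probes` (total unmasked probes on that arm).
#' @export
segment_track <- function(track, min_probes = 10, stat_threshold = 5) {
  assert_cols(track, c("sample_id", "chrom", "arm", "start", "end",
                       "log2_ratio", "masked"))
  usable <- track |>
    dplyr::filter(!.data$masked) |>
    arrange(.data$sample_id, chrom_rank(.data$chrom), .data$start)

  usable |>
    group_by(.data$sample_id, .data$chrom, .data$arm) |>
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < min_probes) {
        warn(sprintf(
          "arm %s of %s has %d < %d usable probes; emitting a single segment",
          g$arm, g$sample_id, nrow(d), min_probes
        ))
      }
      cuts <- rbs_splits(d$log2_ratio, min_probes, stat_threshold)
      bounds <- c(0L, cuts, nrow(d))
      purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
        lo <- bounds[i] + 1L
        hi <- bounds[i + 1L]
        tibble(
          start = d$start[lo], end = d$end[hi],
          first_probe = d$probe_id[lo], last_probe = d$probe_id[hi],
          n_probes = hi - lo + 1L,
          mean_lr = mean(d$log2_ratio[lo:hi]),
          arm_n_probes = nrow(d)
        )
      })
    }) |>
    ungroup() |>
    select("sample_id", "chrom", "arm", "start", "end", "first_probe",
           "last_probe", "n_probes", "mean_lr", "arm_n_probes")
}

# Indices i such that a segment boundary falls between x[i] and x[i+1].
rbs_splits <- function(x, min_probes, stat_threshold) {
  n <- length(x)
  if (n < 2L * min_probes) return(integer())
  s <- cumsum(x)
  ss <- cumsum(x^2)
  idx <- seq.int(min_probes, n - min_probes)
  n1 <- idx
  n2 <- n - idx
  m1 <- s[idx] / n1
  m2 <- (s[n] - s[idx]) / n2
  rss <- (ss[idx] - n1 * m1^2) + (ss[n] - ss[idx] - n2 * m2^2)
  pooled <- pmax(rss / (n - 2L), 1e-12)
  tstat <- abs(m1 - m2) / sqrt(pooled * (1 / n1 + 1 / n2))
  best <- which.max(tstat)
  if (tstat[best] <= stat_threshold) return(integer())
  cut <- idx[best]
  c(rbs_splits(x[seq_len(cut)], min_probes, stat_threshold),
    cut,
    cut + rbs_splits(x[seq.int(cut + 1L, n)], min_probes, stat_threshold))
}
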