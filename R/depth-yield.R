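# Read-count downsampling, the variants-vs-depth yield curve, and the
# diploid-locus clonality summary.

#' Binomially thin variant read counts
#'
#' `ref_count` and `alt_count` are independently thinned at the given
#' fraction and the VAF recomputed; fraction 1 is the identity, fraction 0
#' zeroes all counts. Emulates downsampling the sequencing reads.
#'
#' @param calls Variant call tibble with `ref_count`, `alt_count`.
#' @param fraction Retention fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The calls with thinned counts and recomputed `vaf` (NA where
#'   both counts hit zero).
#' @export
downsample_counts <- function(calls, fraction, seed = 1L) {
  assert_cols(calls, c("ref_count", "alt_count"))
  assert_scalar_in(fraction, 0, 1, "fraction")
  if (fraction == 1) return(calls)
  with_seed(substream_seed(seed, paste0("downsample_", fraction)), {
    out <- calls
    out$ref_count <- rbinom(nrow(calls), calls$ref_count, fraction)
    out$alt_count <- rbinom(nrow(calls), calls$alt_count, fraction)
    tot <- out$ref_count + out$alt_count
    out$vaf <- ifelse(tot > 0, out$alt_count / tot, NA_real_)
    out
  })
}

#' Variant yield as a function of sequencing depth
#'
#' Thins the calls at each fraction, applies the detection rule
#' (`alt_count >= min_alt` and `vaf >= min_vaf`), and reports the number of
#' detected variants against the resulting mean depth, the R-squared of a
#' linear fit of detections on depth, and the plateau fraction: the
#' smallest fraction beyond which every marginal gain per step stays below
#' `plateau_gain` (relative to the detections at that step).
#'
#' @param calls Variant call tibble with `ref_count`, `alt_count`.
#' @param fractions Increasing vector of retention fractions.
#' @param min_alt,min_vaf Detection rule (defaults: alt reads >= 4 and
#'   VAF >= 5%).
#' @param plateau_gain Relative per-step gain below which the curve is
#'   considered flat.
#' @param seed Integer seed.
#' @return A tibble (`fraction`, `mean_depth`, `n_detected`) with
#'   attributes `r_squared` and `plateau_fraction` (NA when the curve never
#'   flattens).
#' @export
yield_curve <- function(calls, fractions = seq(0.1, 1, by = 0.1),
                        min_alt = 4, min_vaf = 0.05,
                        plateau_gain = 0.02, seed = 1L) {
  stopifnot(length(fractions) >= 1, !is.unsorted(fractions))
  rows <- purrr::map_dfr(fractions, function(f) {
    thinned <- downsample_counts(calls, f, seed = seed)
    detected <- thinned$alt_count >= min_alt &
      !is.na(thinned$vaf) & thinned$vaf >= min_vaf
    tibble(
      fraction = f,
      mean_depth = mean(thinned$ref_count + thinned$alt_count),
      n_detected = sum(detected)
    )
  })
  r2 <- if (nrow(rows) >= 3 && sd(rows$n_detected) > 0) {
    stats::cor(rows$mean_depth, rows$n_detected)^2
  } else {
    NA_real_
  }
  plateau <- NA_real_
  if (nrow(rows) >= 2) {
    gain <- diff(rows$n_detected) / pmax(rows$n_detected[-nrow(rows)], 1)
    for (i in seq_along(gain)) {
      if (all(gain[i:length(gain)] < plateau_gain)) {
        plateau <- rows$fraction[i]
        break
      }
    }
  }
  attr(rows, "r_squared") <- r2
  attr(rows, "plateau_fraction") <- plateau
  attr(rows, "detection_rule") <- list(min_alt = min_alt, min_vaf = min_vaf)
  rows
}

#' Summarise clonality of variants at diploid loci
#'
#' Restricts variants to loci with no overlapping non-neutral CNV call in
#' the same sample, then reports per-gene VAF quantiles (linear
#' interpolation between order statistics). A clonal heterozygous variant
#' in a pure diploid tumor sits near VAF 50%.
#'
#' @param calls Variant call tibble with `sample_id`, `chrom`, `pos`
#'   (1-based), `gene`, `vaf`.
#' @param cnv_calls CNV call tibble from [filter_segments()] (0-based
#'   half-open segments); may be `NULL` for an all-diploid assumption.
#' @return A tibble per gene: `n`, `vaf_q1`, `vaf_median`, `vaf_q3`.
#' @export
summarize_clonality <- function(calls, cnv_calls = NULL) {
  assert_cols(calls, c("sample_id", "chrom", "pos", "gene", "vaf"))
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    assert_cols(cnv_calls, c("sample_id", "chrom", "start", "end", "state"))
    events <- cnv_calls[cnv_calls$state != "neutral", , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      hit <- calls$sample_id == events$sample_id[i] &
        calls$chrom == events$chrom[i] &
        calls$pos - 1 >= events$start[i] &
        calls$pos - 1 < events$end[i]
      keep[hit] <- FALSE
    }
  }
  calls[keep, , drop = FALSE] |>
    group_by(.data$gene) |>
    summarise(
      n = n(),
      vaf_q1 = mm_quantile(.data$vaf, 0.25),
      vaf_median = mm_quantile(.data$vaf, 0.5),
      vaf_q3 = mm_quantile(.data$vaf, 0.75),
      .groups = "drop"
    )
}
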