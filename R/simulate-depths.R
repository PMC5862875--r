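# Synthetic cohort: configuration, planted copy-number truth, and paired
# per-probe capture depths.

#' Configure a synthetic tumor/normal capture cohort
#'
#' Defaults follow the study conditions the pipeline is designed for: a
#' 95-pair cohort sequenced to mean depths of 104x (tumor) and 107x
#' (normal). Purity is a single scalar per tumor (clonal events only).
#'
#' @param n_samples Number of tumor/normal pairs (>= 1).
#' @param mean_depth_tumor,mean_depth_normal Mean per-probe depth (reads).
#' @param depth_dispersion Negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`. `0` gives Poisson depths.
#' @param purity Tumor purity, fraction in (0, 1].
#' @param probe_count Total probes on the panel.
#' @param seed Integer root seed; all generators derive named substreams
#'   from it.
#' @return A validated list of class `mm_cohort_config`.
#' @export
cohort_config <- function(n_samples = 95,
                          mean_depth_tumor = 104,
                          mean_depth_normal = 107,
                          depth_dispersion = 0.002,
                          purity = 0.8,
                          probe_count = 5000,
                          seed = 1L) {
  stopifnot(n_samples >= 1, probe_count >= 1)
  assert_scalar_in(purity, 0, 1, "purity", open_lo = TRUE)
  assert_scalar_in(mean_depth_tumor, 0, Inf, "mean_depth_tumor", open_lo = TRUE)
  assert_scalar_in(mean_depth_normal, 0, Inf, "mean_depth_normal", open_lo = TRUE)
  assert_scalar_in(depth_dispersion, 0, Inf, "depth_dispersion")
  structure(
    list(
      n_samples = as.integer(n_samples),
      mean_depth_tumor = mean_depth_tumor,
      mean_depth_normal = mean_depth_normal,
      depth_dispersion = depth_dispersion,
      purity = purity,
      probe_count = as.integer(probe_count),
      seed = as.integer(seed)
    ),
    class = "mm_cohort_config"
  )
}

#' Plant clonal copy-number truth for a cohort
#'
#' Assigns each sample either a hyperdiploid profile (whole-chromosome gains
#' of a random subset of the odd chromosomes 3, 5, 7, 9, 11, 15, 19, 21) or
#' a set of arm-level/focal events (deletions and gains of the recurrently
#' altered arms), emulating the two myeloma CNV subtypes.
#'
#' @param panel A probe panel from [make_panel()].
#' @param config A [cohort_config()].
#' @param hrd_fraction Fraction of samples given a hyperdiploid profile.
#' @param events_per_sample Mean number of arm events for non-HRD samples.
#' @return A tibble of truth events: `sample_id`, `chrom`, `arm`, `start`,
#'   `end`, `cn` (total copy number, never 2).
#' @export
simulate_cnv_truth <- function(panel, config, hrd_fraction = 0.23,
                               events_per_sample = 2) {
  arms <- panel |>
    group_by(.data$chrom, .data$arm) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  odd <- paste0("chr", c(3, 5, 7, 9, 11, 15, 19, 21))
  with_seed(substream_seed(config$seed, "cnv_truth"), {
    purrr::map_dfr(seq_len(config$n_samples), function(i) {
      sid <- sprintf("S%03d", i)
      if (runif(1) < hrd_fraction) {
        gained <- sample(intersect(odd, arms$chrom),
                         size = min(5, length(intersect(odd, arms$chrom))))
        ev <- dplyr::filter(arms, .data$chrom %in% gained)
        if (nrow(ev) == 0) return(tibble())
        ev$cn <- 3L
      } else {
        k <- max(1L, rpois(1, events_per_sample))
        idx <- sample(nrow(arms), size = min(k, nrow(arms)))
        ev <- arms[idx, ]
        ev$cn <- sample(c(1L, 3L), nrow(ev), replace = TRUE)
      }
      mutate(ev, sample_id = sid, .before = 1)
    })
  })
}

#' Simulate paired per-probe capture depths with planted CNVs
#'
#' Normal depth is negative-binomial around `mean_depth_normal`. Tumor depth
#' is negative-binomial around `mean_depth_tumor * (purity * cn/2 +
#' (1 - purity))` on probes covered by a truth event of copy number `cn`,
#' and around `mean_depth_tumor` elsewhere.
#'
#' @param panel A probe panel from [make_panel()].
#' @param truth A truth tibble from [simulate_cnv_truth()] (columns
#'   `sample_id`, `chrom`, `start`, `end`, `cn`); may have zero rows.
#' @param config A [cohort_config()].
#' @return A list of two tibbles, `tumor` and `normal`, each with columns
#'   `probe_id`, `chrom`, `start`, `end`, `sample_id`, `depth`.
#' @export
simulate_depths <- function(panel, truth, config) {
  stopifnot(inherits(config, "mm_cohort_config"))
  if (nrow(truth) > 0) {
    assert_cols(truth, c("sample_id", "chrom", "start", "end", "cn"))
    span_ok <- purrr::pmap_lgl(
      truth[c("chrom", "start", "end")],
      function(chrom, start, end) {
        p <- panel[panel$chrom == chrom, ]
        nrow(p) > 0 && start < max(p$end) && end > min(p$start)
      }
    )
    if (!all(span_ok)) {
      bad <- which(!span_ok)[1]
      abort(sprintf(
        "truth event %d (%s:%g-%g) lies outside the panel span",
        bad, truth$chrom[bad], truth$start[bad], truth$end[bad]
      ))
    }
    if (any(truth$cn == 2L)) abort("copy number 2 truth events are no-ops; remove them")
    overlap_bad <- truth |>
      group_by(.data$sample_id, .data$chrom) |>
      arrange(.data$start, .by_group = TRUE) |>
      summarise(bad = n() > 1 && any(.data$start[-1] < .data$end[-n()]),
                .groups = "drop")
    if (any(overlap_bad$bad)) abort("truth events overlap within a sample")
  }

  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  n_probe <- nrow(panel)

  draw <- function(mu, disp) {
    if (disp <= 1e-12) rpois(length(mu), mu) else {
      rnbinom(length(mu), mu = mu, size = 1 / disp)
    }
  }

  with_seed(substream_seed(config$seed, "depths"), {
    per_sample <- purrr::map(sample_ids, function(sid) {
      cn <- rep(2, n_probe)
      if (nrow(truth) > 0) {
        ev <- truth[truth$sample_id == sid, ]
        for (j in seq_len(nrow(ev))) {
          hit <- panel$chrom == ev$chrom[j] &
            panel$start >= ev$start[j] & panel$start < ev$end[j]
          cn[hit] <- ev$cn[j]
        }
      }
      mu_t <- config$mean_depth_tumor *
        (config$purity * cn / 2 + (1 - config$purity))
      list(
        tumor = draw(mu_t, config$depth_dispersion),
        normal = draw(rep(config$mean_depth_normal, n_probe),
                      config$depth_dispersion)
      )
    })
    base <- panel[c("probe_id", "chrom", "start", "end")]
    make_tbl <- function(field) {
      purrr::map2_dfr(per_sample, sample_ids, function(d, sid) {
        mutate(base, sample_id = sid, depth = as.numeric(d[[field]]))
      })
    }
    list(tumor = make_tbl("tumor"), normal = make_tbl("normal"))
  })
}
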