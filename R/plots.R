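# Figure helpers. Cosmetic, non-contractual: every plot reads from the
# same tidy tables the writers emit.

#' Plot a log2-ratio track with segment means
#'
#' @param track A log2-ratio track (single sample, or pass `sample`).
#' @param segments Optional segment/call tibble from [segment_track()] or
#'   [filter_segments()] for the same sample.
#' @param sample Sample id to display when the track holds several.
#' @return A ggplot object.
#' @export
plot_log_ratio_track <- function(track, segments = NULL, sample = NULL) {
  if (!is.null(sample)) {
    track <- track[track$sample_id == sample, ]
    if (!is.null(segments)) segments <- segments[segments$sample_id == sample, ]
  }
  track <- track[!track$masked, ]
  track$chrom <- factor(track$chrom,
                        levels = unique(track$chrom[order(chrom_rank(track$chrom))]))
  gg <- ggplot2::ggplot(track, ggplot2::aes(x = .data$start,
                                            y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = c(log2(3 / 2), 0, -1),
                        linetype = c("dashed", "solid", "dashed"),
                        linewidth = 0.3, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "log2 tumor/normal depth ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.5, "pt"))
  if (!is.null(segments)) {
    segments$chrom <- factor(segments$chrom, levels = levels(track$chrom))
    gg <- gg + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_lr, yend = .data$mean_lr),
      colour = "blue", linewidth = 1
    )
  }
  gg
}

#' Oncoprint-style plot of a mutation matrix
#'
#' @param object An `mm_matrix`.
#' @param ... Unused.
#' @return A ggplot object (samples as columns, features as rows).
#' @export
autoplot.mm_matrix <- function(object, ...) {
  long <- as_tibble(as.data.frame(unclass(object))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature",
                        values_to = "mutated")
  long$feature <- factor(long$feature, levels = rev(names(feature_types(object))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$feature,
                                     fill = factor(.data$mutated))) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "#2c5d9e"),
                               guide = "none") +
    ggplot2::labs(x = "sample", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Kaplan-Meier plot
#'
#' @param object An `mm_km` from [km_curve()].
#' @param ... Unused.
#' @return A ggplot object of stepped survival curves per group.
#' @export
autoplot.mm_km <- function(object, ...) {
  steps <- object |>
    group_by(.data$group) |>
    dplyr::group_modify(function(d, g) {
      bind_rows(tibble(time = 0, survival = 1),
                d[c("time", "survival")])
    }) |>
    ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "progression-free fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Noise-model fit over the log2-ratio histogram
#'
#' @param object An `mm_noise_model`.
#' @param x_data Optional numeric vector of the ratios the model was fit
#'   to, for the histogram underlay.
#' @param ... Unused.
#' @return A ggplot object with the mixture density and noise band.
#' @export
autoplot.mm_noise_model <- function(object, x_data = NULL, ...) {
  comp <- object$components
  lim <- max(abs(c(object$band_low, object$band_high,
                   comp$mean + 3 * comp$sd, comp$mean - 3 * comp$sd)))
  grid <- tibble(x = seq(-lim, lim, length.out = 400))
  grid$density <- rowSums(vapply(seq_len(nrow(comp)), function(j) {
    comp$weight[j] * stats::dnorm(grid$x, comp$mean[j], comp$sd[j])
  }, numeric(nrow(grid))))
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density))
  if (!is.null(x_data)) {
    gg <- gg + ggplot2::geom_histogram(
      data = tibble(v = x_data),
      ggplot2::aes(x = .data$v, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 60, fill = "grey85"
    )
  }
  gg +
    ggplot2::geom_line(colour = "#2c5d9e") +
    ggplot2::geom_vline(xintercept = c(object$band_low, object$band_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "log2 ratio", y = "density") +
    ggplot2::theme_minimal()
}
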