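#' Plot IOI histograms per site
#'
#' Faceted histogram of per-sequence mean inter-onset intervals (or of raw
#' IOIs when given a numeric vector), the visual used to judge unimodality
#' of the IOI distribution at each site.
#'
#' @param x A `rhythm_analysis` from [run_analyze()], a summary tibble with
#'   `mean_ioi_s` and `site_name`, or a numeric vector of IOIs.
#' @param bin_width_s Bin width in seconds.
#' @return A ggplot object.
#' @export
plot_ioi_histogram <- function(x, bin_width_s = 0.25) {
  check_number(bin_width_s, "bin_width_s", lower = 0, allow_zero = FALSE)
  if (is.numeric(x)) {
    df <- tibble(mean_ioi_s = x, site_name = "all")
  } else {
    df <- if (inherits(x, "rhythm_analysis")) x$summaries else as_tibble(x)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ioi_s)) +
    ggplot2::geom_histogram(binwidth = bin_width_s, boundary = 0,
                            closed = "left", fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_name)) +
    ggplot2::labs(x = "Mean inter-onset interval (s)", y = "Sequences") +
    ggplot2::theme_minimal()
}

#' Plot beat distributions per site
#'
#' Boxplots of the per-sequence best-fitting beat (Hz) by site, the
#' comparison view behind the between-site contrasts.
#'
#' @param x A `rhythm_analysis` or a summary tibble with `beat_hz` and
#'   `site_name`.
#' @return A ggplot object.
#' @export
plot_beat_distribution <- function(x) {
  df <- if (inherits(x, "rhythm_analysis")) x$summaries else as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_name, y = .data$beat_hz)) +
    ggplot2::geom_boxplot(outlier.shape = 1, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "IOI beat (Hz)") +
    ggplot2::theme_minimal()
}

#' @rdname run_analyze
#' @param object A `rhythm_analysis` object.
#' @param ... Unused.
#' @method autoplot rhythm_analysis
#' @export
autoplot.rhythm_analysis <- function(object, ...) {
  plot_beat_distribution(object)
}

#' @rdname best_fit_beat
#' @param object A `beat_fit` object.
#' @method autoplot beat_fit
#' @export
autoplot.beat_fit <- function(object, ...) {
  period <- 1 / object$beat_hz
  k_lo <- floor((min(object$onsets_s) - object$phase_s) / period)
  k_hi <- ceiling((max(object$onsets_s) - object$phase_s) / period)
  grid <- object$phase_s + (k_lo:k_hi) * period
  df <- tibble(onset = object$onsets_s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset, y = 0)) +
    ggplot2::geom_vline(xintercept = grid, colour = "grey70", linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "Time (s)", y = NULL,
      title = sprintf("Best-fitting beat %.3f Hz, mean deviation %.3f",
                      object$beat_hz, object$deviation),
      subtitle = "Points: element onsets; dashed: fitted isochronous grid"
    ) +
    ggplot2::theme_minimal()
}
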