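#' Inter-onset intervals of a sequence
#'
#' The inter-onset interval (IOI) is the time between the onsets of two
#' consecutive elements; a sequence of n onsets yields n - 1 IOIs, in order.
#'
#' @param onsets_s Strictly increasing numeric vector of onset times
#'   (seconds), length >= 2.
#' @return Numeric vector of successive differences (seconds).
#' @examples
#' compute_iois(c(0, 1, 3))
#' @export
compute_iois <- function(onsets_s) {
  if (!is.numeric(onsets_s) || length(onsets_s) < 2 || any(!is.finite(onsets_s))) {
    abort_validation("`onsets_s` must be a finite numeric vector of length >= 2.")
  }
  iois <- diff(onsets_s)
  if (any(iois <= 0)) {
    abort_validation("Onsets must be strictly increasing.")
  }
  iois
}

#' Coefficient of variation of IOIs
#'
#' The ratio between the sample standard deviation (n - 1 denominator) and
#' the sample mean. A low CV within a sequence indicates isochrony: the
#' intervals barely vary around their mean.
#'
#' @param iois Numeric vector of at least 2 positive intervals.
#' @return Dimensionless, non-negative scalar.
#' @examples
#' coefficient_of_variation(c(1, 3))  # sd sqrt(2) over mean 2
#' @export
coefficient_of_variation <- function(iois) {
  if (!is.numeric(iois) || length(iois) < 2 || any(!is.finite(iois))) {
    abort_validation("`iois` must be a finite numeric vector of length >= 2.")
  }
  m <- mean(iois)
  if (m <= 0) {
    abort_validation("Mean IOI must be positive to form a coefficient of variation.")
  }
  sd(iois) / m
}

#' Histogram of IOIs
#'
#' Bins IOIs into left-closed, right-open bins of fixed width starting at
#' zero, the representation used to judge unimodality of the IOI
#' distribution.
#'
#' @param iois Numeric vector of IOIs (seconds); may be empty.
#' @param bin_width_s Positive bin width in seconds.
#' @return A tibble with `bin_lo`, `bin_hi` and `count`; counts sum to
#'   `length(iois)`. Empty input gives a zero-row tibble.
#' @export
ioi_histogram <- function(iois, bin_width_s) {
  check_number(bin_width_s, "bin_width_s", lower = 0, allow_zero = FALSE)
  if (length(iois) == 0) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer()))
  }
  if (!is.numeric(iois) || any(!is.finite(iois)) || any(iois < 0)) {
    abort_validation("`iois` must be finite and non-negative.")
  }
  idx <- floor(iois / bin_width_s)  # left-closed right-open
  n_bins <- max(idx) + 1
  counts <- tabulate(idx + 1, nbins = n_bins)
  tibble(
    bin_lo = (seq_len(n_bins) - 1) * bin_width_s,
    bin_hi = seq_len(n_bins) * bin_width_s,
    count = counts
  )
}

#' Normalized deviation of onsets from an isochronous grid
#'
#' For each onset, the distance to the nearest point of the grid
#' `phase_s + k / beat_hz` is divided by half the beat period, giving a
#' per-onset deviation in [0, 1]: 0 means the onset sits exactly on the
#' grid, 1 means it falls exactly midway between two grid points. The mean
#' over onsets is returned (a ugof-style goodness of fit; 0 = perfect
#' isochrony).
#'
#' @param onsets_s Numeric vector of onset times (seconds).
#' @param beat_hz Grid frequency in Hz (> 0).
#' @param phase_s Grid offset in seconds.
#' @return Mean normalized deviation in [0, 1].
#' @export
goodness_of_fit <- function(onsets_s, beat_hz, phase_s = 0) {
  check_number(beat_hz, "beat_hz", lower = 0, allow_zero = FALSE)
  check_number(phase_s, "phase_s")
  if (!is.numeric(onsets_s) || length(onsets_s) < 1 || any(!is.finite(onsets_s))) {
    abort_validation("`onsets_s` must be a non-empty finite numeric vector.")
  }
  period <- 1 / beat_hz
  mean(grid_distance(onsets_s, period, phase_s)) / (period / 2)
}

# Circular distance of each time to the nearest grid point of the grid
# {phase + k * period}.
grid_distance <- function(t, period, phase) {
  abs(((t - phase + period / 2) %% period) - period / 2)
}

# Exact phase minimizing the mean deviation at a fixed frequency. The mean
# circular distance is piecewise linear in the phase with breakpoints at the
# onset residuals, so the minimum is attained at one of them.
best_phase_at <- function(onsets_s, period) {
  res <- onsets_s %% period
  cand <- unique(res)
  d <- abs(((outer(onsets_s, cand, "-") + period / 2) %% period) - period / 2)
  devs <- colMeans(d) / (period / 2)
  i <- which.min(devs)
  list(phase_s = cand[i], deviation = devs[i])
}

#' Best-fitting isochronous beat of an onset sequence
#'
#' Finds the frequency of the perfect isochronous (metronome-like) grid
#' that best matches the element onsets, reported in Hz (elements per
#' second): a beat of 5 Hz means one element every 200 ms. Fit quality is
#' the mean normalized deviation of [goodness_of_fit()].
#'
#' Any grid at an integer multiple of the true frequency also fits a
#' perfectly isochronous sequence, so an unconstrained search is ill-posed.
#' The search is therefore anchored at the candidate frequency
#' `f0 = 1 / median(IOI)` — robust to occasional missed or doubled
#' elements — and covers `f0 * (1 - window)` to `f0 * (1 + window)` on a
#' grid of step `resolution_hz` that contains `f0` itself. At each
#' frequency the phase is chosen to exactly minimize the mean deviation
#' (the deviation is piecewise linear in the phase, so the minimum lies at
#' one of the onset residuals). Deviation ties within 1e-9 are broken
#' toward the frequency closest to `f0`, then toward the lower frequency.
#'
#' @param onsets_s At least 3 strictly increasing onset times (seconds).
#' @param resolution_hz Frequency grid step in Hz; default 0.001 (one
#'   milli-hertz). Estimates are never rounded internally.
#' @param window Half-width of the search window as a fraction of `f0`;
#'   default 0.5.
#' @return An object of class `beat_fit`: a list with `beat_hz`, `phase_s`,
#'   `deviation`, `search_lo_hz`, `search_hi_hz`, `f0_hz`, `n_onsets` and
#'   the input `onsets_s`. Has [tidy()], [glance()], [autoplot()] and print
#'   methods.
#' @examples
#' fit <- best_fit_beat(c(0, 0.2, 0.4, 0.6, 0.8))
#' fit$beat_hz  # 5 Hz: one element every 200 ms
#' @export
best_fit_beat <- function(onsets_s, resolution_hz = 0.001, window = 0.5) {
  if (!is.numeric(onsets_s) || length(onsets_s) < 3) {
    abort_validation("`onsets_s` must contain at least 3 onsets.")
  }
  iois <- compute_iois(onsets_s)
  check_number(resolution_hz, "resolution_hz", lower = 0, allow_zero = FALSE)
  check_number(window, "window", lower = 0, allow_zero = FALSE)
  if (diff(range(onsets_s)) <= resolution_hz) {
    abort_validation("Degenerate onset sequence: all onsets within one resolution step.")
  }
  f0 <- 1 / median(iois)
  k <- floor(window * f0 / resolution_hz)
  freqs <- f0 + resolution_hz * seq.int(-k, k)
  freqs <- freqs[freqs > 0]

  devs <- numeric(length(freqs))
  phases <- numeric(length(freqs))
  for (j in seq_along(freqs)) {
    ph <- best_phase_at(onsets_s, 1 / freqs[j])
    devs[j] <- ph$deviation
    phases[j] <- ph$phase_s
  }

  tied <- which(devs <= min(devs) + 1e-9)
  # ties: closest to f0, then lower frequency
  best <- tied[order(abs(freqs[tied] - f0), freqs[tied])][1]

  structure(
    list(
      beat_hz = freqs[best],
      phase_s = phases[best],
      deviation = devs[best],
      search_lo_hz = min(freqs),
      search_hi_hz = max(freqs),
      resolution_hz = resolution_hz,
      f0_hz = f0,
      n_onsets = length(onsets_s),
      onsets_s = onsets_s
    ),
    class = "beat_fit"
  )
}

#' @export
print.beat_fit <- function(x, ...) {
  cat(sprintf("Isochronous beat fit (%d onsets)\n", x$n_onsets))
  cat(sprintf("  beat: %.4f Hz (period %.4f s), phase %.4f s\n",
              x$beat_hz, 1 / x$beat_hz, x$phase_s))
  cat(sprintf("  mean normalized deviation: %.4f (0 = perfect isochrony)\n",
              x$deviation))
  cat(sprintf("  searched %.4f-%.4f Hz around f0 = %.4f Hz\n",
              x$search_lo_hz, x$search_hi_hz, x$f0_hz))
  invisible(x)
}

#' @rdname best_fit_beat
#' @param x A `beat_fit` object.
#' @param ... Unused.
#' @method tidy beat_fit
#' @export
tidy.beat_fit <- function(x, ...) {
  tibble(beat_hz = x$beat_hz, phase_s = x$phase_s, deviation = x$deviation)
}

#' @rdname best_fit_beat
#' @method glance beat_fit
#' @export
glance.beat_fit <- function(x, ...) {
  tibble(
    beat_hz = x$beat_hz, phase_s = x$phase_s, deviation = x$deviation,
    f0_hz = x$f0_hz, search_lo_hz = x$search_lo_hz,
    search_hi_hz = x$search_hi_hz, resolution_hz = x$resolution_hz,
    n_onsets = x$n_onsets
  )
}

#' Per-sequence rhythm summaries
#'
#' Bundles the per-sequence rhythm statistics into one tibble row per
#' sequence: number of elements, mean IOI, coefficient of variation of the
#' IOIs, the best-fitting isochronous beat (Hz) with its phase, and the
#' mean normalized deviation of the fit.
#'
#' @param sequences Element tibble with a `sequence_id` column, as returned
#'   by [segment_sequences()]; may span several recordings if `source_id`
#'   distinguishes them.
#' @param resolution_hz,window Passed to [best_fit_beat()].
#' @return A tibble with one row per (source_id, sequence_id):
#'   `source_id`, `sequence_id`, `individual_id` (if present),
#'   `n_elements`, `mean_ioi_s`, `cv`, `beat_hz`, `phase_s`, `deviation`.
#' @examples
#' els <- generate_isochronous_sequence(0.36, 0, 21)
#' els |> segment_sequences(max_silence_s = Inf) |> summarize_rhythm()
#' @export
summarize_rhythm <- function(sequences, resolution_hz = 0.001, window = 0.5) {
  sequences <- as_tibble(sequences)
  if (!"sequence_id" %in% names(sequences)) {
    abort_validation("`sequences` must carry a sequence_id column (run segment_sequences() first).")
  }
  has_ind <- "individual_id" %in% names(sequences)
  sequences |>
    dplyr::group_by(.data$source_id, .data$sequence_id) |>
    dplyr::group_modify(function(d, key) {
      onsets <- sort(d$begin_s)
      iois <- compute_iois(onsets)
      fit <- best_fit_beat(onsets, resolution_hz = resolution_hz, window = window)
      tibble(
        individual_id = if (has_ind) d$individual_id[1] else NA_character_,
        n_elements = length(onsets),
        mean_ioi_s = mean(iois),
        cv = coefficient_of_variation(iois),
        beat_hz = fit$beat_hz,
        phase_s = fit$phase_s,
        deviation = fit$deviation
      )
    }) |>
    dplyr::ungroup()
}
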