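# Build small element tibbles in code; no stored fixtures.

make_elements <- function(onsets, duration = 0.3, source_id = "rec1",
                          snr_db = NULL, low_hz = 100, high_hz = 500) {
  out <- tibble::tibble(
    selection = seq_along(onsets),
    begin_s = onsets,
    end_s = onsets + duration,
    low_hz = low_hz,
    high_hz = high_hz,
    source_id = source_id
  )
  if (!is.null(snr_db)) out$snr_db <- snr_db
  out
}

make_covariates <- function(source_ids, site_names = "siteA") {
  n <- length(source_ids)
  tibble::tibble(
    source_id = source_ids,
    site_name = rep_len(site_names, n),
    year = 2020L, month = 7L, day = 15L, hour = 21L,
    water_temp_c = 24.5, acoustic_richness = 4L,
    vessel_density_total = 10, vessel_density_trade = 3,
    vessel_density_fishing = 2, vessel_density_recreational = 3,
    vessel_density_passenger = 1.5, vessel_density_other = 0.5
  )
}

# Independent dense-grid brute force for the beat estimator: same objective,
# different route (dense phase grid instead of exact breakpoint search,
# 10x finer frequency grid).
brute_force_beat <- function(onsets, resolution_hz, window = 0.5,
                             refine = 10, n_phases = 800) {
  iois <- diff(onsets)
  f0 <- 1 / stats::median(iois)
  step <- resolution_hz / refine
  k <- floor(window * f0 / step)
  freqs <- f0 + step * seq.int(-k, k)
  freqs <- freqs[freqs > 0]
  best_f <- NA_real_
  best_dev <- Inf
  for (f in freqs) {
    period <- 1 / f
    phases <- seq(0, period, length.out = n_phases)
    d <- abs(((outer(onsets, phases, "-") + period / 2) %% period) - period / 2)
    dev <- min(colMeans(d)) / (period / 2)
    if (dev < best_dev - 1e-12) {
      best_dev <- dev
      best_f <- f
    }
  }
  list(beat_hz = best_f, deviation = best_dev)
}
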