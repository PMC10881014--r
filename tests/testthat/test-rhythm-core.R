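test_that("IOIs are successive onset differences", {
  expect_equal(compute_iois(c(0, 1, 3)), c(1, 2))
  expect_equal(compute_iois(c(5, 5.2, 5.4, 5.6)), rep(0.2, 3))
  expect_error(compute_iois(c(0, 0)), class = "isobeat_error_validation")
  expect_error(compute_iois(3), class = "isobeat_error_validation")
})

test_that("coefficient of variation is sample SD over mean and scale invariant", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)  # sd sqrt(2), mean 2
  expect_equal(coefficient_of_variation(c(1, 3)),
               coefficient_of_variation(c(2, 6)))
  expect_error(coefficient_of_variation(1), class = "isobeat_error_validation")
})

test_that("IOI histogram bins left-closed right-open from zero and conserves counts", {
  h <- ioi_histogram(c(0.1, 0.15, 0.35), 0.2)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$bin_lo, c(0, 0.2))
  expect_equal(h$bin_hi, c(0.2, 0.4))

  expect_equal(nrow(ioi_histogram(numeric(0), 0.2)), 0)
  expect_error(ioi_histogram(c(0.1), 0), class = "isobeat_error_validation")

  # value on a bin edge goes into the right-hand bin; counts always conserved
  expect_equal(ioi_histogram(c(0.2), 0.2)$count, c(0L, 1L))
  set.seed(41)
  for (i in 1:20) {
    x <- runif(sample(1:50, 1), 0, 5)
    expect_equal(sum(ioi_histogram(x, 0.37)$count), length(x))
  }
})

test_that("goodness of fit is 0 on the grid, 1 at midpoints, and matches the jitter closed form", {
  expect_equal(goodness_of_fit(seq(0, 2, 0.25), beat_hz = 4, phase_s = 0), 0)
  # single onset exactly midway between grid points
  expect_equal(goodness_of_fit(0.1, beat_hz = 5, phase_s = 0), 1)

  # Gaussian grid-level jitter, SD = 5% of period: per-onset deviation has
  # expectation E|N(0, 0.05 T)| / (T/2) = 0.05 * sqrt(2/pi) * 2 ~ 0.0798
  set.seed(42)
  period <- 2
  devs <- replicate(300, {
    onsets <- seq(0, by = period, length.out = 30) + rnorm(30, 0, 0.05 * period)
    goodness_of_fit(onsets, beat_hz = 1 / period, phase_s = 0)
  })
  expect_equal(mean(devs), 0.05 * sqrt(2 / pi) * 2, tolerance = 0.03)
})

test_that("a noiseless 200 ms train fits a 5 Hz beat with zero deviation", {
  fit <- best_fit_beat(c(0, 0.2, 0.4, 0.6, 0.8))
  expect_equal(fit$beat_hz, 5)
  expect_equal(fit$deviation, 0, tolerance = 1e-9)
  expect_true(fit$search_lo_hz <= fit$beat_hz && fit$beat_hz <= fit$search_hi_hz)
})

test_that("noiseless trains recover the generating beat to within one resolution step", {
  for (beat in c(0.16, 0.36, 0.46, 2)) {
    onsets <- seq(0, by = 1 / beat, length.out = 12)
    fit <- best_fit_beat(onsets)
    expect_equal(fit$beat_hz, beat, tolerance = 1.0001e-3)
    expect_equal(fit$deviation, 0, tolerance = 1e-9)
  }
})

test_that("a slow near-isochronous train matches the dense brute-force oracle", {
  onsets <- c(0, 2.78, 5.56, 8.34)
  fit <- best_fit_beat(onsets)
  expect_equal(fit$beat_hz, 1 / 2.78, tolerance = 1e-3)
  oracle <- brute_force_beat(onsets, resolution_hz = 0.001)
  expect_equal(fit$beat_hz, oracle$beat_hz, tolerance = 1.0001e-3)
})

test_that("beat fit is translation invariant and scale covariant", {
  set.seed(43)
  els <- generate_isochronous_sequence(0.4, 0.15, 12)
  onsets <- els$begin_s

  fit <- best_fit_beat(onsets)
  shifted <- best_fit_beat(onsets + 7.3)
  expect_equal(shifted$beat_hz, fit$beat_hz, tolerance = 1e-9)
  expect_equal(shifted$deviation, fit$deviation, tolerance = 1e-9)
  expect_equal(coefficient_of_variation(diff(onsets + 7.3)),
               coefficient_of_variation(diff(onsets)), tolerance = 1e-12)

  # scaling time by c scales the search grid by 1/c, so beat divides exactly
  cc <- 3.7
  scaled <- best_fit_beat(onsets * cc, resolution_hz = 0.001 / cc)
  expect_equal(scaled$beat_hz, fit$beat_hz / cc, tolerance = 1e-9)
  expect_equal(scaled$deviation, fit$deviation, tolerance = 1e-9)
  expect_equal(coefficient_of_variation(diff(onsets * cc)),
               coefficient_of_variation(diff(onsets)), tolerance = 1e-12)
})

test_that("mean fit deviation increases with generator jitter", {
  set.seed(44)
  mean_dev <- vapply(c(0, 0.05, 0.1, 0.2), function(jit) {
    mean(replicate(40, {
      els <- generate_isochronous_sequence(0.4, jit, 15)
      best_fit_beat(els$begin_s)$deviation
    }))
  }, numeric(1))
  expect_true(all(diff(mean_dev) > 0))
})

test_that("degenerate and too-short inputs are rejected", {
  expect_error(best_fit_beat(c(0, 1)), class = "isobeat_error_validation")
  expect_error(best_fit_beat(c(0, 1, 1)), class = "isobeat_error_validation")
  expect_error(goodness_of_fit(c(0, 1), beat_hz = 0),
               class = "isobeat_error_validation")
})

test_that("summarize_rhythm bundles IOIs, CV and beat per sequence", {
  els <- generate_isochronous_sequence(0.36, 0, 21)  # noiseless
  seqs <- segment_sequences(els, max_silence_s = Inf)
  s <- summarize_rhythm(seqs)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_elements, 21)
  expect_equal(s$cv, 0, tolerance = 1e-12)
  expect_equal(s$beat_hz, 0.36, tolerance = 1.0001e-3)
  # 21 elements at 0.36 Hz span (21 - 1) / 0.36 ~ 55.6 s: fits in one minute
  expect_equal(diff(range(els$begin_s)), 20 / 0.36, tolerance = 1e-9)

  set.seed(45)
  els2 <- generate_isochronous_sequence(0.36, 0.18, 21, source_id = "recB")
  s2 <- summarize_rhythm(segment_sequences(els2, max_silence_s = Inf))
  expect_gt(s2$cv, 0.05)
  expect_lt(s2$cv, 0.4)
})

test_that("tidy, glance and autoplot methods work on beat fits", {
  fit <- best_fit_beat(c(0, 0.2, 0.4, 0.6, 0.8))
  td <- tidy(fit)
  expect_named(td, c("beat_hz", "phase_s", "deviation"))
  gl <- glance(fit)
  expect_true(all(c("f0_hz", "n_onsets") %in% names(gl)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
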