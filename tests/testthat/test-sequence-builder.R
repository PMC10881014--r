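test_that("elements separated by short silences form one sequence", {
  els <- make_elements(seq(0, by = 2.3, length.out = 6))
  out <- segment_sequences(els, max_silence_s = 10)
  expect_equal(unique(out$sequence_id), 1L)
  expect_equal(nrow(out), 6)
  expect_equal(nrow(attr(out, "discards")), 0)
})

test_that("a long silence terminates the sequence and short runs are discarded", {
  # silences of 2 s except a 12 s gap after the third element:
  # candidate runs of 3 and 2; the 2-run falls below min_elements
  onsets <- c(0, 2.3, 4.6, 16.9, 19.2)
  els <- make_elements(onsets)
  out <- segment_sequences(els, max_silence_s = 10, min_elements = 3)
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$sequence_id), 1L)
  disc <- attr(out, "discards")
  expect_equal(nrow(disc), 2)
  expect_match(disc$reason[1], "below min_elements")
})

test_that("fewer elements than min_elements yields an empty result", {
  els <- make_elements(c(0, 2))
  out <- segment_sequences(els)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "discards")), 2)
})

test_that("a gap equal to the threshold terminates the sequence", {
  # 10 seconds of silence exactly: offset 0.3 -> next onset 10.3
  els <- make_elements(c(0, 10.3, 12.3, 14.3))
  out <- segment_sequences(els, max_silence_s = 10, min_elements = 3)
  expect_equal(nrow(out), 3)
  expect_equal(out$begin_s, c(10.3, 12.3, 14.3))
})

test_that("unsorted or overlapping inputs are rejected", {
  els <- make_elements(c(5, 1, 3))
  expect_error(segment_sequences(els), "sorted",
               class = "isobeat_error_validation")
  ovl <- make_elements(c(0, 0.2), duration = 0.3)
  expect_error(segment_sequences(ovl), "Overlap",
               class = "isobeat_error_validation")
})

test_that("segmentation is idempotent and translation invariant", {
  set.seed(21)
  onsets <- sort(c(cumsum(runif(8, 1, 4)), 40 + cumsum(runif(5, 1, 4))))
  els <- make_elements(onsets, duration = 0.2)
  once <- segment_sequences(els, max_silence_s = 10)
  for (sid in unique(once$sequence_id)) {
    sub <- once[once$sequence_id == sid, names(els)]
    again <- segment_sequences(sub, max_silence_s = 10)
    expect_equal(again$begin_s, sub$begin_s)
    expect_equal(unique(again$sequence_id), 1L)
  }
  shifted <- els
  shifted$begin_s <- shifted$begin_s + 123.456
  shifted$end_s <- shifted$end_s + 123.456
  out_shift <- segment_sequences(shifted, max_silence_s = 10)
  expect_equal(out_shift$sequence_id, once$sequence_id)
  expect_equal(out_shift$selection, once$selection)
})

test_that("sequences with similar median SNR chain to the same individual", {
  e1 <- make_elements(c(0, 2, 4), snr_db = 14.0)
  e2 <- make_elements(c(30, 32, 34), snr_db = 14.3)
  e2$selection <- e2$selection + 10L
  e3 <- make_elements(c(60, 62, 64), snr_db = 20.0)
  e3$selection <- e3$selection + 20L
  els <- dplyr::bind_rows(e1, e2, e3)
  seqs <- segment_sequences(els, max_silence_s = 10)
  expect_equal(dplyr::n_distinct(seqs$sequence_id), 3)

  out <- assign_individuals(seqs, snr_tolerance_db = 0.5)
  ids <- dplyr::arrange(dplyr::distinct(out, sequence_id, individual_id), sequence_id)
  expect_equal(ids$individual_id[1], ids$individual_id[2])  # 14.0 vs 14.3 dB
  expect_false(ids$individual_id[3] == ids$individual_id[1])  # 20 dB apart
})

test_that("without SNR each sequence gets a fresh individual; one_per_file overrides", {
  onsets <- c(0, 2, 4, 30, 32, 34, 60, 62, 64)
  els <- make_elements(onsets)
  seqs <- segment_sequences(els, max_silence_s = 10)
  out <- assign_individuals(seqs)
  expect_equal(dplyr::n_distinct(out$individual_id), 3)

  forced <- assign_individuals(seqs, one_per_file = TRUE)
  expect_equal(dplyr::n_distinct(forced$individual_id), 1)
})

test_that("mixed presence and absence of SNR in one recording is an error", {
  e1 <- make_elements(c(0, 2, 4), snr_db = c(14, NA, 14))
  e2 <- make_elements(c(30, 32, 34), snr_db = 15)
  e2$selection <- e2$selection + 10L
  seqs <- segment_sequences(dplyr::bind_rows(e1, e2), max_silence_s = 10)
  expect_error(assign_individuals(seqs), "Mixed",
               class = "isobeat_error_validation")
})

test_that("beat range size is max minus min", {
  expect_equal(beat_range_size(c(0.36)), 0)
  expect_equal(beat_range_size(c(0.32, 0.49, 0.65)), 0.33)
  expect_error(beat_range_size(numeric(0)), class = "isobeat_error_validation")
})

test_that("intra-individual beat ranges are smaller than the dataset-wide range", {
  # individuals with fixed per-individual beats: within-individual range is
  # estimation noise only, dataset-wide range reflects between-individual spread
  set.seed(31)
  ind_beats <- rnorm(10, 0.36, 0.08)
  within_ranges <- numeric(10)
  all_beats <- c()
  for (i in 1:10) {
    ests <- replicate(3, {
      els <- generate_isochronous_sequence(ind_beats[i], 0.18, 21)
      best_fit_beat(els$begin_s)$beat_hz
    })
    within_ranges[i] <- beat_range_size(ests)
    all_beats <- c(all_beats, ests)
  }
  expect_lt(median(within_ranges), beat_range_size(all_beats))
})
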