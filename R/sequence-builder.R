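#' Segment an element stream into call sequences
#'
#' A call sequence is a temporally ordered run of at least `min_elements`
#' elements in which every silence — measured from the end of one element to
#' the beginning of the next — is shorter than `max_silence_s`. A gap of
#' `max_silence_s` or more terminates the sequence. Runs with fewer than
#' `min_elements` elements are discarded and recorded in the `discards`
#' attribute with a reason, so that every input element is accounted for.
#'
#' For 1-minute excerpts annotated as one sequence per file, pass
#' `max_silence_s = Inf` (or the file length) so the whole excerpt forms a
#' single run.
#'
#' @param elements Element tibble from one recording (`source_id` must be
#'   unique), sorted ascending by `begin_s`.
#' @param max_silence_s Silence (offset-to-next-onset gap, seconds) at or
#'   above which a sequence is considered terminated. Default 10 s.
#' @param min_elements Minimum number of elements for a run to count as a
#'   sequence. Default 3.
#'
#' @return The retained elements with an integer `sequence_id` column
#'   (numbered 1, 2, ... in time order). Discarded elements are attached as
#'   a tibble in `attr(, "discards")` with a `reason` column.
#'
#' @examples
#' els <- generate_isochronous_sequence(0.36, 0.18, 21)
#' seqs <- segment_sequences(els, max_silence_s = Inf)
#' dplyr::count(seqs, sequence_id)
#' @export
segment_sequences <- function(elements, max_silence_s = 10, min_elements = 3) {
  elements <- as_tibble(elements)
  validate_elements(elements)
  check_number(max_silence_s, "max_silence_s", lower = 0, allow_zero = FALSE,
               allow_inf = TRUE)
  check_number(min_elements, "min_elements", lower = 1)
  if (length(unique(elements$source_id)) > 1) {
    abort_validation("segment_sequences() expects elements from a single source_id; split by recording first.")
  }
  if (nrow(elements) == 0) {
    out <- dplyr::mutate(elements, sequence_id = integer())
    attr(out, "discards") <- dplyr::mutate(elements, reason = character())
    return(out)
  }
  if (is.unsorted(elements$begin_s, strictly = FALSE)) {
    abort_validation("Elements must be sorted ascending by begin_s.")
  }
  overlap <- which(elements$begin_s[-1] < elements$end_s[-nrow(elements)])
  if (length(overlap) > 0) {
    i <- overlap[1]
    abort_validation(sprintf(
      "Overlapping elements: selection %s (ends %.3f s) and selection %s (begins %.3f s).",
      elements$selection[i], elements$end_s[i],
      elements$selection[i + 1], elements$begin_s[i + 1]))
  }

  gaps <- elements$begin_s[-1] - elements$end_s[-nrow(elements)]
  run_id <- cumsum(c(1L, as.integer(gaps >= max_silence_s)))

  elements$.run <- run_id
  run_sizes <- table(run_id)
  keep_runs <- as.integer(names(run_sizes)[run_sizes >= min_elements])

  kept <- dplyr::filter(elements, .data$.run %in% keep_runs)
  dropped <- dplyr::filter(elements, !(.data$.run %in% keep_runs))
  dropped <- dplyr::mutate(
    dropped,
    reason = sprintf("run of %d element(s) below min_elements = %d",
                     as.integer(table(dropped$.run)[as.character(dropped$.run)]),
                     as.integer(min_elements))
  )
  dropped$.run <- NULL

  kept <- dplyr::mutate(kept, sequence_id = match(.data$.run, keep_runs))
  kept$.run <- NULL
  attr(kept, "discards") <- as_tibble(dropped)
  kept
}

#' Assign call sequences to presumed individuals
#'
#' In long recordings, sequences whose elements share a very similar
#' signal-to-noise ratio are presumed to come from the same (stationary)
#' individual. Sequences are processed in time order; a sequence joins an
#' existing individual when its median element SNR is within
#' `snr_tolerance_db` of the median SNR of any sequence already assigned to
#' that individual (transitive chaining; ties go to the earliest-created
#' individual). Without SNR data each sequence gets a fresh individual —
#' the rule used for non-consecutive 1-minute excerpts, where each sequence
#' is presumed to come from a different individual. `one_per_file = TRUE`
#' forces that one-individual-per-recording convention explicitly.
#'
#' @param sequences Output of [segment_sequences()]: element tibble with a
#'   `sequence_id` column, from a single recording.
#' @param snr_tolerance_db Maximum difference in median element SNR (dB) for
#'   two sequences to be attributed to the same individual. The default of
#'   1 dB is a documented choice standing in for a visual "same SNR"
#'   judgement.
#' @param one_per_file If `TRUE`, all sequences in the recording are
#'   assigned to one individual (1-minute excerpt protocol).
#'
#' @return `sequences` with a character `individual_id` column added.
#' @export
assign_individuals <- function(sequences, snr_tolerance_db = 1, one_per_file = FALSE) {
  sequences <- as_tibble(sequences)
  if (!"sequence_id" %in% names(sequences)) {
    abort_validation("`sequences` must carry a sequence_id column (run segment_sequences() first).")
  }
  if (nrow(sequences) == 0) {
    return(dplyr::mutate(sequences, individual_id = character()))
  }
  src <- unique(sequences$source_id)
  if (length(src) > 1) {
    abort_validation("assign_individuals() expects sequences from a single source_id.")
  }

  if (one_per_file) {
    return(dplyr::mutate(sequences, individual_id = paste0(src, "/ind1")))
  }

  has_snr <- "snr_db" %in% names(sequences) && !all(is.na(sequences$snr_db))
  per_seq <- sequences |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(
      start_s = min(.data$begin_s),
      median_snr = if (has_snr) median(.data$snr_db) else NA_real_,
      n_missing_snr = if (has_snr) sum(is.na(.data$snr_db)) else 0L,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$start_s)

  if (!has_snr) {
    per_seq$individual <- seq_len(nrow(per_seq))
  } else {
    if (any(per_seq$n_missing_snr > 0) || any(is.na(per_seq$median_snr))) {
      abort_validation(
        "Mixed presence/absence of SNR within one recording: cannot attribute individuals.")
    }
    check_number(snr_tolerance_db, "snr_tolerance_db", lower = 0)
    individual <- integer(nrow(per_seq))
    members <- list()  # per individual: vector of member median SNRs
    for (i in seq_len(nrow(per_seq))) {
      snr_i <- per_seq$median_snr[i]
      hit <- which(vapply(members, function(m) any(abs(m - snr_i) <= snr_tolerance_db),
                          logical(1)))
      if (length(hit) > 0) {
        k <- hit[1]
        members[[k]] <- c(members[[k]], snr_i)
      } else {
        k <- length(members) + 1L
        members[[k]] <- snr_i
      }
      individual[i] <- k
    }
    per_seq$individual <- individual
  }

  labels <- stats::setNames(paste0(src, "/ind", per_seq$individual), per_seq$sequence_id)
  dplyr::mutate(sequences,
                individual_id = unname(labels[as.character(.data$sequence_id)]))
}

#' Beat-frequency range size
#'
#' The difference between the fastest and the slowest beat (Hz) in a set of
#' beat estimates — used to contrast within-individual beat variability
#' against the spread across a whole dataset.
#'
#' @param beats_hz Non-empty numeric vector of beat estimates in Hz.
#' @return `max(beats_hz) - min(beats_hz)`, a non-negative scalar in Hz.
#' @examples
#' beat_range_size(c(0.32, 0.49, 0.65))
#' @export
beat_range_size <- function(beats_hz) {
  if (length(beats_hz) == 0 || !is.numeric(beats_hz) || any(is.na(beats_hz))) {
    abort_validation("`beats_hz` must be a non-empty numeric vector without NA.")
  }
  max(beats_hz) - min(beats_hz)
}
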