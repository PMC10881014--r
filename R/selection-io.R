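#' Read a Raven Pro selection table
#'
#' Parses a tab-delimited selection table as exported by Raven Pro: one row
#' per annotated sound element, with the element's start/end time in seconds
#' and its lower/upper frequency bound in Hz. Columns beyond the required
#' five are preserved; a column whose name contains "SNR" is mapped to
#' `snr_db`.
#'
#' Numeric cells must use the dot as decimal separator; decimal-comma
#' exports are rejected with a row-numbered parse error rather than being
#' silently coerced, because annotation exports in the wild vary and an
#' explicit failure beats silent corruption.
#'
#' @param path Path to a tab-delimited selection table with a header row.
#'   Required columns: `Selection`, `Begin Time (s)`, `End Time (s)`,
#'   `Low Freq (Hz)`, `High Freq (Hz)`.
#' @param source_id Identifier for the recording the table belongs to;
#'   defaults to the file name without extension.
#'
#' @return A tibble of elements sorted by onset time, with columns
#'   `selection`, `begin_s`, `end_s`, `low_hz`, `high_hz`, `snr_db` (only
#'   when an SNR-like column is present), `source_id`, and any extra
#'   columns from the file (`View`/`Channel` become `view`/`channel`).
#'
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' els <- generate_isochronous_sequence(0.36, 0, 5)
#' write_selection_table(els, tf)
#' read_selection_table(tf)
#' @export
read_selection_table <- function(path, source_id = NULL) {
  if (!file.exists(path)) {
    abort_io(sprintf("Selection table not found: '%s'.", path))
  }
  if (is.null(source_id)) {
    source_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())

  required <- c("Selection", "Begin Time (s)", "End Time (s)",
                "Low Freq (Hz)", "High Freq (Hz)")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Selection table is missing required column(s): %s.",
                         paste0("'", missing_cols, "'", collapse = ", ")))
  }

  parse_num_col <- function(x, col) {
    out <- suppressWarnings(readr::parse_double(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "Non-numeric value '%s' in column '%s' at data row %d.",
        x[bad[1]], col, bad[1]))
    }
    out
  }

  out <- tibble(
    selection = as.integer(parse_num_col(raw$Selection, "Selection")),
    begin_s   = parse_num_col(raw[["Begin Time (s)"]], "Begin Time (s)"),
    end_s     = parse_num_col(raw[["End Time (s)"]], "End Time (s)"),
    low_hz    = parse_num_col(raw[["Low Freq (Hz)"]], "Low Freq (Hz)"),
    high_hz   = parse_num_col(raw[["High Freq (Hz)"]], "High Freq (Hz)"),
    source_id = source_id
  )

  snr_col <- grep("snr", names(raw), ignore.case = TRUE, value = TRUE)
  if (length(snr_col) > 0) {
    out$snr_db <- parse_num_col(raw[[snr_col[1]]], snr_col[1])
  }
  if ("View" %in% names(raw)) out$view <- raw$View
  if ("Channel" %in% names(raw)) out$channel <- raw$Channel
  extras <- setdiff(names(raw), c(required, snr_col, "View", "Channel"))
  for (col in extras) out[[col]] <- raw[[col]]

  validate_elements(out)
  dplyr::arrange(out, .data$begin_s)
}

#' Write elements as a Raven Pro selection table
#'
#' Emits a tab-delimited selection table that round-trips through
#' [read_selection_table()] to an identical record list. Numeric columns
#' are written at full double precision. The fixed column order is
#' Selection, View, Channel, Begin Time (s), End Time (s), Low Freq (Hz),
#' High Freq (Hz), followed by optional columns (SNR, extras).
#'
#' @param elements Element tibble as returned by [read_selection_table()]
#'   or the synthetic generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(elements, path) {
  elements <- as_tibble(elements)
  validate_elements(elements)
  n <- nrow(elements)
  out <- tibble(
    Selection = if (n > 0) as.integer(elements$selection) else integer(),
    View = if ("view" %in% names(elements)) elements$view else rep("Spectrogram 1", n),
    Channel = if ("channel" %in% names(elements)) elements$channel else rep(1L, n),
    `Begin Time (s)` = elements$begin_s,
    `End Time (s)` = elements$end_s,
    `Low Freq (Hz)` = elements$low_hz,
    `High Freq (Hz)` = elements$high_hz
  )
  if ("snr_db" %in% names(elements)) out$`SNR (dB)` <- elements$snr_db
  extras <- setdiff(names(elements),
                    c("selection", "begin_s", "end_s", "low_hz", "high_hz",
                      "snr_db", "source_id", "view", "channel"))
  for (col in extras) out[[col]] <- elements[[col]]

  ok <- tryCatch({
    readr::write_tsv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("Cannot write selection table to '%s'.", path))
  invisible(path)
}

#' Read a recording covariate table
#'
#' Reads the per-recording covariate table (CSV with header): site, date and
#' hour of recording, water temperature, acoustic richness (number of fish
#' sound types heard at the site) and monthly vessel densities by category,
#' expressed as hours per square kilometer per month.
#'
#' @param path Path to a CSV file with one row per recording. Required
#'   columns: `source_id`, `site_name`, `year`, `month`, `day`, `hour`,
#'   `water_temp_c`, `acoustic_richness`, `vessel_density_total`,
#'   `vessel_density_trade`, `vessel_density_fishing`,
#'   `vessel_density_recreational`, `vessel_density_passenger`,
#'   `vessel_density_other`.
#' @return A tibble with one validated row per recording.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Covariate table not found: '%s'.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("source_id", "site_name", "year", "month", "day", "hour",
                "water_temp_c", "acoustic_richness", covariate_density_cols())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Covariate table is missing required column(s): %s.",
                         paste0("'", missing_cols, "'", collapse = ", ")))
  }
  validate_covariates(raw)
  as_tibble(raw)
}

covariate_density_cols <- function() {
  paste0("vessel_density_",
         c("total", "trade", "fishing", "recreational", "passenger", "other"))
}

validate_covariates <- function(meta) {
  dup <- meta$source_id[duplicated(meta$source_id)]
  if (length(dup) > 0) {
    abort_validation(sprintf("Duplicate source_id in covariate table: %s.",
                             paste(unique(dup), collapse = ", ")))
  }
  check_range <- function(col, lo, hi) {
    x <- meta[[col]]
    bad <- which(is.na(x) | x < lo | x > hi)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Invalid or missing `%s` at row %d (must be in [%g, %g]).",
        col, bad[1], lo, hi))
    }
  }
  check_range("month", 1, 12)
  check_range("day", 1, 31)
  check_range("hour", 0, 23)
  bad_t <- which(is.na(meta$water_temp_c))
  if (length(bad_t) > 0) {
    abort_validation(sprintf("Missing `water_temp_c` at row %d.", bad_t[1]))
  }
  ar <- meta$acoustic_richness
  if (any(is.na(ar) | ar < 0 | ar != floor(ar))) {
    abort_validation("`acoustic_richness` must be a non-negative integer.")
  }
  for (col in covariate_density_cols()) {
    x <- meta[[col]]
    bad <- which(is.na(x) | x < 0)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Negative or missing vessel density `%s` at row %d.", col, bad[1]))
    }
  }
  invisible(meta)
}

# Element-tibble invariants shared by readers, writers and the segmenter.
validate_elements <- function(elements) {
  needed <- c("selection", "begin_s", "end_s", "low_hz", "high_hz", "source_id")
  missing_cols <- setdiff(needed, names(elements))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Element table is missing column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(elements) == 0) return(invisible(elements))
  bad <- which(!(elements$begin_s < elements$end_s))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Element begin time must precede end time (selection %s).",
      elements$selection[bad[1]]))
  }
  bad <- which(elements$low_hz > elements$high_hz)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Element low frequency exceeds high frequency (selection %s).",
      elements$selection[bad[1]]))
  }
  if (any(elements$begin_s < 0)) {
    abort_validation("Element begin times must be >= 0 seconds.")
  }
  dup <- elements |>
    dplyr::count(.data$source_id, .data$selection) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(sprintf(
      "Selection id %s duplicated within source '%s'.",
      dup$selection[1], dup$source_id[1]))
  }
  invisible(elements)
}
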