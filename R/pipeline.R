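#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: either selection
#' table paths plus a covariate table, or a synthetic generator
#' configuration; the segmentation, beat-search and outlier parameters; and
#' the seed. A run is reproducible from the configuration (and input
#' files) alone. `write_pipeline_config()` / `read_pipeline_config()`
#' round-trip the configuration through YAML, and every run writes the
#' resolved configuration next to its outputs.
#'
#' @param selection_tables Character vector of selection table paths
#'   (`NULL` when simulating).
#' @param covariates_table Path to the covariate CSV (`NULL` when
#'   simulating).
#' @param generator A [generator_config()], used when no input paths are
#'   given.
#' @param max_silence_s,min_elements Segmentation parameters (see
#'   [segment_sequences()]). The default `max_silence_s = Inf` matches the
#'   1-minute excerpt protocol (one sequence per file); use 10 for long
#'   recordings.
#' @param resolution_hz,window Beat-search parameters (see
#'   [best_fit_beat()]).
#' @param outlier_k Outlier multiplier for [remove_outliers()].
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(selection_tables = NULL, covariates_table = NULL,
                            generator = generator_config(seed = seed),
                            max_silence_s = Inf, min_elements = 3,
                            resolution_hz = 0.001, window = 0.5,
                            outlier_k = 3, seed = 1L) {
  structure(list(
    selection_tables = selection_tables,
    covariates_table = covariates_table,
    generator = generator,
    max_silence_s = max_silence_s,
    min_elements = min_elements,
    resolution_hz = resolution_hz,
    window = window,
    outlier_k = outlier_k,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- if (!is.null(x$generator)) {
    g <- unclass(x$generator)
    g$presets <- lapply(seq_len(nrow(g$presets)), function(i) {
      row <- as.list(g$presets[i, setdiff(names(g$presets), "covariates")])
      row$covariates <- g$presets$covariates[[i]]
      row
    })
    g
  }
  x$max_silence_s <- if (is.infinite(x$max_silence_s)) ".inf" else x$max_silence_s
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$max_silence_s, ".inf")) x$max_silence_s <- Inf
  gen <- NULL
  if (!is.null(x$generator)) {
    presets <- dplyr::bind_rows(lapply(x$generator$presets, function(row) {
      cov <- row$covariates
      cov$months <- unlist(cov$months)
      cov$hours <- unlist(cov$hours)
      cov$density_ranges <- lapply(cov$density_ranges, unlist)
      row$covariates <- NULL
      out <- as_tibble(row)
      out$covariates <- list(cov)
      out
    }))
    gen <- generator_config(seed = x$generator$seed, presets = presets,
                            mode = x$generator$mode)
  }
  pipeline_config(
    selection_tables = unlist(x$selection_tables),
    covariates_table = x$covariates_table,
    generator = gen,
    max_silence_s = x$max_silence_s, min_elements = x$min_elements,
    resolution_hz = x$resolution_hz, window = x$window,
    outlier_k = x$outlier_k, seed = x$seed
  )
}

#' Simulate a dataset and write it to disk
#'
#' Runs the synthetic generator of the configuration and writes one Raven
#' selection table per recording, the covariate CSV and the ground-truth
#' CSV into `out_dir`.
#'
#' @param config A [pipeline_config()] with a generator.
#' @param out_dir Output directory (created if needed).
#' @return The [generate_dataset()] list, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.null(config$generator)) {
    abort_validation("run_simulate() needs a generator in the pipeline config.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(config$generator)
  for (src in unique(ds$elements$source_id)) {
    write_selection_table(dplyr::filter(ds$elements, .data$source_id == src),
                          file.path(out_dir, paste0(src, ".selections.txt")))
  }
  readr::write_csv(ds$covariates, file.path(out_dir, "covariates.csv"), progress = FALSE)
  readr::write_csv(ds$truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yml"))
  invisible(ds)
}

#' Analyze a dataset: per-sequence rhythm summaries and per-site aggregates
#'
#' Loads (or generates) the element streams and covariates named by the
#' configuration, segments each recording into call sequences, computes the
#' per-sequence rhythm statistics and aggregates them per site. Discarded
#' elements are data, not just log lines: they are returned (and written)
#' with a reason each.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `summaries.csv`, `aggregates.csv`, `discards.csv`, `model_table.csv`
#'   and the resolved `config.yml`.
#' @return An object of class `rhythm_analysis`: a list with tibbles
#'   `summaries` (one row per sequence, joined to site), `aggregates` (per
#'   site: n, mean/SD/min/max of beat and CV), `discards`, `covariates`
#'   and, for synthetic runs, `truth`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_analyze <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort_validation("`config` must be created with pipeline_config().")
  }
  if (!is.null(config$selection_tables)) {
    elements <- dplyr::bind_rows(lapply(config$selection_tables, read_selection_table))
    covariates <- if (!is.null(config$covariates_table)) {
      read_covariates(config$covariates_table)
    } else {
      NULL
    }
    truth <- NULL
  } else {
    ds <- generate_dataset(config$generator)
    elements <- ds$elements
    covariates <- ds$covariates
    truth <- ds$truth
  }

  per_source <- split(elements, elements$source_id)
  segged <- lapply(per_source, segment_sequences,
                   max_silence_s = config$max_silence_s,
                   min_elements = config$min_elements)
  discards <- dplyr::bind_rows(lapply(segged, attr, "discards"))
  if (nrow(discards) == 0) {
    discards <- tibble(selection = integer(), begin_s = numeric(),
                       end_s = numeric(), source_id = character(),
                       reason = character())
  }
  kept <- dplyr::bind_rows(segged)
  if (nrow(kept) == 0) {
    abort_validation(sprintf(
      "No sequences left after segmentation: %d element(s) in, %d discarded.",
      nrow(elements), nrow(discards)))
  }

  summaries <- summarize_rhythm(kept, resolution_hz = config$resolution_hz,
                                window = config$window)
  if (!is.null(covariates)) {
    summaries <- dplyr::left_join(
      summaries,
      dplyr::select(covariates, "source_id", "site_name"),
      by = "source_id")
  } else {
    summaries$site_name <- summaries$source_id
  }

  aggregates <- summaries |>
    dplyr::group_by(.data$site_name) |>
    dplyr::summarise(
      n_sequences = dplyr::n(),
      beat_mean_hz = mean(.data$beat_hz),
      beat_sd_hz = sd(.data$beat_hz),
      beat_min_hz = min(.data$beat_hz),
      beat_max_hz = max(.data$beat_hz),
      cv_mean = mean(.data$cv),
      cv_sd = sd(.data$cv),
      cv_min = min(.data$cv),
      cv_max = max(.data$cv),
      .groups = "drop"
    )

  res <- structure(list(
    summaries = summaries,
    aggregates = aggregates,
    discards = discards,
    covariates = covariates,
    truth = truth,
    config = config
  ), class = "rhythm_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"), progress = FALSE)
    readr::write_csv(aggregates, file.path(out_dir, "aggregates.csv"), progress = FALSE)
    readr::write_csv(discards, file.path(out_dir, "discards.csv"), progress = FALSE)
    if (!is.null(covariates)) {
      export_model_table(summaries, covariates, file.path(out_dir, "model_table.csv"))
    }
    write_pipeline_config(config, file.path(out_dir, "config.yml"))
  }
  res
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat(sprintf("Rhythm analysis: %d sequences across %d site(s), %d discarded element(s)\n",
              nrow(x$summaries), nrow(x$aggregates), nrow(x$discards)))
  print(x$aggregates)
  invisible(x)
}

#' @rdname run_analyze
#' @param x A `rhythm_analysis` object.
#' @param ... Unused.
#' @method tidy rhythm_analysis
#' @export
tidy.rhythm_analysis <- function(x, ...) x$summaries

#' @rdname run_analyze
#' @method glance rhythm_analysis
#' @export
glance.rhythm_analysis <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$summaries),
    n_sites = nrow(x$aggregates),
    n_discarded_elements = nrow(x$discards),
    beat_mean_hz = mean(x$summaries$beat_hz),
    beat_sd_hz = sd(x$summaries$beat_hz),
    cv_mean = mean(x$summaries$cv)
  )
}

#' Between-site comparison of beat estimates
#'
#' Reproduces the between-group analysis stage: a single dataset-level
#' outlier pass on the per-sequence beats (|x - mean| > k SD), a one-way
#' ANOVA across sites, and all pairwise Welch t-tests with Bonferroni
#' correction and Cohen's d.
#'
#' @param analysis A `rhythm_analysis` from [run_analyze()] (or any tibble
#'   with `site_name` and `beat_hz` columns).
#' @param outlier_k Outlier multiplier; defaults to the analysis config.
#' @param out_dir Optional directory for `comparisons.csv`.
#' @return A tibble of class `rhythm_comparisons`: one ANOVA row
#'   (`groups = "all sites"`) followed by one row per site pair, with
#'   `method`, `statistic`, `df`, `df2`, `p_value`, `p_adjusted`,
#'   `effect_size_d` and `n_removed_outliers` columns.
#' @export
run_compare <- function(analysis, outlier_k = NULL, out_dir = NULL) {
  summaries <- if (inherits(analysis, "rhythm_analysis")) analysis$summaries else as_tibble(analysis)
  if (is.null(outlier_k)) {
    outlier_k <- if (inherits(analysis, "rhythm_analysis")) analysis$config$outlier_k else 3
  }
  if (!all(c("site_name", "beat_hz") %in% names(summaries))) {
    abort_validation("`analysis` must provide site_name and beat_hz per sequence.")
  }
  sites <- unique(summaries$site_name)
  if (length(sites) < 2) {
    abort_validation("run_compare() needs at least 2 sites.")
  }
  small <- summaries |> dplyr::count(.data$site_name) |> dplyr::filter(.data$n < 2)
  if (nrow(small) > 0) {
    abort_validation(sprintf("Site '%s' has fewer than 2 sequences.",
                             small$site_name[1]))
  }

  pruned <- remove_outliers(summaries$beat_hz, k = outlier_k)
  kept <- summaries[setdiff(seq_len(nrow(summaries)), pruned$removed), ]
  groups <- split(kept$beat_hz, kept$site_name)
  groups <- groups[order(names(groups))]

  aov_row <- one_way_anova(groups)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pair_rows <- purrr::map_dfr(pairs, function(pr) {
    wt <- welch_t_test(groups[[pr[1]]], groups[[pr[2]]])
    d <- cohens_d(groups[[pr[1]]], groups[[pr[2]]])
    tibble(
      method = "welch_t",
      groups = paste(pr, collapse = " vs "),
      statistic = wt$statistic,
      df = wt$df,
      df2 = NA_real_,
      p_value = wt$p_value,
      effect_size_d = d
    )
  })
  pair_rows$p_adjusted <- bonferroni(pair_rows$p_value)

  out <- dplyr::bind_rows(
    tibble(
      method = "anova",
      groups = "all sites",
      statistic = aov_row$statistic,
      df = aov_row$df1,
      df2 = aov_row$df2,
      p_value = aov_row$p_value,
      effect_size_d = NA_real_,
      p_adjusted = NA_real_
    ),
    pair_rows
  )
  out$n_removed_outliers <- length(pruned$removed)
  class(out) <- c("rhythm_comparisons", class(out))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(out_dir, "comparisons.csv"), progress = FALSE)
  }
  out
}

#' Render a markdown report of an analysis
#'
#' Writes a single human-readable markdown report: per-site IOI histogram
#' tables, beat and CV distribution summaries, and the between-site
#' comparison table. Figures (IOI histograms, beat distributions) are
#' saved as PNG files next to the report. Regeneration from the same
#' inputs is idempotent.
#'
#' @param analysis A `rhythm_analysis` from [run_analyze()].
#' @param comparisons Optional `rhythm_comparisons` from [run_compare()].
#' @param path Output path for the markdown file.
#' @param bin_width_s Histogram bin width in seconds.
#' @param figures If `TRUE`, also save PNG figures next to the report.
#' @return `path`, invisibly.
#' @export
run_report <- function(analysis, comparisons = NULL, path = "report.md",
                       bin_width_s = 0.25, figures = TRUE) {
  if (!inherits(analysis, "rhythm_analysis")) {
    abort_validation("`analysis` must come from run_analyze().")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  md <- c("# Call rhythm analysis report", "")
  g <- glance(analysis)
  md <- c(md, sprintf("%d sequences across %d site(s); %d element(s) discarded during segmentation.",
                      g$n_sequences, g$n_sites, g$n_discarded_elements), "")

  md <- c(md, "## Per-site aggregates", "", md_table(analysis$aggregates), "")

  md <- c(md, "## IOI histograms per site", "")
  seq_tbl <- analysis$summaries
  for (site in sort(unique(seq_tbl$site_name))) {
    md <- c(md, sprintf("### %s", site), "")
    iois <- seq_tbl |>
      dplyr::filter(.data$site_name == site) |>
      dplyr::pull(.data$mean_ioi_s)
    hist_tbl <- ioi_histogram(iois, bin_width_s)
    hist_tbl <- dplyr::filter(hist_tbl, .data$count > 0)
    md <- c(md, md_table(hist_tbl), "")
  }

  md <- c(md, "## Between-site comparisons", "")
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    md <- c(md, "No contrasts computed.", "")
  } else {
    md <- c(md, md_table(as_tibble(comparisons)), "")
  }

  if (figures) {
    fig_dir <- dirname(path)
    p1 <- plot_beat_distribution(analysis)
    ggplot2::ggsave(file.path(fig_dir, "beat_distribution.png"), p1,
                    width = 7, height = 4, dpi = 120)
    p2 <- plot_ioi_histogram(analysis, bin_width_s = bin_width_s)
    ggplot2::ggsave(file.path(fig_dir, "ioi_histogram.png"), p2,
                    width = 7, height = 4, dpi = 120)
    md <- c(md, "## Figures", "",
            "![Beat distribution per site](beat_distribution.png)", "",
            "![IOI histograms per site](ioi_histogram.png)", "")
  }

  writeLines(md, path)
  invisible(path)
}

# Minimal markdown table renderer for small tibbles.
md_table <- function(df) {
  if (nrow(df) == 0) return("(empty)")
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
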