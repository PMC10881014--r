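#' Remove outliers beyond k standard deviations
#'
#' Single-pass rule used on the dataset-level vector of per-sequence beats
#' before modeling: values more than `k` standard deviations away from the
#' mean (both computed once, over the full input) are removed. The rule is
#' not iterated.
#'
#' @param values Numeric vector, length >= 3.
#' @param k Multiplier of the standard deviation; default 3.
#' @return A list with `kept` (the retained values, original order) and
#'   `removed` (integer indices of removed values in the input).
#' @examples
#' remove_outliers(c(rnorm(50, 0.3, 0.05), 10))$removed
#' @export
remove_outliers <- function(values, k = 3) {
  if (!is.numeric(values) || length(values) < 3 || any(!is.finite(values))) {
    abort_validation("`values` must be a finite numeric vector of length >= 3.")
  }
  check_number(k, "k", lower = 0)
  m <- mean(values)
  s <- sd(values)
  out <- which(abs(values - m) > k * s)
  list(kept = values[setdiff(seq_along(values), out)], removed = out)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, as used for the between-year beat
#' comparison. Wraps [stats::t.test()].
#'
#' @param a,b Numeric vectors, each with at least 2 values; at least one
#'   group must have positive variance.
#' @return A one-row tibble: `statistic` (t), `df` (fractional),
#'   `p_value`, `mean_a`, `mean_b`, `method`.
#' @export
welch_t_test <- function(a, b) {
  check_group <- function(x, name) {
    if (!is.numeric(x) || length(x) < 2 || any(!is.finite(x))) {
      abort_validation(sprintf("`%s` must be a finite numeric vector of length >= 2.", name))
    }
  }
  check_group(a, "a")
  check_group(b, "b")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      abort_validation("Both groups constant and equal: t statistic undefined.")
    }
    abort_validation("Both groups have zero variance: t statistic undefined.")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a),
    mean_b = mean(b),
    method = "welch_t"
  )
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (between/within mean-square ratio,
#' equal-variance assumption) across two or more groups, with degrees of
#' freedom (k - 1, N - k). Wraps [stats::oneway.test()] with
#' `var.equal = TRUE`.
#'
#' @param groups Named or unnamed list of numeric vectors, each of length
#'   >= 2; at least 2 groups.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_groups`, `method`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_validation("`groups` must be a list of at least 2 numeric vectors.")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    abort_validation(sprintf("Every group needs >= 2 values (group %d has %d).",
                             which(sizes < 2)[1], min(sizes)))
  }
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) {
    abort_validation("All group values must be finite.")
  }
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]),
    df2 = unname(ht$parameter[2]),
    p_value = ht$p.value,
    n_groups = length(groups),
    method = "anova"
  )
}

#' Cohen's d effect size
#'
#' Absolute standardized mean difference between two groups, using the
#' pooled standard deviation with n - 1 weights.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return Non-negative scalar effect size.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # 1
#' @export
cohens_d <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2 || length(b) < 2 ||
      any(!is.finite(c(a, b)))) {
    abort_validation("`a` and `b` must be finite numeric vectors of length >= 2.")
  }
  na <- length(a)
  nb <- length(b)
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (pooled == 0) {
    abort_validation("Pooled standard deviation is zero: effect size undefined.")
  }
  abs(mean(a) - mean(b)) / pooled
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests and clips at 1, keeping
#' the input order. Wraps [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0 ||
      any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("`p_values` must all lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Export the model-ready covariate table
#'
#' Joins per-sequence rhythm summaries to their recording covariates and
#' writes one CSV row per sequence: the response candidates (`beat_hz`,
#' `cv`, `deviation`) plus every covariate a downstream smooth-regression
#' model would consume (site, date, hour, temperature, acoustic richness,
#' vessel densities by category).
#'
#' @param summaries Output of [summarize_rhythm()].
#' @param metas Covariate tibble as returned by [read_covariates()].
#' @param path Output CSV path, or `NULL` to only return the table.
#' @return The joined tibble, invisibly when written.
#' @export
export_model_table <- function(summaries, metas, path = NULL) {
  summaries <- as_tibble(summaries)
  metas <- as_tibble(metas)
  validate_covariates(metas)
  orphan <- setdiff(unique(summaries$source_id), metas$source_id)
  if (length(orphan) > 0) {
    abort_validation(sprintf(
      "No covariate row for source_id %s.",
      paste0("'", orphan, "'", collapse = ", ")))
  }
  tab <- summaries |>
    dplyr::select("source_id", "sequence_id", "n_elements",
                  "beat_hz", "cv", "deviation") |>
    dplyr::left_join(metas, by = "source_id") |>
    dplyr::select("source_id", "sequence_id", "site_name",
                  "beat_hz", "cv", "deviation", "n_elements",
                  "year", "month", "day", "hour", "water_temp_c",
                  "acoustic_richness", dplyr::all_of(covariate_density_cols()))
  if (!is.null(path)) {
    readr::write_csv(tab, path, progress = FALSE)
    return(invisible(tab))
  }
  tab
}
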