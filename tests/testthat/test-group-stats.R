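test_that("the 3-SD rule removes a gross outlier in a single pass", {
  set.seed(51)
  values <- c(rnorm(50, 0.3, 0.05), 10)
  out <- remove_outliers(values, k = 3)
  expect_equal(out$removed, 51L)
  expect_equal(length(out$kept), 50)

  expect_equal(remove_outliers(c(1, 2, 3))$removed, integer(0))
  expect_equal(remove_outliers(rep(5, 10))$removed, integer(0))  # all identical
  # k = 0 removes every non-mean value
  expect_equal(remove_outliers(c(1, 2, 3), k = 0)$removed, c(1L, 3L))
  expect_error(remove_outliers(c(1, 2)), class = "isobeat_error_validation")
})

test_that("Welch t matches the hand-computed statistic and is antisymmetric", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  res <- welch_t_test(a, b)
  # t = -1 / sqrt(2 * (5/3) / 4) = -1.0954, Welch-Satterthwaite df = 6
  expect_equal(res$statistic, -1 / sqrt(5 / 6), tolerance = 1e-6)
  expect_equal(res$df, 6, tolerance = 1e-9)

  flipped <- welch_t_test(b, a)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p_value, res$p_value)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(welch_t_test(c(1, 1), c(1, 1)), class = "isobeat_error_validation")
})

test_that("one-way ANOVA matches hand computation and is permutation-symmetric", {
  res <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 8)  # SSB 4 (df 1) over SSW 1 (df 2)
  expect_equal(c(res$df1, res$df2), c(1, 2))

  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g)$statistic, 0)

  set.seed(52)
  g2 <- list(rnorm(5), rnorm(6, 1), rnorm(4, 2))
  expect_equal(one_way_anova(g2)$statistic,
               one_way_anova(rev(g2))$statistic, tolerance = 1e-12)

  expect_error(one_way_anova(list(c(1, 2), c(3))),
               class = "isobeat_error_validation")
})

test_that("Welch t and ANOVA agree with a permutation oracle on small groups", {
  set.seed(53)
  a <- rnorm(8, 0.36, 0.08)
  b <- rnorm(9, 0.44, 0.08)
  obs_t <- abs(welch_t_test(a, b)$statistic)
  obs_f <- one_way_anova(list(a, b))$statistic

  pool <- c(a, b)
  n_perm <- 4000
  perm_t <- numeric(n_perm)
  perm_f <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), length(a))
    pa <- pool[idx]
    pb <- pool[-idx]
    se <- sqrt(var(pa) / length(pa) + var(pb) / length(pb))
    perm_t[i] <- abs((mean(pa) - mean(pb)) / se)
    gm <- mean(pool)
    ssb <- length(pa) * (mean(pa) - gm)^2 + length(pb) * (mean(pb) - gm)^2
    ssw <- sum((pa - mean(pa))^2) + sum((pb - mean(pb))^2)
    perm_f[i] <- (ssb / 1) / (ssw / (length(pool) - 2))
  }
  p_perm_t <- mean(perm_t >= obs_t)
  p_perm_f <- mean(perm_f >= obs_f)
  # Monte-Carlo error ~ sqrt(p(1-p)/n) ~ 0.005 at these p
  expect_equal(welch_t_test(a, b)$p_value, p_perm_t, tolerance = 0.03)
  expect_equal(one_way_anova(list(a, b))$p_value, p_perm_f, tolerance = 0.03)
})

test_that("Cohen's d matches pooled-SD arithmetic and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(54)
  a <- rnorm(10)
  b <- rnorm(12, 1)
  expect_equal(cohens_d(2 * a, 2 * b), cohens_d(a, b), tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), class = "isobeat_error_validation")
})

test_that("Cohen's d concentrates near the standardized mean difference as n grows", {
  set.seed(55)
  d_hat <- replicate(30, cohens_d(rnorm(400, 0.36, 0.08), rnorm(400, 0.46, 0.08)))
  expect_equal(mean(d_hat), 0.1 / 0.08, tolerance = 0.05)
})

test_that("Bonferroni multiplies by m, clips at 1 and preserves order", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni(c(0.5, 0.7)), c(1, 1))
  expect_equal(bonferroni(0.2), 0.2)
  expect_error(bonferroni(c(0.5, 1.2)), class = "isobeat_error_validation")
})

test_that("the model table joins summaries to covariates with the documented schema", {
  set.seed(56)
  els1 <- generate_isochronous_sequence(0.36, 0.1, 10, source_id = "rec1")
  els2 <- generate_isochronous_sequence(0.45, 0.1, 10, source_id = "rec2")
  summaries <- dplyr::bind_rows(
    summarize_rhythm(segment_sequences(els1, max_silence_s = Inf)),
    summarize_rhythm(segment_sequences(els2, max_silence_s = Inf))
  )
  metas <- make_covariates(c("rec1", "rec2"), c("siteA", "siteB"))
  tab <- export_model_table(summaries, metas)
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c(
    "source_id", "sequence_id", "site_name", "beat_hz", "cv", "deviation",
    "n_elements", "year", "month", "day", "hour", "water_temp_c",
    "acoustic_richness", "vessel_density_total", "vessel_density_trade",
    "vessel_density_fishing", "vessel_density_recreational",
    "vessel_density_passenger", "vessel_density_other"))

  path <- withr::local_tempfile(fileext = ".csv")
  export_model_table(summaries, metas, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 2)

  expect_error(export_model_table(summaries, metas[1, ]), "rec2",
               class = "isobeat_error_validation")
})
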