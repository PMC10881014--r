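# isobeat

Rhythm analysis of annotated animal call sequences from passive acoustic
monitoring, built for the isochronous (metronome-like) reproductive calls
of soniferous fish such as the brown meagre *Sciaena umbra*. Males of this
species emit trains of pulsatile elements at a strikingly regular beat;
quantifying that regularity — and comparing it between recording sites —
is the job of this package.

`isobeat` takes the analyst from Raven Pro selection tables (one row per
annotated sound element) to per-sequence rhythm statistics and
between-site comparisons:

- **IOI statistics.** For a sequence of element onsets `t_1 < … < t_n`,
  the inter-onset intervals are `IOI_i = t_{i+1} − t_i`. Isochrony shows
  up as a unimodal IOI distribution with a low coefficient of variation
  `CV = sd(IOI) / mean(IOI)`.
- **Best-fitting beat.** The IOI beat (Hz, elements per second) is the
  frequency `f` of the perfect isochronous grid `{φ + k/f}` that best
  matches the onsets. Fit quality is a ugof-style normalized deviation:
  each onset's distance to the nearest grid point, divided by half the
  beat period `1/(2f)`, averaged over onsets — 0 means perfect isochrony,
  1 means maximally off-grid. The search runs on a milli-hertz grid
  anchored at `f0 = 1/median(IOI)` (±50 %), which pins the fundamental and
  avoids the harmonic ambiguity of an unconstrained search; at each
  frequency the grid phase is chosen to exactly minimize the mean
  deviation. A beat of 5 Hz means one element every 200 ms.
- **Sequence building.** A call sequence is a temporally ordered run of at
  least 3 elements; in long recordings a sequence terminates after 10 s of
  silence, and sequences with very similar element signal-to-noise ratios
  are attributed to the same (stationary) individual.
- **Group statistics.** Dataset-level 3-SD outlier removal, one-way ANOVA
  across sites, pairwise Welch t-tests with Bonferroni correction and
  Cohen's d, and export of a model-ready covariate table (site, date,
  hour, temperature, acoustic richness, vessel densities) for downstream
  smooth-regression modelling.
- **Synthetic data.** A pulse-train generator with per-site presets
  (jittered-isochronous IOIs, per-sequence true beats, covariates, plus
  random Poisson-like control sequences) makes every pipeline stage
  verifiable by parameter recovery — no audio or field recordings needed.

## Worked example

The defining worked example: a noiseless train with one element every
200 ms fits a 5 Hz beat with zero deviation.

```r
library(isobeat)

fit <- best_fit_beat(c(0, 0.2, 0.4, 0.6, 0.8))
fit
#> Isochronous beat fit (5 onsets)
#>   beat: 5.0000 Hz (period 0.2000 s), phase 0.0000 s
#>   mean normalized deviation: 0.0000 (0 = perfect isochrony)
#>   searched 2.5000-7.5000 Hz around f0 = 5.0000 Hz
```

A full synthetic run — five site presets, 20 one-minute sequences each,
default jitter (IOI CV 0.18). The Venice preset generates faster beats
(0.46 Hz vs the pooled 0.36 Hz elsewhere), and the pipeline recovers
this:

```r
an <- run_analyze(pipeline_config(seed = 7))
an
#> Rhythm analysis: 100 sequences across 5 site(s), 0 discarded element(s)
#> # A tibble: 5 x 10
#>   site_name   n_sequences beat_mean_hz beat_sd_hz beat_min_hz beat_max_hz cv_mean
#> 1 crete                20        0.368     0.0868       0.236       0.569   0.178
#> 2 mallorca             20        0.388     0.105        0.137       0.587   0.181
#> 3 trieste2009          20        0.351     0.0913       0.165       0.516   0.173
#> 4 trieste2021          20        0.360     0.0978       0.189       0.493   0.179
#> 5 venice               20        0.460     0.0762       0.299       0.591   0.181
```

Each row aggregates the per-sequence summaries (`tidy(an)` returns them):
estimated beat means sit near the generating values and the mean CV near
the generating jitter of 0.18. Between-site contrasts after a single
dataset-level 3-SD outlier pass:

```r
cmp <- run_compare(an)
dplyr::filter(cmp, grepl("venice", groups) | method == "anova")
#>   method  groups                 statistic p_adjusted effect_size_d
#> 1 anova   all sites                  4.55    NA              NA
#> 2 welch_t crete vs venice           -3.55    0.0105          1.12
#> 3 welch_t mallorca vs venice        -2.46    0.192           0.776
#> 4 welch_t trieste2009 vs venice     -4.09    0.00222         1.29
#> 5 welch_t trieste2021 vs venice     -3.60    0.00966         1.14
```

The Venice contrasts carry the largest effect sizes (Cohen's d above 1),
mirroring the faster generating beat. `run_report(an, cmp, "report.md")`
renders a markdown report with per-site IOI histograms, beat
distributions (`autoplot(an)`) and the comparison table;
`export_model_table()` writes the covariate table a GAM-style model would
consume. No isochrony threshold is imposed anywhere: the package reports
CV, beat and deviation, and leaves classification to the analyst.

A thin command-line wrapper over the same functions lives at
`inst/scripts/isobeat-pipeline.R`
(`Rscript isobeat-pipeline.R all --seed 7 --out outdir`).

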