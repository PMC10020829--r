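# bioblitzr

Quantitative analysis of bioblitz outcomes from biodiversity event logs.

A bioblitz is a short, place-based event in which many people record as much
of the local biodiversity as they can, usually on a platform such as
iNaturalist, with an online community helping to identify the records
afterwards. Organizers and researchers routinely ask what these events
actually achieve beyond the day itself: do they produce usable species
inventories, and do they durably change the recording behaviour of the people
who take part? `bioblitzr` answers these questions from plain CSV event logs
(observations, identifications, project metadata), for citizen-science
researchers and platform analysts.

The package provides, as composable tibble-in/tibble-out functions:

* **Ingestion** — validated readers for the three event-log tables with a
  configurable column map (`read_observations()`, `read_identifications()`,
  `read_projects()`, `col_map()`), with per-row rejection reports.
* **Qualification & summaries** — the definitional filter for a bioblitz
  (more than one observer, at least one identifier, bounded duration;
  `qualify_projects()`), per-project summary statistics
  (`summarize_projects()`), start-timing histograms and description word
  frequencies.
* **Engagement** — the *weekly devoted days* metric (distinct recording days
  per 7-day block, `weekly_devoted_days()`), participant classification
  (only-during / lapsed / continuing; `categorize_participants()`), and the
  seasonality-controlled paired-week difference panel
  (`paired_differences()`, `build_panel()`).
* **Decay model** — the package's analytical core (`fit_decay()`): the
  post-event boost in recording activity is modelled as

  ```
  y = a * exp(-b * x)
  ```

  where `x` is weeks since the event, `y` the difference in weekly devoted
  days against the weekday-aligned week one year earlier, `a` the initial
  boost (days/week) and `b` the decay constant (per week). Project-level
  heterogeneity is handled by a two-stage estimator (per-project nonlinear
  least squares, then precision-weighted pooling on the log scale). Derived
  quantities: half-life `ln(2)/b` (`half_life()`), cumulative additional
  recording days `a/b` (`cumulative_boost()`), and the platform-level
  extrapolation (`extrapolate_boost()`).
* **Networks** — the observer–identifier network of an event with node roles
  and identification-weighted degrees (`build_network()`, `degree_table()`,
  GraphML export).
* **Ratings** — rank tallies over the five canonical bioblitz aims and
  Jaccard inter-rater agreement (`rank_tally()`, `jaccard_agreement()`).
* **Synthetic data** — a seeded generator of event logs with the full
  statistical structure above (`generate_bioblitz_data()`,
  `synth_params()`), so every stage is testable without platform downloads.
* **Pipeline** — `run_pipeline()` / `run_pipeline_config()` chain all stages
  and emit tidy CSVs plus a single JSON report.

## Worked example

Simulate a 20-event corpus and run the full analysis:

```r
library(bioblitzr)

sim <- generate_bioblitz_data(synth_params(seed = 1, n_projects = 20))
report <- run_pipeline(sim$observations, sim$identifications, sim$projects)
report
#> Bioblitz outcome analysis
#>   projects: 20 candidate, 20 qualified
#>   participants categorized: 708
#>   mix: only_during 76.8%, lapsed 1.4%, continuing_new 10.7%, continuing_veteran 11.0%
#>   decay: a = 0.337 d/wk, b = 0.046 /wk (SE 0.010), half-life 14.9 wk, cumulative boost 7.3 d
```

All 20 simulated events pass the definitional filter; about 77% of the 708
participants recorded only during their event, ~1.4% lapsed, and ~22%
continued — the generator's configured mix, recovered from the logs alone.
The decay fit says continuing participants recorded ~0.34 days/week more
immediately after their event than in the same weeks a year earlier, the
boost halving every ~15 weeks and integrating to ~7 extra recording days per
continuing participant (at this small corpus size the estimates carry the
standard errors shown; `autoplot(report$fit)` plots observed vs fitted
weekly means).

Broom-style accessors and the platform extrapolation:

```r
glance(report$fit)
#> # A tibble: 1 × 11
#>   a_hat  b_hat   se_a   se_b half_life_weeks cumulative_boost_days n_points
#> 1 0.337 0.0464 0.0408 0.0100            14.9                  7.27     7700
#> # ... n_projects, method, converged, degenerate

extrapolate_boost(n_participants = 113076, continuation_rate = 0.215,
                  cumulative_days = 7.4, obs_per_day = 1,
                  total_observations = 1851444)
#> # A tibble: 1 × 2
#>   additional_observations share_of_total
#> 1                 179904.         0.0972
```

With 113,076 event participants in a year, a 21.5% continuation rate and 7.4
additional recording days each, events would add ~180,000 observations —
about 10% of what the events themselves collected.

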