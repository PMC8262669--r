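# emaflow

A headless engine for home-based **ecological momentary assessment
(EMA)** studies in Parkinson disease. Patients at home complete four
anchor-driven sessions a day — *on waking* (wake + 30 min), *after
medications* (first dose + 60 min), *afternoon*, *evening*, plus
on-demand *nap* sessions — each carrying subjective scales (SCOPA-DC
diary-card items, 0–10 visual analogue scales, the Stanford sleepiness
scale), a 30-second alternating two-key finger-tapping test per hand,
and a once-daily 24-question sleep diary. `emaflow` implements the whole
pipeline behind such a system, headless and reproducible:

* **Protocol model** — versioned protocols (alpha / v1.0 / v2.0) with
  question banks, feature flags, answer-domain validation, and workload
  accounting: over a 14-night home period a patient is expected to
  complete 4n − 1 = 55 scale tasks, 55 tapping tests, and 14 diaries
  (124 tasks, 941 questions at 11 scale questions per session).
* **Session scheduler** — a deterministic state machine: anchors open
  sessions, sessions expire on a half-open window, the diary carries
  over until done, partial records are rejected whole.
* **Tapping-test scoring** — the four BRAIN-test-style parameters:
  kinesia score KS (keystrokes / 30 s), akinesia time AT (mean dwell,
  ms), incoordination score IS (travel-time variance, ms²), dysmetria
  score DS (adjacency-weighted wrong-key rate).
* **Interaction analytics** — the *target ratio*: button hits over total
  screen touches, per session → per patient → cohort (mean of patient
  means), with first/last-day exclusions.
* **Store and forward** — an append-only journal, idempotent sync with
  injectable transport failures, portal-style conjunctive filters
  (patient, date, session, type, hand, H/V0/V1 categorization), and
  round-tripping CSV export.
* **Study analytics** — compliance (completed/expected, half-up 2
  decimals), pooled one-tailed two-proportion z-test for version
  comparisons, satisfaction summaries (1–4 levels, integer percents,
  pooled question groups), daily workload minutes.
* **Patient simulator** — seeded synthetic cohorts with known ground
  truth: anchor jitter, per-session adherence with within-day decline,
  latent-trajectory questionnaire answers, parameterized tapping
  streams, touch logs.

Everything is tidyverse-shaped: functions take and return tibbles,
results have `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

```r
library(emaflow)

p <- default_protocol("v2.0")
expected_tasks(p)
#> # A tibble: 1 × 5
#>   subjective_scales fit_test sleep_diary total_tasks total_questions
#>               <int>    <int>       <int>       <int>           <int>
#> 1                55       55          14         124             941

# a seeded cohort, replayed end to end through the scheduler
sim <- simulate_cohort(sim_params(n_patients = 26, seed = 1))
run <- run_study(sim)
rep <- compliance_report(run_tasks(run), sim$cohort, sim$protocol)
glance(rep)
#> # A tibble: 1 × 3
#>   completed expected percent
#>       <int>    <int>   <dbl>
#> 1      2918     3224    90.5

# compliance on published study tallies
compliance(5707, 6420)
#> [1] 88.89

# tapping-test scoring
score_trial(tapping_stream(rate_hz = 1.7, dwell_mean_ms = 120,
                           dwell_sd_ms = 10, travel_sd_ms = 30,
                           error_rate = 0, seed = 7))
#> # A tibble: 1 × 5
#>   hand  kinesia_score akinesia_time incoordination_score dysmetria_score
#>   <chr>         <int>         <dbl>                <dbl>           <dbl>
#> 1 right            51          122.                1064.               0

# usability
tr <- average_target_ratio(sim$touches, sim$protocol)
glance(tr)
#> # A tibble: 1 × 3
#>   cohort_mean    sd n_patients
#>         <dbl> <dbl>      <int>
#> 1        90.1 0.849         26
```

`glance(rep)` says 2918 of the 3224 protocol-expected tasks
(26 patients × 124) were completed — 90.51% overall compliance, which
tracks the simulator's adherence parameters. The tapping scores recover
the generator's kinematics (dwell 120 ms, travel variance 900 ms²), and
the cohort target ratio sits at the 90% touch-accuracy ground truth.

A thin command-line wrapper lives at `inst/cli/ema.R`
(`simulate` / `report` / `export` subcommands).

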