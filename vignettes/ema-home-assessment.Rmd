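---
title: "Modelling a home-based EMA study: scheduling, tapping kinematics, and compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a home-based EMA study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaflow)
library(dplyr)
```

## The setting

Ecological momentary assessment (EMA) samples a subject's state
repeatedly, prospectively, in their own environment, to avoid the recall
bias of retrospective questionnaires. In Parkinson disease the motor and
non-motor picture fluctuates within a single day — with the dopaminergic
medication cycle, with fatigue, and around sleep (the transient morning
mobility improvement known as *sleep benefit*) — so a home protocol has to
pin observations to clinically meaningful moments rather than clock
times.

`emaflow` is a headless engine for such a protocol. Patients complete
four daily sessions anchored to their own day: *on waking* (30 minutes
after the wake anchor), *after medications* (60 minutes after the first
dopaminergic dose), *afternoon* (before the afternoon dose), and
*evening* (at the bedtime anchor), plus an on-demand *nap* session. Each
session carries a subjective-scales questionnaire and a 30-second
alternating finger-tapping test per hand; a 24-question sleep diary is
completed once per day in any session. The package models the protocol,
drives the session state machine, scores the tapping test, persists
records store-and-forward style, and computes the study-level analytics
(compliance, usability, satisfaction, workload). A synthetic-patient
simulator with known ground truth makes every stage testable without any
real data.

## Workload accounting

The analysed home period spans `home_nights + 1` calendar days: the
arrival evening (study day 0), `home_nights - 1` full days, and a final
morning ending with the after-medications session. Under this
enumeration a 14-night period expects `4n - 1 = 55` scale tasks, 55
tapping tests and 14 diaries — 124 tasks and, with the 11-question scale
bank, 941 questions:

```{r}
expected_tasks(default_protocol("v2.0"))
```

This enumeration is the one point where two readings of the protocol
disagree: counting "day 1 evening through day 14 morning" over 14
calendar days gives 51 sessions, while the published per-patient totals
require 55. We adopt the 15-calendar-day reading (14 *nights*) because it
reproduces the totals exactly; the brute-force calendar oracle in the
test suite enumerates it independently.

The earliest protocol version (alpha) had a 5-question scale bank. Its
published per-day question total is not derivable from `4 × 5 + 24`, so
the alpha bank size is configuration, and no question-total claim is
made for it.

## The session state machine

Anchor events are patient-generated timestamps. Each anchor opens a
`SessionInstance` at `anchor + offset`; an instance not completed before
its expiry transitions to `expired` and its tasks are lost for the day.
Expiry windows were not published, so they are explicit configuration
with defaults chosen to preserve the clinical ordering rather than to
claim real values: the on-waking window closes at the first-medication
anchor or after 3 h, after-medications after 3 h, the afternoon window
at the bedtime anchor or after 4 h, the evening window 60 minutes after
the bedtime anchor. Design choices worth stating:

* **Study-day boundary** is local midnight; the diary is attributed to
  the night ending that morning (days 1 … n). Wake-to-wake boundaries
  would complicate the arrival evening for no analytical gain.
* **The afternoon session** is anchored to the afternoon dose where one
  exists and otherwise synthesized at a configurable local time (15:00
  default), since not every patient has an afternoon dose.
* **Expiry is half-open**: at `now == expires_at` the session is already
  expired. Idempotent sweeps (`expire_sessions()`) both open due
  sessions and expire overdue ones, so a monotone clock can never
  un-complete or un-expire anything.
* **Ties** between simultaneously due sessions break in the fixed order
  on-waking < after-medications < afternoon < evening, nap always last.
* **Session completion** means all attached tasks except the once-daily
  diary are done; the diary is prompted at every session until completed
  but never blocks a session, and remains acceptable in a session whose
  own tasks are already done, until the window closes.
* **All-or-nothing recording**: a questionnaire with any unanswered or
  out-of-domain answer, or a tapping task missing a valid trial for
  either hand, is rejected whole — partial records are never stored.

Replay is deterministic: feeding the same event stream twice produces
bit-identical serialized state, which is what makes the journal a
sufficient crash-recovery record.

## Tapping-test kinematics

The motor task is a keyboard alternation test in the BRAIN-test
tradition; the published protocol defers the parameter formulas to that
test, so the package fixes them explicitly and treats them as its own
contract:

* **Kinesia score (KS)** — number of key-down events in the 30-second
  window, wrong keys included (they are keystrokes).
* **Akinesia time (AT)** — mean key dwell `up − down` in ms over
  counted keystrokes.
* **Incoordination score (IS)** — sample variance (n − 1) of travel
  times, travel measured key-up to next key-down, requiring at least
  three counted keystrokes.
* **Dysmetria score (DS)** — mean strike weight, where a target key
  weighs 0, a key adjacent to a target 1, any other key 2. Adjacency is
  a configured map: physical key separation is not inferable from key
  codes.

Wrong-key strikes are excluded from dwell/travel statistics by default
(`include_errors = FALSE` exposes the alternative). One consequence to
know about: when an error interrupts an alternation run, the travel time
between the surrounding target strikes spans the interruption, so IS
responds to error interruptions as well as to rhythm noise. On
error-free streams the scorer recovers the generator's travel variance
exactly in expectation; with errors injected, IS is by construction
larger than the travel-noise variance alone. Scores are reported per
30-second trial without rescaling.

```{r}
trial <- tapping_stream(rate_hz = 1.7, dwell_mean_ms = 120,
                        dwell_sd_ms = 10, travel_sd_ms = 30,
                        error_rate = 0, seed = 7)
score_trial(trial)
```

## Usability: the target ratio

From v1.0 the application logs every touchscreen interaction with
coordinates and timestamp. The *target ratio* is hits on button regions
over total touches, as a percentage. Averaging order matters and is
fixed: per-session ratios are averaged within each patient, and the
cohort value is the unweighted mean of patient means — not the pooled
ratio, which weights patients by how much they touch the screen. Only
fully completed home days are included: the arrival evening and the two
final-morning sessions are excluded (exactly 3 slots per patient on a
standard run). Zero-touch sessions cannot contribute a ratio and are
dropped; hit-testing uses half-open rectangles with declaration-order
tie-breaks so a touch is never attributed twice.

## Compliance, proportions, rounding

Compliance is completed over expected tasks, as a percentage. Missing
tasks count as non-compliant regardless of cause — the engine cannot
distinguish a refusal from a technical failure, so the estimate is a
floor. Expected counts come from the protocol ledger per version times
cohort size; completions are counted inside the analysis window, naps
excluded (they cannot be scheduled a priori, so no expectation exists).

Version comparisons use the classical pooled two-proportion *z*-test,
one-tailed (later version better), without continuity correction by
default and with a Yates-corrected variant behind a flag, since the
exact published variant is unspecified. Values are returned at full
precision; rounding is presentation.

All printed-style percentages round half-up — 2 decimals for compliance,
integers for satisfaction — because half-to-even rounding does not
reproduce conventional clinical report values. The rule lives in one
place, `round_half_up()`.

Satisfaction answers are categorical 1–4. Per-question percentages use
the respondent count; the three usability questions (and the three
interface questions) are additionally pooled with denominator
`respondents × 3`.

## The simulator and what passing tests mean

`simulate_cohort()` generates anchors with Gaussian jitter (wake 07:00
± 30 min, first dose +45 ± 10 min, afternoon dose 15:00 ± 30 min,
bedtime 22:30 ± 45 min), per-session adherence draws, full response
sets, two-hand tapping streams, and touch logs, all under a single root
seed with per-patient derived substreams so any one patient is
re-generable. Defaults are the study conditions the engine targets: 26
patients on v2.0 for 14 nights; per-session-kind adherence near the
observed v2.0 compliance with a multiplicative within-day decline
(0.985 per session ordinal — the decline is reported qualitatively, so
the factor is a modelling choice); touch accuracy 0.901; tapping at 1.7
strikes/s with 110 ± 25 ms dwell and 50 ms travel sd, in the range
keyboard tapping tests report for mild-to-moderate disease; per-task
durations set so a fully adherent day costs about 11 ¼ minutes on
v1.0/v2.0 and about 8 ⅔ on alpha.

Questionnaire answers follow per-patient latent levels performing small
day-to-day random walks inside each instrument's range — plausible time
series, but no clinical realism is claimed. The simulator emulates *no*
technical failures, no learning effects, no naps by default, and
independence across sessions given the adherence parameters; passing
tests therefore demonstrate that the machinery measures what the
generator put in, not that real patients behave this way.

Session lengths in the simulator respect the session windows (durations
compress when a truncated window leaves little room), which is what
keeps the replayed store in exact agreement with the generator's
adherence draws — the test suite asserts zero rejected events on
simulated cohorts.

## Problem sizes and numerical conventions

The test suite runs cohorts of 1–4 patients over 3–6 nights for
state-machine and analytics checks, 200 trials per setting for
parameter recovery, and one 26-patient × 14-night cohort for the
end-to-end compliance property; the acceptance script uses the same
full-size cohort. For the end-to-end check every task is made marginally
Bernoulli(0.9) by disabling the decline and solving the per-offer diary
probability from `1 − (1 − 0.9q)⁴ = 0.9`; the tolerance is three
standard errors computed at the level of the actual independent units
(sessions carry two coupled tasks, so the naive per-task binomial SE
would be too tight). The final-morning diary is offered in only two
sessions, a knowingly accepted −0.2 percentage-point bias.

Degenerate inputs are defined, not patched over: zero-touch sessions
and empty stores yield `NA` summaries rather than zeros; incoordination
needs three keystrokes; a zero home period expects zero everything.

## Known limitations

* Expiry windows, the alpha question bank, and the exact proportion-test
  variant are configuration or flagged options, not claims about the
  original system.
* The engine is single-timezone per patient and assumes anchors arrive
  in order within a day (out-of-order same-kind anchors are rejected,
  not reconciled).
* The remote store is an in-process object with an injectable failure
  point; real transport, authentication, and the researcher portal UI
  are out of scope, as are case-report-form synchronization and
  polysomnography-derived analyses.
* IS inflation under error interruptions, described above, is inherent
  to excluding wrong-key strikes from travel statistics.
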