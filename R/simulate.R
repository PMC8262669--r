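#' Simulation parameters
#'
#' Ground-truth parameters for the synthetic cohort generator. Defaults
#' describe the study conditions the engine targets: 26 patients on the
#' v2.0 protocol over 14 home nights, anchor times with realistic jitter,
#' per-session-kind adherence probabilities near the observed v2.0
#' compliance with a multiplicative within-day decline (compliance falls
#' from the first morning session to the evening), tapping kinematics in
#' the range reported for mild-to-moderate Parkinson disease on keyboard
#' tapping tests, 90% touch accuracy, and per-task active durations that
#' put the daily workload at about 11 1/4 minutes on v1.0/v2.0 (about
#' 8 2/3 minutes on alpha, whose scale task is shorter).
#'
#' @param n_patients Cohort size.
#' @param version Protocol version for the whole cohort.
#' @param home_nights Home-period length in nights.
#' @param seed Root seed (mandatory); per-patient substreams are derived
#'   from it so individual patients are re-generable.
#' @param wake_mean_h,wake_sd_min Wake anchor: mean local hour and jitter.
#' @param med_delay_mean_min,med_delay_sd_min First dose delay after wake.
#' @param afternoon_mean_h,afternoon_sd_min Afternoon-dose anchor.
#' @param bed_mean_h,bed_sd_min Bedtime anchor.
#' @param adherence Named per-session-kind completion probabilities.
#' @param decline Multiplicative within-day decline per session ordinal
#'   (1 = none).
#' @param diary_p Probability the pending diary is completed in a given
#'   completed session.
#' @param tap_rate_hz,dwell_mean_ms,dwell_sd_ms,travel_sd_ms Tapping
#'   kinematics: strike rate, dwell mean/sd, travel-time sd.
#' @param error_rate Probability a strike lands on a wrong key.
#' @param adjacent_error_frac Fraction of wrong strikes on an adjacent
#'   key (the rest land far off target).
#' @param touch_accuracy Probability a screen touch hits a button region.
#' @param touches_per_session_mean Mean touches logged per session.
#' @param task_min Named per-task mean active durations in minutes.
#' @param between_patient_sd Relative sd of per-patient motor parameters
#'   around the cohort means.
#' @param tz Local time zone of the simulated patients.
#' @return An `ema_sim_params` list.
#' @export
sim_params <- function(n_patients = 26,
                       version = "v2.0",
                       home_nights = 14,
                       seed = 1L,
                       wake_mean_h = 7, wake_sd_min = 30,
                       med_delay_mean_min = 45, med_delay_sd_min = 10,
                       afternoon_mean_h = 15, afternoon_sd_min = 30,
                       bed_mean_h = 22.5, bed_sd_min = 45,
                       adherence = c(on_waking = 0.92,
                                     after_medications = 0.90,
                                     afternoon = 0.92,
                                     evening = 0.90),
                       decline = 0.985,
                       diary_p = 0.95,
                       tap_rate_hz = 1.7,
                       dwell_mean_ms = 110, dwell_sd_ms = 25,
                       travel_sd_ms = 50,
                       error_rate = 0.03,
                       adjacent_error_frac = 0.7,
                       touch_accuracy = 0.901,
                       touches_per_session_mean = 40,
                       task_min = NULL,
                       between_patient_sd = 0.1,
                       tz = "Europe/Zurich") {
  if (is.null(task_min)) {
    task_min <- if (version == "alpha") {
      c(subjective_scales = 0.75, fit_test = 1.20, sleep_diary = 0.883)
    } else {
      c(subjective_scales = 1.30, fit_test = 1.20, sleep_diary = 1.25)
    }
  }
  stopifnot(all(adherence >= 0 & adherence <= 1),
            decline > 0, decline <= 1,
            diary_p >= 0, diary_p <= 1,
            touch_accuracy >= 0, touch_accuracy <= 1,
            tap_rate_hz > 0, dwell_sd_ms >= 0, travel_sd_ms >= 0,
            error_rate >= 0, error_rate <= 1,
            !is.null(seed))
  structure(as.list(environment()), class = "ema_sim_params")
}

#' Synthetic alternating tapping stream
#'
#' Generates a 30-second alternating two-key keystroke stream with
#' Gaussian dwell and travel noise: the subject alternates between the
#' two target keys; each strike dwells `N(dwell_mean, dwell_sd)` ms
#' (truncated at 5 ms) and travel to the next key takes
#' `N(1000/rate - dwell_mean, travel_sd)` ms (truncated at 10 ms), so the
#' mean strike rate is `rate`. With probability `error_rate` a strike
#' lands on a wrong key — adjacent to the intended target with
#' probability `adjacent_error_frac`, far off otherwise.
#'
#' @param rate_hz Mean strike rate per second.
#' @param dwell_mean_ms,dwell_sd_ms Key dwell distribution.
#' @param travel_sd_ms Travel-time standard deviation.
#' @param error_rate,adjacent_error_frac Error injection; see above.
#' @param duration_s Trial length (default 30 s).
#' @param seed Optional seed for a self-contained stream.
#' @param target_keys,adjacency Key geometry; see [default_adjacency()].
#' @param hand Hand label for the resulting trial.
#' @return An [fit_trial()] object.
#' @export
tapping_stream <- function(rate_hz = 1.7, dwell_mean_ms = 110,
                           dwell_sd_ms = 25, travel_sd_ms = 50,
                           error_rate = 0, adjacent_error_frac = 0.7,
                           duration_s = 30, seed = NULL,
                           target_keys = c("s", ";"),
                           adjacency = default_adjacency(),
                           hand = "right") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rate_hz > 0)
  period <- 1000 / rate_hz
  travel_mean <- max(period - dwell_mean_ms, 20)
  lim <- duration_s * 1000
  # generous upper bound on strikes, then truncate to the window
  n_max <- ceiling(lim / min(period, dwell_mean_ms + 20) ) + 10
  dwell <- pmax(stats::rnorm(n_max, dwell_mean_ms, dwell_sd_ms), 5)
  travel <- pmax(stats::rnorm(n_max, travel_mean, travel_sd_ms), 10)
  down <- cumsum(c(0, (dwell + travel)[-n_max]))
  up <- down + dwell
  keep <- up <= lim
  n <- sum(keep)
  intended <- target_keys[rep_len(1:2, n)]
  key <- intended
  distant_keys <- c("q", "g", "m", "3", "8")
  err <- stats::runif(n) < error_rate
  for (i in which(err)) {
    key[i] <- if (stats::runif(1) < adjacent_error_frac) {
      sample(adjacency[[intended[i]]], 1)
    } else {
      sample(distant_keys, 1)
    }
  }
  fit_trial(
    tibble::tibble(key = key, down_ms = down[keep], up_ms = up[keep]),
    hand = hand, target_keys = target_keys, duration_s = duration_s
  )
}

#' Synthetic touch stream
#'
#' Each touch lands inside a (uniformly chosen) button region with
#' probability `p`, and on a background point otherwise; `on_target` is
#' recomputed from the coordinates by [hit_test()], never assumed.
#'
#' @param p Touch accuracy probability.
#' @param layout An `ema_layout`.
#' @param n Number of touches.
#' @param seed Optional seed.
#' @return Tibble of interaction events: `x`, `y`, `t_ms`, `on_target`,
#'   `target_id`.
#' @export
touch_stream <- function(p, layout = default_layout(), n = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(p >= 0, p <= 1)
  r <- layout$regions
  hit <- stats::runif(n) < p
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) {
      j <- sample(nrow(r), 1)
      x[i] <- stats::runif(1, r$x0[j], r$x1[j] - 1e-6)
      y[i] <- stats::runif(1, r$y0[j], r$y1[j] - 1e-6)
    } else {
      repeat {
        x[i] <- stats::runif(1, 0, layout$width - 1e-6)
        y[i] <- stats::runif(1, 0, layout$height - 1e-6)
        if (is.na(hit_test(layout, x[i], y[i]))) break
      }
    }
  }
  tid <- hit_test(layout, x, y)
  tibble::tibble(x = x, y = y,
                 t_ms = sort(stats::runif(n, 0, 120e3)),
                 on_target = !is.na(tid), target_id = tid)
}

# Draw a full answer set for a questionnaire task from per-patient latent
# levels: each question has a latent level that performs a small
# day-to-day random walk inside its range, so time series look like real
# self-ratings rather than white noise.
draw_answers <- function(bank, latent, day) {
  value <- vector("list", nrow(bank))
  for (i in seq_len(nrow(bank))) {
    q <- bank[i, ]
    if (q$type == "timestamp") {
      value[[i]] <- format_iso8601(
        as.POSIXct(sprintf("2000-01-%02d 22:30:00", (day %% 27) + 1),
                   tz = "UTC"))
    } else {
      lv <- latent[[q$id]] + stats::rnorm(1, 0, 0.6)
      value[[i]] <- as.integer(pmin(pmax(round(lv), q$lo), q$hi))
    }
  }
  tibble::tibble(question_id = bank$id, value = value)
}

#' Simulate a synthetic patient cohort
#'
#' Generates the full event record of a home-period study: anchor events
#' (wake, first dose, afternoon dose, bedtime) with Gaussian jitter,
#' per-session adherence decisions with a within-day decline, complete
#' questionnaire responses and two-hand tapping streams for adherent
#' sessions, once-daily diary completion with carryover, and per-session
#' touch logs. Everything is deterministic given the root seed, and the
#' realized ground truth (per-patient parameters and every adherence
#' draw) is returned alongside the streams so each downstream statistic
#' can be recomputed independently.
#'
#' Sessions are generated over the analysed schedule — arrival evening,
#' full days, final morning (see [expected_schedule()]) — which is what
#' makes simulated compliance directly comparable to the protocol
#' expectation.
#'
#' @param params An [sim_params()] object.
#' @param protocol Optional `ema_protocol`; defaults to
#'   `default_protocol(params$version, params$home_nights)`.
#' @param start_date Date of the arrival day (study day 0).
#' @return An `ema_cohort_sim` list: `events` (anchor/task event tibble
#'   across patients), `touches` (touch-log tibble), `truth` (list with
#'   `patients` and `sessions` ground-truth tibbles), `cohort`
#'   (patient-version map), `protocol`.
#' @export
simulate_cohort <- function(params = sim_params(), protocol = NULL,
                            start_date = as.Date("2018-03-05")) {
  stopifnot(inherits(params, "ema_sim_params"))
  if (is.null(protocol)) {
    protocol <- default_protocol(params$version, params$home_nights)
  }
  layout <- default_layout()
  scale_bank <- protocol$questions[protocol$questions$task_kind == "subjective_scales", ]
  diary_bank <- protocol$questions[protocol$questions$task_kind == "sleep_diary", ]
  n_nights <- protocol$home_nights
  sched <- expected_schedule(protocol)
  ordinal <- stats::setNames(0:3, SCHEDULED_KINDS)

  all_events <- list()
  all_touches <- list()
  truth_sessions <- list()
  truth_patients <- list()

  for (pi in seq_len(params$n_patients)) {
    set.seed(derive_seed(params$seed, pi))
    pid <- sprintf("P%03d", pi)

    # per-patient motor/behaviour parameters around cohort means
    jig <- function(m) m * stats::rnorm(1, 1, params$between_patient_sd)
    pp <- list(
      tap_rate_hz = max(jig(params$tap_rate_hz), 0.5),
      dwell_mean_ms = max(jig(params$dwell_mean_ms), 40),
      dwell_sd_ms = max(jig(params$dwell_sd_ms), 2),
      travel_sd_ms = max(jig(params$travel_sd_ms), 5),
      error_rate = min(max(jig(params$error_rate), 0), 0.5),
      # accuracy is a cohort-level condition: jittering it with a ceiling
      # at 1 would bias the cohort mean below the parameter
      touch_accuracy = params$touch_accuracy
    )
    truth_patients[[pi]] <- tibble::as_tibble(c(list(patient_id = pid), pp))

    latent <- stats::setNames(
      lapply(seq_len(nrow(scale_bank)), function(i) {
        q <- scale_bank[i, ]
        stats::runif(1, q$lo, q$hi)
      }), scale_bank$id)
    latent_diary <- stats::setNames(
      lapply(seq_len(nrow(diary_bank)), function(i) {
        q <- diary_bank[i, ]
        if (q$type == "timestamp") 0 else stats::runif(1, q$lo, q$hi)
      }), diary_bank$id)

    events <- list()
    minutes <- function(m) as.difftime(m, units = "mins")
    anchor_times <- list()  # per day: wake, med, bed

    push_anchor <- function(kind, at, day) {
      events[[length(events) + 1L]] <<- tibble::tibble(
        patient_id = pid, event_type = "anchor", kind = kind,
        session_kind = NA_character_, task_kind = NA_character_,
        study_day = day, at = at, payload = list(NULL)
      )
    }
    push_task <- function(session_kind, task_kind, at, day, payload) {
      events[[length(events) + 1L]] <<- tibble::tibble(
        patient_id = pid, event_type = "task", kind = NA_character_,
        session_kind = session_kind, task_kind = task_kind,
        study_day = day, at = at, payload = list(payload)
      )
    }

    day_time <- function(day, hours) {
      as.POSIXct(start_date + day, tz = params$tz) + hours * 3600
    }

    # anchors for every day of the home period
    for (day in 0:n_nights) {
      kinds_today <- sched$kind[sched$study_day == day]
      if ("on_waking" %in% kinds_today || day > 0) {
        wake <- day_time(day, params$wake_mean_h) +
          stats::rnorm(1, 0, params$wake_sd_min * 60)
        med <- wake + minutes(max(
          stats::rnorm(1, params$med_delay_mean_min, params$med_delay_sd_min),
          35))
      } else {
        wake <- NA; med <- NA
      }
      if ("on_waking" %in% kinds_today) push_anchor("wake_time", wake, day)
      if ("after_medications" %in% kinds_today) push_anchor("first_med_intake", med, day)
      if ("afternoon" %in% kinds_today) {
        push_anchor("afternoon_dose_due",
                    day_time(day, params$afternoon_mean_h) +
                      stats::rnorm(1, 0, params$afternoon_sd_min * 60), day)
      }
      if ("evening" %in% kinds_today) {
        push_anchor("bedtime",
                    day_time(day, params$bed_mean_h) +
                      stats::rnorm(1, 0, params$bed_sd_min * 60), day)
      }
    }
    anchors <- dplyr::bind_rows(events)

    # walk the schedule: adherence decisions and task generation
    diary_done <- rep(FALSE, n_nights + 1)
    for (r in seq_len(nrow(sched))) {
      day <- sched$study_day[r]
      skind <- sched$kind[r]
      anchor_at <- function(akind) {
        row <- anchors[anchors$study_day == day & anchors$kind == akind, ]
        if (nrow(row) == 0) as.POSIXct(NA) else row$at[1]
      }
      due <- anchor_at(session_spec_anchor(skind)) +
        minutes(protocol$sessions$offset_min[match(skind, protocol$sessions$kind)])
      window <- protocol$sessions$window_min[match(skind, protocol$sessions$kind)]
      # effective expiry mirrors the scheduler's anchor truncation rules
      expiry <- due + minutes(window)
      if (skind == "on_waking") {
        expiry <- min(expiry, anchor_at("first_med_intake"), na.rm = TRUE)
      } else if (skind == "afternoon") {
        expiry <- min(expiry, anchor_at("bedtime"), na.rm = TRUE)
      }
      avail <- as.numeric(difftime(expiry, due, units = "mins"))

      p_complete <- params$adherence[[skind]] * params$decline^ordinal[[skind]]
      done <- stats::runif(1) < p_complete
      truth_sessions[[length(truth_sessions) + 1L]] <- tibble::tibble(
        patient_id = pid, study_day = day, session_kind = skind,
        p_complete = p_complete, completed = done
      )
      if (!done) next

      do_diary <- day >= 1 && !diary_done[day + 1] &&
        stats::runif(1) < params$diary_p

      # draw task durations, then fit the whole session inside the window
      dur_scales <- max(stats::rnorm(1, params$task_min[["subjective_scales"]], 0.15), 0.2)
      dur_fit <- max(stats::rnorm(1, params$task_min[["fit_test"]], 0.1), 1.0)
      dur_diary <- if (do_diary) {
        max(stats::rnorm(1, params$task_min[["sleep_diary"]], 0.2), 0.3)
      } else 0
      total <- dur_scales + dur_fit + dur_diary + 0.3
      if (total > avail - 0.5) {
        shrink <- max((avail - 0.7) / total, 0.1)
        dur_scales <- dur_scales * shrink
        dur_fit <- dur_fit * shrink
        dur_diary <- dur_diary * shrink
        total <- dur_scales + dur_fit + dur_diary + 0.3
      }
      t0 <- due + minutes(stats::runif(1, 0.2, max(avail - total - 0.2, 0.25)))

      ans <- draw_answers(scale_bank, latent, day)
      push_task(skind, "subjective_scales", t0 + minutes(dur_scales), day,
                list(answers = ans, started_at = t0,
                     ended_at = t0 + minutes(dur_scales)))
      # latent drift day to day
      for (nm in names(latent)) {
        q <- scale_bank[scale_bank$id == nm, ]
        latent[[nm]] <- min(max(latent[[nm]] + stats::rnorm(1, 0, 0.3), q$lo), q$hi)
      }

      t1 <- t0 + minutes(dur_scales + 0.1)
      trials <- lapply(c("left", "right"), function(h) {
        tapping_stream(
          rate_hz = pp$tap_rate_hz, dwell_mean_ms = pp$dwell_mean_ms,
          dwell_sd_ms = pp$dwell_sd_ms, travel_sd_ms = pp$travel_sd_ms,
          error_rate = pp$error_rate,
          adjacent_error_frac = params$adjacent_error_frac, hand = h
        )
      })
      push_task(skind, "fit_test", t1 + minutes(dur_fit), day,
                list(trials = trials, started_at = t1,
                     ended_at = t1 + minutes(dur_fit)))

      # once-daily diary, carried over until completed (none on day 0)
      if (do_diary) {
        t2 <- t1 + minutes(dur_fit + 0.1)
        push_task(skind, "sleep_diary", t2 + minutes(dur_diary), day,
                  list(answers = draw_answers(diary_bank, latent_diary, day),
                       started_at = t2, ended_at = t2 + minutes(dur_diary)))
        diary_done[day + 1] <- TRUE
      }

      # touch log for the enacted session
      n_touch <- stats::rpois(1, params$touches_per_session_mean) + 5
      tl <- touch_stream(pp$touch_accuracy, layout, n_touch)
      tl$patient_id <- pid
      tl$study_day <- day
      tl$session_kind <- skind
      all_touches[[length(all_touches) + 1L]] <- tl
    }
    all_events[[pi]] <- dplyr::bind_rows(events)
  }

  structure(
    list(
      events = dplyr::bind_rows(all_events),
      touches = dplyr::bind_rows(all_touches),
      truth = list(patients = dplyr::bind_rows(truth_patients),
                   sessions = dplyr::bind_rows(truth_sessions)),
      cohort = tibble::tibble(
        patient_id = sprintf("P%03d", seq_len(params$n_patients)),
        version = params$version
      ),
      protocol = protocol,
      params = params
    ),
    class = "ema_cohort_sim"
  )
}

# anchor kind driving each session kind (default plan)
session_spec_anchor <- function(kind) {
  c(on_waking = "wake_time", after_medications = "first_med_intake",
    afternoon = "afternoon_dose_due", evening = "bedtime",
    nap = "nap_end")[[kind]]
}

#' @export
print.ema_cohort_sim <- function(x, ...) {
  cat("<ema_cohort_sim>", nrow(x$cohort), "patients on", x$params$version,
      "|", nrow(x$events), "events |", nrow(x$touches), "touches\n")
  invisible(x)
}
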