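# Fixture builders and independent oracles shared across tests.
# Oracles are deliberately naive (loops, single passes) and share no code
# with the implementation paths they check.

TZ <- "Europe/Zurich"

ts <- function(x) as.POSIXct(x, tz = TZ)

# --- protocol oracle: brute-force calendar enumeration -------------------
# Walk every calendar day of the home period and count the sessions a
# fully adherent patient performs, without using expected_schedule().
oracle_task_counts <- function(n_nights, n_scale_q = 11) {
  scales <- 0L; fit <- 0L
  for (day in 0:n_nights) {
    if (n_nights < 1) break
    kinds <- if (day == 0) "evening"
             else if (day == n_nights) c("on_waking", "after_medications")
             else c("on_waking", "after_medications", "afternoon", "evening")
    for (k in kinds) {
      scales <- scales + 1L
      fit <- fit + 1L
    }
  }
  diary <- if (n_nights >= 1) n_nights else 0L
  list(scales = scales, fit = fit, diary = diary,
       questions = scales * n_scale_q + diary * 24L)
}

# --- fit-test oracle: naive single-pass rescoring ------------------------
oracle_score <- function(trial, adjacency = default_adjacency()) {
  ev <- trial$events
  ks <- 0L; dwell <- c(); travel <- c(); wsum <- 0
  adjacent <- unique(unlist(adjacency[trial$target_keys]))
  prev_up <- NULL
  for (i in seq_len(nrow(ev))) {
    ks <- ks + 1L
    on_target <- ev$key[i] %in% trial$target_keys
    wsum <- wsum + if (on_target) 0 else if (ev$key[i] %in% adjacent) 1 else 2
    if (on_target) {
      dwell <- c(dwell, ev$up_ms[i] - ev$down_ms[i])
      if (!is.null(prev_up)) travel <- c(travel, ev$down_ms[i] - prev_up)
      prev_up <- ev$up_ms[i]
    }
  }
  list(
    ks = ks,
    at = if (length(dwell)) sum(dwell) / length(dwell) else NA_real_,
    is = if (length(travel) >= 2) {
      m <- sum(travel) / length(travel)
      sum((travel - m)^2) / (length(travel) - 1)
    } else NA_real_,
    ds = wsum / ks
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random, not necessarily well-behaved, but valid trial
random_trial <- function(n = NULL, error_rate = 0.1) {
  n <- n %||% sample(5:60, 1)
  gaps <- runif(n, 50, 400)
  dwell <- runif(n, 20, 200)
  down <- cumsum(c(0, (dwell + gaps)[-n]))
  up <- down + dwell
  scale <- (29000) / max(up)
  keys <- sample(c("s", ";", "a", "p", "m"), n, replace = TRUE,
                 prob = c((1 - error_rate) / 2, (1 - error_rate) / 2,
                          error_rate / 3, error_rate / 3, error_rate / 3))
  fit_trial(tibble::tibble(key = keys, down_ms = down * scale,
                           up_ms = up * scale),
            hand = sample(c("left", "right"), 1))
}

# --- questionnaire fixtures ----------------------------------------------
full_answers <- function(protocol, task_kind) {
  bank <- protocol$questions[protocol$questions$task_kind == task_kind, ]
  value <- lapply(seq_len(nrow(bank)), function(i) {
    if (bank$type[i] == "timestamp") "2018-03-05T22:30:00+0000"
    else as.integer(bank$lo[i])
  })
  tibble::tibble(question_id = bank$id, value = value)
}

valid_fit_record <- function() {
  mk <- function(h) fit_trial(
    tibble::tibble(key = rep(c("s", ";"), 10),
                   down_ms = seq(0, by = 600, length.out = 20),
                   up_ms = seq(100, by = 600, length.out = 20)),
    hand = h)
  list(trials = list(mk("left"), mk("right")))
}

# scheduler with a plain morning already anchored
morning_state <- function(protocol = default_protocol("v2.0"),
                          wake = ts("2018-03-06 07:00:00"), day = 1L) {
  st <- new_scheduler(protocol, "PT1", tz = TZ)
  ingest_anchor(st, "wake_time", wake, day)
}

# --- store fixtures ------------------------------------------------------
make_record <- function(i, patient = "P001", type = "scales",
                        session = "on_waking", day = 1L) {
  list(
    record_id = sprintf("%s-%03d", patient, i), patient_id = patient,
    record_type = type, session_kind = session, study_day = day,
    date = as.Date("2018-03-06") + day, categorization = "H",
    created_at = ts("2018-03-06 08:00:00") + i * 60,
    payload = list(answers = tibble::tibble(
      question_id = c("q1", "q2"), value = list(1L, 2L)))
  )
}

filled_journal <- function(n = 5) {
  j <- ema_journal()
  for (i in seq_len(n)) append_record(j, make_record(i))
  j
}

# small simulated cohort shared by scheduler/analytics tests
small_sim <- function(n_patients = 2, nights = 5, seed = 7, ...) {
  simulate_cohort(sim_params(n_patients = n_patients, home_nights = nights,
                             seed = seed, ...))
}
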