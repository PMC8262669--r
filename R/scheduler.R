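#' Session scheduler
#'
#' The scheduler is a pure state machine driving a patient's daily
#' workflow. Patient-generated *anchor events* (wake time, first
#' medication intake, afternoon dose due, bedtime, nap end) open
#' `SessionInstance`s at anchor + offset; a session not completed within
#' its expiry window expires and its tasks cannot be performed again that
#' day. The once-daily sleep diary is offered at every session until it is
#' completed. All operations take a state and return an updated state;
#' replaying the same event sequence always yields the identical state.
#'
#' Instance lifecycle: `pending` (scheduled, not yet due) -> `open`
#' (due_at <= now < expires_at) -> `completed` or `expired`. Expiry is
#' monotone: an expired or completed instance never reopens. The expiry
#' boundary is half-open: at `now == expires_at` the instance is expired.
#'
#' @param protocol An `ema_protocol`.
#' @param patient_id Patient identifier.
#' @param tz Patient's local time zone (all comparisons, and the
#'   local-midnight study-day boundary, use it).
#' @return An `ema_scheduler` state object.
#' @export
new_scheduler <- function(protocol, patient_id, tz = "Europe/Zurich") {
  structure(
    list(
      patient_id = patient_id,
      protocol = protocol,
      tz = tz,
      instances = empty_instances(),
      diary_done_day = integer(0),
      last_anchor = list(),
      records = list(),
      next_instance_id = 1L
    ),
    class = "ema_scheduler"
  )
}

empty_instances <- function() {
  data.frame(
    id = integer(0), kind = character(0), study_day = integer(0),
    due_at = as.POSIXct(character(0)), expires_at = as.POSIXct(character(0)),
    state = character(0), tasks_done = I(list()),
    stringsAsFactors = FALSE
  )
}

session_spec <- function(protocol, kind) {
  as.list(protocol$sessions[protocol$sessions$kind == kind,
                            c("offset_min", "window_min", "tasks")])
}

add_instance <- function(state, kind, study_day, due_at, expires_at) {
  i <- data.frame(
    id = state$next_instance_id, kind = kind,
    study_day = as.integer(study_day), due_at = due_at,
    expires_at = expires_at, state = "pending",
    tasks_done = I(list(character(0))), stringsAsFactors = FALSE
  )
  state$instances <- rbind(state$instances, i)
  state$next_instance_id <- state$next_instance_id + 1L
  state
}

# Row indices of live (pending/open) instances of a kind on a day.
live_idx <- function(state, kind, study_day = NULL) {
  ins <- state$instances
  sel <- ins$kind == kind & ins$state %in% c("pending", "open")
  if (!is.null(study_day)) sel <- sel & ins$study_day == study_day
  which(sel)
}

#' Ingest an anchor event
#'
#' Creates or updates session instances from a patient-generated anchor:
#'
#' * `wake_time` — schedules on-waking at anchor + 30 min; if the
#'   afternoon session has no dose anchor yet that day, an afternoon
#'   instance is synthesized at the protocol's default local time.
#' * `first_med_intake` — schedules after-medications at anchor + 60 min
#'   and truncates the on-waking window at the intake time.
#' * `afternoon_dose_due` — schedules (or re-anchors) the afternoon
#'   session at the anchor.
#' * `bedtime` — opens the evening session at the anchor and truncates any
#'   live afternoon instance.
#' * `nap_end` — creates an on-demand nap instance, due immediately.
#'
#' An anchor earlier than a previous same-kind anchor on the same study
#' day is rejected (timestamps must be strictly increasing).
#'
#' @param state An `ema_scheduler`.
#' @param kind Anchor kind; see [ANCHOR_KINDS] values in the details.
#' @param at Timezone-aware POSIXct timestamp.
#' @param study_day Integer study day (0 = arrival day); defaults to the
#'   local-midnight day index from the first anchor seen.
#' @return Updated state.
#' @export
ingest_anchor <- function(state, kind, at, study_day) {
  if (!kind %in% ANCHOR_KINDS) {
    stop("unknown anchor kind '", kind, "'", call. = FALSE)
  }
  if (!inherits(at, "POSIXct") || is.null(attr(at, "tzone"))) {
    stop("anchor timestamp must be timezone-aware POSIXct", call. = FALSE)
  }
  key <- paste0(kind, "#", study_day)
  prev <- state$last_anchor[[key]]
  if (!is.null(prev) && at <= prev) {
    stop("anchor '", kind, "' not after previous same-kind anchor that day",
         call. = FALSE)
  }
  state$last_anchor[[key]] <- at

  p <- state$protocol
  minutes <- function(m) as.difftime(m, units = "mins")

  schedule <- function(state, skind, due) {
    spec <- session_spec(p, skind)
    expires <- due + minutes(spec$window_min)
    idx <- live_idx(state, skind, study_day)
    if (skind != "nap" && length(idx) > 0) {
      # re-anchor a live instance (late or corrected anchor)
      state$instances$due_at[idx[1]] <- due
      state$instances$expires_at[idx[1]] <- expires
      state
    } else {
      add_instance(state, skind, study_day, due, expires)
    }
  }

  truncate_expiry <- function(state, skind, at_time) {
    idx <- live_idx(state, skind, study_day)
    for (i in idx) {
      cutoff <- max(at_time, state$instances$due_at[i] + 1)
      state$instances$expires_at[i] <-
        min(state$instances$expires_at[i], cutoff)
    }
    state
  }

  if (kind == "wake_time") {
    state <- schedule(state, "on_waking", at + minutes(30))
    # synthesize the afternoon slot when no dose anchor exists yet; the
    # home period ends with after-medications on the final morning, so no
    # afternoon slot is created on study day home_nights
    if (study_day < p$home_nights &&
        length(live_idx(state, "afternoon", study_day)) == 0) {
      hm <- as.integer(strsplit(p$afternoon_default_time, ":")[[1]])
      day_start <- lubridate::floor_date(lubridate::with_tz(at, state$tz), "day")
      state <- schedule(state, "afternoon",
                        day_start + minutes(hm[1] * 60 + hm[2]))
    }
  } else if (kind == "first_med_intake") {
    state <- schedule(state, "after_medications", at + minutes(60))
    state <- truncate_expiry(state, "on_waking", at)
  } else if (kind == "afternoon_dose_due") {
    state <- schedule(state, "afternoon", at)
  } else if (kind == "bedtime") {
    state <- schedule(state, "evening", at)
    state <- truncate_expiry(state, "afternoon", at)
  } else if (kind == "nap_end") {
    spec <- session_spec(p, "nap")
    state <- add_instance(state, "nap", study_day, at,
                          at + minutes(spec$window_min))
  }
  state
}

#' Sweep the clock forward: open due sessions, expire overdue ones
#'
#' Transitions every pending instance whose due time has passed to open,
#' and every pending/open instance with `expires_at <= now` to expired.
#' Idempotent: a second call at the same `now` changes nothing and
#' reports no newly expired instances. With a non-decreasing clock,
#' nothing ever un-expires or un-completes.
#'
#' @param state An `ema_scheduler`.
#' @param now Current time (POSIXct).
#' @return List with `state` (updated) and `expired` (tibble of instances
#'   newly expired by this call).
#' @export
expire_sessions <- function(state, now) {
  ins <- state$instances
  live <- ins$state %in% c("pending", "open")
  newly_expired <- live & ins$expires_at <= now
  opened <- live & !newly_expired & ins$due_at <= now
  ins$state[newly_expired] <- "expired"
  ins$state[opened] <- "open"
  state$instances <- ins
  list(state = state,
       expired = tibble::as_tibble(ins[newly_expired,
                                       c("id", "kind", "study_day")]))
}

#' Next due session under automatic session flow
#'
#' Returns the earliest instance currently performable (`due_at <= now <
#' expires_at`, not completed or expired), breaking ties by the fixed
#' session-kind order on_waking < after_medications < afternoon < evening
#' < nap. Requires the protocol's `auto_session_flow` feature (v1.0+);
#' with manual navigation (alpha) use [list_selectable()].
#'
#' @param state An `ema_scheduler`.
#' @param now Current time.
#' @return One-row tibble describing the due instance, or `NULL` if none.
#' @export
next_due <- function(state, now) {
  if (!isTRUE(state$protocol$features$auto_session_flow)) {
    stop("protocol has no automatic session flow; use list_selectable()",
         call. = FALSE)
  }
  due <- list_selectable(state, now)
  if (nrow(due) == 0) return(NULL)
  due[1, , drop = FALSE]
}

#' All currently performable sessions (manual selection)
#'
#' @inheritParams next_due
#' @return Tibble of performable instances ordered by due time then
#'   session-kind order.
#' @export
list_selectable <- function(state, now) {
  ins <- state$instances
  ok <- ins$state %in% c("pending", "open") &
    ins$due_at <= now & now < ins$expires_at
  out <- ins[ok, , drop = FALSE]
  out <- out[order(out$due_at, session_rank(out$kind)), , drop = FALSE]
  tibble::as_tibble(out[, c("id", "kind", "study_day", "due_at", "expires_at",
                            "state")])
}

#' Is the sleep diary still pending on a study day?
#'
#' The diary is completed once per day, in any session; until then every
#' session offers it. A new study day resets the prompt.
#'
#' @param state An `ema_scheduler`.
#' @param study_day Integer study day.
#' @return `TRUE` iff no diary was completed that day.
#' @export
diary_pending <- function(state, study_day) {
  !study_day %in% state$diary_done_day
}

# Completeness checks: a task record is stored only if fully complete.
check_complete <- function(state, task_kind, record) {
  p <- state$protocol
  if (task_kind %in% c("subjective_scales", "sleep_diary")) {
    bank_kind <- if (task_kind == "subjective_scales") "subjective_scales"
                 else "sleep_diary"
    bank <- p$questions[p$questions$task_kind == bank_kind, ]
    ans <- record$answers
    if (is.null(ans) || !all(c("question_id", "value") %in% names(ans))) {
      return(structure(FALSE, reason = "missing answers"))
    }
    if (!setequal(ans$question_id, bank$id) ||
        nrow(ans) != nrow(bank)) {
      return(structure(FALSE,
                       reason = sprintf("incomplete: %d of %d questions answered",
                                        length(intersect(ans$question_id, bank$id)),
                                        nrow(bank))))
    }
    for (i in seq_len(nrow(ans))) {
      ok <- validate_response(ans$question_id[i], ans$value[[i]], p)
      if (!isTRUE(ok)) {
        return(structure(FALSE, reason = paste0(ans$question_id[i], ": ",
                                                attr(ok, "reason"))))
      }
    }
    return(TRUE)
  }
  if (task_kind == "fit_test") {
    trials <- record$trials
    if (is.null(trials) || length(trials) != 2 ||
        !setequal(vapply(trials, `[[`, "", "hand"), c("left", "right"))) {
      return(structure(FALSE, reason = "fit test requires one trial per hand"))
    }
    for (tr in trials) {
      ok <- validate_trial(tr)
      if (!isTRUE(ok)) {
        return(structure(FALSE, reason = paste0(tr$hand, " hand: ",
                                                attr(ok, "reason"))))
      }
    }
    return(TRUE)
  }
  structure(FALSE, reason = paste0("unknown task kind '", task_kind, "'"))
}

#' Complete a task within an open session
#'
#' Stores a fully completed task record with its exact completion
#' timestamp. Partial records — a questionnaire with any unanswered
#' question, a tapping test missing a valid trial for either hand — are
#' rejected and nothing is stored. Completing the diary marks it done for
#' the study day. A session becomes `completed` once all its attached
#' tasks other than the once-daily diary are done. Completion on an
#' expired instance is rejected with reason `"expired"`.
#'
#' @param state An `ema_scheduler`.
#' @param instance_id Id of the target session instance.
#' @param task_kind One of `subjective_scales`, `fit_test`, `sleep_diary`.
#' @param record The task record: for questionnaires a list with an
#'   `answers` tibble (`question_id`, `value`); for the tapping test a
#'   list with `trials`, a list of two [fit_trial()] objects (left and
#'   right hand). Optional `started_at`/`ended_at` POSIXct for workload
#'   accounting.
#' @param now Completion time.
#' @return Updated state, or an error describing the rejection.
#' @export
complete_task <- function(state, instance_id, task_kind, record, now) {
  state <- expire_sessions(state, now)$state
  ins <- state$instances
  i <- match(instance_id, ins$id)
  if (is.na(i)) stop("no such session instance", call. = FALSE)
  if (ins$state[i] == "expired" || now >= ins$expires_at[i]) {
    stop("expired", call. = FALSE)
  }
  if (ins$state[i] == "pending") stop("session not yet due", call. = FALSE)
  # a "completed" session has all required tasks done; the once-daily
  # diary may still be added until the window closes
  attached <- session_spec(state$protocol, ins$kind[i])$tasks[[1]]
  if (!task_kind %in% attached) {
    stop("task '", task_kind, "' is not part of the ", ins$kind[i],
         " session", call. = FALSE)
  }
  if (task_kind %in% ins$tasks_done[[i]]) {
    stop("task already completed in this session", call. = FALSE)
  }
  if (task_kind == "sleep_diary" && !diary_pending(state, ins$study_day[i])) {
    stop("sleep diary already completed today", call. = FALSE)
  }
  ok <- check_complete(state, task_kind, record)
  if (!isTRUE(ok)) {
    stop("rejected: ", attr(ok, "reason"), call. = FALSE)
  }

  ins$tasks_done[[i]] <- c(ins$tasks_done[[i]], task_kind)
  required <- setdiff(attached, "sleep_diary")
  if (all(required %in% ins$tasks_done[[i]])) ins$state[i] <- "completed"
  state$instances <- ins
  if (task_kind == "sleep_diary") {
    state$diary_done_day <- c(state$diary_done_day, ins$study_day[i])
  }

  day_date <- as.Date(lubridate::with_tz(now, state$tz))
  payload <- if (task_kind == "fit_test") {
    list(scores = dplyr::bind_rows(lapply(record$trials, score_trial)),
         started_at = record$started_at, ended_at = record$ended_at)
  } else {
    list(answers = record$answers,
         started_at = record$started_at, ended_at = record$ended_at)
  }
  state$records[[length(state$records) + 1L]] <- list(
    task_kind = task_kind, session_kind = ins$kind[i],
    study_day = ins$study_day[i], date = day_date,
    completed_at = now, payload = payload
  )
  state
}

#' Completed task records of a scheduler state
#'
#' @param state An `ema_scheduler`.
#' @return Tibble with one row per completed task: `task_kind`,
#'   `session_kind`, `study_day`, `date`, `completed_at`, and a `payload`
#'   list-column (scored trials or answers, plus start/end timestamps).
#' @export
scheduler_records <- function(state) {
  if (length(state$records) == 0) {
    return(tibble::tibble(
      task_kind = character(), session_kind = character(),
      study_day = integer(), date = as.Date(character()),
      completed_at = as.POSIXct(character()), payload = list()
    ))
  }
  tibble::tibble(
    task_kind = vapply(state$records, `[[`, "", "task_kind"),
    session_kind = vapply(state$records, `[[`, "", "session_kind"),
    study_day = vapply(state$records, `[[`, 1L, "study_day"),
    date = as.Date(vapply(state$records, function(r) as.numeric(r$date), 0),
                   origin = "1970-01-01"),
    completed_at = as.POSIXct(
      vapply(state$records, function(r) as.numeric(r$completed_at), 0),
      origin = "1970-01-01", tz = state$tz),
    payload = lapply(state$records, `[[`, "payload")
  )
}

#' Replay an event stream through the scheduler
#'
#' Feeds a time-ordered event stream (anchors and task completions) for a
#' single patient through the state machine. Replay is deterministic: the
#' same stream always produces the identical final state.
#'
#' Events are rows with `event_type` `"anchor"` (columns `kind`, `at`,
#' `study_day`) or `"task"` (columns `session_kind`, `task_kind`, `at`,
#' `study_day`, and a `payload` list-column holding the task record).
#'
#' @param protocol An `ema_protocol`.
#' @param events Event tibble for one patient.
#' @param patient_id Patient identifier.
#' @param tz Local time zone.
#' @param strict Error on a rejected completion (default `FALSE`: the
#'   rejection is recorded in the returned log and replay continues, which
#'   matches how an interactive session simply drops a partial record).
#' @return List with `state` (final `ema_scheduler`) and `log` (tibble of
#'   rejected events, if any).
#' @export
replay_events <- function(protocol, events, patient_id, tz = "Europe/Zurich",
                          strict = FALSE) {
  state <- new_scheduler(protocol, patient_id, tz = tz)
  events <- events[order(events$at), , drop = FALSE]
  rejects <- list()
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    if (ev$event_type == "anchor") {
      state <- ingest_anchor(state, ev$kind, ev$at, ev$study_day)
    } else {
      state <- expire_sessions(state, ev$at)$state
      idx <- which(state$instances$kind == ev$session_kind &
                     state$instances$study_day == ev$study_day &
                     state$instances$state %in% c("open", "pending", "completed"))
      res <- tryCatch({
        if (length(idx) == 0) stop("no live instance", call. = FALSE)
        complete_task(state, state$instances$id[idx[1]], ev$task_kind,
                      ev$payload[[1]], ev$at)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        if (strict) stop(res)
        rejects[[length(rejects) + 1L]] <- tibble::tibble(
          row = r, session_kind = ev$session_kind, task_kind = ev$task_kind,
          at = ev$at, reason = conditionMessage(res)
        )
      } else {
        state <- res
      }
    }
  }
  list(state = state, log = dplyr::bind_rows(rejects))
}

#' @export
print.ema_scheduler <- function(x, ...) {
  tab <- table(factor(x$instances$state,
                      levels = c("pending", "open", "completed", "expired")))
  cat("<ema_scheduler> patient", x$patient_id, "|",
      nrow(x$instances), "instances:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
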