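#' Run a study: replay event streams into a store
#'
#' The end-to-end pipeline: each patient's event stream is replayed
#' through the session scheduler ([replay_events()]), completed task
#' records are scored and appended to a store-and-forward journal
#' ([ema_journal()]) together with anchor records and per-session
#' interaction summaries from the touch log. The run is deterministic:
#' the same input always produces the same store content.
#'
#' @param sim An `ema_cohort_sim` from [simulate_cohort()], or a list with
#'   `events`, `touches` (optional), `cohort`, `protocol` in the same
#'   shapes.
#' @param categorization Provenance tag for the records (default `"H"`,
#'   collected at home).
#' @return An `ema_run` list: `journal` (the populated store), `states`
#'   (per-patient final scheduler states), `rejections` (tibble of
#'   dropped partial/late completions), `cohort`, `protocol`.
#' @export
run_study <- function(sim, categorization = "H") {
  protocol <- sim$protocol
  journal <- ema_journal()
  states <- list()
  rejections <- list()
  tz <- if (!is.null(sim$params)) sim$params$tz else "Europe/Zurich"

  for (pid in sim$cohort$patient_id) {
    ev <- sim$events[sim$events$patient_id == pid, , drop = FALSE]
    res <- replay_events(protocol, ev, pid, tz = tz)
    states[[pid]] <- res$state
    if (nrow(res$log) > 0) {
      res$log$patient_id <- pid
      rejections[[pid]] <- res$log
    }

    seq_no <- 0L
    next_id <- function() {
      seq_no <<- seq_no + 1L
      sprintf("%s-%05d", pid, seq_no)
    }

    # anchor records
    anchors <- ev[ev$event_type == "anchor", , drop = FALSE]
    for (r in seq_len(nrow(anchors))) {
      a <- anchors[r, ]
      append_record(journal, list(
        record_id = next_id(), patient_id = pid, record_type = "anchor",
        session_kind = NA_character_, study_day = a$study_day,
        date = as.Date(lubridate::with_tz(a$at, tz)),
        categorization = categorization, created_at = a$at,
        payload = list(kind = a$kind, at = format_iso8601(a$at, tz = "UTC"))
      ))
    }

    # completed task records (fit tests split per hand)
    recs <- scheduler_records(res$state)
    for (r in seq_len(nrow(recs))) {
      rec <- recs[r, ]
      p <- rec$payload[[1]]
      type <- c(subjective_scales = "scales", fit_test = "fit_test",
                sleep_diary = "sleep_diary")[[rec$task_kind]]
      if (type == "fit_test") {
        for (h in p$scores$hand) {
          s <- p$scores[p$scores$hand == h, ]
          append_record(journal, list(
            record_id = next_id(), patient_id = pid, record_type = "fit_test",
            session_kind = rec$session_kind, study_day = rec$study_day,
            date = rec$date, hand = h, categorization = categorization,
            created_at = rec$completed_at,
            payload = list(scores = s, started_at = p$started_at,
                           ended_at = p$ended_at)
          ))
        }
      } else {
        append_record(journal, list(
          record_id = next_id(), patient_id = pid, record_type = type,
          session_kind = rec$session_kind, study_day = rec$study_day,
          date = rec$date, categorization = categorization,
          created_at = rec$completed_at,
          payload = p
        ))
      }
    }

    # per-session interaction summaries from the touch log
    if (!is.null(sim$touches) && nrow(sim$touches) > 0) {
      tl <- sim$touches[sim$touches$patient_id == pid, , drop = FALSE]
      if (nrow(tl) > 0) {
        agg <- tl |>
          dplyr::group_by(.data$study_day, .data$session_kind) |>
          dplyr::summarise(hits = sum(.data$on_target),
                           touches = dplyr::n(), .groups = "drop")
        for (r in seq_len(nrow(agg))) {
          g <- agg[r, ]
          append_record(journal, list(
            record_id = next_id(), patient_id = pid,
            record_type = "interaction", session_kind = g$session_kind,
            study_day = g$study_day, categorization = categorization,
            created_at = as.POSIXct(NA),
            payload = list(hits = g$hits, touches = g$touches)
          ))
        }
      }
    }
  }

  structure(
    list(journal = journal, states = states,
         rejections = dplyr::bind_rows(rejections),
         cohort = sim$cohort, protocol = sim$protocol),
    class = "ema_run"
  )
}

#' Completed-task table of a run
#'
#' Convenience accessor: one row per completed task (fit tests collapsed
#' back to one task across hands), ready for [compliance_report()] and
#' [workload_summary()].
#'
#' @param run An `ema_run`.
#' @return Tibble: `patient_id`, `task_kind`, `session_kind`, `study_day`,
#'   `date`, `completed_at`, `duration_min`.
#' @export
run_tasks <- function(run) {
  purrr::imap_dfr(run$states, function(state, pid) {
    recs <- scheduler_records(state)
    if (nrow(recs) == 0) return(NULL)
    recs$patient_id <- pid
    recs$duration_min <- vapply(recs$payload, function(p) {
      if (is.null(p$started_at) || is.null(p$ended_at)) NA_real_
      else as.numeric(difftime(p$ended_at, p$started_at, units = "mins"))
    }, 0)
    recs[, c("patient_id", "task_kind", "session_kind", "study_day",
             "date", "completed_at", "duration_min")]
  })
}

#' @export
print.ema_run <- function(x, ...) {
  cat("<ema_run>", length(x$states), "patients |",
      length(x$journal$records), "journal records |",
      nrow(x$rejections), "rejected events\n")
  invisible(x)
}
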