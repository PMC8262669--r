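#' Screen layouts and touch hit-testing
#'
#' From v1.0 the application logs every interaction with the touchscreen —
#' x/y coordinates and timestamp — whether or not the touch lands on a
#' command. A `ScreenLayout` is the set of rectangular button regions
#' active on screen; a touch is a *hit* when it falls inside one.
#' Rectangles are half-open, `[x0, x1) x [y0, y1)`, so shared edges belong
#' to exactly one region.
#'
#' @param width,height Screen size in pixels.
#' @param regions Tibble with columns `target_id`, `x0`, `y0`, `x1`, `y1`.
#' @return An object of class `ema_layout`.
#' @export
screen_layout <- function(regions, width = 1280, height = 800) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("target_id", "x0", "y0", "x1", "y1") %in% names(regions)))
  if (any(regions$x0 < 0 | regions$y0 < 0 |
          regions$x1 > width | regions$y1 > height |
          regions$x0 >= regions$x1 | regions$y0 >= regions$y1)) {
    stop("target regions must be non-empty rectangles within screen bounds",
         call. = FALSE)
  }
  structure(list(width = width, height = height, regions = regions),
            class = "ema_layout")
}

#' Default tablet screen layout
#'
#' A plausible one-question-per-page layout with large, well-separated
#' buttons: answer buttons, +/- steppers, and navigation. Used by the
#' simulator; studies supply their own layout config.
#'
#' @return An `ema_layout`.
#' @export
default_layout <- function() {
  screen_layout(tibble::tibble(
    target_id = c("answer_1", "answer_2", "answer_3", "answer_4",
                  "minus", "plus", "back", "next"),
    x0 = c(140, 440, 740, 1040, 340, 740, 40, 1040),
    y0 = c(260, 260, 260, 260, 470, 470, 660, 660),
    x1 = c(340, 640, 940, 1240, 540, 940, 240, 1240),
    y1 = c(420, 420, 420, 420, 600, 600, 780, 780)
  ))
}

#' Hit-test a touch against a layout
#'
#' Deterministic point-in-rectangle lookup with the half-open convention;
#' where regions overlap, the earliest-declared region wins. Vectorized
#' over coordinates.
#'
#' @param layout An `ema_layout`.
#' @param x,y Touch coordinates in pixels.
#' @return Character vector of `target_id`s, `NA` where no region is hit.
#' @export
#' @examples
#' hit_test(default_layout(), 140, 260)  # corner belongs to the region
#' hit_test(default_layout(), 0, 0)      # NA: background
hit_test <- function(layout, x, y) {
  r <- layout$regions
  vapply(seq_along(x), function(i) {
    inside <- x[i] >= r$x0 & x[i] < r$x1 & y[i] >= r$y0 & y[i] < r$y1
    if (any(inside)) r$target_id[which(inside)[1]] else NA_character_
  }, character(1))
}

#' Target ratio of a touch log
#'
#' The usability statistic: hits on button regions divided by total screen
#' touches, as a percentage. A log with zero touches has an undefined
#' ratio (`NA`) and is excluded from averages.
#'
#' @param events Tibble of interaction events with a logical `on_target`
#'   column (or an `ema_layout` plus `x`/`y` columns to hit-test first).
#' @param layout Optional `ema_layout`; when supplied, `on_target` is
#'   recomputed from coordinates.
#' @return One-row tibble: `hits`, `touches`, `ratio` (percent).
#' @export
#' @examples
#' target_ratio(tibble::tibble(on_target = c(rep(TRUE, 9), FALSE)))
target_ratio <- function(events, layout = NULL) {
  events <- tibble::as_tibble(events)
  if (!is.null(layout)) {
    events$on_target <- !is.na(hit_test(layout, events$x, events$y))
  }
  touches <- nrow(events)
  hits <- sum(events$on_target)
  tibble::tibble(
    hits = hits, touches = touches,
    ratio = if (touches > 0) 100 * hits / touches else NA_real_
  )
}

#' Cohort-average target ratio with full-day exclusions
#'
#' Computes per-session target ratios, averages them per patient over the
#' *included* sessions, then averages the patient means (unweighted) into
#' a cohort value. Only fully completed home days contribute: the evening
#' session of the first day (study day 0) and the two morning sessions
#' (on waking, after medications) of the final day are excluded — exactly
#' 3 session slots per patient over a standard run. Sessions with zero
#' touches cannot contribute a ratio and are dropped; a patient whose
#' touches all fall in excluded sessions is dropped from the cohort mean.
#'
#' @param touch_log Tibble of touches with columns `patient_id`,
#'   `study_day`, `session_kind`, `on_target`.
#' @param protocol An `ema_protocol` (supplies the final study day).
#' @return An `ema_target_ratio` object: list with `per_session`,
#'   `per_patient` tibbles and scalar `cohort_mean`.
#' @export
average_target_ratio <- function(touch_log, protocol) {
  touch_log <- tibble::as_tibble(touch_log)
  n <- protocol$home_nights
  included <- !((touch_log$study_day == 0 & touch_log$session_kind == "evening") |
                  (touch_log$study_day == n &
                     touch_log$session_kind %in% c("on_waking", "after_medications")))
  per_session <- touch_log[included, ] |>
    dplyr::group_by(.data$patient_id, .data$study_day, .data$session_kind) |>
    dplyr::summarise(
      hits = sum(.data$on_target), touches = dplyr::n(),
      ratio = 100 * .data$hits / .data$touches, .groups = "drop"
    )
  per_patient <- per_session |>
    dplyr::filter(.data$touches > 0) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     n_sessions = dplyr::n(), .groups = "drop")
  structure(
    list(
      per_session = per_session,
      per_patient = per_patient,
      cohort_mean = if (nrow(per_patient) > 0) mean(per_patient$mean_ratio) else NA_real_
    ),
    class = "ema_target_ratio"
  )
}

#' @export
print.ema_target_ratio <- function(x, ...) {
  cat("<ema_target_ratio>", nrow(x$per_patient), "patients | cohort mean",
      format(round_half_up(x$cohort_mean, 1), nsmall = 1), "%\n")
  invisible(x)
}
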