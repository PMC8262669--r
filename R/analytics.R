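#' Compliance percentage
#'
#' Compliance is the ratio of completed tasks to protocol-expected tasks,
#' expressed as a percentage rounded half-up to 2 decimals — the
#' convention used for every printed compliance figure (e.g. 5707 of 6420
#' tasks is 88.89%).
#'
#' @param completed Number of tasks completed.
#' @param expected Number of tasks expected (> 0, and `completed <=
#'   expected`).
#' @return Percentage, 2 decimals.
#' @export
#' @examples
#' compliance(5707, 6420) # 88.89
#' compliance(2070, 2356) # 87.86
compliance <- function(completed, expected) {
  stopifnot(expected > 0, completed <= expected, completed >= 0)
  pct(completed, expected, digits = 2)
}

#' Cohort compliance report
#'
#' Crosses completed task records against the protocol-expected schedule
#' to produce the version x session x task compliance table. Expected
#' counts come from [expected_tasks()] / [expected_schedule()] per
#' protocol version, multiplied by the number of patients on that
#' version; completed counts are taken from stored records restricted to
#' the analysis window (the evening session of the arrival day through
#' the after-medications session of the final morning). On-demand nap
#' sessions are excluded: they cannot be scheduled a priori, so no
#' expectation exists for them. The once-daily diary has no session
#' attribution in the breakdown (it may be completed in any session); it
#' appears in per-version totals only.
#'
#' @param records Completed-task records: tibble with `patient_id`,
#'   `task_kind` (or `record_type`), `session_kind`, `study_day`.
#' @param cohort Tibble mapping `patient_id` to protocol `version`.
#' @param protocols A single `ema_protocol` (whole cohort on one version),
#'   or a named list of `ema_protocol`s keyed by version id; defaults to
#'   the built-in 14-night protocols for the versions present.
#' @return An `ema_compliance` object: list with `overall` (completed,
#'   expected, percent), `by_version`, `cells` tibbles.
#' @export
compliance_report <- function(records, cohort,
                              protocols = NULL) {
  records <- tibble::as_tibble(records)
  if (!"task_kind" %in% names(records) && "record_type" %in% names(records)) {
    records$task_kind <- dplyr::recode(records$record_type,
                                       scales = "subjective_scales",
                                       fit_test = "fit_test",
                                       sleep_diary = "sleep_diary")
  }
  cohort <- tibble::as_tibble(cohort)
  versions <- sort(unique(cohort$version))
  if (is.null(protocols)) {
    protocols <- stats::setNames(lapply(versions, default_protocol), versions)
  } else if (inherits(protocols, "ema_protocol")) {
    protocols <- stats::setNames(list(protocols), protocols$version_id)
  }
  missing_v <- setdiff(versions, names(protocols))
  if (length(missing_v) > 0) {
    stop("no protocol supplied for version(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }

  records <- dplyr::inner_join(records, cohort, by = "patient_id")

  # expected cells per version: session-attributed scales/fit + diary total
  expected_cells <- purrr::map_dfr(versions, function(v) {
    p <- protocols[[v]]
    sched <- expected_schedule(p)
    n_pat <- sum(cohort$version == v)
    per_session <- sched |>
      dplyr::count(.data$kind, name = "slots") |>
      tidyr::expand_grid(task_kind = c("subjective_scales", "fit_test")) |>
      dplyr::filter(purrr::map2_lgl(
        .data$kind, .data$task_kind,
        function(k, tk) tk %in% p$sessions$tasks[[match(k, p$sessions$kind)]]
      )) |>
      dplyr::transmute(version = v, session_kind = .data$kind,
                       task_kind = .data$task_kind,
                       expected = .data$slots * n_pat)
    diary <- tibble::tibble(version = v, session_kind = NA_character_,
                            task_kind = "sleep_diary",
                            expected = p$home_nights * n_pat)
    dplyr::bind_rows(per_session, diary)
  })

  # completed counts within the analysis window, naps excluded
  in_window <- purrr::pmap_lgl(
    records[, c("version", "study_day", "session_kind")],
    function(version, study_day, session_kind) {
      sched <- expected_schedule(protocols[[version]])
      any(sched$study_day == study_day & sched$kind == session_kind)
    }
  )
  analysed <- records[in_window & records$session_kind != "nap", ]
  done <- analysed |>
    dplyr::mutate(session_kind = ifelse(.data$task_kind == "sleep_diary",
                                        NA_character_, .data$session_kind)) |>
    dplyr::count(.data$version, .data$session_kind, .data$task_kind,
                 name = "completed")

  cells <- expected_cells |>
    dplyr::left_join(done, by = c("version", "session_kind", "task_kind")) |>
    dplyr::mutate(completed = dplyr::coalesce(.data$completed, 0L),
                  percent = pct(.data$completed, .data$expected))

  by_version <- cells |>
    dplyr::group_by(.data$version) |>
    dplyr::summarise(completed = sum(.data$completed),
                     expected = sum(.data$expected), .groups = "drop") |>
    dplyr::mutate(percent = pct(.data$completed, .data$expected))

  structure(
    list(
      overall = list(completed = sum(cells$completed),
                     expected = sum(cells$expected),
                     percent = pct(sum(cells$completed), sum(cells$expected))),
      by_version = by_version,
      cells = cells
    ),
    class = "ema_compliance"
  )
}

#' @export
print.ema_compliance <- function(x, ...) {
  cat("<ema_compliance> overall ", x$overall$percent, "% (",
      x$overall$completed, "/", x$overall$expected, ")\n", sep = "")
  print(x$by_version)
  invisible(x)
}

#' One-tailed two-sample proportion test (pooled z)
#'
#' Classical pooled two-proportion z-test of whether group B's proportion
#' exceeds group A's, used to assess compliance improvement between
#' protocol versions. The pooled estimate is
#' `p = (x_a + x_b) / (n_a + n_b)` and
#' `z = (p_b - p_a) / sqrt(p (1 - p) (1/n_a + 1/n_b))`, with one-tailed
#' `p`-value `P(Z > z)`. A Yates continuity correction is available but
#' off by default.
#'
#' @param done_a,total_a Successes and trials in group A (baseline).
#' @param done_b,total_b Successes and trials in group B (comparison).
#' @param correct Apply Yates' continuity correction.
#' @return One-row tibble: `z`, `p_one_tailed` (full precision; round for
#'   display).
#' @export
#' @examples
#' compare_proportions(2070, 2356, 2899, 3224)
compare_proportions <- function(done_a, total_a, done_b, total_b,
                                correct = FALSE) {
  stopifnot(total_a > 0, total_b > 0,
            done_a >= 0, done_b >= 0, done_a <= total_a, done_b <= total_b)
  pa <- done_a / total_a
  pb <- done_b / total_b
  pool <- (done_a + done_b) / (total_a + total_b)
  se <- sqrt(pool * (1 - pool) * (1 / total_a + 1 / total_b))
  num <- pb - pa
  if (correct) {
    cc <- 0.5 * (1 / total_a + 1 / total_b)
    num <- sign(num) * max(0, abs(num) - cc)
  }
  z <- num / se
  tibble::tibble(z = z, p_one_tailed = stats::pnorm(z, lower.tail = FALSE))
}

#' Satisfaction survey summary
#'
#' Summarises end-of-study satisfaction responses. All answers are
#' categorical on a 1 (low satisfaction) to 4 (high satisfaction) scale.
#' Per-question level counts are converted to integer percentages
#' (half-up) of the question's respondent count; question *groups* (the
#' three usability questions, the three graphical-interface questions)
#' are additionally pooled, with denominator `respondents x questions in
#' the group` (e.g. 55 "no difficulty" answers out of 26 x 3 = 78 pooled
#' usability answers is 71%).
#'
#' @param responses Tibble with columns `respondent`, `question_id`,
#'   `level` (integer 1-4), and optionally `group`.
#' @return An `ema_satisfaction` object: list with `per_question` and
#'   `per_group` tibbles.
#' @export
satisfaction_summary <- function(responses) {
  responses <- tibble::as_tibble(responses)
  stopifnot(all(responses$level %in% 1:4))
  dup <- responses |>
    dplyr::count(.data$respondent, .data$question_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("one response per respondent per question required", call. = FALSE)
  }
  per_question <- responses |>
    dplyr::count(.data$question_id, .data$level, name = "count") |>
    dplyr::group_by(.data$question_id) |>
    dplyr::mutate(respondents = sum(.data$count),
                  percent = pct(.data$count, .data$respondents, digits = 0)) |>
    dplyr::ungroup()
  per_group <- NULL
  if ("group" %in% names(responses)) {
    per_group <- responses |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(pooled_n = dplyr::n()) |>
      dplyr::group_by(.data$group, .data$level) |>
      dplyr::summarise(count = dplyr::n(),
                       pooled_n = .data$pooled_n[1], .groups = "drop") |>
      dplyr::mutate(percent = pct(.data$count, .data$pooled_n, digits = 0))
  }
  structure(list(per_question = per_question, per_group = per_group),
            class = "ema_satisfaction")
}

#' @export
print.ema_satisfaction <- function(x, ...) {
  cat("<ema_satisfaction>\n")
  print(x$per_question)
  invisible(x)
}

#' Average daily active workload
#'
#' Sums per-task active durations within each patient-day, averages the
#' daily sums within each patient, then averages the patient means into a
#' cohort value — the "minutes per day spent on study tasks" figure.
#'
#' @param task_durations Tibble with `patient_id`, `study_day`, and either
#'   `duration_min` or `started_at`/`ended_at` POSIXct columns.
#' @return List with `per_patient` tibble (`patient_id`,
#'   `mean_daily_min`) and scalar `cohort_mean_min` (`NA` when empty).
#' @export
workload_summary <- function(task_durations) {
  d <- tibble::as_tibble(task_durations)
  if (nrow(d) == 0) {
    return(list(per_patient = tibble::tibble(patient_id = character(),
                                             mean_daily_min = numeric()),
                cohort_mean_min = NA_real_))
  }
  if (!"duration_min" %in% names(d)) {
    d$duration_min <- as.numeric(difftime(d$ended_at, d$started_at,
                                          units = "mins"))
  }
  per_patient <- d |>
    dplyr::group_by(.data$patient_id, .data$study_day) |>
    dplyr::summarise(day_min = sum(.data$duration_min), .groups = "drop") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(mean_daily_min = mean(.data$day_min), .groups = "drop")
  list(per_patient = per_patient,
       cohort_mean_min = mean(per_patient$mean_daily_min))
}
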