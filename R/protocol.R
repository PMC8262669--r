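#' Versioned EMA study protocols
#'
#' An `ema_protocol` describes one released version of the home-assessment
#' protocol: which sessions exist and what anchors/offsets/windows drive
#' them, which tasks each session carries, the question banks behind the
#' subjective-scales and sleep-diary instruments, per-version feature
#' flags, and the length of the home period in nights.
#'
#' Three protocol versions are built in:
#'
#' * `alpha` — 5 subjective-scale questions per session, manual session
#'   selection (`auto_session_flow = FALSE`), no interaction logging, no
#'   local store-and-forward journal.
#' * `v1.0` — 11 scale questions, automatic session flow, interaction
#'   logging and store-and-forward enabled.
#' * `v2.0` — as v1.0 plus kiosk mode.
#'
#' All versions schedule four daily sessions (on waking, 30 min after the
#' wake anchor; after medications, 60 min after the first dopaminergic
#' dose; afternoon, before the afternoon dose; evening, at the bedtime
#' anchor) plus an on-demand nap session, and a 24-question sleep diary
#' completed once per day in any session.
#'
#' @param version One of `"alpha"`, `"v1.0"`, `"v2.0"`.
#' @param home_nights Number of nights in the home period (default 14).
#'   The home period spans `home_nights + 1` calendar days: the arrival
#'   evening, `home_nights - 1` full days, and a final morning.
#' @return An object of class `ema_protocol`.
#' @export
#' @examples
#' p <- default_protocol("v2.0")
#' expected_tasks(p)
#' expected_questions(p)
default_protocol <- function(version = c("v2.0", "v1.0", "alpha"),
                             home_nights = 14) {
  version <- match.arg(version)
  build_protocol(list(version_id = version, home_nights = home_nights))
}

# Session plan shared by all versions. Windows are configurable; the
# defaults preserve the clinical ordering (morning windows truncated by
# the next anchor, evening by bedtime) without inventing published values.
default_sessions <- function() {
  tibble::tibble(
    kind       = SESSION_KINDS,
    anchor     = c("wake_time", "first_med_intake", "afternoon_dose_due",
                   "bedtime", "nap_end"),
    offset_min = c(30, 60, 0, 0, 0),
    window_min = c(180, 180, 240, 60, 60),
    tasks = list(
      c("subjective_scales", "fit_test", "sleep_diary"),
      c("subjective_scales", "fit_test", "sleep_diary"),
      c("subjective_scales", "fit_test", "sleep_diary"),
      c("subjective_scales", "fit_test", "sleep_diary"),
      c("subjective_scales", "fit_test")
    )
  )
}

# Question banks. Item texts are placeholders carrying the instrument,
# domain and count; studies override them in config (texts are
# customizable by design). No free-text domains exist.
scales_bank <- function(version) {
  scopa <- tibble::tibble(
    id = paste0("scopa_dc_", 1:4),
    instrument = "scopa_dc_item", type = "int", lo = 0, hi = 3,
    text = paste0("Momentary motor status item ", 1:4, " (diary card)")
  )
  stanford <- tibble::tibble(
    id = "stanford_sleepiness", instrument = "stanford_sleepiness",
    type = "int", lo = 1, hi = 7, text = "How sleepy do you feel right now?"
  )
  if (version == "alpha") {
    bank <- dplyr::bind_rows(scopa, stanford)
  } else {
    vas_items <- c("mobility", "tremor", "mood", "anxiety", "fatigue", "pain")
    vas <- tibble::tibble(
      id = paste0("vas_", vas_items),
      instrument = "vas", type = "int", lo = 0, hi = 10,
      text = paste0("Rate your current ", vas_items, " (0-10)")
    )
    bank <- dplyr::bind_rows(scopa, vas, stanford)
  }
  bank$task_kind <- "subjective_scales"
  bank
}

diary_bank <- function() {
  items <- tibble::tibble(
    id = sprintf("diary_%02d", 1:24),
    instrument = "diary_item",
    type = c("timestamp", "timestamp", rep("int", 22)),
    lo = c(NA, NA, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    hi = c(NA, NA, 300, 20, 10, 10, 10, 5, 5, 5, 5, 1, 1, 1, 1, 1, 10, 10, 10, 10, 10, 10, 10, 10),
    text = c(
      "At what time did you go to bed last night?",
      "At what time did you wake up this morning?",
      "How many minutes did it take you to fall asleep?",
      "How many times did you wake up during the night?",
      "Overall, how did you sleep? (0-10)",
      "This morning, upon awakening, how do you feel? (0-10)",
      "How rested do you feel? (0-10)",
      "Cups of coffee yesterday",
      "Cups of tea yesterday",
      "Alcoholic drinks yesterday",
      "Overall sleep quality (1 very poor - 5 very good)",
      "Did you take a sleep-promoting drug last night?",
      "Did you experience tremor during the night?",
      "Did you have difficulty turning in bed?",
      "Did you have vivid dreams or act them out?",
      "Did you snore or stop breathing?",
      "Restlessness in the legs at night (0-10)",
      "Pain during the night (0-10)",
      "Nocturia episodes (0-10)",
      "Morning stiffness (0-10)",
      "Daytime sleepiness yesterday (0-10)",
      "Number of naps yesterday (0-10)",
      "Mood on waking (0-10)",
      "Anxiety on waking (0-10)"
    )
  )
  items$task_kind <- "sleep_diary"
  items
}

default_features <- function(version) {
  list(
    auto_session_flow   = version != "alpha",
    kiosk_mode          = version == "v2.0",
    interaction_logging = version != "alpha",
    store_and_forward   = version != "alpha"
  )
}

# Build + validate a protocol from a (possibly partial) config list.
build_protocol <- function(config) {
  known <- c("version_id", "home_nights", "features", "sessions",
             "questions", "afternoon_default_time")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown protocol field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  version <- config$version_id
  if (is.null(version) || !version %in% c("alpha", "v1.0", "v2.0")) {
    stop("field 'version_id' must be one of alpha, v1.0, v2.0", call. = FALSE)
  }
  home_nights <- config$home_nights %||% 14L
  if (!is.numeric(home_nights) || home_nights < 0 || home_nights != floor(home_nights)) {
    stop("field 'home_nights' must be a non-negative integer", call. = FALSE)
  }

  sessions <- default_sessions()
  if (!is.null(config$sessions)) {
    for (s in config$sessions) {
      if (is.null(s$kind) || !s$kind %in% SESSION_KINDS) {
        stop("field 'sessions': unknown session kind '", s$kind %||% "<missing>",
             "'", call. = FALSE)
      }
      i <- match(s$kind, sessions$kind)
      for (f in setdiff(names(s), "kind")) {
        if (!f %in% c("offset_min", "window_min", "tasks", "anchor")) {
          stop("field 'sessions.", f, "' is not recognized", call. = FALSE)
        }
        if (f == "tasks") sessions$tasks[[i]] <- unlist(s$tasks)
        else sessions[[f]][i] <- s[[f]]
      }
    }
  }

  questions <- dplyr::bind_rows(scales_bank(version), diary_bank())
  if (!is.null(config$questions)) {
    q <- tibble::as_tibble(config$questions)
    need <- c("id", "instrument", "type", "lo", "hi", "text", "task_kind")
    missing_cols <- setdiff(need, names(q))
    if (length(missing_cols) > 0) {
      stop("field 'questions' is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    questions <- q[, need]
  }

  features <- utils::modifyList(default_features(version),
                                config$features %||% list())

  p <- structure(
    list(
      version_id = version,
      home_nights = as.integer(home_nights),
      features = features,
      sessions = sessions,
      questions = questions,
      afternoon_default_time = config$afternoon_default_time %||% "15:00"
    ),
    class = "ema_protocol"
  )
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  s <- p$sessions
  if (!setequal(s$kind, SESSION_KINDS)) {
    stop("protocol must define the four scheduled session kinds plus 'nap'",
         call. = FALSE)
  }
  if (any(s$window_min <= 0)) {
    stop("field 'sessions.window_min': every expiry window must be > 0",
         call. = FALSE)
  }
  if (s$offset_min[s$kind == "on_waking"] != 30) {
    stop("field 'sessions.offset_min': on_waking must be 30 min after wake",
         call. = FALSE)
  }
  if (s$offset_min[s$kind == "after_medications"] != 60) {
    stop("field 'sessions.offset_min': after_medications must be 60 min after first dose",
         call. = FALSE)
  }
  attached <- unique(unlist(s$tasks))
  if (!all(TASK_KINDS %in% attached)) {
    stop("every task kind must be attached to at least one session",
         call. = FALSE)
  }
  q <- p$questions
  bad_free <- !q$instrument %in% c("scopa_dc_item", "vas", "stanford_sleepiness",
                                   "diary_item")
  if (any(bad_free)) {
    stop("field 'questions.instrument': unknown instrument '",
         q$instrument[bad_free][1], "'", call. = FALSE)
  }
  vas <- q[q$instrument == "vas", ]
  if (nrow(vas) > 0 && any(vas$lo != 0 | vas$hi != 10)) {
    stop("field 'questions': vas answer domain must be integers 0-10",
         call. = FALSE)
  }
  ss <- q[q$instrument == "stanford_sleepiness", ]
  if (nrow(ss) > 0 && any(ss$lo != 1 | ss$hi != 7)) {
    stop("field 'questions': stanford_sleepiness domain must be 1-7",
         call. = FALSE)
  }
  n_diary <- sum(q$task_kind == "sleep_diary")
  if (n_diary != 24) {
    stop("field 'questions': sleep diary must have 24 items, found ", n_diary,
         call. = FALSE)
  }
  n_scales <- sum(q$task_kind == "subjective_scales")
  expect_n <- if (p$version_id == "alpha") 5L else 11L
  if (n_scales != expect_n) {
    stop("field 'questions': ", p$version_id, " subjective scales must have ",
         expect_n, " items, found ", n_scales, call. = FALSE)
  }
  if (p$version_id == "alpha" && isTRUE(p$features$auto_session_flow)) {
    stop("field 'features.auto_session_flow': alpha relies on patient session selection",
         call. = FALSE)
  }
  invisible(p)
}

#' Load a protocol from a YAML configuration file
#'
#' Reads a structured-text protocol definition, merges it onto the built-in
#' defaults for the stated `version_id`, and validates every protocol
#' invariant (session plan, answer domains, question counts, feature
#' flags). Unknown fields are rejected with an error naming the field.
#'
#' @param path Path to a YAML file, or a pre-parsed config list.
#' @return An `ema_protocol`.
#' @seealso [default_protocol()]
#' @export
load_protocol <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(config)) stop("protocol config must parse to a mapping", call. = FALSE)
  build_protocol(config)
}

#' @export
print.ema_protocol <- function(x, ...) {
  cat("<ema_protocol> version", x$version_id,
      "|", x$home_nights, "home nights\n")
  cat("  scale questions:", sum(x$questions$task_kind == "subjective_scales"),
      "| diary items:", sum(x$questions$task_kind == "sleep_diary"), "\n")
  flags <- names(Filter(isTRUE, x$features))
  cat("  features:", if (length(flags)) paste(flags, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Validate a questionnaire answer against its question's domain
#'
#' Acceptance is a pure predicate over the question's answer domain: integer
#' questions accept whole numbers within `[lo, hi]`; timestamp questions
#' accept date-times (or ISO-8601 strings that parse to one). There are no
#' free-text domains. Rejection is a return value, never an error.
#'
#' @param question A one-row question definition (a row of
#'   `protocol$questions`), or a question id plus the `protocol` argument.
#' @param value The proposed answer.
#' @param protocol Optionally, the protocol to resolve a question id in.
#' @return `TRUE` if accepted; otherwise `FALSE` with a `reason` attribute.
#' @export
#' @examples
#' p <- default_protocol("v2.0")
#' validate_response("vas_mobility", 10, p)  # TRUE
#' validate_response("vas_mobility", 11, p)  # FALSE, out of range
validate_response <- function(question, value, protocol = NULL) {
  if (is.character(question)) {
    stopifnot(!is.null(protocol))
    question <- protocol$questions[protocol$questions$id == question, ]
    if (nrow(question) == 0) {
      return(structure(FALSE, reason = "unknown question id"))
    }
  }
  q <- as.list(question[1, ])
  if (identical(q$type, "timestamp")) {
    ok <- inherits(value, "POSIXt") ||
      (is.character(value) && !is.na(parse_iso8601(value)))
    return(if (ok) TRUE else structure(FALSE, reason = "not a timestamp"))
  }
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    return(structure(FALSE, reason = "not a number"))
  }
  if (value != floor(value)) {
    return(structure(FALSE, reason = "not an integer"))
  }
  if (value < q$lo || value > q$hi) {
    return(structure(FALSE, reason = sprintf("outside range %d-%d", q$lo, q$hi)))
  }
  TRUE
}

#' Enumerate the analysed home-period schedule
#'
#' The analysed home period spans `home_nights + 1` calendar days: the
#' evening session of the arrival day (study day 0), all four scheduled
#' sessions on each full day (study days 1 to `home_nights - 1`), and the
#' on-waking and after-medications sessions of the final morning (study
#' day `home_nights`). Nap sessions are on demand and excluded. One sleep
#' diary is expected per night, attributed to the morning ending it
#' (study days 1 to `home_nights`).
#'
#' @param protocol An `ema_protocol`.
#' @return A tibble with columns `study_day` and `kind`, one row per
#'   expected scheduled session slot.
#' @export
expected_schedule <- function(protocol) {
  n <- protocol$home_nights
  if (n < 1) {
    return(tibble::tibble(study_day = integer(), kind = character()))
  }
  rows <- list(tibble::tibble(study_day = 0L, kind = "evening"))
  if (n >= 2) {
    full <- tidyr::expand_grid(study_day = seq_len(n - 1L),
                               kind = SCHEDULED_KINDS)
    rows <- c(rows, list(full))
  }
  rows <- c(rows, list(tibble::tibble(
    study_day = n, kind = c("on_waking", "after_medications")
  )))
  out <- dplyr::bind_rows(rows)
  out$study_day <- as.integer(out$study_day)
  dplyr::arrange(out, .data$study_day, session_rank(.data$kind))
}

#' Expected per-task workload over the home period
#'
#' Counts the tasks a fully adherent patient completes over the home
#' period, by enumerating the schedule from [expected_schedule()] and the
#' per-session task attachments. Under the default protocol with `n`
#' nights this yields `4n - 1` subjective-scales tasks, `4n - 1` Fit
#' Tests, and `n` sleep diaries — 55, 55 and 14 for the default 14-night
#' period (124 tasks in total).
#'
#' @param protocol An `ema_protocol`.
#' @return A one-row tibble: `subjective_scales`, `fit_test`,
#'   `sleep_diary`, `total_tasks`, `total_questions`.
#' @export
#' @examples
#' expected_tasks(default_protocol("v2.0"))
expected_tasks <- function(protocol) {
  sched <- expected_schedule(protocol)
  task_of <- function(kind, task) {
    vapply(protocol$sessions$tasks[match(kind, protocol$sessions$kind)],
           function(t) task %in% t, logical(1))
  }
  n_scales <- sum(task_of(sched$kind, "subjective_scales"))
  n_fit <- sum(task_of(sched$kind, "fit_test"))
  n_diary <- if (protocol$home_nights >= 1) protocol$home_nights else 0L
  tibble::tibble(
    subjective_scales = as.integer(n_scales),
    fit_test = as.integer(n_fit),
    sleep_diary = as.integer(n_diary),
    total_tasks = as.integer(n_scales + n_fit + n_diary),
    total_questions = expected_questions(protocol)
  )
}

#' Expected number of questions over the home period
#'
#' `scale sessions x scale-bank size + nights x 24` diary items. For the
#' default 14-night v1.0/v2.0 protocol (11 scale questions) this is 941;
#' each full mid-study day adds `4 x 11 + 24 = 68` questions.
#'
#' @param protocol An `ema_protocol`.
#' @return Integer question count.
#' @export
expected_questions <- function(protocol) {
  sched <- expected_schedule(protocol)
  if (nrow(sched) == 0) return(0L)
  has_scales <- vapply(
    protocol$sessions$tasks[match(sched$kind, protocol$sessions$kind)],
    function(t) "subjective_scales" %in% t, logical(1))
  n_scale_q <- sum(protocol$questions$task_kind == "subjective_scales")
  n_diary_q <- sum(protocol$questions$task_kind == "sleep_diary")
  as.integer(sum(has_scales) * n_scale_q + protocol$home_nights * n_diary_q)
}
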