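#' Alternating two-key tapping trials
#'
#' The motor task is a 30-second alternating finger-tapping trial per hand
#' on two physical keys about 10 cm apart, in the tradition of the BRAIN
#' (Bradykinesia-Akinesia Incoordination) keyboard test. A trial holds the
#' raw keystroke stream — key identifier, key-down and key-up timestamps
#' in milliseconds from trial start — and is scored into four kinematic
#' parameters:
#'
#' * **kinesia score (KS)** — number of keystrokes in the window (speed);
#' * **akinesia time (AT)** — mean key dwell time in ms (hesitation);
#' * **incoordination score (IS)** — variance of inter-key travel times in
#'   ms^2 (rhythm irregularity);
#' * **dysmetria score (DS)** — adjacency-weighted rate of incorrect key
#'   strikes (accuracy).
#'
#' @param events Tibble/data frame with columns `key`, `down_ms`, `up_ms`.
#' @param hand `"left"` or `"right"`.
#' @param target_keys The two keys the subject is asked to alternate on.
#' @param duration_s Trial length in seconds (default 30).
#' @return An object of class `ema_fit_trial`.
#' @export
#' @examples
#' tr <- fit_trial(
#'   tibble::tibble(key = c("s", ";", "s"),
#'                  down_ms = c(0, 500, 1000),
#'                  up_ms = c(100, 620, 1100)),
#'   hand = "right"
#' )
#' score_trial(tr)
fit_trial <- function(events, hand = c("right", "left"),
                      target_keys = c("s", ";"), duration_s = 30) {
  hand <- match.arg(hand)
  stopifnot(all(c("key", "down_ms", "up_ms") %in% names(events)),
            length(target_keys) == 2, target_keys[1] != target_keys[2])
  events <- tibble::as_tibble(events)[, c("key", "down_ms", "up_ms")]
  structure(
    list(hand = hand, target_keys = target_keys,
         duration_s = duration_s, events = events),
    class = "ema_fit_trial"
  )
}

#' Validate a tapping trial
#'
#' A trial is scoreable only if it contains at least one keystroke, every
#' event lies inside the `[0, duration]` window, key-up never precedes
#' key-down, events are ordered by key-down time, and no two key holds
#' overlap (one hand cannot hold two keys of this task at once).
#'
#' @param trial An `ema_fit_trial`.
#' @return `TRUE` if scoreable, else `FALSE` with a `reason` attribute.
#' @export
validate_trial <- function(trial) {
  ev <- trial$events
  if (nrow(ev) == 0) return(structure(FALSE, reason = "no keystrokes"))
  if (any(ev$up_ms < ev$down_ms)) {
    return(structure(FALSE, reason = "key-up before key-down"))
  }
  if (is.unsorted(ev$down_ms)) {
    return(structure(FALSE, reason = "events not ordered by key-down"))
  }
  lim <- trial$duration_s * 1000
  if (any(ev$down_ms < 0 | ev$up_ms > lim)) {
    return(structure(FALSE, reason = "outside window"))
  }
  if (nrow(ev) > 1 && any(ev$down_ms[-1] < ev$up_ms[-nrow(ev)])) {
    return(structure(FALSE, reason = "overlapping key holds"))
  }
  TRUE
}

# Events that count toward dwell/travel statistics. Incorrect strikes are
# keystrokes (they count for KS and DS) but by default are excluded from
# the dwell and travel kinematics; include_errors = TRUE pools them.
counted_events <- function(trial, include_errors = FALSE) {
  if (include_errors) trial$events
  else trial$events[trial$events$key %in% trial$target_keys, , drop = FALSE]
}

#' Kinesia score: keystroke count
#'
#' Number of key-down events on any key during the trial window. Incorrect
#' strikes are keystrokes and are counted.
#'
#' @param trial A validated `ema_fit_trial`.
#' @return Integer count per trial window.
#' @export
kinesia_score <- function(trial) {
  nrow(trial$events)
}

#' Akinesia time: mean key dwell
#'
#' Arithmetic mean of `up_ms - down_ms` over counted keystrokes, in
#' milliseconds.
#'
#' @inheritParams kinesia_score
#' @param include_errors Include non-target keystrokes in the mean
#'   (default `FALSE`).
#' @return Mean dwell time in ms (`NA` if no counted keystroke).
#' @export
akinesia_time <- function(trial, include_errors = FALSE) {
  ev <- counted_events(trial, include_errors)
  if (nrow(ev) == 0) return(NA_real_)
  mean(ev$up_ms - ev$down_ms)
}

# Travel times between consecutive counted keystrokes: key-up of one
# stroke to key-down of the next.
travel_times <- function(trial, include_errors = FALSE) {
  ev <- counted_events(trial, include_errors)
  if (nrow(ev) < 2) return(numeric(0))
  ev$down_ms[-1] - ev$up_ms[-nrow(ev)]
}

#' Incoordination score: travel-time variance
#'
#' Sample variance (n - 1 denominator) of the travel times between
#' consecutive counted keystrokes, where travel is measured key-up to next
#' key-down. Requires at least three counted keystrokes (two travel
#' intervals); otherwise the result is undefined and `NA` is returned.
#'
#' @inheritParams akinesia_time
#' @return Variance in ms^2, or `NA` when fewer than 3 keystrokes.
#' @export
incoordination_score <- function(trial, include_errors = FALSE) {
  tt <- travel_times(trial, include_errors)
  if (length(tt) < 2) return(NA_real_)
  stats::var(tt)
}

#' Default key adjacency map
#'
#' Physical neighbourhood of the two default target keys on a QWERTY
#' layout, used to weight incorrect strikes: a miss on a key adjacent to a
#' target weighs 1, any other key weighs 2. Geometry is supplied as
#' configuration because physical key separation is not inferable from key
#' codes.
#'
#' @return Named list mapping each target key to its adjacent keys.
#' @export
default_adjacency <- function() {
  list(
    "s" = c("a", "w", "e", "d", "x", "z"),
    ";" = c("p", "l", ".", "/", "[", "'")
  )
}

#' Dysmetria score: accuracy-weighted error rate
#'
#' Each keystroke receives weight 0 if on a target key, 1 if on a key
#' adjacent to a target (per the adjacency map), 2 otherwise; the score is
#' the total weight divided by the kinesia score. 0 means every strike was
#' on target; 2 is the maximum (all strikes far off target).
#'
#' @inheritParams kinesia_score
#' @param adjacency Named list mapping target keys to adjacent keys; see
#'   [default_adjacency()].
#' @return Dimensionless score in `[0, 2]`.
#' @export
dysmetria_score <- function(trial, adjacency = default_adjacency()) {
  keys <- trial$events$key
  adjacent <- unique(unlist(adjacency[trial$target_keys]))
  w <- ifelse(keys %in% trial$target_keys, 0,
              ifelse(keys %in% adjacent, 1, 2))
  sum(w) / kinesia_score(trial)
}

#' Score a tapping trial into the four kinematic parameters
#'
#' Bundles [kinesia_score()], [akinesia_time()], [incoordination_score()]
#' and [dysmetria_score()] for a validated trial. Deterministic for a
#' fixed input; a rejected trial raises an error (only fully valid trials
#' are ever recorded).
#'
#' @inheritParams dysmetria_score
#' @param include_errors Pool incorrect strikes into dwell/travel
#'   statistics (default `FALSE`).
#' @return One-row tibble: `hand`, `kinesia_score`, `akinesia_time`,
#'   `incoordination_score`, `dysmetria_score`.
#' @export
score_trial <- function(trial, adjacency = default_adjacency(),
                        include_errors = FALSE) {
  ok <- validate_trial(trial)
  if (!isTRUE(ok)) {
    stop("trial rejected: ", attr(ok, "reason"), call. = FALSE)
  }
  tibble::tibble(
    hand = trial$hand,
    kinesia_score = kinesia_score(trial),
    akinesia_time = akinesia_time(trial, include_errors),
    incoordination_score = incoordination_score(trial, include_errors),
    dysmetria_score = dysmetria_score(trial, adjacency)
  )
}

#' @export
print.ema_fit_trial <- function(x, ...) {
  cat("<ema_fit_trial>", x$hand, "hand,", nrow(x$events), "keystrokes in",
      x$duration_s, "s on keys", paste(x$target_keys, collapse = "/"), "\n")
  invisible(x)
}
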