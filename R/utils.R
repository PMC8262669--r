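# Shared vocabulary and numeric helpers.

# Canonical ordering of session kinds; ties between simultaneously due
# sessions break in this order, nap always last.
SESSION_KINDS <- c("on_waking", "after_medications", "afternoon", "evening", "nap")
SCHEDULED_KINDS <- SESSION_KINDS[1:4]
TASK_KINDS <- c("subjective_scales", "fit_test", "sleep_diary")
ANCHOR_KINDS <- c("wake_time", "first_med_intake", "afternoon_dose_due",
                  "bedtime", "nap_end")
CATEGORIZATIONS <- c("H", "V0", "V1")

#' Round half away from zero
#'
#' Rounding used for every printed-style percentage in the package
#' (2-decimal compliance percents, integer satisfaction percents). Base
#' [round()] rounds half to even, which does not reproduce printed clinical
#' report values such as 89.92; this helper rounds .5 up.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(100 * 2899 / 3224, 2) # 89.92
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage with printed-style rounding; NA when the denominator is 0.
pct <- function(num, denom, digits = 2) {
  ifelse(denom > 0, round_half_up(100 * num / denom, digits), NA_real_)
}

# ISO-8601 with numeric UTC offset, second resolution.
format_iso8601 <- function(t, tz = NULL) {
  if (is.null(tz)) tz <- attr(t, "tzone") %||% "UTC"
  strftime(t, "%Y-%m-%dT%H:%M:%S%z", tz = tz)
}

parse_iso8601 <- function(x, tz = "UTC") {
  lubridate::with_tz(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE), tz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer factor for ordered session sorting.
session_rank <- function(kind) match(kind, SESSION_KINDS)

# Derive a per-unit substream seed from a root seed; kept inside 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 7919 + as.double(index) * 104729) %% 2147483647)
}
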