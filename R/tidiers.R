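#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a compliance report
#'
#' @param x An `ema_compliance`.
#' @param ... Unused.
#' @return The version x session x task cell tibble (`version`,
#'   `session_kind`, `task_kind`, `completed`, `expected`, `percent`).
#' @method tidy ema_compliance
#' @export
tidy.ema_compliance <- function(x, ...) x$cells

#' @rdname tidy.ema_compliance
#' @return For `glance()`: a one-row tibble with overall `completed`,
#'   `expected`, `percent`.
#' @method glance ema_compliance
#' @export
glance.ema_compliance <- function(x, ...) {
  tibble::tibble(completed = x$overall$completed,
                 expected = x$overall$expected,
                 percent = x$overall$percent)
}

#' Plot a compliance report
#'
#' Bar chart of per-cell compliance percentages, sessions on the x axis,
#' faceted by protocol version; the once-daily diary (no session
#' attribution) is shown as its own column.
#'
#' @param object An `ema_compliance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ema_compliance
#' @export
autoplot.ema_compliance <- function(object, ...) {
  d <- object$cells
  d$session <- factor(ifelse(is.na(d$session_kind), "daily", d$session_kind),
                      levels = c(SCHEDULED_KINDS, "daily"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$session, y = .data$percent,
                                  fill = .data$task_kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$version)) +
    ggplot2::labs(x = NULL, y = "compliance (%)", fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Tidy a target-ratio analysis
#'
#' @param x An `ema_target_ratio`.
#' @param ... Unused.
#' @return Per-patient mean ratios.
#' @method tidy ema_target_ratio
#' @export
tidy.ema_target_ratio <- function(x, ...) x$per_patient

#' @rdname tidy.ema_target_ratio
#' @method glance ema_target_ratio
#' @export
glance.ema_target_ratio <- function(x, ...) {
  tibble::tibble(cohort_mean = x$cohort_mean,
                 sd = stats::sd(x$per_patient$mean_ratio),
                 n_patients = nrow(x$per_patient))
}

#' Plot per-patient target ratios
#'
#' One point per patient (mean target ratio over included home-period
#' sessions) with the cohort mean as a horizontal line.
#'
#' @param object An `ema_target_ratio`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ema_target_ratio
#' @export
autoplot.ema_target_ratio <- function(object, ...) {
  d <- object$per_patient
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$patient_id,
                                                     .data$mean_ratio),
                                  y = .data$mean_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$cohort_mean, linetype = 2) +
    ggplot2::labs(x = NULL, y = "target ratio (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Tidy a satisfaction summary
#'
#' @param x An `ema_satisfaction`.
#' @param ... Unused.
#' @return Per-question level counts and integer percentages.
#' @method tidy ema_satisfaction
#' @export
tidy.ema_satisfaction <- function(x, ...) x$per_question

#' @rdname tidy.ema_satisfaction
#' @method glance ema_satisfaction
#' @export
glance.ema_satisfaction <- function(x, ...) {
  tibble::tibble(
    questions = length(unique(x$per_question$question_id)),
    respondents = max(x$per_question$respondents),
    groups = if (is.null(x$per_group)) 0L
             else length(unique(x$per_group$group))
  )
}
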