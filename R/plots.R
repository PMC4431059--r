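#' Plot the cost-effectiveness plane
#'
#' Scatter of the per-iteration incremental cost against incremental
#' QALYs, with the willingness-to-pay threshold drawn through the origin.
#'
#' @param object A `psa_result`.
#' @param lambda Willingness-to-pay line to draw (GBP per QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, lambda = 20000, ...) {
  it <- object$iterations
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = lambda, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: £%s per QALY",
                                     format(lambda, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier time-to-threshold curve
#'
#' @param object A `survival_curve` from [estimate_time_to_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, n_risk = NA_real_, n_event = NA_real_,
                         survival = 1),
                  as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months since first visit",
                  y = "Proportion still above 6/12",
                  title = "Time to acuity below 6/12 (fellow eyes)") +
    ggplot2::theme_minimal()
}

#' Plot a single patient trajectory
#'
#' @param object A `patient_trajectory` from [simulate_patient()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patient_trajectory <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(month = cumsum(.data$months) - .data$months)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$state)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$phase)) +
    ggplot2::scale_y_reverse(breaks = 1:5, labels = va_states()$label) +
    ggplot2::labs(x = "Month", y = "Acuity state",
                  title = "Simulated patient trajectory") +
    ggplot2::theme_minimal()
}
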