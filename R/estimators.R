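#' Estimate a monthly (or k-monthly) transition matrix from visit records
#'
#' Counts observed state pairs at the requested spacing within each eye
#' and converts row counts to row proportions: entry (i, j) is the
#' fraction of transitions out of state i that land in state j over
#' `cycle_months` months. States with no observed departures fall back to
#' an identity row with a warning.
#'
#' @param visits Visit tibble (see [generate_cohort()]).
#' @param eye_role `"treated"` or `"fellow"`.
#' @param cycle_months Transition spacing in months (default 1).
#' @return A 5x5 row-stochastic matrix with a `counts` attribute (the raw
#'   transition counts) and a `sparse_rows` attribute (states filled with
#'   the identity fallback).
#' @examples
#' v <- generate_cohort(generator_config(n_patients = 100), seed = 1)
#' estimate_transition_matrix(v, "treated")
#' @export
estimate_transition_matrix <- function(visits, eye_role = c("treated", "fellow"),
                                       cycle_months = 1) {
  eye_role <- arg_match(eye_role)
  v <- filter(visits, .data$eye_role == !!eye_role)
  from <- select(v, "patient_id", "month_index", va_state = "va_state")
  to <- v |>
    mutate(month_index = .data$month_index - cycle_months) |>
    select("patient_id", "month_index", to_state = "va_state")
  pairs <- dplyr::inner_join(from, to, by = c("patient_id", "month_index"))
  if (nrow(pairs) == 0) {
    abort(sprintf(
      "No consecutive %s-eye visit pairs at %d-month spacing.", eye_role,
      cycle_months))
  }
  counts <- matrix(0, 5, 5)
  tab <- table(factor(pairs$va_state, levels = 1:5),
               factor(pairs$to_state, levels = 1:5))
  counts[] <- as.numeric(tab)
  sparse <- which(rowSums(counts) == 0)
  P <- counts
  for (i in 1:5) {
    P[i, ] <- if (i %in% sparse) as.numeric(seq_len(5) == i) else
      counts[i, ] / sum(counts[i, ])
  }
  if (length(sparse)) {
    warn(sprintf("No observed departures from state(s) %s; identity row used.",
                 paste(sparse, collapse = ", ")))
  }
  lbl <- va_states()$label
  dimnames(P) <- list(lbl, lbl)
  attr(P, "counts") <- counts
  attr(P, "sparse_rows") <- sparse
  P
}

#' Kaplan-Meier curve for time to acuity below 6/12 (fellow eyes)
#'
#' For each fellow eye, the event is the first visit in state 2 or worse
#' (below 6/12, the treatment gate); eyes never observed below the gate
#' are censored at their last visit. The product-limit estimate is
#' computed with [survival::survfit()].
#'
#' @param visits Visit tibble containing fellow-eye records.
#' @return A tibble of class `survival_curve` with columns `time` (months),
#'   `n_risk`, `n_event`, `survival`; the median is attached as the
#'   `median_months` attribute (`NA` if the curve never reaches 0.5).
#' @examples
#' v <- generate_cohort(generator_config(n_patients = 100), seed = 1)
#' km <- estimate_time_to_threshold(v)
#' attr(km, "median_months")
#' @export
estimate_time_to_threshold <- function(visits) {
  fe <- filter(visits, .data$eye_role == "fellow")
  if (nrow(fe) == 0) abort("No fellow-eye records present.")
  per_eye <- fe |>
    group_by(.data$patient_id) |>
    summarise(
      first_month = min(.data$month_index),
      event_month = suppressWarnings(min(.data$month_index[.data$va_state >= 2])),
      last_month = max(.data$month_index),
      .groups = "drop"
    ) |>
    mutate(
      event = is.finite(.data$event_month),
      time = ifelse(.data$event, .data$event_month, .data$last_month) -
        .data$first_month
    )
  fit <- survival::survfit(
    survival::Surv(per_eye$time, as.integer(per_eye$event)) ~ 1)
  curve <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, survival = fit$surv)
  stab <- summary(fit)$table
  structure(curve, class = c("survival_curve", class(curve)),
            median_months = unname(stab["median"]),
            median_lcl = unname(stab["0.95LCL"]),
            median_ucl = unname(stab["0.95UCL"]),
            n_subjects = nrow(per_eye))
}

#' Write a survival curve as CSV
#'
#' @param curve A `survival_curve` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate the PRN injection rate from treated-eye visits
#'
#' Injections per post-loading treated-eye visit-month.
#'
#' @param visits Visit tibble.
#' @param loading_months Months considered loading (excluded; default 3).
#' @return A probability per month in \[0, 1\].
#' @export
estimate_injection_rate <- function(visits, loading_months = 3) {
  post <- filter(visits, .data$eye_role == "treated",
                 .data$month_index >= loading_months)
  if (nrow(post) == 0) abort("No post-loading treated-eye visits present.")
  mean(post$injected)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (any(n <= 0)) abort("`n` must be positive.")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  tibble(estimate = p, lower = pmax(0, centre - half),
         upper = pmin(1, centre + half))
}
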