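#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Classifies the (incremental cost, incremental effect) pair into the
#' four cost-effectiveness-plane quadrants: a positive ratio is reported
#' when both increments are positive (north-east) — the usual trade-off —
#' or when both are negative (south-west, flagged, where a ratio is still
#' meaningful but must be read as savings per QALY forgone); the
#' intervention is `"dominant"` when it gains QALYs at no extra cost and
#' `"dominated"` when it loses QALYs at no saving. A zero QALY difference
#' leaves the ratio undefined.
#'
#' @param delta_cost Incremental cost (intervention minus comparator, GBP).
#' @param delta_qaly Incremental QALYs.
#' @return Tibble with one row per input pair: `delta_cost`, `delta_qaly`,
#'   `icer` (GBP per QALY; `NA` when not a ratio) and `decision`
#'   (`"icer"`, `"dominant"`, `"dominated"`, `"sw_ratio"`, `"undefined"`).
#' @examples
#' icer(1009.58, 0.24)
#' icer(-1, 0.1)
#' @export
icer <- function(delta_cost, delta_qaly) {
  n <- max(length(delta_cost), length(delta_qaly))
  delta_cost <- rep_len(delta_cost, n)
  delta_qaly <- rep_len(delta_qaly, n)
  decision <- dplyr::case_when(
    delta_qaly == 0 ~ "undefined",
    delta_qaly > 0 & delta_cost <= 0 ~ "dominant",
    delta_qaly < 0 & delta_cost >= 0 ~ "dominated",
    delta_qaly < 0 & delta_cost < 0 ~ "sw_ratio",
    .default = "icer"
  )
  tibble(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icer = ifelse(decision %in% c("icer", "sw_ratio"),
                  delta_cost / delta_qaly, NA_real_),
    decision = decision
  )
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB}(\lambda) = \lambda \Delta E - \Delta C}: positive
#' when the intervention is cost-effective at willingness-to-pay
#' \eqn{\lambda}.
#'
#' @inheritParams icer
#' @param lambda Willingness to pay (GBP per QALY), non-negative.
#' @return Numeric NMB in GBP (vectorised).
#' @examples
#' net_monetary_benefit(1009.58, 0.24, 20000)
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) abort("`lambda` must be non-negative.")
  lambda * delta_qaly - delta_cost
}

#' Incremental comparison of two arm results
#'
#' @param comparator,intervention `arm_result` objects (from [run_arm()]
#'   or [cohort_expectation()]).
#' @return One-row tibble with per-arm means, increments and the ICER
#'   classification.
#' @export
incremental_result <- function(comparator, intervention) {
  stopifnot(inherits(comparator, "arm_result"), inherits(intervention, "arm_result"))
  cs <- comparator$summary; is <- intervention$summary
  ic <- icer(is$mean_cost - cs$mean_cost, is$mean_qaly - cs$mean_qaly)
  tibble(
    comparator_cost = cs$mean_cost, intervention_cost = is$mean_cost,
    delta_cost = ic$delta_cost,
    comparator_qaly = cs$mean_qaly, intervention_qaly = is$mean_qaly,
    delta_qaly = ic$delta_qaly,
    icer = ic$icer, decision = ic$decision
  )
}

#' Scenario specification for one-way sensitivity analysis
#'
#' Declares a named set of parameter overrides relative to the base case.
#' Only the declared knobs can be touched; anything else is a config
#' error.
#'
#' @param name Scenario label.
#' @param utilities Optional replacement vector of 5 state utility means
#'   (e.g. standard-gamble values in place of time trade-off).
#' @param drug_only If `TRUE`, drop assessment and monitoring costs.
#' @param horizon_months Optional horizon override.
#' @param fixed_age Optional fixed starting age for the whole cohort.
#' @return A `scenario_spec` list.
#' @examples
#' scenario_spec("5-year horizon", horizon_months = 60)
#' @export
scenario_spec <- function(name, utilities = NULL, drug_only = FALSE,
                          horizon_months = NULL, fixed_age = NULL) {
  if (!is.null(utilities) &&
      (length(utilities) != 5 || any(utilities < 0 | utilities > 1))) {
    abort("`utilities` override must be 5 values in [0, 1].")
  }
  structure(list(name = name, utilities = utilities, drug_only = drug_only,
                 horizon_months = horizon_months, fixed_age = fixed_age),
            class = "scenario_spec")
}

# Overrides are applied without re-running base-case validation:
# alternative utility sets (e.g. standard gamble) need not be strictly
# monotone; range checks are done in scenario_spec().
apply_scenario <- function(spec, params) {
  stopifnot(inherits(spec, "scenario_spec"))
  p <- params
  if (!is.null(spec$utilities)) p$utilities$mean <- spec$utilities
  if (spec$drug_only) p$costs$drug_only <- TRUE
  if (!is.null(spec$horizon_months)) p$horizon_months <- spec$horizon_months
  p
}

#' Run the one-way sensitivity-analysis scenario table
#'
#' Re-runs both arms for the base case and each scenario under a common
#' root seed (common random numbers, so a pure cost scenario leaves the
#' QALY columns identical to the base case) and reports the scenario
#' table: per-arm costs and QALYs, increments, ICER and the percent
#' change in ICER versus the base case (rounded to the nearest integer).
#'
#' @param scenarios List of [scenario_spec()] objects.
#' @param params Base-case [amd_parameters()].
#' @param n_patients Patients per arm per scenario.
#' @param seed Root seed shared across scenarios.
#' @param engine `"micro"` (microsimulation) or `"expectation"`
#'   (deterministic cohort expectation).
#' @return Tibble with one row per scenario (base case first).
#' @export
run_scenarios <- function(scenarios, params, n_patients = 2000, seed = 1,
                          engine = c("micro", "expectation")) {
  engine <- arg_match(engine)
  all_specs <- c(list(scenario_spec("base case")), scenarios)
  rows <- purrr::imap(all_specs, function(spec, i) {
    p <- apply_scenario(spec, params)
    horizon <- spec$horizon_months %||% p$horizon_months
    run1 <- function(arm) {
      st <- strategy_config(arm, horizon_months = horizon,
                            loading_months = p$loading_months,
                            fixed_age = spec$fixed_age)
      if (engine == "micro") run_arm(st, p, n_patients, seed = seed)
      else cohort_expectation(st, p)
    }
    inc <- incremental_result(run1("delayed"), run1("immediate"))
    mutate(inc, scenario = spec$name, .before = 1)
  }) |> purrr::list_rbind()
  base_icer <- rows$icer[1]
  mutate(rows,
         icer_change_pct = ifelse(row_number() == 1, NA_real_,
                                  round(100 * (.data$icer - base_icer) / base_icer)))
}

#' Write the scenario table as CSV
#'
#' @param scenario_table Output of [run_scenarios()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenario_table, path) {
  utils::write.csv(scenario_table, path, row.names = FALSE)
  invisible(path)
}
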