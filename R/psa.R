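#' Build the PSA parameter distributions
#'
#' Fits the second-order distributions used by the probabilistic
#' sensitivity analysis: beta distributions for the five state utilities
#' (from their published means and SDs), gamma distributions for the
#' three unit costs (SD taken as `sd_fraction` of the mean, by
#' convention 10\%), and Dirichlet distributions for the loading row and
#' each monthly matrix row (concentration = row times `effective_n`).
#' Parameters are sampled independently.
#'
#' @param params An [amd_parameters()] list.
#' @param effective_n Dirichlet pseudo-count per row; `Inf` makes the
#'   transition rows degenerate.
#' @param sd_scale Multiplier on every utility/cost SD; `0` collapses all
#'   scalar distributions to point masses (used to check that a
#'   degenerate PSA reproduces the base case).
#' @return A `psa_distributions` list of `dist_spec` objects.
#' @export
psa_distributions <- function(params, effective_n = params$effective_n,
                              sd_scale = 1) {
  u <- params$utilities
  cc <- params$costs
  structure(list(
    utilities = purrr::map2(u$mean, u$sd * sd_scale, beta_params_from_moments),
    costs = list(
      drug_per_injection = gamma_params_from_moments(
        cc$drug_per_injection, cc$drug_per_injection * cc$sd_fraction * sd_scale),
      assessment = gamma_params_from_moments(
        cc$assessment, cc$assessment * cc$sd_fraction * sd_scale),
      monitoring = gamma_params_from_moments(
        cc$monitoring, cc$monitoring * cc$sd_fraction * sd_scale)
    ),
    loading_row = dirichlet_alpha_from_row(params$loading_row, effective_n),
    monthly = purrr::map(seq_len(5), function(i)
      dirichlet_alpha_from_row(params$monthly[i, ], effective_n))
  ), class = "psa_distributions")
}

#' Draw one parameter set for a PSA iteration
#'
#' @param distributions A [psa_distributions()] list.
#' @param params Base-case parameters (non-sampled components are kept).
#' @param seed Optional seed for this draw.
#' @return An `amd_params` list with sampled utilities, unit costs and
#'   transition rows.
#' @export
sample_parameter_set <- function(distributions, params, seed = NULL) {
  stopifnot(inherits(distributions, "psa_distributions"))
  with_seed_if(seed, {
    p <- params
    p$utilities$mean <- map_dbl(distributions$utilities, sample_dist)
    p$costs$drug_per_injection <- sample_dist(distributions$costs$drug_per_injection)
    p$costs$assessment <- sample_dist(distributions$costs$assessment)
    p$costs$monitoring <- sample_dist(distributions$costs$monitoring)
    p$loading_row <- as.numeric(sample_dist(distributions$loading_row))
    for (i in seq_len(5)) {
      p$monthly[i, ] <- as.numeric(sample_dist(distributions$monthly[[i]]))
    }
    p
  })
}

#' Probabilistic sensitivity analysis
#'
#' For each iteration, draws a fresh parameter set from the second-order
#' distributions and runs both strategies with common random numbers
#' (the same sub-seed drives both arms, reducing variance on the
#' increments). The default of one patient path per iteration treats each
#' Monte-Carlo simulation as one parameter draw plus one patient; nested
#' designs are available through `n_patients`.
#'
#' @param params Base-case [amd_parameters()].
#' @param n_iterations Number of parameter draws.
#' @param n_patients Patient paths per arm within an iteration.
#' @param seed Root seed (sub-seeds are derived per iteration).
#' @param horizon_months Model horizon (default from `params`).
#' @param distributions Optional pre-built [psa_distributions()].
#' @return A `psa_result`: [tidy()] gives per-iteration rows (`iteration`,
#'   per-arm cost/QALYs, `delta_cost`, `delta_qaly`); [glance()] gives the
#'   central estimates, with the central ICER computed as the ratio of the
#'   mean increments over iterations.
#' @examples
#' psa <- run_psa(amd_parameters(), n_iterations = 20, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(params, n_iterations = 1000, n_patients = 1, seed = 1,
                    horizon_months = params$horizon_months,
                    distributions = psa_distributions(params)) {
  if (n_iterations < 1) abort("`n_iterations` must be at least 1.")
  st_imm <- strategy_config("immediate", horizon_months = horizon_months)
  st_del <- strategy_config("delayed", horizon_months = horizon_months)
  iters <- purrr::map(seq_len(n_iterations), function(i) {
    p_i <- sample_parameter_set(distributions, params,
                                seed = derive_seed(seed, 2L * i))
    arm_seed <- derive_seed(seed, 2L * i + 1L)
    imm <- run_arm(st_imm, p_i, n_patients, seed = arm_seed)$summary
    del <- run_arm(st_del, p_i, n_patients, seed = arm_seed)$summary
    tibble(
      iteration = i,
      cost_comparator = del$mean_cost, qaly_comparator = del$mean_qaly,
      cost_intervention = imm$mean_cost, qaly_intervention = imm$mean_qaly,
      delta_cost = imm$mean_cost - del$mean_cost,
      delta_qaly = imm$mean_qaly - del$mean_qaly
    )
  }) |> purrr::list_rbind()
  if (!all(is.finite(iters$delta_cost)) || !all(is.finite(iters$delta_qaly))) {
    abort("PSA produced non-finite increments.")
  }
  structure(list(iterations = iters, n_iterations = n_iterations,
                 n_patients = n_patients, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_iterations, "iterations x", x$n_patients,
      "patient path(s) per arm (seed", paste0(x$seed, ")"), "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `psa_result`.
#' @param ... Unused.
#' @export
tidy.psa_result <- function(x, ...) x$iterations

#' @rdname run_psa
#' @export
glance.psa_result <- function(x, ...) {
  it <- x$iterations
  central <- icer(mean(it$delta_cost), mean(it$delta_qaly))
  tibble(
    n_iterations = x$n_iterations,
    mean_cost_comparator = mean(it$cost_comparator),
    mean_cost_intervention = mean(it$cost_intervention),
    mean_qaly_comparator = mean(it$qaly_comparator),
    mean_qaly_intervention = mean(it$qaly_intervention),
    mean_delta_cost = central$delta_cost,
    mean_delta_qaly = central$delta_qaly,
    central_icer = central$icer,
    prob_ce_20k = mean(net_monetary_benefit(it$delta_cost, it$delta_qaly,
                                            20000) > 0)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value. At \eqn{\lambda = 0} this is the fraction of
#' iterations in which the intervention saves money.
#'
#' @param result A [run_psa()] result, or a tibble with `delta_cost` and
#'   `delta_qaly` columns.
#' @param lambda_grid Willingness-to-pay grid in GBP per QALY (default 0
#'   to 50,000 in steps of 500).
#' @return Tibble of class `ceac_curve`: `lambda`, `probability`.
#' @examples
#' draws <- tibble::tibble(delta_cost = c(100, -50, 200),
#'                         delta_qaly = c(0.1, 0.05, -0.01))
#' ceac(draws, lambda_grid = c(0, 2000))
#' @export
ceac <- function(result, lambda_grid = seq(0, 50000, by = 500)) {
  if (length(lambda_grid) == 0) abort("`lambda_grid` must be non-empty.")
  if (any(lambda_grid < 0)) abort("`lambda_grid` must be non-negative.")
  it <- if (inherits(result, "psa_result")) result$iterations else as_tibble(result)
  if (nrow(it) == 0) abort("No PSA iterations supplied.")
  pts <- tibble(
    lambda = lambda_grid,
    probability = map_dbl(lambda_grid, function(l)
      mean(net_monetary_benefit(it$delta_cost, it$delta_qaly, l) > 0))
  )
  structure(pts, class = c("ceac_curve", class(pts)))
}

#' Write CE-plane draws / CEAC points as CSV
#'
#' @param result A `psa_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ce_plane <- function(result, path) {
  stopifnot(inherits(result, "psa_result"))
  utils::write.csv(
    select(result$iterations, "iteration", "delta_cost", "delta_qaly"),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ce_plane
#' @param curve A `ceac_curve` tibble.
#' @export
write_ceac <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
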