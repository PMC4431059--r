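#' Strategy configuration
#'
#' Describes one arm of the comparison. The immediate arm treats at entry:
#' one 3-month loading cycle (three injections) from the best acuity state,
#' then monthly PRN cycles to the horizon. The delayed arm waits in the
#' best state, untreated and uncosted, for a sampled time until acuity
#' drops below 6/12; it then enters the loading cycle in a state drawn
#' from the re-entry distribution and continues under PRN for the rest of
#' the horizon (which includes the delay).
#'
#' @param arm `"immediate"` or `"delayed"`.
#' @param horizon_months Total simulated months per patient (default 24).
#' @param loading_months Length of the loading cycle (default 3; one
#'   injection per month).
#' @param half_cycle If `TRUE`, patients dying within a cycle accrue half
#'   that cycle's utility instead of none.
#' @param fixed_age If non-`NULL`, every patient starts at this age
#'   instead of sampling the cohort age distribution.
#' @return A `strategy_config` list.
#' @examples
#' strategy_config("immediate")
#' strategy_config("delayed", horizon_months = 60)
#' @export
strategy_config <- function(arm = c("immediate", "delayed"),
                            horizon_months = 24,
                            loading_months = 3,
                            half_cycle = FALSE,
                            fixed_age = NULL) {
  arm <- arg_match(arm)
  if (horizon_months < loading_months) {
    abort("`horizon_months` must be at least `loading_months`.")
  }
  structure(list(arm = arm, horizon_months = horizon_months,
                 loading_months = loading_months, half_cycle = half_cycle,
                 fixed_age = fixed_age),
            class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat("<strategy_config>", x$arm, "arm,", x$horizon_months, "month horizon\n")
  invisible(x)
}

# Effective per-event costs given the drug-only switch.
effective_costs <- function(costs) {
  list(
    injection = costs$drug_per_injection + if (costs$drug_only) 0 else costs$assessment,
    monitoring = if (costs$drug_only) 0 else costs$monitoring,
    prn = costs$prn_injection_rate
  )
}

# Loading-cycle transition kernel: the printed 3-month row from the best
# state; rows 2-5 (delayed-arm loading entries, unprinted) use the monthly
# matrix composed three times.
loading_kernel <- function(params) {
  M3 <- params$monthly %*% params$monthly %*% params$monthly
  K <- rbind(params$loading_row, M3[2:5, , drop = FALSE])
  dimnames(K) <- dimnames(params$monthly)
  K
}

# Integer-age probability table per gender: truncated normal discretised
# to whole years. Shared by the microsimulation sampler and the
# deterministic expectation so the two integrate over the same mixture.
age_tables <- function(params, fixed_age = NULL) {
  demo <- params$demographics
  purrr::map(seq_len(nrow(demo)), function(i) {
    d <- demo[i, ]
    if (!is.null(fixed_age)) {
      tibble(gender = d$gender, prop = d$proportion,
             age = fixed_age, w = 1)
    } else {
      ages <- seq(d$age_min, d$age_max)
      w <- dnorm(ages, d$age_mean, d$age_sd)
      tibble(gender = d$gender, prop = d$proportion, age = ages, w = w / sum(w))
    }
  }) |> purrr::list_rbind()
}

# Delay pmf on monthly support: delay d = ceiling(T) months in the best
# state before treatment; d >= horizon means never treated in-horizon.
delay_pmf <- function(params, horizon) {
  rate <- log(2) / params$delay$median_months
  k <- seq_len(horizon - 1)
  p <- pexp(k, rate) - pexp(k - 1, rate)
  tibble(delay = c(k, horizon), prob = c(p, 1 - pexp(horizon - 1, rate)))
}

# Vectorised one-step Markov draw: state[i] -> next state via inverse cdf.
step_markov <- function(state, P, u) {
  cp <- t(apply(P, 1L, cumsum))
  idx <- 1L + rowSums(cp[state, , drop = FALSE] < u)
  pmin(idx, ncol(P))
}

# Simulate one homogeneous group: n patients sharing a delay d (0 for the
# immediate arm). Mortality is drawn at each cycle start (deaths accrue
# nothing unless half_cycle); survivors accrue utility and costs for the
# full cycle, then make the VA transition.
simulate_group <- function(n, d, gender, age0, params, strategy) {
  horizon <- strategy$horizon_months
  Lm <- strategy$loading_months
  u <- params$utilities$mean
  ec <- effective_costs(params$costs)
  K <- loading_kernel(params)
  M <- params$monthly
  hc <- strategy$half_cycle

  state <- rep(1L, n)
  alive <- rep(TRUE, n)
  age <- age0
  qaly <- cost <- inj <- numeric(n)

  mortality_step <- function(months) {
    q <- cycle_death_prob(age, gender, params$mortality, months)
    die <- alive & (runif(n) < q)
    if (hc && any(die)) {
      qaly[die] <<- qaly[die] + u[state[die]] * months / 24
    }
    alive <<- alive & !die
    invisible(NULL)
  }

  for (t in seq_len(d)) {   # untreated wait: best state, no costs
    mortality_step(1)
    qaly[alive] <- qaly[alive] + u[1] / 12
    age <- age + 1 / 12
  }

  if (d < horizon) {
    L <- min(Lm, horizon - d)
    if (strategy$arm == "delayed") {
      state <- step_markov(rep(1L, n), rbind(params$reentry)[rep(1L, 5), ], runif(n))
    }
    mortality_step(L)
    qaly[alive] <- qaly[alive] + u[state[alive]] * L / 12
    cost[alive] <- cost[alive] + L * ec$injection
    inj[alive] <- inj[alive] + L
    state <- step_markov(state, K, runif(n))
    age <- age + L / 12

    for (t in seq_len(horizon - d - L)) {
      mortality_step(1)
      qaly[alive] <- qaly[alive] + u[state[alive]] / 12
      z <- runif(n) < ec$prn
      cost[alive & z] <- cost[alive & z] + ec$injection
      inj[alive & z] <- inj[alive & z] + 1
      cost[alive & !z] <- cost[alive & !z] + ec$monitoring
      state <- step_markov(state, M, runif(n))
      age <- age + 1 / 12
    }
  }

  tibble(gender = gender, age = age0, delay_months = d,
         qaly = qaly, cost = cost, injections = inj, alive_end = alive)
}

#' Simulate one arm for a cohort of patients
#'
#' Patient-level Markov microsimulation: each patient receives an age
#' (integer years from a truncated-normal cohort distribution) and gender,
#' then moves through acuity states cycle by cycle with background
#' mortality applied at every cycle start. Returns per-patient accruals
#' plus arm-level means with Monte-Carlo standard errors.
#'
#' @param strategy A [strategy_config()].
#' @param params An [amd_parameters()] list.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; the run is reproducible given (strategy,
#'   params, n_patients, seed).
#' @return An `arm_result`: use [glance()] for the summary row
#'   (`mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`, `mean_injections`)
#'   and [tidy()] for per-patient rows.
#' @examples
#' res <- run_arm(strategy_config("immediate"), amd_parameters(),
#'                n_patients = 200, seed = 1)
#' glance(res)
#' @export
run_arm <- function(strategy, params, n_patients, seed = NULL) {
  stopifnot(inherits(strategy, "strategy_config"), inherits(params, "amd_params"))
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  patients <- with_seed_if(seed, {
    at <- age_tables(params, strategy$fixed_age)
    gi <- sample(nrow(at), n_patients, replace = TRUE, prob = at$prop * at$w)
    gender <- at$gender[gi]
    age0 <- as.numeric(at$age[gi])
    if (strategy$arm == "delayed") {
      rate <- log(2) / params$delay$median_months
      d <- pmin(ceiling(rexp(n_patients, rate)), strategy$horizon_months)
    } else {
      d <- rep(0, n_patients)
    }
    ord <- order(d, method = "radix")
    out <- vector("list", length(unique(d)))
    k <- 0L
    for (dv in sort(unique(d))) {
      idx <- ord[d[ord] == dv]
      k <- k + 1L
      out[[k]] <- simulate_group(length(idx), dv, gender[idx], age0[idx],
                                 params, strategy) |>
        mutate(patient_id = idx)
    }
    purrr::list_rbind(out) |> arrange(.data$patient_id) |>
      select("patient_id", dplyr::everything())
  })
  new_arm_result(strategy, patients = patients, seed = seed)
}

new_arm_result <- function(strategy, patients = NULL, expectation = NULL,
                           seed = NULL) {
  if (!is.null(patients)) {
    summary <- tibble(
      arm = strategy$arm,
      n = nrow(patients),
      mean_cost = mean(patients$cost),
      se_cost = sd(patients$cost) / sqrt(nrow(patients)),
      mean_qaly = mean(patients$qaly),
      se_qaly = sd(patients$qaly) / sqrt(nrow(patients)),
      mean_injections = mean(patients$injections)
    )
  } else {
    summary <- expectation
  }
  structure(list(summary = summary, patients = patients,
                 strategy = strategy, seed = seed),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result>", x$summary$arm, "arm",
      if (is.null(x$patients)) "(cohort expectation)" else
        sprintf("(%d simulated patients)", x$summary$n), "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_arm
#' @param x An `arm_result`.
#' @param ... Unused.
#' @export
glance.arm_result <- function(x, ...) x$summary

#' @rdname run_arm
#' @export
tidy.arm_result <- function(x, ...) {
  if (is.null(x$patients)) {
    abort("Cohort-expectation results carry no per-patient rows.")
  }
  x$patients
}

# Deterministic propagation for one (gender, age, delay) branch.
# Returns accrued expectations and, optionally, the per-cycle trace.
propagate_branch <- function(d, gender, age0, params, strategy,
                             trace = FALSE) {
  horizon <- strategy$horizon_months
  u <- params$utilities$mean
  ec <- effective_costs(params$costs)
  K <- loading_kernel(params)
  M <- params$monthly
  hc <- strategy$half_cycle

  alive <- 1; age <- age0
  qaly <- cost <- inj <- 0
  occ <- c(1, 0, 0, 0, 0)
  rows <- list()
  note <- function(cycle, months, phase) {
    if (trace) rows[[length(rows) + 1L]] <<- tibble(
      cycle = cycle, months = months, phase = phase,
      occupancy = list(occ * alive), alive = alive, cum_dead = 1 - alive)
  }
  cyc <- 0L
  step <- function(months, phase, occ_new, cost_add, inj_add) {
    q <- cycle_death_prob(age, gender, params$mortality, months)
    dying <- alive * q
    if (hc) qaly <<- qaly + dying * sum(u * occ) * months / 24
    alive <<- alive * (1 - q)
    qaly <<- qaly + alive * sum(u * occ) * months / 12
    cost <<- cost + alive * cost_add
    inj <<- inj + alive * inj_add
    occ <<- occ_new
    age <<- age + months / 12
    cyc <<- cyc + 1L
    note(cyc, months, phase)
  }
  note(0L, 0, "start")
  for (t in seq_len(d)) step(1, "untreated", occ, 0, 0)
  if (d < horizon) {
    L <- min(strategy$loading_months, horizon - d)
    if (strategy$arm == "delayed") occ <- params$reentry
    occ_after <- as.numeric(occ %*% K)
    step(L, "loading", occ_after, L * ec$injection, L)
    for (t in seq_len(horizon - d - L)) {
      step(1, "prn", as.numeric(occ %*% M),
           ec$prn * ec$injection + (1 - ec$prn) * ec$monitoring, ec$prn)
    }
  }
  list(qaly = qaly, cost = cost, injections = inj, alive = alive,
       trace = if (trace) purrr::list_rbind(rows) else NULL)
}

#' Deterministic cohort expectation for one arm
#'
#' Exact expectation of the microsimulation, obtained by propagating the
#' state-occupancy vector through the loading and monthly matrices with
#' per-cycle survival factors, and integrating over the gender/integer-age
#' mixture (and, for the delayed arm, the monthly delay distribution)
#' by direct summation. Serves as the oracle that the Monte-Carlo engine
#' must agree with.
#'
#' @inheritParams run_arm
#' @return An `arm_result` whose summary carries zero standard errors.
#' @examples
#' glance(cohort_expectation(strategy_config("immediate"), amd_parameters()))
#' @export
cohort_expectation <- function(strategy, params) {
  stopifnot(inherits(strategy, "strategy_config"), inherits(params, "amd_params"))
  at <- age_tables(params, strategy$fixed_age)
  dp <- if (strategy$arm == "delayed") {
    delay_pmf(params, strategy$horizon_months)
  } else {
    tibble(delay = 0, prob = 1)
  }
  acc <- c(qaly = 0, cost = 0, injections = 0)
  for (i in seq_len(nrow(at))) {
    for (j in seq_len(nrow(dp))) {
      w <- at$prop[i] * at$w[i] * dp$prob[j]
      if (w < 1e-14) next
      b <- propagate_branch(dp$delay[j], at$gender[i], as.numeric(at$age[i]),
                            params, strategy)
      acc <- acc + w * c(b$qaly, b$cost, b$injections)
    }
  }
  new_arm_result(strategy, expectation = tibble(
    arm = strategy$arm, n = NA_integer_,
    mean_cost = acc[["cost"]], se_cost = 0,
    mean_qaly = acc[["qaly"]], se_qaly = 0,
    mean_injections = acc[["injections"]]
  ))
}

#' Per-cycle state-occupancy trace for one cohort branch
#'
#' Deterministic trace of the occupancy vector, survival fraction and
#' cumulative death probability for a single gender/age/delay branch;
#' occupancy mass plus cumulative deaths is conserved at every cycle.
#'
#' @inheritParams run_arm
#' @param gender `"male"` or `"female"`.
#' @param age Starting age in years.
#' @param delay Delay months before treatment (0 for the immediate arm).
#' @return Tibble with one row per cycle: `cycle`, `months`, `phase`,
#'   `occupancy` (list of 5 state masses scaled by survival), `alive`,
#'   `cum_dead`.
#' @export
cohort_trace <- function(strategy, params, gender = "female", age = 80,
                         delay = 0) {
  propagate_branch(delay, gender, age, params, strategy, trace = TRUE)$trace
}

#' Simulate a single patient trajectory
#'
#' Cycle-by-cycle record for one simulated patient: phase, acuity state at
#' cycle start, survival, and the utility, cost and injections accrued in
#' the cycle. Useful for audit and for plotting individual paths.
#'
#' @inheritParams run_arm
#' @param gender,age Optional fixed demographics; sampled when `NULL`.
#' @return A tibble with class `patient_trajectory`.
#' @examples
#' simulate_patient(strategy_config("immediate"), amd_parameters(), seed = 7)
#' @export
simulate_patient <- function(strategy, params, seed = NULL,
                             gender = NULL, age = NULL) {
  stopifnot(inherits(strategy, "strategy_config"), inherits(params, "amd_params"))
  with_seed_if(seed, {
    at <- age_tables(params, strategy$fixed_age)
    if (is.null(gender) || is.null(age)) {
      gi <- sample(nrow(at), 1, prob = at$prop * at$w)
      gender <- gender %||% at$gender[gi]
      age <- age %||% as.numeric(at$age[gi])
    }
    horizon <- strategy$horizon_months
    d <- if (strategy$arm == "delayed") {
      min(ceiling(rexp(1, log(2) / params$delay$median_months)), horizon)
    } else 0
    u <- params$utilities$mean
    ec <- effective_costs(params$costs)
    K <- loading_kernel(params)
    M <- params$monthly
    state <- 1L; alive <- TRUE; a <- age
    rows <- list()
    emit <- function(cycle, months, phase, utility, cost, injections) {
      rows[[length(rows) + 1L]] <<- tibble(
        cycle = cycle, months = months, phase = phase, state = state,
        alive = alive, utility_accrued = utility, cost_accrued = cost,
        injections = injections)
    }
    cyc <- 0L
    cycle_step <- function(months, phase, cost_if_alive, inj_if_alive,
                           transition) {
      cyc <<- cyc + 1L
      q <- cycle_death_prob(a, gender, params$mortality, months)
      died <- alive && runif(1) < q
      util <- 0
      if (died) {
        util <- if (strategy$half_cycle) u[state] * months / 24 else 0
        alive <<- FALSE
      }
      if (alive) {
        util <- u[state] * months / 12
        emit(cyc, months, phase, util, cost_if_alive, inj_if_alive)
        state <<- step_markov(state, transition, runif(1))
      } else {
        emit(cyc, months, phase, util, 0, 0)
      }
      a <<- a + months / 12
    }
    for (t in seq_len(d)) cycle_step(1, "untreated", 0, 0, diag(5))
    if (d < horizon) {
      L <- min(strategy$loading_months, horizon - d)
      if (strategy$arm == "delayed" && alive) {
        state <- step_markov(1L, rbind(params$reentry)[rep(1L, 5), ], runif(1))
      }
      cycle_step(L, "loading", L * ec$injection, L, K)
      for (t in seq_len(horizon - d - L)) {
        z <- runif(1) < ec$prn
        cycle_step(1, "prn", if (z) ec$injection else ec$monitoring,
                   as.numeric(z), M)
      }
    }
    traj <- purrr::list_rbind(rows)
    structure(
      mutate(traj, patient_gender = gender, starting_age = age,
             delay_months = d),
      class = c("patient_trajectory", class(traj)))
  })
}
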