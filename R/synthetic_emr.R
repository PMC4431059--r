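#' Default natural-history (fellow-eye) transition matrix
#'
#' The untreated fellow eye deteriorates faster than the treated eye. No
#' untreated matrix is published, so the packaged default is a synthetic
#' construction derived from the treated monthly matrix: the probability
#' of leaving the best state is doubled (split over worse states in the
#' treated row's proportions), and in every other row the recovery mass
#' (moves to better states) is halved, with the freed mass shifted onto
#' the worse-state entries proportionally. Rows are renormalised.
#'
#' @param treated Treated monthly matrix (defaults to the packaged one).
#' @return A 5x5 row-stochastic matrix.
#' @export
natural_history_matrix <- function(treated = amd_parameters()$monthly) {
  M <- treated
  out <- M
  # best state: exit mass doubled
  exit1 <- 1 - M[1, 1]
  out[1, 1] <- 1 - 2 * exit1
  out[1, 2:5] <- M[1, 2:5] * 2
  for (i in 2:5) {
    better <- seq_len(i - 1)
    worse <- if (i < 5) seq(i + 1, 5) else integer(0)
    freed <- sum(M[i, better]) / 2
    out[i, better] <- M[i, better] / 2
    if (length(worse)) {
      out[i, worse] <- M[i, worse] + freed * M[i, worse] / sum(M[i, worse])
    } else {
      out[i, i] <- M[i, i] + freed
    }
  }
  renormalize_matrix(out)
}

#' Synthetic-EMR generator configuration
#'
#' Describes the ground truth for a synthetic longitudinal visit table:
#' each patient contributes a treated eye, whose monthly acuity states
#' follow `treated_matrix` from the best state (injections at months 0-2,
#' then per-month with probability `injection_prob`), and a fellow
#' (untreated) eye following `fellow_matrix`. The time from the first
#' fellow-eye visit to the first visit below 6/12 (state 2 or worse) is
#' governed by `time_to_threshold`: family `"markov"` leaves it implied by
#' the fellow matrix's first row (a pure Markov chain), while
#' `"exponential"` overrides the first dwell in the best state with an
#' exponential time of the given median, so the Kaplan-Meier estimator can
#' be validated against a known curve.
#'
#' @param n_patients Number of patients (one treated + one fellow eye each).
#' @param treated_matrix,fellow_matrix Row-stochastic 5x5 monthly matrices.
#' @param time_to_threshold List: `family` (`"markov"` or `"exponential"`)
#'   and `median_months` (exponential only).
#' @param injection_prob Per-month PRN injection probability after loading.
#' @param n_months Follow-up per eye (visits at months 0..n_months).
#' @param loading_months Months of loading injections for treated eyes.
#' @param emit_letters If `TRUE`, add an ETDRS `letters` column (band
#'   midpoints) to exercise letter binning.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 500,
                             treated_matrix = amd_parameters()$monthly,
                             fellow_matrix = natural_history_matrix(),
                             time_to_threshold = list(family = "markov",
                                                      median_months = 6),
                             injection_prob = amd_parameters()$costs$prn_injection_rate,
                             n_months = 24,
                             loading_months = 3,
                             emit_letters = FALSE) {
  check_matrix <- function(m, what) {
    if (!is.matrix(m) || any(dim(m) != 5) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9)) {
      abort(sprintf("`%s` must be a row-stochastic 5x5 matrix.", what))
    }
  }
  check_matrix(treated_matrix, "treated_matrix")
  check_matrix(fellow_matrix, "fellow_matrix")
  if (!time_to_threshold$family %in% c("markov", "exponential")) {
    abort("time_to_threshold$family must be 'markov' or 'exponential'.")
  }
  if (injection_prob < 0 || injection_prob > 1) {
    abort("`injection_prob` must be a probability.")
  }
  structure(list(n_patients = n_patients, treated_matrix = treated_matrix,
                 fellow_matrix = fellow_matrix,
                 time_to_threshold = time_to_threshold,
                 injection_prob = injection_prob, n_months = n_months,
                 loading_months = loading_months,
                 emit_letters = emit_letters),
            class = "generator_config")
}

# Simulate monthly Markov state paths for n eyes (start may be a vector).
markov_paths <- function(n, n_months, P, start = 1L) {
  states <- matrix(0L, n, n_months + 1)
  states[, 1] <- start
  for (t in seq_len(n_months)) {
    states[, t + 1] <- step_markov(states[, t], P, runif(n))
  }
  states
}

#' Generate a synthetic longitudinal visit table
#'
#' Emits one row per eye per monthly visit in long format, mirroring the
#' structure of an anonymised treatment-register extract:
#' `patient_id`, `eye_role` (`"treated"`/`"fellow"`), `month_index`,
#' `va_state` (1-5), optionally `letters`, and `injected` (always `FALSE`
#' for fellow eyes). Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble of visit records.
#' @examples
#' visits <- generate_cohort(generator_config(n_patients = 20), seed = 1)
#' dplyr::count(visits, eye_role)
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_seed_if(seed, {
    n <- config$n_patients
    nm <- config$n_months

    treated <- markov_paths(n, nm, config$treated_matrix)
    inj <- matrix(runif(n * (nm + 1)) < config$injection_prob, n, nm + 1)
    inj[, seq_len(min(config$loading_months, nm + 1))] <- TRUE

    fellow <- markov_paths(n, nm, config$fellow_matrix)
    if (config$time_to_threshold$family == "exponential") {
      # override the first dwell in the best state: hold state 1 until an
      # exponential threshold time, then continue the chain from the state
      # the matrix's first row moves to (conditional on leaving)
      rate <- log(2) / config$time_to_threshold$median_months
      tthr <- ceiling(rexp(n, rate))
      exit_probs <- renormalize_row(config$fellow_matrix[1, 2:5])
      hit <- which(tthr <= nm)
      if (length(hit)) {
        s0 <- 1L + step_markov(rep(1L, length(hit)),
                               rbind(exit_probs)[rep(1L, 4), ],
                               runif(length(hit)))
        post <- markov_paths(length(hit), nm, config$fellow_matrix, start = s0)
        fellow[] <- 1L
        for (k in seq_along(hit)) {
          ti <- tthr[hit[k]]
          fellow[hit[k], (ti + 1):(nm + 1)] <- post[k, 1:(nm - ti + 1)]
        }
      } else {
        fellow[] <- 1L
      }
    }

    long <- function(states, role, injected) {
      tibble(
        patient_id = rep(seq_len(n), each = nm + 1),
        eye_role = role,
        month_index = rep(0:nm, times = n),
        va_state = as.integer(t(states)),
        injected = as.logical(t(injected))
      )
    }
    visits <- bind_rows(
      long(treated, "treated", inj),
      long(fellow, "fellow", matrix(FALSE, n, nm + 1))
    ) |> arrange(.data$patient_id, .data$eye_role, .data$month_index)
    if (config$emit_letters) {
      visits <- mutate(visits, letters = state_to_etdrs(.data$va_state),
                       .before = "injected")
    }
    visits
  })
}

#' Write / read visit tables as CSV
#'
#' Long-format CSV with the documented header
#' `patient_id,eye_role,month_index,va_state[,letters],injected`.
#'
#' @param visits Visit tibble from [generate_cohort()].
#' @param path CSV file path.
#' @return `path` (writer) or the visit tibble (reader).
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df) |>
    mutate(va_state = as.integer(.data$va_state),
           injected = as.logical(.data$injected))
}
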