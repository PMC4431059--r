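#' Visual-acuity health states
#'
#' The model's living states are five Snellen acuity bands in the better
#' seeing eye, ordered from best to worst; death is an additional
#' absorbing state handled by the mortality model.
#'
#' @return Tibble with columns `state` (1-5) and `label`.
#' @export
va_states <- function() {
  tibble(
    state = 1:5,
    label = c("6/6 to >6/12", "6/12 to 6/24", "6/24 to 6/60",
              "6/60 to 3/60", "<3/60")
  )
}

#' Bin ETDRS letter scores into model acuity states
#'
#' Letter cut points follow the usual conversion letters = 85 - 50 x logMAR,
#' so the band boundaries 6/12, 6/24, 6/60 and 3/60 map to 70, 55, 35 and
#' 20 letters.
#'
#' @param letters Integer ETDRS letter scores (0-100).
#' @return Integer state indices 1-5.
#' @export
etdrs_to_state <- function(letters) {
  if (any(letters < 0 | letters > 100, na.rm = TRUE)) {
    abort("ETDRS letter scores must lie in [0, 100].")
  }
  # >= 70 letters is band 1; >= 55 band 2; >= 35 band 3; >= 20 band 4
  5L - findInterval(letters, c(20, 35, 55, 70))
}

# Midpoint letter score for each state, used when the generator emits letters.
state_to_etdrs <- function(state) {
  c(78L, 62L, 45L, 27L, 10L)[state]
}

#' Load model parameters from a YAML configuration file
#'
#' Reads the base-case parameter file shipped with the package (transition
#' matrices, state utilities, unit costs, re-entry distribution,
#' demographics, mortality anchors, delay model) and validates it: every
#' transition row is renormalised and checked, utility means must be
#' strictly decreasing in state severity and lie in \[0, 1\], costs must be
#' non-negative, and gender proportions must sum to 1.
#'
#' @param path Path to a YAML file; defaults to the packaged base case.
#' @return A validated `amd_params` list.
#' @seealso [amd_parameters()]
#' @export
read_parameters <- function(path = system.file("extdata", "parameters.yaml",
                                               package = "namdcea")) {
  raw <- yaml::read_yaml(path)
  p <- structure(list(
    version = raw$version %||% "unversioned",
    states = va_states(),
    loading_row = renormalize_row(as.numeric(raw$transitions$loading_row)),
    monthly = renormalize_matrix(do.call(rbind, lapply(raw$transitions$monthly, as.numeric))),
    utilities = tibble(
      state = 1:5,
      label = va_states()$label,
      mean = as.numeric(raw$utilities$mean),
      sd = as.numeric(raw$utilities$sd)
    ),
    costs = list(
      drug_per_injection = raw$costs$drug_per_injection,
      assessment = raw$costs$assessment,
      monitoring = raw$costs$monitoring,
      prn_injection_rate = raw$costs$prn_injection_rate,
      drug_only = isTRUE(raw$costs$drug_only),
      sd_fraction = raw$costs$sd_fraction %||% 0.10
    ),
    reentry = renormalize_row(as.numeric(raw$reentry$probabilities)),
    demographics = tibble(
      gender = c("male", "female"),
      proportion = c(raw$demographics$male$proportion,
                     raw$demographics$female$proportion),
      age_mean = c(raw$demographics$male$age_mean, raw$demographics$female$age_mean),
      age_sd = c(raw$demographics$male$age_sd, raw$demographics$female$age_sd),
      age_min = c(raw$demographics$male$age_min, raw$demographics$female$age_min),
      age_max = c(raw$demographics$male$age_max, raw$demographics$female$age_max)
    ),
    mortality = gompertz_mortality(
      male_anchor = c(q65 = raw$mortality$male$q65, q85 = raw$mortality$male$q85),
      female_anchor = c(q65 = raw$mortality$female$q65, q85 = raw$mortality$female$q85),
      q_cap = raw$mortality$q_cap %||% 0.7,
      age_range = as.numeric(raw$mortality$age_range %||% c(55, 110))
    ),
    delay = list(
      family = raw$delay$family %||% "exponential",
      median_months = raw$delay$median_months %||% 6
    ),
    horizon_months = raw$horizon_months %||% 24,
    loading_months = raw$loading_months %||% 3,
    effective_n = raw$psa$effective_n %||% 100
  ), class = "amd_params")
  rownames(p$monthly) <- colnames(p$monthly) <- p$states$label
  validate_parameters(p)
}

#' Base-case model parameters
#'
#' Convenience wrapper returning the packaged base case; individual
#' components can be overridden by name.
#'
#' @param ... Named components of the parameter list to replace (e.g.
#'   `horizon_months = 60`).
#' @return A validated `amd_params` list.
#' @examples
#' p <- amd_parameters()
#' p$utilities
#' amd_parameters(horizon_months = 60)$horizon_months
#' @export
amd_parameters <- function(...) {
  p <- read_parameters()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      abort(paste0("Unknown parameter component(s): ",
                   paste(unknown, collapse = ", "), "."))
    }
    p[names(dots)] <- dots
    p <- validate_parameters(p)
  }
  p
}

#' Validate a parameter list
#'
#' @param p An `amd_params` list.
#' @return `p`, invisibly unchanged, or an error describing the violated
#'   invariant.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "amd_params"))
  check_row <- function(row, what) {
    if (length(row) != 5 || any(row < 0) || any(row > 1) ||
        abs(sum(row) - 1) > 1e-12) {
      abort(sprintf("%s is not a valid probability row over the 5 states.", what))
    }
  }
  check_row(p$loading_row, "Loading transition row")
  for (i in 1:5) check_row(p$monthly[i, ], sprintf("Monthly matrix row %d", i))
  check_row(p$reentry, "Re-entry distribution")
  u <- p$utilities$mean
  if (any(u < 0 | u > 1)) abort("Utility means must lie in [0, 1].")
  if (any(diff(u) >= 0)) {
    abort("Utility means must be strictly decreasing with worsening acuity.")
  }
  if (any(p$utilities$sd < 0)) abort("Utility SDs must be non-negative.")
  cc <- p$costs
  if (cc$drug_per_injection < 0 || cc$assessment < 0 || cc$monitoring < 0) {
    abort("Unit costs must be non-negative.")
  }
  if (cc$prn_injection_rate < 0 || cc$prn_injection_rate > 1) {
    abort("`prn_injection_rate` must be a monthly probability in [0, 1].")
  }
  if (abs(sum(p$demographics$proportion) - 1) > 1e-6) {
    abort("Gender proportions must sum to 1.")
  }
  if (p$horizon_months < p$loading_months) {
    abort("Horizon must be at least as long as the loading cycle.")
  }
  if (!p$delay$family %in% c("exponential")) {
    abort("Delay model family must be 'exponential'.")
  }
  if (p$delay$median_months <= 0) abort("Delay median must be positive.")
  invisible(p)
}

#' @export
print.amd_params <- function(x, ...) {
  cat("<amd_params> version", x$version, "\n")
  cat("  horizon:", x$horizon_months, "months; loading cycle:",
      x$loading_months, "months\n")
  cat("  costs (GBP): drug", x$costs$drug_per_injection, "| assessment",
      x$costs$assessment, "| monitoring", x$costs$monitoring,
      "| PRN rate", x$costs$prn_injection_rate, "/month\n")
  cat("  utilities:", paste(sprintf("%.2f", x$utilities$mean), collapse = " "), "\n")
  invisible(x)
}

#' Write a parameter list back to YAML
#'
#' Inverse of [read_parameters()]; round-trips the base case.
#'
#' @param p An `amd_params` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "amd_params"))
  dem <- function(g) {
    d <- p$demographics[p$demographics$gender == g, ]
    list(proportion = d$proportion, age_mean = d$age_mean, age_sd = d$age_sd,
         age_min = d$age_min, age_max = d$age_max)
  }
  raw <- list(
    version = p$version,
    states = list(labels = p$states$label),
    transitions = list(
      loading_row = as.numeric(p$loading_row),
      monthly = lapply(seq_len(5), function(i) as.numeric(p$monthly[i, ]))
    ),
    utilities = list(mean = p$utilities$mean, sd = p$utilities$sd),
    costs = list(
      drug_per_injection = p$costs$drug_per_injection,
      assessment = p$costs$assessment,
      monitoring = p$costs$monitoring,
      prn_injection_rate = p$costs$prn_injection_rate,
      drug_only = p$costs$drug_only,
      sd_fraction = p$costs$sd_fraction
    ),
    reentry = list(probabilities = as.numeric(p$reentry)),
    demographics = list(male = dem("male"), female = dem("female")),
    mortality = list(
      male = list(q65 = p$mortality$male["q65"][[1]], q85 = p$mortality$male["q85"][[1]]),
      female = list(q65 = p$mortality$female["q65"][[1]], q85 = p$mortality$female["q85"][[1]]),
      q_cap = p$mortality$q_cap,
      age_range = p$mortality$age_range
    ),
    delay = p$delay,
    horizon_months = p$horizon_months,
    loading_months = p$loading_months,
    psa = list(effective_n = p$effective_n)
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}
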