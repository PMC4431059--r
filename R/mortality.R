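#' Gender-specific Gompertz background-mortality model
#'
#' Annual death probability follows the Gompertz law
#' \eqn{q(a) = A e^{B a}} per gender, with \eqn{(A, B)} solved from two
#' anchor probabilities at ages 65 and 85. The packaged anchors reproduce
#' UK 2010-12 interim life table values; the probability is capped and the
#' age clamped to the supported range at the extremes of old age.
#'
#' @param male_anchor,female_anchor Named vectors `c(q65 =, q85 =)` of
#'   annual death probabilities.
#' @param q_cap Upper bound on the annual probability (default 0.7).
#' @param age_range Ages outside this range are clamped with a warning.
#' @return A `mortality_model` list.
#' @export
gompertz_mortality <- function(male_anchor = c(q65 = 0.0143, q85 = 0.0998),
                               female_anchor = c(q65 = 0.0087, q85 = 0.0726),
                               q_cap = 0.7,
                               age_range = c(55, 110)) {
  fit <- function(anchor) {
    if (any(anchor <= 0) || any(anchor >= 1)) {
      abort("Mortality anchors must be probabilities in (0, 1).")
    }
    B <- log(anchor[["q85"]] / anchor[["q65"]]) / 20
    A <- anchor[["q65"]] / exp(B * 65)
    c(anchor, A = A, B = B)
  }
  structure(list(
    male = fit(male_anchor),
    female = fit(female_anchor),
    q_cap = q_cap,
    age_range = age_range
  ), class = "mortality_model")
}

# Scale a mortality model's hazard (used by monotonicity checks).
scale_mortality <- function(mortality, factor) {
  mortality$male[["A"]] <- mortality$male[["A"]] * factor
  mortality$female[["A"]] <- mortality$female[["A"]] * factor
  mortality
}

#' Annual death probability by age and gender
#'
#' @param age Age(s) in years; values outside the model's supported range
#'   are clamped to the nearest boundary with a warning.
#' @param gender `"male"` or `"female"` (recycled against `age`).
#' @param mortality A `mortality_model`; defaults to the packaged anchors.
#' @return Annual death probabilities in \[0, 1\].
#' @export
annual_death_probability <- function(age, gender,
                                     mortality = gompertz_mortality()) {
  stopifnot(inherits(mortality, "mortality_model"))
  if (!all(gender %in% c("male", "female"))) {
    abort("`gender` must be 'male' or 'female'.")
  }
  rng <- mortality$age_range
  if (any(age < rng[1] | age > rng[2])) {
    warn(sprintf("Ages outside [%g, %g] clamped to the boundary.", rng[1], rng[2]))
    age <- pmin(pmax(age, rng[1]), rng[2])
  }
  A <- ifelse(gender == "male", mortality$male[["A"]], mortality$female[["A"]])
  B <- ifelse(gender == "male", mortality$male[["B"]], mortality$female[["B"]])
  unname(pmin(A * exp(B * age), mortality$q_cap))
}

# Engine-internal per-cycle probability: identical to
# monthly_death_probability but clamps ages silently (the clamp at the
# extreme of old age is expected on long horizons, not a user error).
cycle_death_prob <- function(age, gender, mortality, months) {
  rng <- mortality$age_range
  age <- pmin(pmax(age, rng[1]), rng[2])
  q <- suppressWarnings(annual_death_probability(age, gender, mortality))
  1 - (1 - q)^(months / 12)
}

#' Per-cycle death probability from an annual probability
#'
#' Converts the annual probability to the cycle length by constant hazard
#' within the year: \eqn{q_c = 1 - (1 - q)^{m/12}} for an `m`-month cycle.
#'
#' @inheritParams annual_death_probability
#' @param months Cycle length in months (default 1).
#' @return Per-cycle death probabilities.
#' @examples
#' monthly_death_probability(70, "female")
#' @export
monthly_death_probability <- function(age, gender,
                                      mortality = gompertz_mortality(),
                                      months = 1) {
  q <- annual_death_probability(age, gender, mortality)
  1 - (1 - q)^(months / 12)
}
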