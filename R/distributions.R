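#' Renormalise a transition-probability row
#'
#' Published transition rows often sum to 0.9999 or 1.0001 because the
#' entries are rounded for print. Dividing each entry by the row sum
#' restores row-stochasticity while preserving the printed ratios.
#'
#' @param row Numeric vector of non-negative probabilities with a positive
#'   sum.
#' @return Numeric vector of the same length summing to 1 (within 1e-12).
#' @examples
#' renormalize_row(c(0.8778, 0.1163, 0.0046, 0.0006, 0.0008))
#' @export
renormalize_row <- function(row) {
  if (!is.numeric(row) || anyNA(row)) {
    abort("`row` must be a numeric vector without missing values.")
  }
  if (any(row < 0)) abort("`row` must be non-negative.")
  s <- sum(row)
  if (s <= 0) abort("`row` sums to zero; cannot renormalise an all-zero row.")
  row / s
}

#' Renormalise every row of a transition matrix
#'
#' @param mat Numeric matrix of non-negative entries, no all-zero rows.
#' @return Row-stochastic matrix of the same dimensions.
#' @export
renormalize_matrix <- function(mat) {
  t(apply(mat, 1L, renormalize_row))
}

new_dist_spec <- function(family, ...) {
  structure(list(family = family, ...), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<dist_spec> ", x$family, ": ",
      paste(names(pars), vapply(pars, function(p) paste(signif(p, 6), collapse = ","),
                                character(1)), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Beta distribution parameters from a mean and standard deviation
#'
#' Method-of-moments fit used to propagate utility uncertainty in the
#' probabilistic sensitivity analysis: with
#' \eqn{\nu = m(1-m)/s^2 - 1}, the shape parameters are
#' \eqn{\alpha = m\nu} and \eqn{\beta = (1-m)\nu}.
#' An `sd` of zero yields a degenerate (point-mass) spec, used to collapse
#' the PSA onto the base case.
#'
#' @param mean Mean on the utility (0, 1) scale.
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return A `dist_spec` with family `"beta"` (`alpha`, `beta`) or
#'   `"degenerate"` when `sd = 0`.
#' @examples
#' beta_params_from_moments(0.89, 0.16)
#' @export
beta_params_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) abort("`mean` must lie strictly inside (0, 1).")
  if (sd < 0) abort("`sd` must be non-negative.")
  if (sd == 0) return(new_dist_spec("degenerate", value = mean))
  bound <- mean * (1 - mean)
  if (sd^2 >= bound) {
    abort(sprintf(
      "Infeasible beta moments: need sd^2 < mean*(1-mean) = %.6g, got sd^2 = %.6g.",
      bound, sd^2))
  }
  nu <- bound / sd^2 - 1
  new_dist_spec("beta", alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution parameters from a mean and standard deviation
#'
#' Moment matching for cost parameters: `shape = mean^2/sd^2`,
#' `scale = sd^2/mean`. Cost standard deviations are conventionally taken
#' as 10\% of the mean when unreported.
#'
#' @param mean Positive mean (GBP).
#' @param sd Positive standard deviation (GBP); zero gives a point mass.
#' @return A `dist_spec` with family `"gamma"` (`shape`, `scale`) or
#'   `"degenerate"`.
#' @examples
#' gamma_params_from_moments(742.17, 74.217)
#' @export
gamma_params_from_moments <- function(mean, sd) {
  if (mean <= 0) abort("`mean` must be positive.")
  if (sd < 0) abort("`sd` must be non-negative.")
  if (sd == 0) return(new_dist_spec("degenerate", value = mean))
  new_dist_spec("gamma", shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Dirichlet concentration vector for a transition row
#'
#' Scales a row-stochastic probability vector by a pseudo-count
#' `effective_n`, so the Dirichlet mean equals the row and the spread
#' shrinks as `effective_n` grows. Zero entries are floored at a tiny
#' pseudo-count to keep the distribution proper. `effective_n = Inf`
#' yields a degenerate spec (the row itself).
#'
#' @param row Row-stochastic numeric vector.
#' @param effective_n Positive pseudo-count controlling PSA spread
#'   (default 100).
#' @param floor Minimum pseudo-count per component (default 1e-6).
#' @return A `dist_spec` with family `"dirichlet"` (`alpha`) or
#'   `"degenerate"`.
#' @examples
#' dirichlet_alpha_from_row(c(0.2, 0.2, 0.2, 0.2, 0.2), effective_n = 5)
#' @export
dirichlet_alpha_from_row <- function(row, effective_n = 100, floor = 1e-6) {
  if (abs(sum(row) - 1) > 1e-8) abort("`row` must be row-stochastic.")
  if (is.na(effective_n) || effective_n <= 0) {
    abort("`effective_n` must be strictly positive.")
  }
  if (is.infinite(effective_n)) return(new_dist_spec("degenerate", value = row))
  new_dist_spec("dirichlet", alpha = pmax(row * effective_n, floor))
}

#' Draw from a fitted parameter distribution
#'
#' @param spec A `dist_spec` from one of the moment-matching constructors.
#' @param n Number of draws.
#' @return For beta/gamma/degenerate scalars, a numeric vector of length
#'   `n`; for dirichlet, an `n` x k matrix whose rows sum to 1.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    degenerate = if (length(spec$value) > 1) {
      matrix(spec$value, nrow = n, ncol = length(spec$value), byrow = TRUE)
    } else {
      rep(spec$value, n)
    },
    # clamp away from the endpoints: utilities must stay strictly in (0, 1)
    # even when a shape parameter below 1 lets rbeta round to the boundary
    beta = pmin(pmax(rbeta(n, spec$alpha, spec$beta), 1e-12), 1 - 1e-12),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    dirichlet = rdirichlet(n, spec$alpha),
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

# Dirichlet draws via normalised gamma variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
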