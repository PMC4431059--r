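# Independent brute-force product-limit estimator: S(t) over distinct
# event times, S(t) = prod_{t_j <= t} (1 - d_j / n_j).
brute_force_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (k in seq_along(ev_times)) {
    tk <- ev_times[k]
    n_k <- sum(time >= tk)
    d_k <- sum(time == tk & event == 1)
    s <- s * (1 - d_k / n_k)
    surv[k] <- s
  }
  tibble::tibble(time = ev_times, survival = surv)
}

# Build a long-format visit tibble from per-eye state sequences.
# `sequences` is a list of lists with fields patient_id, eye_role, states
# (month_index starts at 0), and optionally injected.
make_visits <- function(sequences) {
  purrr::map(sequences, function(s) {
    n <- length(s$states)
    tibble::tibble(
      patient_id = s$patient_id,
      eye_role = s$eye_role,
      month_index = seq_len(n) - 1L,
      va_state = as.integer(s$states),
      injected = s$injected %||% rep(FALSE, n)
    )
  }) |> purrr::list_rbind()
}

# Parameters with (numerically) zero background mortality.
params_no_mortality <- function(...) {
  p <- amd_parameters(...)
  p$mortality <- gompertz_mortality(
    male_anchor = c(q65 = 1e-15, q85 = 1e-15),
    female_anchor = c(q65 = 1e-15, q85 = 1e-15))
  p
}

`%||%` <- rlang::`%||%`
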