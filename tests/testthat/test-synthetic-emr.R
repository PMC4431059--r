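test_that("generated cohorts respect degenerate configurations", {
  cfg <- generator_config(n_patients = 30, treated_matrix = diag(5),
                          fellow_matrix = diag(5), injection_prob = 0,
                          n_months = 12)
  v <- generate_cohort(cfg, seed = 1)
  treated <- dplyr::filter(v, eye_role == "treated")
  # identity matrix: states constant over follow-up
  expect_true(all(treated$va_state == 1L))
  # injection probability 0: nothing after the loading months
  expect_true(all(!treated$injected[treated$month_index >= 3]))
  expect_true(all(treated$injected[treated$month_index < 3]))
  # fellow eyes are never injected
  expect_true(all(!v$injected[v$eye_role == "fellow"]))
})

test_that("cohorts are bitwise reproducible given a seed", {
  cfg <- generator_config(n_patients = 40)
  expect_identical(generate_cohort(cfg, seed = 7), generate_cohort(cfg, seed = 7))
  expect_false(identical(generate_cohort(cfg, seed = 7),
                         generate_cohort(cfg, seed = 8)))
  # month index strictly increasing within each eye
  v <- generate_cohort(cfg, seed = 7)
  gaps <- v |>
    dplyr::group_by(patient_id, eye_role) |>
    dplyr::summarise(ok = all(diff(month_index) > 0), .groups = "drop")
  expect_true(all(gaps$ok))
})

test_that("transition estimation matches hand counts on a tiny instance", {
  v <- make_visits(list(
    list(patient_id = 1, eye_role = "treated", states = c(1, 1, 2, 1))
  ))
  suppressWarnings(P <- estimate_transition_matrix(v, "treated"))
  expect_equal(unname(P[1, ]), c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(P[2, ]), c(1, 0, 0, 0, 0))
  # unobserved rows fall back to identity, with a warning naming them
  expect_warning(estimate_transition_matrix(v, "treated"), "identity row")
  expect_equal(unname(P[4, ]), c(0, 0, 0, 1, 0))
  # eyes constant in one state yield an identity row for that state
  v3 <- make_visits(list(
    list(patient_id = 1, eye_role = "treated", states = rep(3, 6)),
    list(patient_id = 2, eye_role = "treated", states = rep(3, 4))
  ))
  suppressWarnings(P3 <- estimate_transition_matrix(v3, "treated"))
  expect_equal(unname(P3[3, ]), c(0, 0, 1, 0, 0))
  expect_error(estimate_transition_matrix(v, "fellow"), "No consecutive")
})

test_that("transition estimation recovers the generating matrix", {
  p <- amd_parameters()
  cfg <- generator_config(n_patients = 3000)
  v <- generate_cohort(cfg, seed = 21)
  P <- estimate_transition_matrix(v, "treated")
  counts <- attr(P, "counts")
  inside <- 0L
  for (i in 1:5) {
    ci <- wilson_ci(counts[i, ], sum(counts[i, ]))
    inside <- inside + sum(p$monthly[i, ] >= ci$lower & p$monthly[i, ] <= ci$upper)
  }
  expect_gte(inside, 22)  # ~95% of the 25 entries
  expect_true(all(abs(P - p$monthly) < 0.05))
  # fellow eyes follow the natural-history matrix
  Pf <- estimate_transition_matrix(v, "fellow")
  expect_true(all(abs(Pf - natural_history_matrix()) < 0.05))
  # 3-month spacing estimates the 3-step kernel
  P3 <- estimate_transition_matrix(v, "treated", cycle_months = 3)
  M3 <- p$monthly %*% p$monthly %*% p$monthly
  expect_true(all(abs(P3 - M3) < 0.07))
})

test_that("Kaplan-Meier estimator matches hand computation and brute force", {
  # events at months 3 and 5, one censoring at 4
  v <- make_visits(list(
    list(patient_id = 1, eye_role = "fellow", states = c(1, 1, 1, 2)),
    list(patient_id = 2, eye_role = "fellow", states = c(1, 1, 1, 1, 1)),
    list(patient_id = 3, eye_role = "fellow", states = c(1, 1, 1, 1, 1, 2))
  ))
  km <- estimate_time_to_threshold(v)
  expect_equal(km$survival[km$time == 3], 2 / 3, tolerance = 1e-12)
  expect_equal(km$survival[km$time == 5], 0, tolerance = 1e-12)

  # brute-force product-limit agreement on random small instances
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(3:10, 1)
      time <- sample(1:8, n, replace = TRUE)
      event <- rbinom(n, 1, 0.7)
    })
    if (sum(event) == 0) next
    seqs <- lapply(seq_len(n), function(i) {
      # event: first state >= 2 at month time[i]; censored: last visit there
      st <- c(rep(1, time[i]), if (event[i] == 1) 2 else 1)
      list(patient_id = i, eye_role = "fellow", states = st)
    })
    km <- estimate_time_to_threshold(make_visits(seqs))
    bf <- brute_force_km(time, event)
    got <- km$survival[km$n_event > 0]
    expect_equal(got, bf$survival, tolerance = 1e-12)
  }
})

test_that("all-censored data give a flat curve; absent fellow eyes error", {
  v <- make_visits(list(
    list(patient_id = 1, eye_role = "fellow", states = rep(1, 6)),
    list(patient_id = 2, eye_role = "fellow", states = rep(1, 4))
  ))
  km <- estimate_time_to_threshold(v)
  expect_true(all(km$survival == 1))
  expect_true(is.na(attr(km, "median_months")))
  vt <- make_visits(list(
    list(patient_id = 1, eye_role = "treated", states = rep(1, 6))))
  expect_error(estimate_time_to_threshold(vt), "fellow")
})

test_that("KM median recovers a known exponential threshold time", {
  cfg <- generator_config(
    n_patients = 2000, n_months = 48,
    time_to_threshold = list(family = "exponential", median_months = 12))
  v <- generate_cohort(cfg, seed = 5)
  km <- estimate_time_to_threshold(v)
  expect_lte(abs(attr(km, "median_months") - 12), 1)
  # S non-increasing, within [0, 1]
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("injection rate is the post-loading injection fraction", {
  inj <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
           TRUE, FALSE, FALSE, FALSE)  # 4 of the 10 post-loading months
  v <- make_visits(list(
    list(patient_id = 1, eye_role = "treated", states = rep(1, 13),
         injected = inj)))
  expect_equal(estimate_injection_rate(v), 0.4)
  v0 <- make_visits(list(
    list(patient_id = 1, eye_role = "treated", states = rep(1, 13))))
  expect_equal(estimate_injection_rate(v0), 0)
  expect_error(estimate_injection_rate(dplyr::filter(v, month_index < 3)),
               "post-loading")
  # recovery at scale
  cfg <- generator_config(n_patients = 2000, injection_prob = 0.3)
  rate <- estimate_injection_rate(generate_cohort(cfg, seed = 3))
  expect_lte(abs(rate - 0.3), 0.02)
})

test_that("letter emission is consistent with the state binning", {
  cfg <- generator_config(n_patients = 10, emit_letters = TRUE)
  v <- generate_cohort(cfg, seed = 2)
  expect_true("letters" %in% names(v))
  expect_equal(etdrs_to_state(v$letters), v$va_state)
})

test_that("visit tables round-trip through CSV", {
  v <- generate_cohort(generator_config(n_patients = 5), seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_visits(v, tmp)
  v2 <- read_visits(tmp)
  expect_equal(as.data.frame(v2), as.data.frame(v))
})

test_that("the default natural-history matrix deteriorates faster", {
  M <- amd_parameters()$monthly
  N <- natural_history_matrix()
  expect_equal(unname(rowSums(N)), rep(1, 5), tolerance = 1e-12)
  # leaving the best state is about twice as likely untreated
  expect_equal((1 - N[1, 1]) / (1 - M[1, 1]), 2, tolerance = 1e-6)
  # recovery (moving to better states) never increases
  for (i in 2:5) {
    expect_lte(sum(N[i, 1:(i - 1)]), sum(M[i, 1:(i - 1)]) + 1e-12)
  }
})
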