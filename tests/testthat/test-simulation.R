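test_that("identity dynamics with no mortality give the closed-form QALYs", {
  p <- params_no_mortality()
  p$monthly <- diag(5)
  p$loading_row <- c(1, 0, 0, 0, 0)
  st <- strategy_config("immediate", horizon_months = 24)
  # 24 months in the best state: 0.89 * 2 years
  expect_equal(glance(cohort_expectation(st, p))$mean_qaly, 1.78,
               tolerance = 1e-9)
  mc <- run_arm(st, p, n_patients = 20, seed = 1)
  expect_equal(tidy(mc)$qaly, rep(1.78, 20), tolerance = 1e-9)
  # everyone survives, so everyone gets the three loading injections
  expect_true(all(tidy(mc)$injections >= 3))
})

test_that("a two-state toy matches hand matrix propagation", {
  # stay 0.9 / move 0.1 to a (near) zero-utility absorbing band;
  # one loading month + one monthly cycle, occupancies 1 then 0.9
  p <- params_no_mortality()
  p$utilities$mean <- c(1, 4e-9, 3e-9, 2e-9, 1e-9)
  row <- c(0.9, 0.1, 0, 0, 0)
  p$monthly <- rbind(row, c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0),
                     c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))
  p$loading_row <- row
  st <- strategy_config("immediate", horizon_months = 2, loading_months = 1)
  expect_equal(glance(cohort_expectation(st, p))$mean_qaly, (1 + 0.9) / 12,
               tolerance = 1e-6)
})

test_that("trajectories are reproducible and structurally sound", {
  p <- amd_parameters()
  st <- strategy_config("immediate")
  expect_identical(glance(run_arm(st, p, 300, seed = 4)),
                   glance(run_arm(st, p, 300, seed = 4)))
  t1 <- simulate_patient(st, p, seed = 11)
  t2 <- simulate_patient(st, p, seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # cycle months sum to the horizon; dead cycles accrue nothing
  expect_equal(sum(t1$months), 24)
  dead <- !t1$alive
  expect_true(all(t1$cost_accrued[dead] == 0))
  expect_true(all(t1$injections[dead] == 0))
  # QALY accrual identity: sum of u(state) * months/12 over alive cycles
  u <- p$utilities$mean
  expect_equal(sum(t1$utility_accrued),
               sum((u[t1$state] * t1$months / 12)[t1$alive]), tolerance = 1e-12)
})

test_that("occupancy mass plus cumulative deaths is conserved every cycle", {
  p <- amd_parameters()
  for (case in list(list(arm = "immediate", delay = 0),
                    list(arm = "delayed", delay = 5))) {
    tr <- cohort_trace(strategy_config(case$arm), p, gender = "female",
                       age = 80, delay = case$delay)
    tot <- purrr::map_dbl(tr$occupancy, sum) + tr$cum_dead
    expect_equal(tot, rep(1, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("microsimulation agrees with the cohort expectation oracle", {
  p <- amd_parameters()
  for (arm in c("immediate", "delayed")) {
    st <- strategy_config(arm)
    ex <- glance(cohort_expectation(st, p))
    mc <- glance(run_arm(st, p, 4000, seed = 17))
    expect_lte(abs(mc$mean_qaly - ex$mean_qaly), 3 * mc$se_qaly)
    expect_lte(abs(mc$mean_cost - ex$mean_cost), 3 * mc$se_cost)
  }
})

test_that("QALYs fall monotonically as mortality scales up", {
  p <- amd_parameters()
  st <- strategy_config("immediate")
  q <- purrr::map_dbl(c(0.5, 1, 2, 4), function(f) {
    p$mortality <- namdcea:::scale_mortality(amd_parameters()$mortality, f)
    glance(cohort_expectation(st, p))$mean_qaly
  })
  expect_true(all(diff(q) < 0))
})

test_that("immediate treatment dominates the delayed arm on QALYs", {
  p <- amd_parameters()
  qi <- glance(cohort_expectation(strategy_config("immediate"), p))$mean_qaly
  qd <- glance(cohort_expectation(strategy_config("delayed"), p))$mean_qaly
  expect_gt(qi, qd)
})

test_that("no patient exceeds the utility-ceiling QALY bound", {
  p <- amd_parameters()
  for (arm in c("immediate", "delayed")) {
    mc <- run_arm(strategy_config(arm), p, 2000, seed = 23)
    expect_lte(max(tidy(mc)$qaly), 0.89 * 2 + 1e-12)
    expect_gte(min(tidy(mc)$qaly), 0)
  }
})

test_that("the delayed arm costs nothing until treatment starts", {
  p <- amd_parameters()
  mc <- run_arm(strategy_config("delayed"), p, 1500, seed = 31)
  pts <- tidy(mc)
  expect_true(all(pts$delay_months >= 1))
  never <- pts$delay_months >= 24
  expect_gt(sum(never), 0)
  expect_true(all(pts$cost[never] == 0))
  expect_true(all(pts$injections[never] == 0))
  # per-patient mean injections lower than immediate under the same seed
  mi <- run_arm(strategy_config("immediate"), p, 1500, seed = 31)
  expect_gt(glance(mi)$mean_injections, glance(mc)$mean_injections)
})

test_that("short horizons truncate the loading cycle gracefully", {
  p <- amd_parameters()
  st <- strategy_config("delayed", horizon_months = 4)
  mc <- run_arm(st, p, 200, seed = 2)
  expect_equal(glance(mc)$n, 200)
  ex <- glance(cohort_expectation(st, p))
  expect_true(ex$mean_qaly > 0 && ex$mean_qaly <= 0.89 * 4 / 12 + 1e-12)
})

test_that("the half-cycle correction adds the dying half-cycle", {
  p <- amd_parameters()
  q0 <- glance(cohort_expectation(strategy_config("immediate"), p))$mean_qaly
  q1 <- glance(cohort_expectation(
    strategy_config("immediate", half_cycle = TRUE), p))$mean_qaly
  expect_gt(q1, q0)
  expect_lt(q1 - q0, 0.02)
})

test_that("n_patients = 1 reduces run_arm to a single trajectory", {
  p <- amd_parameters()
  mc <- run_arm(strategy_config("immediate"), p, 1, seed = 3)
  g <- glance(mc)
  pt <- tidy(mc)
  expect_equal(g$mean_qaly, pt$qaly)
  expect_equal(g$mean_cost, pt$cost)
  # zero-cost schedule gives zero mean cost
  pz <- amd_parameters()
  pz$costs$drug_per_injection <- 0
  pz$costs$assessment <- 0
  pz$costs$monitoring <- 0
  expect_equal(glance(run_arm(strategy_config("immediate"), pz, 50,
                              seed = 3))$mean_cost, 0)
})
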