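test_that("ICER quadrant logic is exhaustively correct", {
  grid <- expand.grid(dc = c(-1, 0, 1), de = c(-1, 0, 1))
  out <- icer(grid$dc, grid$de)
  expected <- character(9)
  for (k in seq_len(9)) {
    dc <- grid$dc[k]; de <- grid$de[k]
    expected[k] <-
      if (de == 0) "undefined"
      else if (de > 0 && dc <= 0) "dominant"
      else if (de < 0 && dc >= 0) "dominated"
      else if (de < 0 && dc < 0) "sw_ratio"
      else "icer"
  }
  expect_equal(out$decision, expected)
  expect_equal(out$icer[out$decision == "icer"], 1)       # (1, 1)
  expect_equal(out$icer[out$decision == "sw_ratio"], 1)   # (-1, -1)
  expect_true(all(is.na(out$icer[out$decision %in%
                                   c("dominant", "dominated", "undefined")])))
})

test_that("central increments reproduce the headline arithmetic", {
  out <- icer(1009.58, 0.24)
  expect_equal(out$icer, 4206.583, tolerance = 1e-3)
  expect_equal(out$decision, "icer")
  expect_equal(net_monetary_benefit(1009.58, 0.24, 20000), 3790.42,
               tolerance = 1e-9)
  expect_equal(net_monetary_benefit(0, 0, 35000), 0)
  # threshold identity: NMB vanishes at lambda = ICER
  expect_equal(net_monetary_benefit(1009.58, 0.24, 1009.58 / 0.24), 0,
               tolerance = 1e-9)
})

test_that("NMB is linear in the willingness to pay", {
  withr::with_seed(5, {
    dc <- rnorm(20, 500, 300); de <- rnorm(20, 0.2, 0.1)
  })
  l1 <- 8000; l2 <- 31000; w <- 0.3
  expect_equal(net_monetary_benefit(dc, de, w * l1 + (1 - w) * l2),
               w * net_monetary_benefit(dc, de, l1) +
                 (1 - w) * net_monetary_benefit(dc, de, l2),
               tolerance = 1e-9)
  expect_error(net_monetary_benefit(1, 1, -5), "non-negative")
})

test_that("scenario driver reproduces the one-way sensitivity structure", {
  p <- amd_parameters()
  scen <- list(
    scenario_spec("drug only", drug_only = TRUE),
    scenario_spec("horizon copy", horizon_months = 24),
    scenario_spec("5-year horizon", horizon_months = 60),
    scenario_spec("starting age 60", fixed_age = 60)
  )
  tab <- run_scenarios(scen, p, engine = "expectation")
  base <- tab[tab$scenario == "base case", ]

  # pure cost scenario: QALY columns identical to the base case
  drug <- tab[tab$scenario == "drug only", ]
  expect_equal(drug$comparator_qaly, base$comparator_qaly, tolerance = 1e-12)
  expect_equal(drug$intervention_qaly, base$intervention_qaly, tolerance = 1e-12)
  expect_lt(drug$delta_cost, base$delta_cost)
  expect_lt(drug$icer, base$icer)

  # a no-op override duplicates the base case exactly
  copy <- tab[tab$scenario == "horizon copy", ]
  expect_equal(as.data.frame(copy[-c(1, ncol(copy))]),
               as.data.frame(base[-c(1, ncol(base))]), tolerance = 1e-12)
  expect_equal(copy$icer_change_pct, 0)

  # longer horizon accumulates more QALYs and lowers the ICER
  long <- tab[tab$scenario == "5-year horizon", ]
  expect_gt(long$intervention_qaly, base$intervention_qaly)
  expect_lt(long$icer, base$icer)

  # younger cohort: less mortality, more intervention QALYs
  young <- tab[tab$scenario == "starting age 60", ]
  expect_gt(young$intervention_qaly, base$intervention_qaly)

  # percent changes are integers relative to the base ICER
  expect_true(all(tab$icer_change_pct[-1] == round(tab$icer_change_pct[-1])))
  expect_error(scenario_spec("bad", discount_rate = 0.035), "unused argument")
  expect_error(scenario_spec("bad", utilities = c(2, 1, 1, 1, 1)), "5 values")
})

test_that("common random numbers hold QALYs fixed across cost scenarios", {
  p <- amd_parameters()
  tab <- run_scenarios(list(scenario_spec("drug only", drug_only = TRUE)),
                       p, n_patients = 300, seed = 9, engine = "micro")
  expect_equal(tab$comparator_qaly[1], tab$comparator_qaly[2], tolerance = 1e-12)
  expect_equal(tab$intervention_qaly[1], tab$intervention_qaly[2],
               tolerance = 1e-12)
})

test_that("an alternative utility table changes QALYs but not costs", {
  p <- amd_parameters()
  sg <- c(0.92, 0.84, 0.66, 0.59, 0.47)  # illustrative alternative values
  tab <- run_scenarios(list(scenario_spec("alt utilities", utilities = sg)),
                       p, engine = "expectation")
  expect_equal(tab$intervention_cost[1], tab$intervention_cost[2],
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(tab$intervention_qaly[1],
                                tab$intervention_qaly[2])))
})
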