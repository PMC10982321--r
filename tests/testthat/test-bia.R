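test_that("funnel stages round half up and reproduce the printed counts", {
  expect_equal(
    unname(build_funnel(funnel_spec(245771, c(ra = 0.12, elig = 0.60)))),
    c(29493L, 17696L))
  expect_equal(
    unname(build_funnel(funnel_spec(0, c(ra = 0.12, elig = 0.60)))),
    c(0L, 0L))
  expect_equal(
    unname(build_funnel(funnel_spec(1e6, c(ra = 0.12, elig = 0.60)))),
    c(120000L, 72000L))
  # half-up, not half-even: 5 * 0.5 = 2.5 -> 3
  expect_equal(unname(build_funnel(funnel_spec(5, c(s = 0.5)))), 3L)
})

test_that("market trajectory is linear, complementary and bounded", {
  expect_equal(market_trajectory(market_mix_spec(0.015, 0.0035, 5)),
               c(0.015, 0.0185, 0.022, 0.0255, 0.029))
  expect_equal(market_trajectory(market_mix_spec(0.01, 0, 5)), rep(0.01, 5))
  # device + comparator shares always sum to exactly 1
  sh <- market_trajectory(market_mix_spec(0.123, 0.017, 9))
  expect_identical(sh + (1 - sh), rep(1, 9))
  expect_error(market_trajectory(market_mix_spec(0.9, 0.05, 5)), "\\[0, 1\\]")
})

test_that("per-patient annual costs match the term-by-term oracle", {
  p <- base_params()
  # independent hand-summed oracles from the unit costs, rates and drug mix
  soc_oracle <- 3.4 * 1870 + 0.2 * 193 + 1 * 2142 + 2.1 * 88.06 +
    0.3 * 6434 + 386.4377
  red_y1_oracle <- 7000 + 1 * 1870 + 0.1 * 193 + 0.2 * 2142 + 0.7 * 88.06 +
    0.1 * 6434 + 386.4377
  expect_equal(per_patient_annual_cost("soc", 1, p$costs, p$hru, p$drugs),
               soc_oracle, tolerance = 1e-10)
  expect_equal(soc_oracle, 11040.17, tolerance = 1e-5)
  expect_equal(per_patient_annual_cost("reducer", 1, p$costs, p$hru, p$drugs),
               red_y1_oracle, tolerance = 1e-10)
  expect_equal(red_y1_oracle, 10409.18, tolerance = 1e-6)
  # later years drop only the implant
  expect_equal(
    per_patient_annual_cost("reducer", 2, p$costs, p$hru, p$drugs),
    red_y1_oracle - 7000, tolerance = 1e-10)
  # all-zero rates and no drugs cost nothing
  zero <- hru_profile(
    reducer = c(hospitalizations = 0, ed_admissions = 0, coronarographies = 0,
                outpatient_visits = 0, pci = 0),
    soc = c(hospitalizations = 0, ed_admissions = 0, coronarographies = 0,
            outpatient_visits = 0, pci = 0))
  no_drugs <- tibble::tibble(name = character(), annual_cost = numeric(),
                             usage_rate = numeric())
  expect_identical(
    per_patient_annual_cost("soc", 1, p$costs, zero, no_drugs), 0)
  # drug reduction only touches the reducer arm
  expect_equal(
    per_patient_annual_cost("soc", 1, p$costs, p$hru, p$drugs, 0.5),
    per_patient_annual_cost("soc", 1, p$costs, p$hru, p$drugs))
})

test_that("a single 100% SoC patient costs exactly the per-patient rate", {
  p <- single_patient_params()
  p$horizon_years <- 1L
  mix <- market_mix_spec(0, 0, 1)
  s <- run_scenario(p, mix)
  expect_equal(s$total,
               per_patient_annual_cost("soc", 1, p$costs, p$hru, p$drugs))
  expect_equal(s$n_reducer + s$n_soc, 1)
})

test_that("identical market mixes give a zero differential everywhere", {
  p <- base_params()
  p$revised_mix <- p$current_mix
  r <- differential_budget_impact(p)
  expect_equal(r$differential$differential, rep(0, 5))
  expect_equal(r$cumulative_differential, 0)
  for (d in c("hospitalizations", "ed_admissions", "coronarographies",
              "outpatient_visits", "pci")) {
    expect_equal(r$avoided_hru[[d]], rep(0, 5))
  }
})

test_that("scaling the eligible population scales every output linearly", {
  p <- base_params()
  p2 <- p
  p2$funnel <- funnel_spec(p$funnel$base_population * 2, p$funnel$stages)
  r1 <- differential_budget_impact(p)
  r2 <- differential_budget_impact(p2)
  k <- eligible_population(p2) / eligible_population(p)
  expect_equal(r2$totals, k * r1$totals, tolerance = 1e-12)
  expect_equal(r2$cumulative_differential, k * r1$cumulative_differential,
               tolerance = 1e-12)
  expect_equal(r2$scenario1$hospitalizations,
               k * r1$scenario1$hospitalizations, tolerance = 1e-12)
})

test_that("average annual impact times horizon equals the total exactly", {
  r <- differential_budget_impact(base_params())
  expect_identical(unname(r$average_annual * r$horizon_years),
                   unname(r$totals))
})

test_that("yearly differential decreases in the uptake increment after year 1", {
  # with SoC costlier per patient-year than the implanted steady state, a
  # faster-rising share saves more each year from year 2 onward
  p <- base_params()
  base_diff <- differential_budget_impact(p)$differential$differential
  p2 <- set_param(p, "revised_mix.annual_increment", 0.007)
  fast_diff <- differential_budget_impact(p2)$differential$differential
  expect_true(all(fast_diff[2:5] < base_diff[2:5]))
})

test_that("avoided event counts are non-negative when uptake rises", {
  r <- differential_budget_impact(base_params())
  for (d in c("hospitalizations", "ed_admissions", "coronarographies",
              "outpatient_visits", "pci")) {
    expect_true(all(r$avoided_hru[[d]] >= 0))
  }
})

test_that("responder fraction moves the budget impact", {
  p <- base_params()
  full <- set_param(p, "tree.p_success", 1)
  none <- set_param(p, "tree.p_success", 0)
  d_full <- differential_budget_impact(full)$cumulative_differential
  d_none <- differential_budget_impact(none)$cumulative_differential
  # with no responders the implanted patients keep SoC resource use, so the
  # revised scenario only adds implant costs
  expect_gt(d_none, 0)
  expect_lt(d_full, d_none)
})

test_that("mortality and incidence reshape the eligible pool", {
  p <- base_params()
  p$annual_mortality <- 0.1
  p$annual_incident_eligible <- 500
  s <- run_scenario(p, p$current_mix)
  pool <- s$n_reducer + s$n_soc
  expect_equal(pool[2], pool[1] * 0.9 + 500)
  expect_equal(pool[3], pool[2] * 0.9 + 500)
})
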