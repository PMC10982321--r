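test_that("tornado entries equal brute-force full-model recomputation", {
  p <- base_params()
  p$annual_mortality <- 0.02   # give the mortality lever a non-zero base
  reg <- dsa_parameter_registry()

  for (target in c("bia_differential", "cua_icer")) {
    tor <- one_way_dsa(p, target, delta = 0.15)
    outcome <- if (target == "bia_differential") {
      function(q) differential_budget_impact(q)$cumulative_differential
    } else {
      function(q) {
        r <- cua_over_horizons(q, horizons = q$horizon_years)
        r$delta_cost / r$delta_qaly
      }
    }
    for (i in seq_len(nrow(tor))) {
      e <- reg[[tor$parameter[i]]]
      lo <- e$set(p, tor$low_value[i])
      hi <- e$set(p, tor$high_value[i])
      expect_identical(tor$low_outcome[i], outcome(lo))
      expect_identical(tor$high_outcome[i], outcome(hi))
    }
    # sorted by descending swing, swing = |high - low|
    expect_identical(tor$swing, abs(tor$high_outcome - tor$low_outcome))
    expect_true(all(diff(tor$swing) <= 0))
  }
})

test_that("parameters without influence on the target have zero swing", {
  p <- base_params()
  # the decision tree uses registry-derived annual costs, not the SoC event
  # rates, so an event rate cannot move the cost-utility ratio
  tor <- one_way_dsa(p, "cua_icer", parameters = "soc_hospitalization_rate")
  expect_equal(tor$swing, 0)
  # an outcome linear in the parameter is symmetric about the base
  tor2 <- one_way_dsa(p, "bia_differential",
                      parameters = "soc_hospitalization_rate")
  expect_equal(tor2$high_outcome - tor2$base_outcome,
               tor2$base_outcome - tor2$low_outcome, tolerance = 1e-9)
})

test_that("probabilities perturbed beyond their bounds are clamped", {
  p <- base_params()  # p_success 0.9451; +15% would exceed 1
  tor <- one_way_dsa(p, "cua_icer", parameters = "responder_fraction")
  expect_identical(tor$high_value, 1)
  expect_equal(tor$low_value, 0.9451 * 0.85)
  expect_error(one_way_dsa(p, "cua_icer", parameters = "no_such"), "no_such")
})

test_that("distributions are built by the method of moments", {
  d <- build_distribution(0.594, 0.15, "beta")
  # independent check: the implied beta mean and variance equal the moments
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.594)
  expect_equal(d$shape1 * d$shape2 /
                 ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1)),
               (0.15 * 0.594)^2)
  expect_equal(d$shape1, 17.45, tolerance = 1e-4)
  expect_equal(d$shape2, 11.9274, tolerance = 1e-4)

  n <- build_distribution(3.4, 0.15, "normal")
  expect_equal(n$sd, 0.51)

  pt <- build_distribution(3.4, 0, "normal")
  expect_identical(pt$family, "fixed")
  expect_identical(draw_from_distribution(pt, 3), rep(3.4, 3))

  expect_error(build_distribution(1.2, 0.15, "beta"), "\\(0, 1\\)")
  # infeasible moments: variance >= m(1-m)
  expect_error(build_distribution(0.5, 1.1, "beta"), "infeasible")
})

test_that("draw supports respect the family constraints", {
  set.seed(11)
  b <- draw_from_distribution(build_distribution(0.594, 0.15, "beta"), 5000)
  expect_true(all(b > 0 & b < 1))
  expect_equal(mean(b), 0.594, tolerance = 0.01)

  # heavy truncation: normal with mean close to zero still never negative
  tn <- draw_from_distribution(build_distribution(0.1, 2, "normal"), 5000)
  expect_true(all(tn >= 0))
})

test_that("PSA collapses to the deterministic base case at zero uncertainty", {
  p <- base_params()
  det <- cua_over_horizons(p, horizons = 5)
  psa <- run_psa(p, n_draws = 8, seed = 1, relative_sd = 0)
  expect_equal(psa$draws$delta_cost, rep(det$delta_cost, 8))
  expect_equal(psa$draws$delta_qaly, rep(det$delta_qaly, 8))
})

test_that("a fixed seed reproduces the PSA bit-exactly", {
  p <- base_params()
  a <- run_psa(p, n_draws = 50, seed = 7)
  b <- run_psa(p, n_draws = 50, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary$ceac, b$summary$ceac)
  c2 <- run_psa(p, n_draws = 50, seed = 8)
  expect_false(identical(a$draws$delta_cost, c2$draws$delta_cost))
})

test_that("PSA quadrants are consistent with the increment signs", {
  p <- base_params()
  psa <- run_psa(p, n_draws = 300, seed = 21)
  d <- psa$draws
  expect_true(all(d$quadrant[d$delta_qaly > 0 & d$delta_cost > 0] == "NE"))
  expect_true(all(d$quadrant[d$delta_qaly > 0 & d$delta_cost <= 0] == "SE"))
  expect_true(all(d$quadrant[d$delta_qaly <= 0 & d$delta_cost > 0] == "NW"))
  expect_equal(psa$summary$proportion_dominant, mean(d$quadrant == "SE"))
  # base case is strongly dominant at 5 years; the cloud should mostly sit
  # in the dominance region
  expect_gt(psa$summary$proportion_dominant, 0.5)
})

test_that("CEAC starts at the cost-saving fraction and is monotone", {
  p <- base_params()
  psa <- run_psa(p, n_draws = 400, seed = 3)
  ceac <- psa$summary$ceac
  expect_equal(ceac$probability_cost_effective[ceac$wtp == 0],
               mean(psa$draws$delta_cost <= 0))
  if (all(psa$draws$delta_qaly > 0)) {
    expect_true(all(diff(ceac$probability_cost_effective) >= 0))
  }
  expect_true(all(ceac$probability_cost_effective >= 0 &
                    ceac$probability_cost_effective <= 1))
})

test_that("PSA means agree with the deterministic base case (MC consistency)", {
  p <- base_params()
  psa <- run_psa(p, n_draws = 4000, seed = 5)
  det <- cua_over_horizons(p, horizons = 5)
  se_q <- stats::sd(psa$draws$delta_qaly) / sqrt(psa$summary$n_draws)
  se_c <- stats::sd(psa$draws$delta_cost) / sqrt(psa$summary$n_draws)
  expect_lt(abs(psa$summary$mean_delta_qaly - det$delta_qaly), 3 * se_q)
  expect_lt(abs(psa$summary$mean_delta_cost - det$delta_cost), 3 * se_c)
})
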