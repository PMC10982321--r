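# Budget impact engine: patient funnel, market-share trajectories, per-patient
# annual costs, scenario runs and the differential analysis between the
# current and the revised market mix.

#' Build the patient eligibility funnel
#'
#' Applies each stage proportion to the previous stage's count, rounding half
#' up to whole patients at every stage.
#'
#' @param spec A [funnel_spec()].
#' @return Named integer vector of stage counts (the base population is not
#'   repeated).
#' @examples
#' build_funnel(funnel_spec(245771, c(refractory = 0.12, eligible = 0.60)))
#' @export
build_funnel <- function(spec) {
  prev <- as.numeric(spec$base_population)
  counts <- numeric(length(spec$stages))
  for (i in seq_along(spec$stages)) {
    prev <- round_half_up(prev * spec$stages[[i]])
    counts[i] <- prev
  }
  stats::setNames(as.integer(counts), names(spec$stages))
}

#' Eligible population at the bottom of the funnel
#'
#' @param params An `rha_parameter_set`.
#' @return Integer count of treatment-eligible patients.
#' @export
eligible_population <- function(params) {
  unname(build_funnel(params$funnel)[length(params$funnel$stages)])
}

#' Device-share trajectory of a market mix
#'
#' Linear uptake: `share(y) = share(1) + (y - 1) * increment`, kept at full
#' precision. The comparator share is exactly `1 - share(y)`.
#'
#' @param spec A [market_mix_spec()].
#' @param years Number of years (defaults to the spec's own).
#' @return Numeric vector of device shares (fractions).
#' @export
market_trajectory <- function(spec, years = spec$years) {
  shares <- spec$device_share_year1 +
    (seq_len(years) - 1) * spec$annual_increment
  if (any(shares < 0 | shares > 1)) {
    stop("market trajectory leaves [0, 1]: share(",
         which(shares < 0 | shares > 1)[1], ") = ",
         signif(shares[which(shares < 0 | shares > 1)[1]], 4), call. = FALSE)
  }
  shares
}

#' Per-patient annual cost of an arm
#'
#' Sum over cost drivers of annual event rate times unit cost, plus the
#' usage-weighted drug-therapy cost (reduced by `drug_reduction` in the
#' implant arm), plus the implant cost if and only if the arm is `"reducer"`
#' and `year_in_arm == 1`.
#'
#' @param arm `"reducer"` or `"soc"`.
#' @param year_in_arm 1-based year since the patient entered the arm; only
#'   the first year differs (implant cost).
#' @param costs A [unit_costs()].
#' @param hru An [hru_profile()] (both arms; the arm's rates are selected).
#' @param drugs Drug-mix data frame (see [parameter_set()]).
#' @param drug_reduction Therapy-reduction fraction for the implant arm.
#' @return EUR per patient for that year.
#' @export
per_patient_annual_cost <- function(arm = c("reducer", "soc"), year_in_arm,
                                    costs, hru, drugs, drug_reduction = 0) {
  arm <- match.arg(arm)
  r <- hru[[arm]]
  driver_cost <- r$hospitalizations * costs$hospitalization +
    r$ed_admissions * costs$ed_admission +
    r$coronarographies * costs$coronarography +
    r$outpatient_visits * costs$outpatient_visit +
    r$pci * costs$elective_pci
  drug_cost <- weighted_drug_cost(
    drugs, reduction = if (arm == "reducer") drug_reduction else 0)
  implant <- if (arm == "reducer" && year_in_arm == 1) costs$reducer_implant else 0
  driver_cost + drug_cost + implant
}

#' Run one market scenario of the budget impact model
#'
#' The eligible pool starts at the bottom of the funnel and evolves by the
#' configured annual mortality and incident inflow (both zero in the base
#' case, i.e. a constant prevalent pool). Arm headcounts follow the market
#' trajectory; patients newly captured by a rising device share are new
#' implants that year and pay the implant cost once. Implanted patients'
#' recurring costs and event counts are the responder mixture
#' `p_success * reducer-profile + (1 - p_success) * SoC-profile`
#' (non-responders revert to standard-of-care resource use; responders get
#' any configured drug-therapy reduction).
#'
#' @param params An `rha_parameter_set`.
#' @param mix A [market_mix_spec()] (one of `params$current_mix` /
#'   `params$revised_mix`, or any other).
#' @param discounted Budget impact is undiscounted by default, as is standard
#'   for affordability analyses; set `TRUE` to apply the cost discount.
#' @return A tibble with one row per year: headcounts, new implants, arm
#'   costs, total, and expected event counts per driver.
#' @export
run_scenario <- function(params, mix, discounted = FALSE) {
  h <- params$horizon_years
  shares <- market_trajectory(mix, years = h)
  m <- params$annual_mortality

  pool <- numeric(h)
  pool[1] <- eligible_population(params)
  if (h > 1) {
    for (y in 2:h) {
      pool[y] <- pool[y - 1] * (1 - m) + params$annual_incident_eligible
    }
  }
  n_reducer <- shares * pool
  n_soc <- pool - n_reducer

  new_implants <- numeric(h)
  for (y in seq_len(h)) {
    surviving_prev <- if (y == 1) 0 else n_reducer[y - 1] * (1 - m)
    new_implants[y] <- max(0, n_reducer[y] - surviving_prev)
  }

  p <- params$tree$p_success
  recur_reducer <- per_patient_annual_cost(
    "reducer", 2, params$costs, params$hru, params$drugs,
    params$drug_reduction_on_reducer)
  recur_soc <- per_patient_annual_cost(
    "soc", 2, params$costs, params$hru, params$drugs)
  recur_implanted <- p * recur_reducer + (1 - p) * recur_soc

  cost_reducer_arm <- new_implants * params$costs$reducer_implant +
    n_reducer * recur_implanted
  cost_soc_arm <- n_soc * recur_soc

  if (discounted) {
    df <- discount_factor(params$discount$rate, seq_len(h),
                          params$discount$first_year_discounted)
    cost_reducer_arm <- cost_reducer_arm * df
    cost_soc_arm <- cost_soc_arm * df
  }

  out <- tibble::tibble(
    year = seq_len(h),
    n_reducer = n_reducer,
    n_soc = n_soc,
    new_implants = new_implants,
    cost_reducer_arm = cost_reducer_arm,
    cost_soc_arm = cost_soc_arm,
    total = cost_reducer_arm + cost_soc_arm
  )
  rates_soc <- unlist(params$hru$soc)
  rates_reducer <- unlist(params$hru$reducer)
  rates_implanted <- p * rates_reducer + (1 - p) * rates_soc
  for (d in hru_drivers()) {
    out[[d]] <- n_reducer * rates_implanted[[d]] + n_soc * rates_soc[[d]]
  }
  out
}

#' Differential budget impact between the two market scenarios
#'
#' Runs the current and the revised market mix on identical populations and
#' reports yearly and cumulative differentials (revised minus current),
#' avoided event counts per driver (current minus revised), per-scenario
#' horizon totals and average annual impacts.
#'
#' @param params An `rha_parameter_set`.
#' @param discounted See [run_scenario()].
#' @return An object of class `rha_bia_result`: a list with tibbles
#'   `scenario1` (current mix), `scenario2` (revised mix), `differential`
#'   (year, EUR), `avoided_hru` (year by driver), and scalars
#'   `cumulative_differential`, `totals`, `average_annual`.
#' @export
differential_budget_impact <- function(params, discounted = FALSE) {
  s1 <- run_scenario(params, params$current_mix, discounted = discounted)
  s2 <- run_scenario(params, params$revised_mix, discounted = discounted)
  diff_year <- s2$total - s1$total
  avoided <- tibble::tibble(year = s1$year)
  for (d in hru_drivers()) avoided[[d]] <- s1[[d]] - s2[[d]]
  totals <- c(scenario1 = sum(s1$total), scenario2 = sum(s2$total))
  structure(
    list(
      scenario1 = s1,
      scenario2 = s2,
      differential = tibble::tibble(year = s1$year, differential = diff_year),
      cumulative_differential = sum(diff_year),
      avoided_hru = avoided,
      totals = totals,
      average_annual = totals / params$horizon_years,
      horizon_years = params$horizon_years
    ),
    class = "rha_bia_result"
  )
}

#' @export
print.rha_bia_result <- function(x, ...) {
  cat("<rha_bia_result>", x$horizon_years, "year horizon\n")
  cat(sprintf("  scenario totals    : current %s EUR | revised %s EUR\n",
              format(x$totals[["scenario1"]], big.mark = ",", nsmall = 2),
              format(x$totals[["scenario2"]], big.mark = ",", nsmall = 2)))
  cat(sprintf("  average annual     : current %s EUR | revised %s EUR\n",
              format(x$average_annual[["scenario1"]], big.mark = ",", nsmall = 2),
              format(x$average_annual[["scenario2"]], big.mark = ",", nsmall = 2)))
  cat(sprintf("  cumulative impact  : %s EUR (revised - current)\n",
              format(x$cumulative_differential, big.mark = ",", nsmall = 2)))
  cat("  yearly differential:",
      paste(formatC(x$differential$differential, format = "f", digits = 2,
                    big.mark = ","), collapse = " | "), "\n")
  invisible(x)
}
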