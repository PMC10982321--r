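# Cost-utility engine: the success/failure decision tree with alive/dead
# annual cycles, discounting, and ICER-or-dominance classification over 1..5
# year horizons.

#' Discount factor for a model year
#'
#' With the default convention the first model year is undiscounted
#' (exponent `year - 1`); with `first_year_discounted = TRUE` the exponent is
#' `year`.
#'
#' @param rate Annual discount rate (fraction/year).
#' @param year 1-based model year (vectorised).
#' @param first_year_discounted Convention flag.
#' @return Multiplier in `(0, 1]`.
#' @export
discount_factor <- function(rate, year, first_year_discounted = FALSE) {
  stopifnot(rate >= 0, all(year >= 1))
  expo <- if (first_year_discounted) year else year - 1
  1 / (1 + rate)^expo
}

#' Expected yearly costs and QALYs of the decision tree
#'
#' Per arm and year, the cohort-level expected cost and QALYs. The implant
#' arm branches on implant success: a responder accrues the responder utility
#' and (after year 1) the responder annual cost; a non-responder reverts to
#' the standard-of-care utility and cost. Year 1 of the implant arm uses the
#' implant-inclusive annual cost for every implanted patient. Dead patients
#' accrue zero cost and zero utility; the alive fraction is the cumulative
#' product of the per-year survival schedule times `(1 - annual_mortality)`.
#' Effectiveness is constant over the horizon (no decay).
#'
#' @param tree A [tree_params()].
#' @param discount A [discount_spec()].
#' @param horizon Number of years.
#' @param annual_mortality Additional background annual death probability
#'   applied multiplicatively to both arms' survival schedules.
#' @return Tibble with columns `arm`, `year`, `alive_fraction`,
#'   `expected_cost`, `expected_qaly` (cohort totals).
#' @export
tree_expected_values <- function(tree, discount, horizon,
                                 annual_mortality = 0) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  years <- seq_len(horizon)

  extend <- function(s, h) {
    if (length(s) >= h) s[seq_len(h)] else c(s, rep(s[length(s)], h - length(s)))
  }
  alive <- function(arm) {
    cumprod(extend(tree$annual_survival[[arm]], horizon) *
              (1 - annual_mortality))
  }
  df_cost <- if (discount$apply_to_costs) {
    discount_factor(discount$rate, years, discount$first_year_discounted)
  } else rep(1, horizon)
  df_out <- if (discount$apply_to_outcomes) {
    discount_factor(discount$rate, years, discount$first_year_discounted)
  } else rep(1, horizon)

  p <- tree$p_success
  u_reducer <- p * tree$utility_success + (1 - p) * tree$utility_soc
  cost_reducer_pp <- ifelse(
    years == 1, tree$annual_cost_reducer_year1,
    p * tree$annual_cost_reducer_later + (1 - p) * tree$annual_cost_soc)

  alive_r <- alive("reducer")
  alive_s <- alive("soc")
  n <- tree$cohort_size

  tibble::tibble(
    arm = rep(c("reducer", "soc"), each = horizon),
    year = c(years, years),
    alive_fraction = c(alive_r, alive_s),
    expected_cost = c(n * alive_r * cost_reducer_pp * df_cost,
                      n * alive_s * tree$annual_cost_soc * df_cost),
    expected_qaly = c(n * alive_r * u_reducer * df_out,
                      n * alive_s * tree$utility_soc * df_out)
  )
}

#' Classify an incremental result as ICER, dominant or dominated
#'
#' Increments are implant arm minus comparator. A strategy that is no more
#' costly and strictly more effective is `"dominant"`; strictly more costly
#' and no more effective is `"dominated"`; both increments zero is
#' `"equivalent"`. The edge case of equal effectiveness at strictly lower
#' cost is also labelled `"dominant"` (weak dominance), so no division by a
#' zero QALY increment ever occurs. Otherwise the ICER
#' `delta_cost / delta_qaly` is returned with verdict `"icer"`.
#'
#' @param delta_cost Incremental cost (EUR).
#' @param delta_qaly Incremental QALYs.
#' @return List with `verdict` (`"icer"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`) and `icer` (EUR/QALY, `NA` unless verdict is `"icer"`).
#' @examples
#' icer_or_dominance(8714, 0.138)      # per-patient year-1 ICER
#' icer_or_dominance(-62276530.29, 8846.060046)  # dominant
#' @export
icer_or_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(verdict = "equivalent", icer = NA_real_))
  }
  if (delta_cost <= 0 && delta_qaly >= 0) {
    return(list(verdict = "dominant", icer = NA_real_))
  }
  if (delta_cost >= 0 && delta_qaly <= 0) {
    return(list(verdict = "dominated", icer = NA_real_))
  }
  list(verdict = "icer", icer = delta_cost / delta_qaly)
}

#' Cost-utility results over nested horizons
#'
#' Cumulates the decision-tree expected values per arm over each horizon and
#' classifies the incremental result.
#'
#' @param params An `rha_parameter_set`.
#' @param horizons Horizons (years) to report; default 1 to the parameter
#'   set's horizon.
#' @return Tibble with one row per horizon: cumulative arm costs and QALYs,
#'   increments (`reducer - soc`), `icer` and `verdict`.
#' @export
cua_over_horizons <- function(params, horizons = seq_len(params$horizon_years)) {
  h_max <- max(horizons)
  ev <- tree_expected_values(params$tree, params$discount, h_max,
                             annual_mortality = params$annual_mortality)
  evr <- ev[ev$arm == "reducer", ]
  evs <- ev[ev$arm == "soc", ]
  cc_r <- cumsum(evr$expected_cost)
  cq_r <- cumsum(evr$expected_qaly)
  cc_s <- cumsum(evs$expected_cost)
  cq_s <- cumsum(evs$expected_qaly)

  out <- tibble::tibble(
    horizon = horizons,
    cost_reducer = cc_r[horizons],
    cost_soc = cc_s[horizons],
    qaly_reducer = cq_r[horizons],
    qaly_soc = cq_s[horizons],
    delta_cost = cc_r[horizons] - cc_s[horizons],
    delta_qaly = cq_r[horizons] - cq_s[horizons]
  )
  cls <- lapply(seq_len(nrow(out)), function(i) {
    icer_or_dominance(out$delta_cost[i], out$delta_qaly[i])
  })
  out$icer <- vapply(cls, function(x) x$icer, numeric(1))
  out$verdict <- vapply(cls, function(x) x$verdict, character(1))
  out
}

#' Relative decrease between two ratios, in percent
#'
#' `100 * (old - new) / old`; e.g. the year-over-year decrease of an ICER.
#'
#' @param old,new The two values (old must be non-zero).
#' @return Percent decrease (negative if `new > old`).
#' @export
percent_change <- function(old, new) {
  if (old == 0) stop("percent_change: 'old' must be non-zero", call. = FALSE)
  100 * (old - new) / old
}
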