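# Sensitivity analyses: one-way deterministic (tornado) perturbation of the
# registered parameters, and probabilistic Monte Carlo sampling of the
# cost-utility inputs summarised on the cost-effectiveness plane and as an
# acceptability curve.

#' Registry of parameters for the one-way sensitivity analysis
#'
#' Named accessors into a parameter set for the levers the tornado analysis
#' perturbs: the responder fraction, the standard-of-care event rates per
#' driver, the annual mortality and the drug-therapy reduction. Fractions are
#' clamped to `[0, 1]` after perturbation.
#'
#' @return Named list; each entry has `label`, `bounds` (or `NULL`), `get`
#'   and `set` functions.
#' @export
dsa_parameter_registry <- function() {
  rate <- function(field) {
    list(
      label = paste("SoC", gsub("_", " ", field), "rate"),
      bounds = NULL,
      get = function(p) p$hru$soc[[field]],
      set = function(p, v) { p$hru$soc[[field]] <- v; p }
    )
  }
  list(
    responder_fraction = list(
      label = "Responder fraction (implant success)", bounds = c(0, 1),
      get = function(p) p$tree$p_success,
      set = function(p, v) { p$tree$p_success <- v; p }
    ),
    soc_hospitalization_rate = rate("hospitalizations"),
    soc_coronarography_rate = rate("coronarographies"),
    soc_pci_rate = rate("pci"),
    soc_ed_admission_rate = rate("ed_admissions"),
    soc_outpatient_visit_rate = rate("outpatient_visits"),
    annual_mortality = list(
      label = "Annual mortality", bounds = c(0, 1),
      get = function(p) p$annual_mortality,
      set = function(p, v) { p$annual_mortality <- v; p }
    ),
    drug_reduction_on_reducer = list(
      label = "Drug-therapy reduction on reducer", bounds = c(0, 1),
      get = function(p) p$drug_reduction_on_reducer,
      set = function(p, v) { p$drug_reduction_on_reducer <- v; p }
    )
  )
}

dsa_outcome_fun <- function(target) {
  switch(target,
    bia_differential = function(p) {
      differential_budget_impact(p)$cumulative_differential
    },
    cua_icer = function(p) {
      r <- cua_over_horizons(p, horizons = p$horizon_years)
      # raw cost/QALY ratio as a continuous outcome; negative values sit in
      # the dominance region of the plane
      r$delta_cost / r$delta_qaly
    }
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the target outcome with each registered parameter set to
#' `base * (1 - delta)` and `base * (1 + delta)` (all other parameters at
#' base), and ranks parameters by the absolute outcome swing.
#'
#' @param params An `rha_parameter_set`.
#' @param target `"bia_differential"` (cumulative budget impact, EUR) or
#'   `"cua_icer"` (cost/QALY ratio at the full horizon).
#' @param delta Relative perturbation (default the parameter set's
#'   `uncertainty$dsa_delta`, 0.15).
#' @param parameters Subset of [dsa_parameter_registry()] names.
#' @return Tibble sorted by descending `swing` with columns `parameter`,
#'   `low_value`, `high_value`, `low_outcome`, `high_outcome`, `swing`,
#'   `base_outcome`.
#' @export
one_way_dsa <- function(params, target = c("bia_differential", "cua_icer"),
                        delta = params$uncertainty$dsa_delta,
                        parameters = names(dsa_parameter_registry())) {
  target <- match.arg(target)
  stopifnot(delta > 0)
  reg <- dsa_parameter_registry()
  unknown <- setdiff(parameters, names(reg))
  if (length(unknown)) {
    stop("unknown DSA parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  outcome <- dsa_outcome_fun(target)
  base_outcome <- outcome(params)

  rows <- lapply(parameters, function(nm) {
    e <- reg[[nm]]
    v <- e$get(params)
    clamp <- function(x) {
      if (is.null(e$bounds)) x else min(max(x, e$bounds[1]), e$bounds[2])
    }
    lo <- clamp(v * (1 - delta))
    hi <- clamp(v * (1 + delta))
    tibble::tibble(
      parameter = nm,
      low_value = lo,
      high_value = hi,
      low_outcome = outcome(e$set(params, lo)),
      high_outcome = outcome(e$set(params, hi)),
      base_outcome = base_outcome
    )
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$high_outcome - out$low_outcome)
  out <- out[order(-out$swing), ]
  out[, c("parameter", "low_value", "high_value", "low_outcome",
          "high_outcome", "swing", "base_outcome")]
}

#' Build a parameter distribution for probabilistic analysis
#'
#' Frequencies get a normal distribution truncated at zero; probabilities and
#' utilities get a beta distribution with shape parameters by the method of
#' moments (`k = m(1-m)/v - 1`, `shape1 = m k`, `shape2 = (1-m) k`, with
#' `v = (relative_sd * m)^2`). A zero relative SD yields a point mass for any
#' family.
#'
#' @param mean Distribution mean.
#' @param relative_sd Relative standard deviation (sd/mean).
#' @param family `"normal"` or `"beta"`.
#' @return List of class `rha_distribution` with the family and its
#'   parameters.
#' @export
build_distribution <- function(mean, relative_sd, family = c("normal", "beta")) {
  family <- match.arg(family)
  if (relative_sd == 0) {
    return(structure(list(family = "fixed", mean = mean),
                     class = "rha_distribution"))
  }
  sd <- relative_sd * mean
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      stop("beta distribution requires mean in (0, 1), got ", mean,
           call. = FALSE)
    }
    v <- sd^2
    if (v >= mean * (1 - mean)) {
      stop("beta method of moments infeasible: variance ", signif(v, 4),
           " >= m(1-m) = ", signif(mean * (1 - mean), 4), call. = FALSE)
    }
    k <- mean * (1 - mean) / v - 1
    structure(list(family = "beta", mean = mean, sd = sd,
                   shape1 = mean * k, shape2 = (1 - mean) * k),
              class = "rha_distribution")
  } else {
    structure(list(family = "normal", mean = mean, sd = sd, lower = 0),
              class = "rha_distribution")
  }
}

#' Draw from a parameter distribution
#'
#' Beta draws lie in `(0, 1)`; normal draws are truncated at zero via the
#' inverse-CDF method (so frequencies are never negative); a point mass
#' returns its mean.
#'
#' @param dist An `rha_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_from_distribution <- function(dist, n) {
  switch(dist$family,
    fixed = rep(dist$mean, n),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    normal = {
      p0 <- stats::pnorm(dist$lower, dist$mean, dist$sd)
      stats::qnorm(stats::runif(n, p0, 1), dist$mean, dist$sd)
    },
    stop("unknown distribution family: ", dist$family, call. = FALSE)
  )
}

psa_parameter_registry <- function() {
  tree_num <- function(field, family) {
    list(
      family = family,
      get = function(p) p$tree[[field]],
      set = function(p, v) { p$tree[[field]] <- v; p }
    )
  }
  list(
    p_success = tree_num("p_success", "beta"),
    utility_success = tree_num("utility_success", "beta"),
    utility_soc = tree_num("utility_soc", "beta"),
    annual_cost_reducer_year1 = tree_num("annual_cost_reducer_year1", "normal"),
    annual_cost_reducer_later = tree_num("annual_cost_reducer_later", "normal"),
    annual_cost_soc = tree_num("annual_cost_soc", "normal")
  )
}

#' Probabilistic sensitivity analysis of the cost-utility model
#'
#' Samples every uncertain cost-utility input from its distribution (beta for
#' the responder probability and the utilities, truncated normal for the
#' annual costs; all at the configured relative SD), reruns the full-horizon
#' decision tree per draw, and records the incremental cost and QALY pair on
#' the cost-effectiveness plane. Draws are independent across parameters.
#'
#' Random-number contract: one generator seeded once per run; parameters are
#' drawn in registry order, vectorised across simulations, so a fixed seed
#' gives bit-identical reruns.
#'
#' @param params An `rha_parameter_set`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param relative_sd Relative SD applied to every sampled parameter.
#' @param wtp_grid Willingness-to-pay thresholds (EUR/QALY) for the
#'   acceptability curve.
#' @return List of class `rha_psa` with `draws` (tibble: `draw`,
#'   `delta_cost`, `delta_qaly`, `quadrant`, `icer`) and `summary` (list:
#'   `n_draws`, `proportion_dominant`, `mean_delta_cost`, `mean_delta_qaly`,
#'   `ceac` tibble). Quadrants follow the plane convention with incremental
#'   QALYs on x and incremental costs on y: `SE` (more effective, cheaper) is
#'   the dominance region. The ICER is left undefined (`NA`) for draws with a
#'   zero QALY increment; quadrant and CEAC logic never divide.
#' @export
run_psa <- function(params, n_draws = params$uncertainty$n_draws,
                    seed = params$uncertainty$seed,
                    relative_sd = params$uncertainty$relative_sd,
                    wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(n_draws >= 1)
  reg <- psa_parameter_registry()
  set.seed(seed)
  draw_mat <- matrix(NA_real_, nrow = n_draws, ncol = length(reg),
                     dimnames = list(NULL, names(reg)))
  for (j in seq_along(reg)) {
    e <- reg[[j]]
    d <- build_distribution(e$get(params), relative_sd, e$family)
    draw_mat[, j] <- draw_from_distribution(d, n_draws)
  }

  dc <- numeric(n_draws)
  dq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    p2 <- params
    for (j in seq_along(reg)) p2 <- reg[[j]]$set(p2, draw_mat[i, j])
    r <- cua_over_horizons(p2, horizons = params$horizon_years)
    dc[i] <- r$delta_cost
    dq[i] <- r$delta_qaly
  }

  quadrant <- ifelse(dq > 0 & dc > 0, "NE",
              ifelse(dq > 0, "SE",
              ifelse(dc > 0, "NW", "SW")))
  draws <- tibble::tibble(
    draw = seq_len(n_draws),
    delta_cost = dc,
    delta_qaly = dq,
    quadrant = quadrant,
    icer = ifelse(dq != 0, dc / dq, NA_real_)
  )
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    probability_cost_effective = vapply(
      wtp_grid, function(l) mean(l * dq - dc >= 0), numeric(1))
  )
  structure(
    list(
      draws = draws,
      summary = list(
        n_draws = n_draws,
        proportion_dominant = mean(quadrant == "SE"),
        mean_delta_cost = mean(dc),
        mean_delta_qaly = mean(dq),
        ceac = ceac
      )
    ),
    class = "rha_psa"
  )
}

#' @export
print.rha_psa <- function(x, ...) {
  s <- x$summary
  cat("<rha_psa>", s$n_draws, "Monte Carlo draws\n")
  cat(sprintf("  dominant (SE quadrant): %.1f%%\n", 100 * s$proportion_dominant))
  cat(sprintf("  mean increments       : %s EUR, %.2f QALYs\n",
              formatC(s$mean_delta_cost, format = "f", digits = 2,
                      big.mark = ","), s$mean_delta_qaly))
  invisible(x)
}
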