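#' Round half away from zero
#'
#' Commercial ("round half up") rounding used when converting fractional
#' patient counts to whole patients along the eligibility funnel. Base R's
#' `round()` rounds half to even, which does not reproduce standard
#' epidemiological funnel tables.
#'
#' @param x Numeric vector.
#' @return `floor(x + 0.5)` for non-negative `x`.
#' @export
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Driver names used everywhere a healthcare-resource profile appears.
hru_drivers <- function() {
  c("hospitalizations", "ed_admissions", "coronarographies",
    "outpatient_visits", "pci")
}
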