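# Shared fixtures for the model tests, all built in code.

base_params <- function() default_parameter_set()

# A tiny, fully deterministic parameter set: one eligible patient, no
# uncertainty, unit survival.
single_patient_params <- function() {
  p <- default_parameter_set()
  p$funnel <- funnel_spec(1, c(eligible = 1))
  p$uncertainty$relative_sd <- 0
  p
}

# Hand-built cohort of identical, fully observed patients (one year each).
uniform_cohort <- function(n, events_per_driver = 2L, died = FALSE) {
  x <- tibble::tibble(
    patient = seq_len(n),
    arm = "soc",
    follow_up_years = 1L,
    death_year = if (died) 1L else NA_integer_,
    years_observed = 1L,
    hospitalizations = events_per_driver,
    ed_admissions = events_per_driver,
    coronarographies = events_per_driver,
    outpatient_visits = events_per_driver,
    pci = events_per_driver,
    responder = 0L,
    utility = 0.5
  )
  class(x) <- c("rha_cohort", class(x))
  x
}
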