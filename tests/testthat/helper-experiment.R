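# Shared default-world fixture for the acceptance tests: the 85-bone synthetic
# cohort at the default parameter ranges, shortened in 10% steps, with the
# calibrated manual-placement simulator. Computed once per test run.

.radcs_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.radcs_cache$cohort)) {
    .radcs_cache$cohort <- generate_cohort(85, seed = 1)
  }
  .radcs_cache$cohort
}

default_experiment <- function() {
  if (is.null(.radcs_cache$records)) {
    .radcs_cache$records <- run_experiment(default_cohort(),
                                           lengths = seq(10L, 100L, 10L),
                                           manual_noise = manual_noise_model(),
                                           seed = 1)
  }
  .radcs_cache$records
}
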