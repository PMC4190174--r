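# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

# Pooled 13-study cohort from the reference mean curve with constant
# log-scale noise sigma = 0.15, harmonized; about 10,100 modelling points.
pooled_cohort_015 <- function() {
  if (is.null(.cohort_cache$pooled)) {
    d <- simulate_cohort(sd_profile = sd_profile_constant(0.15), seed = 42)
    .cohort_cache$pooled <- harmonize(d)
  }
  .cohort_cache$pooled
}

# Single-study adult cohort (no zero-clipping in play) on the reference scale.
adult_profile <- function(n = 10000, amin = 20, amax = 80, amed = 50,
                          assay = "LC-MS/MS") {
  data.frame(study = "sim", n = as.integer(n), age_median = amed,
             age_min = amin, age_max = amax, assay = assay,
             stringsAsFactors = FALSE)
}
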