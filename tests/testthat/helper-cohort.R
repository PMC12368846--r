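# small cohorts used across test files; all generation is seeded in code

small_cohort <- function(n_sites = 400, seed = 1, n_individuals = 60,
                         availability = c(55, 50, 48), ...) {
  generate_cohort(cohort_config(n_sites = n_sites,
                                n_individuals = n_individuals,
                                availability = availability,
                                seed = seed, ...))
}

# full-size sample structure (182/168/164) but few sites: cheap to generate,
# realistic per-group power
study_cohort <- function(n_sites = 600, seed = 1, ...) {
  generate_cohort(cohort_config(n_sites = n_sites, seed = seed, ...))
}

# homoskedastic variant: equal SD moments across cell types
flat_moments <- function(mean = 0.04, sd = 0.02) {
  list(NeuNPos = c(mean, sd), Sox10Pos = c(mean, sd),
       DoubleNeg = c(mean, sd))
}

expect_config_error <- function(expr) {
  expect_error(expr, class = "sortedmeth_config_error")
}
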