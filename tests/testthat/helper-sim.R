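# small, fast default configuration for unit tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_studies = 2, n_per_study = 400, n_metabolites = 8,
                   block_sizes = c(4, 4), seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# one cohort table for a single study
one_cohort <- function(n = 400, ...) {
  cfg <- small_config(n_studies = 1, n_per_study = n, ...)
  simulate_cohorts(cfg)
}
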