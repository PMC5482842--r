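## One default-config scenario, generated once and shared across test files
## (the generator is deterministic, so this is a fixture built in code).
.scenario_cache <- new.env(parent = emptyenv())

default_scenario <- function() {
  if (is.null(.scenario_cache$scen))
    .scenario_cache$scen <- simulate_scenario(sim_config(seed = 101))
  .scenario_cache$scen
}

## a reduced-k full-model fit on the shared scenario (cheap, reused)
default_fit <- function() {
  if (is.null(.scenario_cache$fit))
    .scenario_cache$fit <- fit_gamm(default_scenario()$plants, gamm_spec(k = 5))
  .scenario_cache$fit
}

## small fast config for pipeline smoke tests
small_config <- function(seed = 1) {
  sim_config(extent_m = c(340, 340), n_plots = 4, n_canopies = 8,
             seed = seed)
}
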