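# Shared small-scale model setups used across test files. Everything is
# generated in code; sizes are kept small so single tests run in seconds.

tiny_config <- function(n_countries = 12, n_segments = 40, ...) {
  scc_config(scenario_config = calibrate_generator(n_countries = n_countries),
             n_segments = n_segments, ...)
}

tiny_draw <- function(seed = 42, n_countries = 12) {
  sample_scenario(calibrate_generator(n_countries = n_countries), seed = seed)
}

# A fixed climate path for damage tests: constant temperature anomaly over
# the scenario years (plus history so align_temp finds every year).
flat_climate <- function(temp = 1.5, years = 1750:2300) {
  structure(list(years = years, temp = rep(temp, length(years))),
            class = "climate_path")
}

# A climate-path-like object with a prescribed anomaly over 2020-2300.
ramp_climate <- function(t2300 = 3, years = 1750:2300) {
  temp <- pmax(0, (years - 2020) / (2300 - 2020)) * t2300
  structure(list(years = years, temp = temp), class = "climate_path")
}
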