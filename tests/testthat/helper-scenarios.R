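# small, fast scenarios shared across test files

quick_scenario <- function(seed = 1, n_years = 3, base_deaths = 150,
                           curve = linear_curve(0.0014), ...) {
  city_scenario("TestCity", n_years = n_years, base_deaths = base_deaths,
                curve = curve, seed = seed, ...)
}

quick_series <- function(seed = 1, ...) generate_city(quick_scenario(seed, ...))
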