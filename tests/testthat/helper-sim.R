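# Shared fixtures: everything is generated in code, no stored data.

# Small synthetic world for fast tests: 8-12 districts, one or two years.
tiny_sim <- function(seed = 1, n_districts = 8, end = "2002-12-31", ...) {
  generate_panel(sim_config(seed = seed, n_districts = n_districts,
                            start = "2002-01-01", end = end, ...))
}

# Model spec scaled down for small panels.
tiny_spec <- function(..., n_basis_time = 8, n_basis_temp = 6) {
  model_spec(n_basis_time = n_basis_time, n_basis_temp = n_basis_temp, ...)
}

# Events table used in several calendar tests (subset of the 2002 row).
toy_events <- function() {
  parse_ads_events(data.frame(year = 2002,
                              intervals = "2/11-2/12, 3/31-4/1, 4/8-4/15"))
}
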