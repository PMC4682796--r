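# Shared fixtures for the unit suites. Everything is generated in code;
# expensive states are built lazily and memoized for the session.

.fixture_env <- new.env()

# small grid used by most field tests
test_grid <- function(n = 64) grid_spec(n)

# flow-solved 3x3 toy grid network
solved_grid3x3 <- function() solve_flow(make_toy_network("grid3x3"))

# the baseline study state: default configuration grown to the injection
# day. Expensive (~20 s), shared across the acceptance suite.
grown_baseline_sim <- function() {
  if (!is.null(.fixture_env$baseline)) return(.fixture_env$baseline)
  sim <- sim_init(default_config())
  sim_grow(sim, 18)
  .fixture_env$baseline <- sim
  sim
}
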