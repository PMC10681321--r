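# Shared test fixtures: all inputs are built in code at test time.

# small healing geometry resolving the full 0.7 mm gap at the 0.01 mm pitch
mini_domain <- function(pitch = 0.01) {
  healing_domain(gap_width = 0.7, cortex_thickness = 0.2, marrow_width = 1.0,
                 domain_width = 1.7, domain_height = 1.5,
                 callus_radius = 0.72, pitch = pitch)
}

mini_config <- function(scenario = "baseline-rigid", seed = 1, ...) {
  scenario_config(scenario, domain = mini_domain(), seed = seed,
                  replicates = 6, ...)
}

# state on a homogeneous square with an imposed uniform strain field
uniform_strain_state <- function(ep, theta, size = 30, seed = 1, ...) {
  cfg <- make_fixture("uniform-strain", size = size, ep = ep, theta = theta, ...)
  sim_init(cfg, seed = seed)
}

# run a state for n iterations and return the result snapshot
run_steps <- function(state, n) {
  for (i in seq_len(n)) sim_step(state)
  sim_result(state)
}

# independent 2x2 principal decomposition oracle via eigen()
eigen_oracle <- function(exx, eyy, gxy) {
  M <- matrix(c(exx, gxy / 2, gxy / 2, eyy), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  i <- which.max(abs(e$values))
  v <- e$vectors[, i]
  list(ep = e$values[i], theta = (atan2(v[2], v[1]) * 180 / pi) %% 180)
}
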