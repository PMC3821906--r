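# Shared fixtures: small, fast scenarios built in code.

# Conventional-course scenario around a minimal-model truth; dense enough
# that all four parameters are identifiable.
quick_m_scenario <- function(seed = 3, noise_cv = 0,
                             K = 15, D = 0.5, Td = 200, V0 = 8.5) {
  scenario_spec("L", growth_params(Td = Td),
                effect_model("M", K = K, D = D),
                V0 = V0, schedule = make_schedule("L", 46),
                noise_cv = noise_cv, detection_limit = 0.001, seed = seed)
}

# Fast fit configuration for unit tests.
quick_cfg <- function(n_starts = 8, seed = 2, ...) {
  fit_config(n_starts = n_starts, seed = seed, ...)
}

# A small balanced state at GF proportions.
balanced_state <- function(N0 = 1e9, Td = 100, GF = 0.2, Tc = 3, gamma = 0) {
  g <- growth_params(Td = Td, GF = GF, Tc = Tc, gamma = gamma)
  list(g = g, d = derive_rates(g), s = init_state(N0, g))
}
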