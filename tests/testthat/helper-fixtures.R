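# Shared fixtures: a 48 h aqueous exposure followed by 48 h depuration, the
# silver-uptake-like kinetics used across the fitting tests, and a reduced
# GA configuration for simulation studies (full defaults are exercised where
# single fits are checked).

silver_scenario <- function(dt = 1) {
  exposure_scenario(c_exposure = 1, t_e = 48, t_total = 96, dt = dt)
}

silver_oc_params <- function() kinetic_params(k1 = 0.196, k2 = 0.033)

silver_ocsf_params <- function() kinetic_params(k1 = 0.426, k2 = 0.155,
                                                sf = 0.086)

# 12 sampling times spanning both phases
twelve_times <- function() {
  c(seq(6, 48, length.out = 6), seq(56, 96, length.out = 6))
}

# reduced GA configuration for multi-fit simulation studies
study_config <- function(seed = 1L) {
  fit_config(population_size = 200L, steady_fitness_generations = 100L,
             seed = seed)
}

# small configuration for behavioural (non-accuracy) checks
tiny_config <- function(seed = 1L, max_generations = 400L, ...) {
  fit_config(population_size = 60L, steady_fitness_generations = 40L,
             max_generations = max_generations, seed = seed, ...)
}

random_valid_params <- function() {
  kinetic_params(k1 = 10^stats::runif(1, -2, 3),
                 k2 = 10^stats::runif(1, -2, 1),
                 sf = stats::runif(1))
}
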