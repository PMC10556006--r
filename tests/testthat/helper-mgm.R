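# shared builders for the test suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# composition with a single explicit energy density (E_M = E, E_S = 0)
flat_composition <- function(E = 1) {
  composition_params(E_CP = E, E_L = 0, E_MR = 0,
                     E_SSD = 0, E_SSG = 0, E_SR = 0,
                     f_CP = 1, f_L = 0, f_R = 0)
}

# full model whose growth equation is exactly dW/dt = a W^beta - b W
# (b_N = 0, E_M + E_S = 1, phi = 1)
mgm_vb <- function(a, b, beta = 2 / 3, a_N = 0, delta = 1) {
  e <- 0.7
  k_F <- 0.1
  mgm_params(
    ingestion = ingestion_params(alpha = a / (e - k_F), beta = beta),
    composition = flat_composition(1),
    feeding = feeding_params(k_F = k_F),
    # at phi = 1 the effective decay rate is gamma_BS / (1 - a_N)
    maintenance = maintenance_params(gamma_BS = b * (1 - a_N),
                                     a_NS = a_N, b_NS = 0, delta = delta),
    e = e
  )
}

# the package default reduced to its ad-libitum four-parameter form
default_eq33 <- function() as_mgm33(mgm_default_params())

# deterministic (noise- and mortality-free) synthetic configuration
noiseless_config <- function(...) {
  synthetic_config(individual_cv = 0, measurement_cv = 0, mortality_rate = 0,
                   ...)
}
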