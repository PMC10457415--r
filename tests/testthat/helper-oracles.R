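# Shared fixtures and independent oracles, built in code.

rt <- function(temperature) R_gas * temperature

# explicit mole bookkeeping for a water+solute mixture: concentrations from
# (n_w, n_s) and the partial molar volumes, no mole-fraction shortcut
mole_balance_concentrations <- function(n_w, n_s, v_w, v_s) {
  V <- n_w * v_w + n_s * v_s
  c(c_w = n_w / V, c_s = n_s / V)
}

std_plateau <- function(U_rt = 30, temperature = 300, h = 5e-9, width = h / 20) {
  membrane_potential("plateau", U_max = U_rt * rt(temperature), h = h,
                     interface_width = width)
}

std_gaussian <- function(U_rt = 30, temperature = 300, h = 5e-9, width = h / 20) {
  membrane_potential("gaussian", U_max = U_rt * rt(temperature), h = h,
                     interface_width = width)
}

# reduced-unit particle configuration used across the particle tests
reduced_config <- function(U_rt = 30, shape = "plateau", N = 2000,
                           n_steps = 20000, seed = 1, ...) {
  pot <- membrane_potential(shape, U_max = U_rt, h = 20, interface_width = 1)
  particle_sim_config(pot, N = N, D_s = 1, reduced = TRUE,
                      n_steps = n_steps, seed = seed, ...)
}

# closed-form exponential solution of the permeant-exchange kinetics
donnan_A_closed <- function(t, A0, A_e, k, p = 0) {
  (A_e - p / k) + (A0 - (A_e - p / k)) * exp(-k * t)
}
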