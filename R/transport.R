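#' Volume and molar water flux
#'
#' Fluxes follow one global sign convention: the membrane is perpendicular to
#' the x axis, differences are right minus left (`delta_q = q_right - q_left`),
#' and flux is positive in the +x direction (left to right), with the solution
#' of higher osmolarity conventionally on the right.  When the volume flux is
#' carried by water alone, the molar water flux is `phi_w = phi_V / v_w0`.
#'
#' @param phi_V volume flux of water per unit membrane area \[m s^-1\].
#' @param v_w0 molar volume of pure water \[m^3 mol^-1\].
#' @return an object of class `flux_result` with elements `phi_V` and `phi_w`.
#' @export
flux_result <- function(phi_V, v_w0 = v_w0_default) {
  .check_scalar(phi_V, "phi_V")
  .check_scalar(v_w0, "v_w0", lower = 0, strict = TRUE)
  structure(list(phi_V = phi_V, phi_w = phi_V / v_w0, v_w0 = v_w0),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("Water flux: phi_V = %g m/s, phi_w = %g mol m^-2 s^-1\n",
              x$phi_V, x$phi_w))
  invisible(x)
}

#' van 't Hoff equilibrium pressure difference
#'
#' The hydrostatic pressure difference that stops osmotic flow across a
#' semipermeable membrane separating dilute solutions differing in osmolarity
#' by `delta_c`: `delta_P = R T delta_c`.  Linear in the osmolarity
#' difference and independent of solute identity.
#'
#' @param delta_c osmolarity difference, right minus left \[mol m^-3\].
#' @param temperature absolute temperature \[K\].
#' @return equilibrium pressure difference \[Pa\].
#' @examples
#' van_t_hoff_delta_p(100, 300)  # 249420 Pa, about 2.5 atm
#' @export
van_t_hoff_delta_p <- function(delta_c, temperature = default_temperature) {
  .check_scalar(delta_c, "delta_c")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  R_gas * temperature * delta_c
}

#' Darcy (hydraulic) water flux
#'
#' Pressure-driven volume flux through a membrane, `phi_V = -Lp * delta_P`:
#' water flows toward the side with lower pressure.
#'
#' @param Lp hydraulic permeability \[m s^-1 Pa^-1\], >= 0.
#' @param delta_P hydrostatic pressure difference, right minus left \[Pa\].
#' @param v_w0 molar volume of pure water, for the molar flux.
#' @return a [flux_result()].
#' @export
darcy_flux <- function(Lp, delta_P, v_w0 = v_w0_default) {
  .check_scalar(Lp, "Lp", lower = 0)
  .check_scalar(delta_P, "delta_P")
  flux_result(-Lp * delta_P, v_w0)
}

#' Combined osmotic and hydraulic water flux
#'
#' The combined flux law `phi_V = -Lp (delta_P - R T delta_c)`: an imposed
#' pressure difference and an osmolarity difference drive water through the
#' same coefficient `Lp`.  It reduces to [darcy_flux()] at `delta_c = 0` and
#' vanishes exactly at the van 't Hoff balance `delta_P = R T delta_c`.
#'
#' @inheritParams darcy_flux
#' @param delta_c osmolarity difference, right minus left \[mol m^-3\].
#' @param temperature absolute temperature \[K\].
#' @return a [flux_result()].
#' @examples
#' # pure water left, 100 mol/m^3 right, equal pressures: flow to the right
#' fundamental_flux(Lp = 1e-12, delta_P = 0, delta_c = 100, temperature = 300)
#' @export
fundamental_flux <- function(Lp, delta_P, delta_c,
                             temperature = default_temperature,
                             v_w0 = v_w0_default) {
  .check_scalar(Lp, "Lp", lower = 0)
  .check_scalar(delta_P, "delta_P")
  .check_scalar(delta_c, "delta_c")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  flux_result(-Lp * (delta_P - R_gas * temperature * delta_c), v_w0)
}

#' Molar-flux form of the combined law
#'
#' `phi_w = -Pf (delta_P / (R T) - delta_c)`.  With `Pf = R T Lp / v_w0`
#' (see [pf_from_lp()]) this is algebraically identical to
#' [fundamental_flux()] divided by `v_w0`.
#'
#' @param Pf osmotic permeability \[m s^-1\], >= 0.
#' @param delta_P pressure difference, right minus left \[Pa\].
#' @param delta_c osmolarity difference, right minus left \[mol m^-3\].
#' @param temperature absolute temperature \[K\].
#' @return molar water flux \[mol m^-2 s^-1\].
#' @export
molar_flux_form <- function(Pf, delta_P, delta_c,
                            temperature = default_temperature) {
  .check_scalar(Pf, "Pf", lower = 0)
  .check_scalar(delta_P, "delta_P")
  .check_scalar(delta_c, "delta_c")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  -Pf * (delta_P / (R_gas * temperature) - delta_c)
}

#' Osmotic permeability from hydraulic permeability
#'
#' `Pf = R T Lp / v_w0`.  The printed form of this relation omits the
#' division bar; dimensional analysis (`Pf` in m s^-1) and the requirement
#' that the molar-flux form reproduce the volume-flux law fix it as a
#' division by the molar volume of water.
#'
#' @param Lp hydraulic permeability \[m s^-1 Pa^-1\], >= 0.
#' @param temperature absolute temperature \[K\].
#' @param v_w0 molar volume of pure water \[m^3 mol^-1\], > 0.
#' @return osmotic permeability Pf \[m s^-1\].
#' @export
pf_from_lp <- function(Lp, temperature = default_temperature,
                       v_w0 = v_w0_default) {
  .check_scalar(Lp, "Lp", lower = 0)
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  .check_scalar(v_w0, "v_w0", lower = 0, strict = TRUE)
  R_gas * temperature * Lp / v_w0
}

#' Tracer (labeled-water) diffusional flux
#'
#' Fick's-law flux of isotopically labeled water measured with no pressure or
#' osmolarity difference: `phi_w_star = -Pd * delta_c_star`.  This experiment
#' defines the diffusional permeability `Pd`.
#'
#' @param Pd diffusional permeability \[m s^-1\], >= 0.
#' @param delta_c_star labeled-water concentration difference, right minus
#'   left \[mol m^-3\].
#' @return molar tracer flux \[mol m^-2 s^-1\].
#' @export
tracer_flux <- function(Pd, delta_c_star) {
  .check_scalar(Pd, "Pd", lower = 0)
  .check_scalar(delta_c_star, "delta_c_star")
  -Pd * delta_c_star
}

#' Diffusive water flux driven by a pressure difference
#'
#' The diffusive component of pressure-driven water flux is governed by the
#' same `Pd` measured in the tracer experiment:
#' `phi_w_d = -Pd * delta_P / (R T)`.  (A force per molecule imposed by the
#' pressure gradient biases the random motion exactly as a tracer
#' concentration gradient of `delta_P / (R T)` would.)
#'
#' @inheritParams tracer_flux
#' @param delta_P pressure difference, right minus left \[Pa\].
#' @param temperature absolute temperature \[K\].
#' @return molar diffusive water flux \[mol m^-2 s^-1\].
#' @export
diffusive_flux_under_pressure <- function(Pd, delta_P,
                                          temperature = default_temperature) {
  .check_scalar(Pd, "Pd", lower = 0)
  .check_scalar(delta_P, "delta_P")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  -Pd * delta_P / (R_gas * temperature)
}

#' Convective fraction of water transport
#'
#' With diffusive and convective flows additive (`Pf = Pc + Pd`), the ratio
#' `Pc/Pd = Pf/Pd - 1` measures how much of the observed flow is convection.
#' `Pf/Pd = 1` means purely diffusive transport (isolated lipid bilayers);
#' large values mean convection dominates (porous synthetic membranes).
#' `Pf < Pd` is rejected as inconsistent with a non-negative convective
#' component.
#'
#' @param Pf osmotic permeability \[m s^-1\].
#' @param Pd diffusional permeability \[m s^-1\], > 0.
#' @return the dimensionless ratio Pc/Pd.
#' @examples
#' convective_fraction(Pf = 730, Pd = 1)  # open collodion membrane: 729
#' convective_fraction(Pf = 36, Pd = 1)   # dense collodion membrane: 35
#' @export
convective_fraction <- function(Pf, Pd) {
  .check_scalar(Pf, "Pf", lower = 0)
  .check_scalar(Pd, "Pd", lower = 0, strict = TRUE)
  if (Pf < Pd * (1 - 1e-12))
    stop("Pf < Pd is inconsistent with Pc >= 0: the smallest admissible Pf/Pd is 1",
         call. = FALSE)
  Pf / Pd - 1
}

#' Solubility-diffusion permeability of a lipid bilayer
#'
#' For a membrane crossed by water as dispersed independent molecules, the
#' permeability is `Pf = K D / h`, with `K` the water partition coefficient,
#' `D` the in-membrane self-diffusion constant and `h` the thickness.  The
#' same expression governs pressure-driven and osmotic flux, and the implied
#' diffusional permeability `Pd` is identical, so `Pf/Pd = 1` exactly: no
#' convective component.
#'
#' @param K partition coefficient (ratio of water concentration inside the
#'   membrane to bulk), dimensionless, >= 0.
#' @param D in-membrane water diffusion constant \[m^2 s^-1\], >= 0.
#' @param h membrane thickness \[m\], > 0.
#' @return permeability \[m s^-1\].
#' @examples
#' solubility_diffusion_pf(K = 2e-3, D = 1e-9, h = 4e-9)  # 5e-4 m/s
#' solubility_diffusion_ratio(K = 2e-3, D = 1e-9, h = 4e-9)  # exactly 1
#' @export
solubility_diffusion_pf <- function(K, D, h) {
  .check_scalar(K, "K", lower = 0)
  .check_scalar(D, "D", lower = 0)
  .check_scalar(h, "h", lower = 0, strict = TRUE)
  K * D / h
}

#' @rdname solubility_diffusion_pf
#' @export
solubility_diffusion_pd <- function(K, D, h) {
  # same expression by inspection: tracer diffusion picks up the same
  # partition factor and diffusion constant as the force-driven flux
  solubility_diffusion_pf(K, D, h)
}

#' @rdname solubility_diffusion_pf
#' @export
solubility_diffusion_ratio <- function(K, D, h) {
  pf <- solubility_diffusion_pf(K, D, h)
  pd <- solubility_diffusion_pd(K, D, h)
  if (pd == 0) {
    if (pf == 0) return(NaN)
    stop("Pd = 0 with Pf > 0 is not representable in this model", call. = FALSE)
  }
  pf / pd
}
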