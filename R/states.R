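#' Well-stirred solution chamber state
#'
#' A bulk chamber is described by its osmolarity (total solute concentration),
#' hydrostatic pressure, and absolute temperature.  Internal units are SI;
#' convert with [to_si_concentration()] / [atm_to_pa()] at the boundary.
#'
#' @param osmolarity total solute concentration \[mol m^-3\], >= 0.
#' @param pressure hydrostatic pressure \[Pa\].
#' @param temperature absolute temperature \[K\], > 0; defaults to
#'   [default_temperature].
#' @return an object of class `solution_state`.
#' @examples
#' solution_state(osmolarity = 100, pressure = 0, temperature = 300)
#' @export
solution_state <- function(osmolarity, pressure = 0,
                           temperature = default_temperature) {
  .check_scalar(osmolarity, "osmolarity", lower = 0)
  .check_scalar(pressure, "pressure")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  structure(
    list(osmolarity = osmolarity, pressure = pressure, temperature = temperature),
    class = "solution_state"
  )
}

#' @export
print.solution_state <- function(x, ...) {
  cat("Solution chamber state\n")
  cat(sprintf("  osmolarity : %g mol/m^3 (%g M)\n",
              x$osmolarity, from_si_concentration(x$osmolarity)))
  cat(sprintf("  pressure   : %g Pa\n", x$pressure))
  cat(sprintf("  temperature: %g K\n", x$temperature))
  invisible(x)
}

#' Membrane transport coefficients
#'
#' Container for the algebraically related permeability coefficients of a
#' water-transporting membrane: the hydraulic permeability `Lp`
#' \[m s^-1 Pa^-1\], the osmotic permeability `Pf` and diffusional
#' permeability `Pd` \[m s^-1\], the convective contribution `Pc = Pf - Pd`,
#' and the solubility-diffusion descriptors `K` (partition coefficient,
#' dimensionless), `D` (in-membrane water diffusion constant \[m^2 s^-1\])
#' and `h` (membrane thickness \[m\]).
#'
#' Whenever `Pf`, `Pd` and `Pc` are jointly determined they must satisfy the
#' additivity of diffusive and convective water flow, `Pf = Pc + Pd`, and
#' since convection cannot be negative, `Pf/Pd >= 1`.  Violations are errors.
#' If `Pf` and `Pd` are supplied without `Pc`, `Pc` is filled in as
#' `Pf - Pd`.
#'
#' @param Lp,Pf,Pd,Pc,K,D,h see description; all >= 0, `NA` when unknown.
#' @param v_w0 molar volume of pure water \[m^3 mol^-1\], default
#'   [v_w0_default].
#' @return an object of class `transport_coefficients`.
#' @examples
#' transport_coefficients(Lp = 1e-12, Pf = 1.4e-4, Pd = 1e-4)
#' @export
transport_coefficients <- function(Lp = NA_real_, Pf = NA_real_, Pd = NA_real_,
                                   Pc = NA_real_, v_w0 = v_w0_default,
                                   K = NA_real_, D = NA_real_, h = NA_real_) {
  chk <- function(x, name, strict = FALSE) {
    if (!is.na(x)) .check_scalar(x, name, lower = 0, strict = strict)
    x
  }
  Lp <- chk(Lp, "Lp"); Pf <- chk(Pf, "Pf"); Pd <- chk(Pd, "Pd")
  Pc <- chk(Pc, "Pc"); K <- chk(K, "K"); D <- chk(D, "D")
  h <- chk(h, "h", strict = TRUE)
  .check_scalar(v_w0, "v_w0", lower = 0, strict = TRUE)

  if (!is.na(Pf) && !is.na(Pd) && is.na(Pc)) {
    if (Pf < Pd * (1 - 1e-12))
      stop("Pf < Pd is inconsistent with a non-negative convective component (Pf/Pd >= 1)",
           call. = FALSE)
    Pc <- max(Pf - Pd, 0)
  }
  if (!is.na(Pf) && !is.na(Pd) && !is.na(Pc)) {
    if (abs(Pf - (Pc + Pd)) > 1e-9 * max(Pf, Pc + Pd, .Machine$double.xmin))
      stop(sprintf("Pf (%g) must equal Pc + Pd (%g): diffusive and convective flows add",
                   Pf, Pc + Pd), call. = FALSE)
  }
  structure(
    list(Lp = Lp, Pf = Pf, Pd = Pd, Pc = Pc, v_w0 = v_w0, K = K, D = D, h = h),
    class = "transport_coefficients"
  )
}

#' @export
print.transport_coefficients <- function(x, ...) {
  cat("Membrane transport coefficients\n")
  fmt <- function(v, unit) if (is.na(v)) "unset" else sprintf("%g %s", v, unit)
  cat(sprintf("  Lp  : %s\n", fmt(x$Lp, "m s^-1 Pa^-1")))
  cat(sprintf("  Pf  : %s\n", fmt(x$Pf, "m s^-1")))
  cat(sprintf("  Pd  : %s\n", fmt(x$Pd, "m s^-1")))
  cat(sprintf("  Pc  : %s\n", fmt(x$Pc, "m s^-1")))
  if (!is.na(x$Pf) && !is.na(x$Pd) && x$Pd > 0)
    cat(sprintf("  Pf/Pd: %g\n", x$Pf / x$Pd))
  cat(sprintf("  v_w0: %g m^3 mol^-1\n", x$v_w0))
  cat(sprintf("  K   : %s\n", fmt(x$K, "")))
  cat(sprintf("  D   : %s\n", fmt(x$D, "m^2 s^-1")))
  cat(sprintf("  h   : %s\n", fmt(x$h, "m")))
  invisible(x)
}
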