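#' Dilute binary mixture specification
#'
#' A water + single-solute mixture described by the solute mole fraction
#' `X_s = n_s / (n_w + n_s)` and the (composition-independent) partial molar
#' volumes of water and solute.
#'
#' @param X_s solute mole fraction, `0 <= X_s < 1`.
#' @param v_w partial molar volume of water \[m^3 mol^-1\], > 0; default
#'   [v_w0_default].
#' @param v_s partial molar volume of solute \[m^3 mol^-1\], > 0.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(X_s, v_w = v_w0_default, v_s = v_w0_default) {
  .check_scalar(X_s, "X_s", lower = 0)
  if (X_s >= 1) stop("`X_s` must be < 1", call. = FALSE)
  .check_scalar(v_w, "v_w", lower = 0, strict = TRUE)
  .check_scalar(v_s, "v_s", lower = 0, strict = TRUE)
  structure(list(X_s = X_s, v_w = v_w, v_s = v_s), class = "mixture_spec")
}

#' Sum of water and solute molar concentrations
#'
#' From the definitions `c_w + c_s = (n_w + n_s) / (n_w v_w + n_s v_s)` and
#' `X_s = n_s / (n_w + n_s)`:
#' `c_w + c_s = (1 / v_w) / (1 + X_s (v_s/v_w - 1))`.
#' When the solute is volumetrically identical to water
#' (`v_s = v_w = v_w0`, e.g. heavy water) this is 55.5 M at every mole
#' fraction; in general the sum — and hence the water concentration at fixed
#' solute concentration — depends on the solute species through `v_s/v_w`.
#'
#' @param spec a [mixture_spec()].
#' @return total concentration `c_w + c_s` \[mol m^-3\].
#' @examples
#' from_si_concentration(concentration_sum(mixture_spec(X_s = 0.01)))  # 55.5 M
#' @export
concentration_sum <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  denom <- 1 + spec$X_s * (spec$v_s / spec$v_w - 1)
  if (denom <= 0)
    stop(sprintf("nonphysical volumes: 1 + X_s (v_s/v_w - 1) = %g <= 0", denom),
         call. = FALSE)
  (1 / spec$v_w) / denom
}

#' Water and solute concentrations of a mixture
#'
#' Explicit mole bookkeeping at `n_w + n_s = 1`: the individual
#' concentrations `c_w = (1 - X_s) / V` and `c_s = X_s / V` with
#' `V = (1 - X_s) v_w + X_s v_s`.
#'
#' @inheritParams concentration_sum
#' @return named numeric vector `c(c_w, c_s)` \[mol m^-3\].
#' @export
mixture_concentrations <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  V <- (1 - spec$X_s) * spec$v_w + spec$X_s * spec$v_s
  if (V <= 0) stop("nonphysical volumes: total molar volume <= 0", call. = FALSE)
  c(c_w = (1 - spec$X_s) / V, c_s = spec$X_s / V)
}

#' Water-concentration deficit of a dilute solution
#'
#' `c_w(pure water) - c_w(solution)` for a dilute solution of concentration
#' `solute_conc` whose solute has partial molar volume `v_s`.  Exact mole
#' balance at unit solution volume gives `delta_c_w = c_s v_s / v_w0`: at
#' fixed solute concentration the water-concentration difference scales
#' with the solute's molar volume, i.e. it is specific to the solute
#' species (only a `v_s = v_w0` solute such as heavy water gives
#' `delta_c_w = c_s`).  A species-specific driver cannot underlie osmotic
#' flow, which is observed to depend on osmolarity alone — the quantitative
#' form of the argument against the water-concentration-gradient picture.
#'
#' @param solute_conc solute concentration `c_s` \[mol m^-3\], >= 0.
#' @param v_s partial molar volume of the solute \[m^3 mol^-1\], > 0.
#' @param v_w0 molar volume of pure water \[m^3 mol^-1\].
#' @param dilute_limit maximum admissible volume fraction `c_s v_s`
#'   (default 0.1); beyond it the dilute-regime formula is refused.
#' @return water-concentration difference \[mol m^-3\].
#' @examples
#' water_concentration_difference(100, v_s = v_w0_default)   # = 100
#' water_concentration_difference(100, v_s = 2 * v_w0_default)  # = 200
#' @export
water_concentration_difference <- function(solute_conc, v_s,
                                           v_w0 = v_w0_default,
                                           dilute_limit = 0.1) {
  .check_scalar(solute_conc, "solute_conc", lower = 0)
  .check_scalar(v_s, "v_s", lower = 0, strict = TRUE)
  .check_scalar(v_w0, "v_w0", lower = 0, strict = TRUE)
  frac <- solute_conc * v_s
  if (frac > dilute_limit)
    stop(sprintf("not dilute: c_s * v_s = %g exceeds %g; the dilute-regime formula does not apply",
                 frac, dilute_limit), call. = FALSE)
  # unit solution volume: n_s = c_s, water fills the rest: c_w = (1 - c_s v_s)/v_w0
  (1 / v_w0) - (1 - frac) / v_w0
}
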