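#' Physical constants and unit conventions
#'
#' All quantities inside the package are SI: concentrations in mol m^-3,
#' pressures in Pa, lengths in m, temperatures in K.  Conversions from the
#' bench units commonly used in configs (M, mM, atm) are explicit helper
#' functions; nothing converts implicitly.
#'
#' * `R_gas` — universal gas constant, 8.314 J mol^-1 K^-1.
#' * `N_avogadro` — Avogadro constant, mol^-1.
#' * `v_w0_default` — molar volume of pure water, 1.802e-5 m^3 mol^-1,
#'   the reciprocal of the 55.5 M concentration of pure water.
#' * `atm_Pa` — one standard atmosphere in Pa.
#'
#' @name constants
#' @aliases R_gas N_avogadro v_w0_default atm_Pa
NULL

#' @export
R_gas <- 8.314

#' @export
N_avogadro <- 6.02214076e23

#' @export
v_w0_default <- 1.802e-5

#' @export
atm_Pa <- 101325

#' Default absolute temperature \[K\]
#'
#' Used whenever a temperature is not supplied explicitly (298.15 K, 25 C).
#' @export
default_temperature <- 298.15

.check_scalar <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  invisible(x)
}

#' Unit conversions
#'
#' Molar concentration (mol L^-1) to the internal SI unit mol m^-3, and back;
#' atmospheres to pascal, and back.  Negative concentrations are rejected.
#'
#' @param value numeric vector of values to convert.
#' @return the converted numeric vector.
#' @examples
#' to_si_concentration(1)      # 1 M  -> 1000 mol/m^3
#' to_si_concentration(55.5)   # pure water -> 55500 mol/m^3
#' pa_to_atm(atm_to_pa(2.5))   # round trip
#' @export
to_si_concentration <- function(value) {
  if (!is.numeric(value) || anyNA(value))
    stop("concentration must be numeric and non-missing", call. = FALSE)
  if (any(value < 0))
    stop("concentration must be >= 0", call. = FALSE)
  value * 1000
}

#' @rdname to_si_concentration
#' @export
from_si_concentration <- function(value) {
  if (!is.numeric(value) || anyNA(value))
    stop("concentration must be numeric and non-missing", call. = FALSE)
  if (any(value < 0))
    stop("concentration must be >= 0", call. = FALSE)
  value / 1000
}

#' @rdname to_si_concentration
#' @export
atm_to_pa <- function(value) {
  if (!is.numeric(value) || anyNA(value))
    stop("pressure must be numeric and non-missing", call. = FALSE)
  value * atm_Pa
}

#' @rdname to_si_concentration
#' @export
pa_to_atm <- function(value) {
  if (!is.numeric(value) || anyNA(value))
    stop("pressure must be numeric and non-missing", call. = FALSE)
  value / atm_Pa
}
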