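#' Parameters of the pump-leak toy cell
#'
#' A spherical "cell" with a pliant membrane permeable to water and to a
#' single uncharged solute A, placed in an infinite bath.  Exchange of A is
#' first order with rate constant `k`; the cell may contain `b` moles of an
#' uncharged impermeant solute B; the bath may contain an impermeant at
#' concentration `B_e`; a pump may remove A from the cell at constant rate
#' `p`.  Because the membrane is pliant the pressure difference stays near
#' zero and any osmotic imbalance moves water: the volume responds as
#' `dw/dt = lam * (osmolarity_in - osmolarity_out)`.
#'
#' @param k first-order exchange rate of A \[s^-1\], >= 0.
#' @param A_e external concentration of A \[mol m^-3\], >= 0.
#' @param b moles of internal impermeant B \[mol\], >= 0.
#' @param B_e external impermeant concentration \[mol m^-3\], >= 0.
#' @param p pump rate removing A from the cell \[mol m^-3 s^-1\], >= 0.
#' @param lam osmotic volume coupling \[m^3 s^-1 per mol m^-3\], >= 0.
#' @return an object of class `donnan_params`.
#' @export
donnan_params <- function(k, A_e, b = 0, B_e = 0, p = 0, lam = 0) {
  for (nm in c("k", "A_e", "b", "B_e", "p", "lam"))
    .check_scalar(get(nm), nm, lower = 0)
  structure(list(k = k, A_e = A_e, b = b, B_e = B_e, p = p, lam = lam),
            class = "donnan_params")
}

#' State of the toy cell
#'
#' @param w cell volume \[m^3\], > 0.
#' @param A_in internal concentration of the permeant A \[mol m^-3\], >= 0.
#' @param t time \[s\].
#' @return an object of class `donnan_state`.
#' @export
donnan_state <- function(w, A_in, t = 0) {
  .check_scalar(w, "w", lower = 0, strict = TRUE)
  .check_scalar(A_in, "A_in", lower = 0)
  .check_scalar(t, "t")
  structure(list(w = w, A_in = A_in, t = t), class = "donnan_state")
}

#' Time derivatives of the pump-leak cell
#'
#' `dA_in/dt = k (A_e - A_in) - p` (first-order exchange, literal
#' concentration form, minus the pump) and
#' `dw/dt = lam (A_in + b/w - A_e - B_e)` (water follows the osmotic
#' imbalance; internal osmolarity is the permeant plus the impermeant at
#' `b/w`).  With `b = 0` the cell equilibrates at `A_in = A_e` and is
#' stable; with an internal impermeant and no external impermeant or pump,
#' both constraints can only be met as `w` grows without bound.
#'
#' @param state a [donnan_state()].
#' @param params a [donnan_params()].
#' @return named numeric vector `c(dA_in, dw)`.
#' @export
donnan_rhs <- function(state, params) {
  stopifnot(inherits(state, "donnan_state"), inherits(params, "donnan_params"))
  if (state$w <= 0) stop("cell volume must stay positive", call. = FALSE)
  dA <- params$k * (params$A_e - state$A_in) - params$p
  dw <- params$lam * (state$A_in + params$b / state$w - params$A_e - params$B_e)
  c(dA_in = dA, dw = dw)
}

#' Simulate the pump-leak cell
#'
#' Adaptive ODE integration (`deSolve::lsoda`) of [donnan_rhs()] from an
#' initial state.  `A_in` relaxes exponentially at rate `k` toward
#' `A_e - p/k`; the volume follows the regime predicted by
#' [classify_regime()].
#'
#' @param initial a [donnan_state()].
#' @param params a [donnan_params()].
#' @param t_end simulation horizon \[s\], > 0.
#' @param n_out number of output samples (including t = 0).
#' @return a data.frame of class `donnan_series` with columns `t`, `w`,
#'   `A_in`, `osm_in`, `osm_out`.
#' @examples
#' par <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, p = 0.5, lam = 1e-16)
#' out <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par,
#'                        t_end = 1000, n_out = 200)
#' tail(out, 1)$w  # -> b k / p = 3e-15
#' @export
simulate_donnan <- function(initial, params, t_end, n_out = 200) {
  stopifnot(inherits(initial, "donnan_state"), inherits(params, "donnan_params"))
  .check_scalar(t_end, "t_end", lower = 0, strict = TRUE)
  .check_scalar(n_out, "n_out", lower = 2)

  times <- seq(0, t_end, length.out = as.integer(n_out))
  rhs <- function(t, y, parms) {
    if (y[["w"]] <= 0)
      stop(sprintf("nonphysical volume collapse at t = %g (w = %g)", t, y[["w"]]),
           call. = FALSE)
    dA <- parms$k * (parms$A_e - y[["A_in"]]) - parms$p
    dw <- parms$lam * (y[["A_in"]] + parms$b / y[["w"]] - parms$A_e - parms$B_e)
    list(c(dA, dw))
  }
  y0 <- c(A_in = initial$A_in, w = initial$w)
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = times, func = rhs, parms = params,
                   rtol = 1e-10, atol = c(1e-12 * max(params$A_e, 1),
                                          1e-12 * initial$w)),
    warning = function(wrn) stop(sprintf(
      "integration failed (%s); last good state may precede t_end = %g",
      conditionMessage(wrn), t_end), call. = FALSE)
  )
  out <- data.frame(t = sol[, "time"], w = sol[, "w"], A_in = sol[, "A_in"])
  out$osm_in <- out$A_in + params$b / out$w
  out$osm_out <- params$A_e + params$B_e
  class(out) <- c("donnan_series", "data.frame")
  out
}

#' Classify the volume regime of the pump-leak cell
#'
#' \describe{
#'   \item{`stable`}{`b = 0`: the permeant equilibrates (`A_in -> A_e`) and
#'     osmolarities balance at any volume.}
#'   \item{`unbounded-swelling`}{`b > 0` with no external impermeant and no
#'     pump: the osmotic and kinetic constraints can only both hold as
#'     `w -> Inf`; water flows in without ceasing.}
#'   \item{`externally-stabilized`}{`b > 0`, `B_e > 0`, `p = 0`: finite
#'     fixed point `w* = b / B_e`.}
#'   \item{`pump-stabilized`}{`b > 0`, `p > 0`: finite fixed point; with an
#'     external impermeant as well, the combined fixed point is
#'     `w* = b / (B_e + p/k)` (pure pump: `w* = b k / p`).}
#' }
#'
#' @param params a [donnan_params()].
#' @return a character scalar regime label with attribute `w_star` (the
#'   fixed-point volume; `Inf` for unbounded swelling, `NA` for stable,
#'   where any volume is stationary).
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "donnan_params"))
  if (params$b == 0) {
    regime <- "stable"; w_star <- NA_real_
  } else if (params$p > 0) {
    regime <- "pump-stabilized"
    w_star <- params$b / (params$B_e + params$p / params$k)
  } else if (params$B_e > 0) {
    regime <- "externally-stabilized"
    w_star <- params$b / params$B_e
  } else {
    regime <- "unbounded-swelling"; w_star <- Inf
  }
  structure(regime, w_star = w_star)
}
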