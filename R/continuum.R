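#' Continuum solute-concentration and pressure profile
#'
#' Value class returned by [equilibrium_profile()], [steady_state_profile()]
#' and [numeric_ode_solution()]: a spatial grid with the solute concentration
#' `c(x)` \[mol m^-3\], the pressure `P(x)` \[Pa\], and the single scalar
#' volume flux `phi_V` \[m s^-1\] (zero at equilibrium; 1-D incompressibility
#' makes it position-independent in the steady state).
#'
#' @param x grid coordinates \[m\].
#' @param conc solute concentration at each x \[mol m^-3\].
#' @param pressure pressure at each x \[Pa\].
#' @param phi_V scalar volume flux \[m s^-1\].
#' @param meta list of provenance fields (potential, temperature, chamber
#'   states, kind).
#' @return an object of class `continuum_profile`.
#' @export
continuum_profile <- function(x, conc, pressure, phi_V, meta = list()) {
  stopifnot(length(x) == length(conc), length(x) == length(pressure))
  if (any(conc < -1e-12 * max(conc, 1)))
    stop("concentration profile has negative values", call. = FALSE)
  structure(
    list(x = x, c = pmax(conc, 0), P = pressure, phi_V = phi_V, meta = meta),
    class = "continuum_profile"
  )
}

#' @export
print.continuum_profile <- function(x, ...) {
  cat(sprintf("Continuum membrane profile (%s)\n",
              if (is.null(x$meta$kind)) "unspecified" else x$meta$kind))
  cat(sprintf("  grid      : %d points on [%g, %g] m\n",
              length(x$x), min(x$x), max(x$x)))
  cat(sprintf("  c range   : [%g, %g] mol/m^3\n", min(x$c), max(x$c)))
  cat(sprintf("  P chambers: left %g Pa, right %g Pa (delta %g Pa)\n",
              x$P[1], x$P[length(x$P)], x$P[length(x$P)] - x$P[1]))
  cat(sprintf("  phi_V     : %g m/s\n", x$phi_V))
  invisible(x)
}

#' @export
plot.continuum_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4.5, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$c, type = "l", xlab = "x [m]",
                 ylab = expression(c[s] ~ "[mol/m"^3 * "]"), ...)
  h <- if (!is.null(x$meta$potential)) x$meta$potential$h else NA_real_
  if (is.finite(h)) graphics::abline(v = c(0, h), lty = 3, col = "grey50")
  graphics::plot(x$x, x$P, type = "l", col = "red3", xlab = "x [m]",
                 ylab = "P [Pa]", ...)
  if (is.finite(h)) graphics::abline(v = c(0, h), lty = 3, col = "grey50")
  invisible(x)
}

#' Chamber-to-chamber pressure difference of a profile
#'
#' `P` at the right end of the grid minus `P` at the left end (solution side
#' minus pure-solvent side under the standard geometry).
#'
#' @param profile a [continuum_profile()].
#' @return pressure difference \[Pa\].
#' @export
chamber_pressure_difference <- function(profile) {
  stopifnot(inherits(profile, "continuum_profile"))
  profile$P[length(profile$P)] - profile$P[1]
}

#' Equilibrium Debye profile across a semipermeable membrane
#'
#' Closed-form solution of the zero-solute-flux balance between Fickian
#' diffusion and the membrane force, with pure solvent on the left and a
#' well-stirred solution of osmolarity `c_bulk_right` on the right.  Setting
#' the solute flux to zero gives the Boltzmann profile
#' `c(x) = c_r exp(-U(x)/RT)` on the solution side (and `c = 0` on the
#' solvent side, which the impermeable barrier insulates), and mechanical
#' balance of each fluid slice (`dP/dx = c F`) integrates to
#' `P(x) = P_right - RT (c_r - c(x))`.  The chamber pressure difference is
#' therefore `RT c_r (1 - exp(-U_max/RT))` — van 't Hoff's law up to the
#' quantified exclusion error, independent of the barrier shape.
#'
#' @param potential a [membrane_potential()].
#' @param c_bulk_right solution-chamber osmolarity \[mol m^-3\], >= 0.
#' @param P_right solution-chamber pressure \[Pa\].
#' @param temperature absolute temperature \[K\].
#' @param grid a [spatial_grid()]; defaults to the standard grid for the
#'   potential's thickness.
#' @return a [continuum_profile()] with `phi_V = 0`.
#' @examples
#' pot <- membrane_potential("plateau", U_max = 30 * R_gas * 300, h = 5e-9)
#' prof <- equilibrium_profile(pot, c_bulk_right = 100, temperature = 300)
#' chamber_pressure_difference(prof)  # ~ RT c = 249420 Pa
#' @export
equilibrium_profile <- function(potential, c_bulk_right, P_right = 0,
                                temperature = default_temperature,
                                grid = NULL) {
  stopifnot(inherits(potential, "membrane_potential"))
  .check_scalar(c_bulk_right, "c_bulk_right", lower = 0)
  .check_scalar(P_right, "P_right")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  if (is.null(grid)) grid <- spatial_grid(potential$h)
  .check_grid_resolution(grid, potential)

  rt <- R_gas * temperature
  x <- grid$x
  mid <- potential$h / 2
  U <- potential_energy(potential, x)
  bolt <- exp(-U / rt)
  conc <- ifelse(x >= mid, c_bulk_right * bolt, 0)
  # anchor at the attained barrier-top energy U(h/2); for an impermeable
  # barrier this is U_max to within the stated exclusion error
  U_top <- potential_energy(potential, mid)
  P_left <- P_right - rt * c_bulk_right * (1 - exp(-U_top / rt))
  pressure <- ifelse(x >= mid, P_right - rt * (c_bulk_right - conc), P_left)

  continuum_profile(x, conc, pressure, phi_V = 0,
                    meta = list(kind = "equilibrium", potential = potential,
                                temperature = temperature,
                                c_right = c_bulk_right, c_left = 0,
                                P_right = P_right, P_left = P_left))
}

#' Osmotic steady-state (Vegard) profile
#'
#' Profile across an impermeable membrane separating two large well-stirred
#' chambers whose osmolarities and pressures are held fixed.  The interfaces
#' remain quasi-equilibrated (the Boltzmann relation between concentration
#' gradient and membrane force continues to hold there), which produces a
#' pressure drop of `RT c_s` at each solution-side interface — the Vegard
#' drop.  Across the membrane interior, where the solute concentration and
#' its gradient vanish, the pressure falls linearly with slope
#' `-phi_V / (h Lp)`, the Darcy gradient that actually carries the water.
#' The resulting scalar flux is exactly the combined flux law
#' `phi_V = -Lp (delta_P - RT delta_c)`.
#'
#' The solver is semi-analytic: Boltzmann interface factors composed with an
#' exactly linear Darcy segment on `[0, h]` (the interface width enters the
#' concentration profile but not the partition of the pressure drop, which
#' is the sharp-interface idealization the integral argument across a narrow
#' interface justifies).
#'
#' @param potential a [membrane_potential()]; must be impermeable
#'   (`U_max >= 30 RT`), leaky membranes are out of scope.
#' @param Lp hydraulic permeability \[m s^-1 Pa^-1\], >= 0.
#' @param left,right [solution_state()] objects for the two chambers
#'   (left = lower-x side).
#' @param temperature absolute temperature \[K\]; defaults to the chamber
#'   states' common temperature.
#' @param grid a [spatial_grid()]; defaults to the standard grid.
#' @return a [continuum_profile()] whose `phi_V` is the steady volume flux.
#' @examples
#' pot <- membrane_potential("plateau", U_max = 30 * R_gas * 300, h = 5e-9)
#' prof <- steady_state_profile(pot, Lp = 1e-12,
#'                              left = solution_state(0, 0, 300),
#'                              right = solution_state(100, 0, 300))
#' prof$phi_V          # +2.4942e-7 m/s, toward the solution
#' vegard_drop(prof)   # ~ RT c = 249420 Pa
#' @export
steady_state_profile <- function(potential, Lp, left, right,
                                 temperature = NULL, grid = NULL) {
  stopifnot(inherits(potential, "membrane_potential"),
            inherits(left, "solution_state"),
            inherits(right, "solution_state"))
  .check_scalar(Lp, "Lp", lower = 0)
  if (is.null(temperature)) {
    if (abs(left$temperature - right$temperature) > 1e-9 * left$temperature)
      stop("chamber temperatures differ; pass `temperature` explicitly",
           call. = FALSE)
    temperature <- left$temperature
  }
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  if (!is_impermeable(potential, temperature))
    stop(sprintf(paste0("barrier is not in the impermeable regime ",
                        "(U_max = %g RT < 30 RT); leaky membranes are out of scope"),
                 potential$U_max / (R_gas * temperature)), call. = FALSE)
  if (is.null(grid)) grid <- spatial_grid(potential$h)
  .check_grid_resolution(grid, potential)

  rt <- R_gas * temperature
  h <- potential$h
  x <- grid$x
  mid <- h / 2
  delta_P <- right$pressure - left$pressure
  delta_c <- right$osmolarity - left$osmolarity
  phi_V <- -Lp * (delta_P - rt * delta_c)
  lin <- delta_P - rt * delta_c        # total Darcy part of the drop

  U <- potential_energy(potential, x)
  bolt <- exp(-U / rt)
  ramp <- pmin(pmax(x / h, 0), 1)
  on_right <- x >= mid
  conc <- ifelse(on_right, right$osmolarity * bolt, left$osmolarity * bolt)
  pressure <- ifelse(
    on_right,
    right$pressure + rt * (conc - right$osmolarity) + lin * (ramp - 1),
    left$pressure + rt * (conc - left$osmolarity) + lin * ramp
  )

  continuum_profile(x, conc, pressure, phi_V = phi_V,
                    meta = list(kind = "steady_state", potential = potential,
                                temperature = temperature, Lp = Lp,
                                c_right = right$osmolarity,
                                c_left = left$osmolarity,
                                P_right = right$pressure,
                                P_left = left$pressure))
}

#' Vegard pressure drop at the solution-side interface
#'
#' The pressure drop from the bulk solution to just inside the membrane on
#' the solution side: the linear intramembrane (Darcy) segment is identified
#' around the membrane midpoint — where the solute concentration vanishes —
#' and extrapolated to the solution-side face at `x = h`; the drop is the
#' bulk solution pressure minus that extrapolated face pressure.  In the
#' impermeable regime it equals `RT c_s,r` for both the equilibrium and the
#' steady-state profile: the drop is a property of the interface alone, not
#' of the flow.
#'
#' @param profile a [continuum_profile()] from [equilibrium_profile()],
#'   [steady_state_profile()] or [numeric_ode_solution()].
#' @return interface pressure drop \[Pa\].
#' @export
vegard_drop <- function(profile) {
  stopifnot(inherits(profile, "continuum_profile"))
  pot <- profile$meta$potential
  if (is.null(pot))
    stop("profile carries no membrane description; cannot locate the interface",
         call. = FALSE)
  h <- pot$h
  mid <- h / 2
  sel <- abs(profile$x - mid) <= max(pot$interface_width, h / 50)
  if (sum(sel) < 3)
    stop("profile grid does not resolve the membrane interior around x = h/2",
         call. = FALSE)
  fit <- stats::lm(P ~ x, data = data.frame(x = profile$x[sel],
                                            P = profile$P[sel]))
  P_face_inside <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * h)
  profile$P[length(profile$P)] - P_face_inside
}

#' Direct numerical integration of the equilibrium balance laws
#'
#' Independent cross-check of [equilibrium_profile()]: the coupled ODEs for
#' the zero-flux solute balance (`RT dc/dx = c F`) and the mechanical slice
#' balance (`dP/dx = c F`) are integrated with `deSolve::lsoda` from the
#' solution bulk inward to the barrier top at `x = h/2`.  The barrier
#' interior is the zero-flux insulation between the two chambers, so the
#' pure-solvent side is closed with `c = 0` and constant pressure, exactly
#' as in the closed form.  Agreement with the Boltzmann closed form is at
#' the integrator tolerance (well below 1e-8 of the bulk concentration).
#'
#' @inheritParams equilibrium_profile
#' @return a [continuum_profile()] with `phi_V = 0`.
#' @export
numeric_ode_solution <- function(potential, c_bulk_right, P_right = 0,
                                 temperature = default_temperature,
                                 grid = NULL) {
  stopifnot(inherits(potential, "membrane_potential"))
  .check_scalar(c_bulk_right, "c_bulk_right", lower = 0)
  .check_scalar(P_right, "P_right")
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  if (is.null(grid)) grid <- spatial_grid(potential$h)
  .check_grid_resolution(grid, potential)

  rt <- R_gas * temperature
  x <- grid$x
  mid <- potential$h / 2
  right_idx <- which(x >= mid)
  xs <- x[right_idx]
  # anchor the solvent side at the barrier top exactly, not at the nearest node
  added_mid <- xs[1] > mid
  if (added_mid) xs <- c(mid, xs)

  rhs <- function(xx, y, parms) {
    Fm <- membrane_force(potential, xx)
    list(c(y[1] * Fm / rt, y[1] * Fm))
  }
  y0 <- c(conc = c_bulk_right, P = P_right)
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = rev(xs), func = rhs, parms = NULL,
                   rtol = 1e-13,
                   atol = c(1e-17 * max(c_bulk_right, 1),
                            1e-17 * max(rt * c_bulk_right, 1))),
    warning = function(w) stop(sprintf(
      "ODE integration of the interface region failed near x in [%g, %g]: %s",
      mid, max(xs), conditionMessage(w)), call. = FALSE)
  )
  conc_r <- rev(sol[, "conc"])
  P_r <- rev(sol[, "P"])
  P_mid <- P_r[1]
  if (added_mid) { conc_r <- conc_r[-1]; P_r <- P_r[-1] }

  conc <- numeric(length(x))
  pressure <- numeric(length(x))
  conc[right_idx] <- pmax(conc_r, 0)
  pressure[right_idx] <- P_r
  left_idx <- setdiff(seq_along(x), right_idx)
  conc[left_idx] <- 0
  pressure[left_idx] <- P_mid

  continuum_profile(x, conc, pressure, phi_V = 0,
                    meta = list(kind = "numeric_equilibrium",
                                potential = potential,
                                temperature = temperature,
                                c_right = c_bulk_right, c_left = 0,
                                P_right = P_right, P_left = P_mid))
}
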