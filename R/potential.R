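#' Repulsive membrane-solute potential
#'
#' The semipermeable membrane is modelled as a smooth repulsive potential
#' `U(x) >= 0` acting on solute molecules, occupying the interval `[0, h]`
#' on the x axis and decaying to zero in both bulk chambers.  The force the
#' membrane exerts on a solute molecule is `F(x) = -dU/dx` \[J mol^-1 m^-1\],
#' finite everywhere — an idealized infinitely hard membrane is replaced by a
#' finite smooth barrier, with the exclusion error quantified by
#' `exp(-U_max / RT)`.  A barrier is declared *impermeable* when
#' `U_max >= 30 RT` (exclusion error below 1e-13).
#'
#' Two shapes are provided:
#' \describe{
#'   \item{`"plateau"`}{difference of two logistic steps of width
#'     `interface_width` centred at `x = 0` and `x = h`; flat top of height
#'     `U_max` across the membrane interior.}
#'   \item{`"gaussian"`}{Gaussian bump of height `U_max` centred at `h/2`
#'     with standard deviation `interface_width`.}
#' }
#' The closed-form results the package tests (chamber pressure difference,
#' Vegard drop) are invariant under the choice of shape: the membrane force
#' profile cancels from the final results.
#'
#' @param shape `"plateau"` or `"gaussian"`.
#' @param U_max barrier height \[J mol^-1\], >= 0.
#' @param h membrane thickness (the span `[0, h]`) \[m\], > 0.
#' @param interface_width smoothing length of each membrane edge \[m\];
#'   default `h/20`.
#' @return an object of class `membrane_potential`.
#' @examples
#' pot <- membrane_potential("plateau", U_max = 30 * R_gas * 300, h = 5e-9)
#' potential_energy(pot, c(-1e-9, 2.5e-9, 6e-9))
#' @export
membrane_potential <- function(shape = c("plateau", "gaussian"), U_max, h,
                               interface_width = h / 20) {
  shape <- match.arg(shape)
  .check_scalar(U_max, "U_max", lower = 0)
  .check_scalar(h, "h", lower = 0, strict = TRUE)
  .check_scalar(interface_width, "interface_width", lower = 0, strict = TRUE)
  if (shape == "plateau" && interface_width > h / 4)
    stop("interface_width must be <= h/4 for a plateau barrier to have a flat top",
         call. = FALSE)
  if (shape == "gaussian" && interface_width > h / 6)
    stop("interface_width must be <= h/6 for a gaussian barrier to vanish in the chambers",
         call. = FALSE)
  structure(
    list(shape = shape, U_max = U_max, h = h, interface_width = interface_width),
    class = "membrane_potential"
  )
}

#' @export
print.membrane_potential <- function(x, ...) {
  cat(sprintf("Membrane potential: %s barrier, U_max = %g J/mol, h = %g m, edge width = %g m\n",
              x$shape, x$U_max, x$h, x$interface_width))
  invisible(x)
}

#' Evaluate the membrane potential and force
#'
#' `potential_energy()` returns `U(x)` \[J mol^-1\]; `membrane_force()`
#' returns the analytic force `F(x) = -dU/dx` \[J mol^-1 m^-1\], finite for
#' all x.
#'
#' @param potential a [membrane_potential()].
#' @param x numeric vector of positions \[m\].
#' @return numeric vector of the same length as `x`.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "membrane_potential"))
  w <- potential$interface_width; h <- potential$h; U <- potential$U_max
  switch(potential$shape,
    plateau  = U * (stats::plogis(x / w) - stats::plogis((x - h) / w)),
    gaussian = U * exp(-(x - h / 2)^2 / (2 * w^2))
  )
}

#' @rdname potential_energy
#' @export
membrane_force <- function(potential, x) {
  stopifnot(inherits(potential, "membrane_potential"))
  w <- potential$interface_width; h <- potential$h; U <- potential$U_max
  switch(potential$shape,
    plateau = {
      s0 <- stats::plogis(x / w); s1 <- stats::plogis((x - h) / w)
      -U / w * (s0 * (1 - s0) - s1 * (1 - s1))
    },
    gaussian = U * (x - h / 2) / w^2 * exp(-(x - h / 2)^2 / (2 * w^2))
  )
}

#' Is the barrier in the impermeable regime?
#'
#' `TRUE` when `U_max >= 30 RT`, i.e. the Boltzmann exclusion error
#' `exp(-U_max/RT)` is below 1e-13 and the membrane is effectively
#' solute-tight.
#'
#' @inheritParams potential_energy
#' @param temperature absolute temperature \[K\].
#' @export
is_impermeable <- function(potential, temperature = default_temperature) {
  stopifnot(inherits(potential, "membrane_potential"))
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  potential$U_max >= 30 * R_gas * temperature
}

#' Spatial grid for continuum profiles
#'
#' Strictly increasing coordinates spanning `[-chamber_width, h +
#' chamber_width]` with the membrane on `[0, h]` and the solution chamber on
#' the right.  The default (2001 points, chambers 5 h wide) resolves the
#' default membrane edges.
#'
#' @param h membrane thickness \[m\], > 0.
#' @param chamber_width width of each bulk chamber \[m\]; default `5 * h`.
#' @param n number of grid points, default 2001.
#' @return an object of class `spatial_grid` with fields `x`, `h`,
#'   `chamber_width`.
#' @export
spatial_grid <- function(h, chamber_width = 5 * h, n = 2001) {
  .check_scalar(h, "h", lower = 0, strict = TRUE)
  .check_scalar(chamber_width, "chamber_width", lower = 0, strict = TRUE)
  .check_scalar(n, "n", lower = 8, strict = FALSE)
  x <- seq(-chamber_width, h + chamber_width, length.out = as.integer(n))
  structure(list(x = x, h = h, chamber_width = chamber_width),
            class = "spatial_grid")
}

# Require >= 20 grid points across each ~4*interface_width edge transition
# (dx <= interface_width / 5); error names the resolution actually needed.
.check_grid_resolution <- function(grid, potential) {
  stopifnot(inherits(grid, "spatial_grid"))
  dx <- max(diff(grid$x))
  need <- potential$interface_width / 5
  if (dx > need) {
    n_req <- ceiling(diff(range(grid$x)) / need) + 1
    stop(sprintf(paste0("grid too coarse to resolve the membrane interface: ",
                        "spacing %g m exceeds interface_width/5 = %g m; ",
                        "use at least %d points over this span"),
                 dx, need, n_req), call. = FALSE)
  }
  invisible(TRUE)
}
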