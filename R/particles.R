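#' Configuration for the Brownian-dynamics membrane simulation
#'
#' Overdamped Langevin (Brownian) dynamics of `N` ideal, non-interacting
#' solute particles in a 1-D closed chamber bounded by reflecting walls,
#' with the membrane represented purely by its repulsive potential.  The
#' solvent is implicit: it enters only through the mobility
#' `mu = D_s / RT` (Einstein relation) and the thermal noise.  The chamber
#' is one-sided: the left reflecting wall sits at the barrier-plateau
#' midpoint `h/2` (deep inside the membrane), the solution chamber extends
#' to `box_max` on the right, and the membrane's right edge is the
#' interface the solute pushes against.
#'
#' Positions advance by Euler-Maruyama: drift `mu F(x) dt` plus diffusion
#' `sqrt(2 D_s dt) xi`.  The default time step satisfies
#' `mu |F|_max dt = interface_width / 25`, 2.5 times stricter than the
#' stability bound `mu |F|_max dt <= interface_width / 10` below which the
#' scheme is accepted at all (a configured `dt` beyond the stability bound
#' is refused with a suggested value).  The default balances the O(dt)
#' invariant-measure bias of the Euler scheme against the need to cover
#' many interface-occupancy correlation times, which is what makes the
#' averaging blocks statistically independent.  For the same reason the
#' default chamber is compact: the occupancy of the interface region
#' decorrelates by particle exchange with the whole chamber, on a timescale
#' that grows with the chamber length, so an unnecessarily long box makes
#' the block standard error dishonest without improving the physics.
#'
#' In reduced mode lengths are naturally expressed in interface widths and
#' `RT = 1` (pass `temperature` as the reduced temperature, default 1);
#' Avogadro's number is also 1, so concentrations are particles per volume.
#'
#' @param potential a [membrane_potential()].
#' @param N particle count.
#' @param D_s solute diffusion constant \[m^2 s^-1\].
#' @param temperature absolute temperature \[K\] (reduced temperature when
#'   `reduced = TRUE`).
#' @param box length-2 numeric, reflecting-wall positions; default
#'   `c(h/2, 2 h)` (left wall at the plateau midpoint, bulk chamber one
#'   membrane-thickness long).
#' @param dt time step \[s\]; default from the accuracy rule above.
#' @param n_steps number of measured steps.
#' @param n_equilibration discarded equilibration steps; default
#'   `n_steps / 5`.
#' @param seed RNG seed (integer).
#' @param cross_section_area nominal membrane area \[m^2\] used to convert
#'   summed molar forces to force per area; default 1.
#' @param reduced logical; reduced-unit mode (`RT = 1`, Avogadro = 1).
#' @param n_bins histogram bins across the box.
#' @param n_blocks independent averaging blocks for the standard error
#'   (>= 20 unless fewer steps are available).
#' @return an object of class `particle_sim_config`.
#' @export
particle_sim_config <- function(potential, N = 10000, D_s, temperature = NULL,
                                box = NULL, dt = NULL, n_steps = 1e5,
                                n_equilibration = NULL, seed = 1,
                                cross_section_area = 1, reduced = FALSE,
                                n_bins = 200, n_blocks = 20) {
  stopifnot(inherits(potential, "membrane_potential"))
  .check_scalar(N, "N", lower = 1)
  .check_scalar(D_s, "D_s", lower = 0, strict = TRUE)
  if (is.null(temperature)) temperature <- if (reduced) 1 else default_temperature
  .check_scalar(temperature, "temperature", lower = 0, strict = TRUE)
  .check_scalar(cross_section_area, "cross_section_area", lower = 0, strict = TRUE)
  .check_scalar(seed, "seed")
  .check_scalar(n_steps, "n_steps", lower = 1)
  if (is.null(n_equilibration)) n_equilibration <- floor(n_steps / 5)
  .check_scalar(n_equilibration, "n_equilibration", lower = 0)
  .check_scalar(n_blocks, "n_blocks", lower = 2)
  if (n_blocks < 20 && n_steps >= 20)
    stop("use at least 20 averaging blocks for a trustworthy standard error",
         call. = FALSE)

  rt <- (if (reduced) 1 else R_gas) * temperature
  mu <- D_s / rt
  if (is.null(box)) box <- c(potential$h / 2, 2 * potential$h)
  stopifnot(length(box) == 2, box[1] < box[2])
  if (box[1] < potential$h / 2 - 1e-12 * potential$h && potential$shape == "plateau")
    stop("left wall must sit at or right of the plateau midpoint h/2 (one-sided chamber)",
         call. = FALSE)

  f_max <- .max_force(potential)
  if (is.null(dt)) {
    # drift-accuracy rule, capped by the diffusive resolution of the
    # interface (relevant for weak or absent barriers)
    dt <- min(potential$interface_width / (25 * mu * f_max),
              potential$interface_width^2 / (2 * D_s))
  }
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)

  structure(
    list(potential = potential, N = as.integer(N), D_s = D_s,
         temperature = temperature, rt = rt, mu = mu, box = box, dt = dt,
         n_steps = as.integer(n_steps),
         n_equilibration = as.integer(n_equilibration),
         seed = as.integer(seed), cross_section_area = cross_section_area,
         reduced = reduced, n_bins = as.integer(n_bins),
         n_blocks = as.integer(n_blocks)),
    class = "particle_sim_config"
  )
}

# analytic maximum of |F| for each barrier shape
.max_force <- function(potential) {
  w <- potential$interface_width
  if (potential$U_max == 0) return(.Machine$double.xmin)
  switch(potential$shape,
    plateau  = potential$U_max / (4 * w),
    gaussian = potential$U_max / w * exp(-0.5)
  )
}

#' Bulk concentration implied by a particle configuration
#'
#' The Boltzmann-equilibrium bulk (zero-potential) concentration set by `N`
#' and the box: `c_b = (N / N_A) / (A * L_acc)` with the accessible length
#' `L_acc = integral of exp(-U/RT)` over the box.  This is the reference
#' against which the measured membrane force per area is compared
#' (`RT c_b (1 - exp(-U_max/RT))`).
#'
#' @param config a [particle_sim_config()].
#' @return bulk concentration \[mol m^-3\] (particles per volume in reduced
#'   mode).
#' @export
c_bulk_reference <- function(config) {
  stopifnot(inherits(config, "particle_sim_config"))
  avog <- if (config$reduced) 1 else N_avogadro
  xs <- seq(config$box[1], config$box[2],
            length.out = max(5001L, 50L * ceiling(diff(config$box) /
                               config$potential$interface_width)))
  bw <- exp(-potential_energy(config$potential, xs) / config$rt)
  l_acc <- sum((bw[-1] + bw[-length(bw)]) / 2) * (xs[2] - xs[1])
  (config$N / avog) / (config$cross_section_area * l_acc)
}

#' Run the Brownian-dynamics membrane simulation
#'
#' Advances the configured particles, then reports the time-averaged
#' membrane reaction force per unit area (Newton's third law: minus the
#' mean of the summed membrane forces on the particles, reported as the
#' positive push of the solute on the membrane), its standard error from
#' block averaging, and the binned concentration profile.  Runs are
#' bit-reproducible for a given config and seed.
#'
#' At equilibrium the force per area equals `RT c_b (1 - exp(-U_max/RT))`
#' where `c_b` is the bulk concentration — van 't Hoff's pressure for an
#' impermeable barrier — independent of the barrier's shape: the particle
#' statement of the mechanical derivation of osmotic pressure.
#'
#' @param config a [particle_sim_config()].
#' @return an object of class `sim_result`: fields
#'   `concentration_histogram` (data.frame `x`, `c` \[mol m^-3\]),
#'   `mean_force_per_area` \[Pa\], `stderr` \[Pa\], `trajectory_summary`
#'   (per-block force/area means), `rt_c_reference` \[Pa\], `z_score`, and
#'   the echoed `config`.
#' @examples
#' \donttest{
#' pot <- membrane_potential("plateau", U_max = 30, h = 20)
#' cfg <- particle_sim_config(pot, N = 2000, D_s = 1, reduced = TRUE,
#'                            n_steps = 5000, seed = 42)
#' res <- run_brownian(cfg)
#' res$z_score  # consistent with 0
#' }
#' @export
run_brownian <- function(config) {
  stopifnot(inherits(config, "particle_sim_config"))
  pot <- config$potential
  w <- pot$interface_width
  f_max <- .max_force(pot)
  drift <- config$mu * f_max * config$dt
  if (drift > w / 10) {
    stop(sprintf(paste0("time step violates the stability bound ",
                        "mu*|F|max*dt <= interface_width/10 ",
                        "(drift %g > %g); use dt <= %g"),
                 drift, w / 10, w / (10 * config$mu * f_max)), call. = FALSE)
  }

  set.seed(config$seed)
  # start from the Boltzmann distribution (rejection sampling), so the
  # equilibration phase only decorrelates rather than transports mass
  x0 <- numeric(0)
  while (length(x0) < config$N) {
    cand <- stats::runif(2 * config$N, config$box[1], config$box[2])
    keep <- stats::runif(length(cand)) <
      exp(-potential_energy(pot, cand) / config$rt)
    x0 <- c(x0, cand[keep])
  }
  x0 <- x0[seq_len(config$N)]

  shape_code <- if (pot$shape == "plateau") 0L else 1L
  out <- brownian_core(x0, config$mu, config$D_s, config$dt,
                       config$n_equilibration, config$n_steps,
                       config$n_blocks, config$box[1], config$box[2],
                       shape_code, pot$U_max, pot$h, w,
                       config$box[1], config$box[2], config$n_bins)

  avog <- if (config$reduced) 1 else N_avogadro
  area <- config$cross_section_area
  # push of the solute on the membrane, per unit area (sign: positive = the
  # membrane is pushed away from the solution chamber)
  block_fpa <- out$block_force / (area * avog)
  mean_fpa <- mean(block_fpa)
  se_fpa <- stats::sd(block_fpa) / sqrt(length(block_fpa))

  bw <- diff(config$box) / config$n_bins
  edges <- seq(config$box[1], config$box[2], length.out = config$n_bins + 1)
  counts <- colSums(out$hist)
  conc <- counts / out$n_steps_used / avog / (area * bw)
  hist_df <- data.frame(x = (edges[-1] + edges[-length(edges)]) / 2, c = conc)

  c_b <- c_bulk_reference(config)
  rt_c <- config$rt * c_b * (1 - exp(-pot$U_max / config$rt))
  z <- if (se_fpa > 0) (mean_fpa - rt_c) / se_fpa else NA_real_

  structure(
    list(concentration_histogram = hist_df,
         mean_force_per_area = mean_fpa,
         stderr = se_fpa,
         trajectory_summary = data.frame(block = seq_along(block_fpa),
                                         force_per_area = block_fpa),
         hist_blocks = out$hist,
         n_steps_used = out$n_steps_used,
         rt_c_reference = rt_c,
         c_bulk = c_b,
         z_score = z,
         final_positions = out$final_x,
         config = config),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Brownian membrane simulation\n")
  cat(sprintf("  N = %d, steps = %d (+%d equilibration), dt = %g, seed = %d\n",
              x$config$N, x$config$n_steps, x$config$n_equilibration,
              x$config$dt, x$config$seed))
  cat(sprintf("  force/area : %g +/- %g\n", x$mean_force_per_area, x$stderr))
  cat(sprintf("  RT c_b ref : %g (z = %.2f)\n", x$rt_c_reference, x$z_score))
  invisible(x)
}

#' Compare a simulated concentration histogram with a continuum profile
#'
#' Normalizes the simulated occupancy histogram and the closed-form
#' continuum concentration profile to unit mass over the simulation box and
#' reports the per-bin deviations with their block-sampling standard
#' errors, the supremum-norm deviation, and the largest per-bin z score.
#'
#' @param result a `sim_result` from [run_brownian()].
#' @param reference a [continuum_profile()] on a grid covering the
#'   simulation box, computed for the same membrane potential.
#' @return a list with `per_bin` (data.frame `x`, `p_sim`, `p_ref`,
#'   `deviation`, `stderr`, `z`), `max_deviation`, `max_abs_z`.
#' @export
measure_concentration_profile <- function(result, reference) {
  stopifnot(inherits(result, "sim_result"),
            inherits(reference, "continuum_profile"))
  cfg <- result$config
  ref_pot <- reference$meta$potential
  if (!is.null(ref_pot)) {
    same <- identical(ref_pot$shape, cfg$potential$shape) &&
      isTRUE(all.equal(ref_pot$h, cfg$potential$h)) &&
      isTRUE(all.equal(ref_pot$interface_width, cfg$potential$interface_width))
    if (!same)
      stop("geometry mismatch: reference profile was computed for a different membrane",
           call. = FALSE)
  }
  xb <- result$concentration_histogram$x
  if (min(xb) < min(reference$x) || max(xb) > max(reference$x))
    stop("geometry mismatch: reference grid does not cover the simulation box",
         call. = FALSE)

  p_ref <- stats::approx(reference$x, reference$c, xout = xb)$y
  if (sum(p_ref) <= 0) stop("reference profile vanishes over the box", call. = FALSE)
  p_ref <- p_ref / sum(p_ref)

  blocks <- result$hist_blocks
  block_p <- blocks / rowSums(blocks)
  p_sim <- colMeans(block_p)
  se <- apply(block_p, 2, stats::sd) / sqrt(nrow(block_p))

  dev <- p_sim - p_ref
  z <- ifelse(se > 0, dev / se, ifelse(abs(dev) < 1e-9, 0, Inf))
  list(per_bin = data.frame(x = xb, p_sim = p_sim, p_ref = p_ref,
                            deviation = dev, stderr = se, z = z),
       max_deviation = max(abs(dev)),
       max_abs_z = max(abs(z)))
}
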