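#' Run a configured scenario
#'
#' Dispatches a validated [load_config()] object to the corresponding model
#' functions and returns a machine-readable result: a `summary` list of
#' scalars and zero or more `tables` (data frames).  With `out_dir` set, the
#' summary is written as JSON, each table as CSV, and a plain-text log with
#' the resolved SI parameters, seed and package version alongside.
#'
#' Scenario outputs:
#' \describe{
#'   \item{flux}{`phi_V`, `phi_w`, `Pf`, `Pd`, `Pc_over_Pd`,
#'     `equilibrium_delta_P`.  The membrane is given either as `Lp` or as
#'     the solubility-diffusion triple `K`, `D`, `h` (then `Pf = K D / h`
#'     and `Pd = K D / h`).}
#'   \item{profile}{CSV table `x_m`, `c_mol_per_m3`, `P_Pa`; summary
#'     `delta_P_chambers`, `vegard_drop`, `phi_V`.}
#'   \item{particles}{summary `force_per_area`, `stderr`, `RTc_reference`,
#'     `z_score`; CSV histogram.}
#'   \item{donnan}{CSV time series `t`, `w`, `A_in`, `osm_in`, `osm_out`;
#'     summary `regime`, `w_star`, `w_final`, `A_in_final`.}
#'   \item{mixture}{`c_w_plus_c_s`, `c_w`, `c_s`, `delta_c_w_vs_pure`.}
#' }
#'
#' @param config a `scenario_config` from [load_config()].
#' @param out_dir optional directory for JSON/CSV/log output.
#' @param stem file-name stem for outputs; default the scenario name.
#' @return a list with elements `scenario`, `summary`, `tables`
#'   (invisibly when writing).
#' @export
run_scenario <- function(config, out_dir = NULL, stem = config$scenario) {
  stopifnot(inherits(config, "scenario_config"))
  res <- switch(config$scenario,
    flux = .run_flux(config),
    profile = .run_profile(config),
    particles = .run_particles(config),
    donnan = .run_donnan(config),
    mixture = .run_mixture(config)
  )
  res$scenario <- config$scenario
  if (!is.null(out_dir)) {
    .write_outputs(res, config, out_dir, stem)
    return(invisible(res))
  }
  res
}

.write_outputs <- function(res, config, out_dir, stem) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(res$summary, file.path(out_dir, paste0(stem, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(res$tables))
    write.csv(res$tables[[nm]],
              file.path(out_dir, paste0(stem, "_", nm, ".csv")),
              row.names = FALSE)
  writeLines(.config_log_lines(config), file.path(out_dir, paste0(stem, ".log")))
  invisible(res)
}

.run_flux <- function(config) {
  p <- config$parameters
  .require_keys(p, c("left", "right"), "parameters")
  temperature <- p$temperature
  v_w0 <- if (is.null(p$v_w0)) v_w0_default else p$v_w0
  delta_P <- p$right$pressure - p$left$pressure
  delta_c <- p$right$osmolarity - p$left$osmolarity

  if (!is.null(p$K) || !is.null(p$D) || !is.null(p$h)) {
    .require_keys(p, c("K", "D", "h"), "parameters")
    Pf <- solubility_diffusion_pf(p$K, p$D, p$h)
    Pd <- solubility_diffusion_pd(p$K, p$D, p$h)
    Lp <- Pf * v_w0 / (R_gas * temperature)
  } else {
    .require_keys(p, "Lp", "parameters")
    Lp <- p$Lp
    Pf <- pf_from_lp(Lp, temperature, v_w0)
    Pd <- p$Pd
  }
  fx <- fundamental_flux(Lp, delta_P, delta_c, temperature, v_w0)
  summary <- list(
    phi_V = fx$phi_V, phi_w = fx$phi_w, Pf = Pf,
    Pd = if (is.null(Pd)) NA else Pd,
    Pc_over_Pd = if (is.null(Pd)) NA else convective_fraction(Pf, Pd),
    equilibrium_delta_P = van_t_hoff_delta_p(delta_c, temperature)
  )
  list(summary = summary, tables = list())
}

.build_potential <- function(p) {
  pw <- p$potential
  if (is.null(pw[["interface_width"]]))
    membrane_potential(pw[["shape"]], pw[["U_max"]], pw[["h"]])
  else
    membrane_potential(pw[["shape"]], pw[["U_max"]], pw[["h"]],
                       pw[["interface_width"]])
}

.run_profile <- function(config) {
  p <- config$parameters
  .require_keys(p, c("mode", "potential"), "parameters")
  if (!p$mode %in% c("equilibrium", "steady-state"))
    stop("parameters.mode must be `equilibrium` or `steady-state`", call. = FALSE)
  pot <- .build_potential(p)
  grid <- if (is.null(p$grid)) {
    spatial_grid(pot$h)
  } else {
    spatial_grid(pot$h,
                 chamber_width = (if (is.null(p$grid$chamber_width_factor)) 5
                                  else p$grid$chamber_width_factor) * pot$h,
                 n = if (is.null(p$grid$n)) 2001 else p$grid$n)
  }
  if (p$mode == "equilibrium") {
    .require_keys(p, "right", "parameters")
    prof <- equilibrium_profile(pot, p$right$osmolarity, p$right$pressure,
                                p$temperature, grid)
  } else {
    .require_keys(p, c("Lp", "left", "right"), "parameters")
    prof <- steady_state_profile(
      pot, p$Lp,
      left = solution_state(p$left$osmolarity, p$left$pressure, p$temperature),
      right = solution_state(p$right$osmolarity, p$right$pressure, p$temperature),
      grid = grid)
  }
  list(summary = list(delta_P_chambers = chamber_pressure_difference(prof),
                      vegard_drop = vegard_drop(prof),
                      phi_V = prof$phi_V),
       tables = list(profile = data.frame(x_m = prof$x,
                                          c_mol_per_m3 = prof$c,
                                          P_Pa = prof$P)),
       profile = prof)
}

.run_particles <- function(config) {
  p <- config$parameters
  .require_keys(p, c("potential", "n_particles", "D_s", "n_steps"), "parameters")
  pot <- .build_potential(p)
  seed <- if (is.na(config$seed)) 1L else config$seed
  args <- list(potential = pot, N = p$n_particles, D_s = p$D_s,
               temperature = p$temperature, n_steps = p$n_steps, seed = seed,
               reduced = isTRUE(p$reduced))
  for (k in c("box", "dt", "n_equilibration", "cross_section_area",
              "n_bins", "n_blocks"))
    if (!is.null(p[[k]])) args[[k]] <- if (k == "box") unlist(p[[k]]) else p[[k]]
  cfg <- do.call(particle_sim_config, args)
  res <- run_brownian(cfg)
  list(summary = list(force_per_area = res$mean_force_per_area,
                      stderr = res$stderr,
                      RTc_reference = res$rt_c_reference,
                      z_score = res$z_score,
                      seed = seed, dt = cfg$dt),
       tables = list(histogram = res$concentration_histogram),
       result = res)
}

.run_donnan <- function(config) {
  p <- config$parameters
  .require_keys(p, c("k", "A_e", "lam", "w0", "t_end"), "parameters")
  par <- donnan_params(k = p$k, A_e = p$A_e,
                       b = if (is.null(p$b)) 0 else p$b,
                       B_e = if (is.null(p$B_e)) 0 else p$B_e,
                       p = if (is.null(p$p)) 0 else p$p,
                       lam = p$lam)
  init <- donnan_state(w = p$w0,
                       A_in = if (is.null(p$A0)) p$A_e else p$A0)
  series <- simulate_donnan(init, par, t_end = p$t_end,
                            n_out = if (is.null(p$n_out)) 200 else p$n_out)
  regime <- classify_regime(par)
  n <- nrow(series)
  list(summary = list(regime = as.character(regime),
                      w_star = attr(regime, "w_star"),
                      w_final = series$w[n],
                      A_in_final = series$A_in[n]),
       tables = list(timeseries = series))
}

.run_mixture <- function(config) {
  p <- config$parameters
  if (!is.null(p$c_s)) {
    .require_keys(p, "v_s", "parameters")
    v_w <- if (is.null(p$v_w)) v_w0_default else p$v_w
    delta <- water_concentration_difference(p$c_s, p$v_s, v_w)
    c_w <- 1 / v_w - delta
    summary <- list(c_w_plus_c_s = c_w + p$c_s, c_w = c_w, c_s = p$c_s,
                    delta_c_w_vs_pure = delta)
  } else {
    .require_keys(p, "X_s", "parameters")
    spec <- mixture_spec(p$X_s,
                         v_w = if (is.null(p$v_w)) v_w0_default else p$v_w,
                         v_s = if (is.null(p$v_s)) v_w0_default else p$v_s)
    both <- mixture_concentrations(spec)
    delta <- 1 / spec$v_w - both[["c_w"]]
    summary <- list(c_w_plus_c_s = concentration_sum(spec),
                    c_w = both[["c_w"]], c_s = both[["c_s"]],
                    delta_c_w_vs_pure = delta)
  }
  list(summary = summary, tables = list())
}

#' Write the canonical scenario configs
#'
#' Emits one YAML config per study scenario into `output_dir`: the van 't
#' Hoff flux example, the solubility-diffusion bilayer, the equilibrium and
#' Vegard steady-state profiles, the particle-level van 't Hoff check
#' (reduced units), the four Donnan regimes, and the 55.5 M mixture
#' identity.  Each fixture is sized to run in minutes on one CPU and is
#' deterministic at its recorded seed.
#'
#' @param output_dir writable directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
generate_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  fx <- list(
    vant_hoff_flux = list(
      scenario = "flux",
      parameters = list(temperature = 300,
                        left = list(osmolarity = 0, pressure = 0),
                        right = list(osmolarity = 100, pressure = 0),
                        Lp = 1e-12, Pd = 1e-4)
    ),
    bilayer_solubility_diffusion = list(
      scenario = "flux",
      parameters = list(temperature = 300,
                        left = list(osmolarity = 0, pressure = 0),
                        right = list(osmolarity = 100, pressure = 0),
                        K = 2e-3, D = 1e-9, h = 4e-9)
    ),
    equilibrium_profile = list(
      scenario = "profile",
      parameters = list(mode = "equilibrium", temperature = 300,
                        potential = list(shape = "plateau", U_max_rt = 30,
                                         h = 5e-9),
                        right = list(osmolarity = 100, pressure = 0))
    ),
    vegard_steady_state = list(
      scenario = "profile",
      parameters = list(mode = "steady-state", temperature = 300, Lp = 1e-12,
                        potential = list(shape = "plateau", U_max_rt = 30,
                                         h = 5e-9),
                        left = list(osmolarity = 0, pressure = 0),
                        right = list(osmolarity = 100, pressure = 0))
    ),
    particles_vant_hoff = list(
      scenario = "particles", seed = 1,
      parameters = list(reduced = TRUE, temperature = 1,
                        potential = list(shape = "plateau", U_max_rt = 30,
                                         h = 20, interface_width = 1),
                        n_particles = 10000, D_s = 1, n_steps = 100000,
                        n_equilibration = 20000)
    ),
    donnan_stable = list(
      scenario = "donnan",
      parameters = list(k = 0.05, A_e = 300, b = 0, lam = 1e-19,
                        w0 = 1e-15, A0 = 250, t_end = 1000)
    ),
    donnan_swelling = list(
      scenario = "donnan",
      parameters = list(k = 0.05, A_e = 300, b = 3e-14, lam = 1e-16,
                        w0 = 1e-15, A0 = 300, t_end = 10000)
    ),
    donnan_external = list(
      scenario = "donnan",
      parameters = list(k = 0.05, A_e = 300, b = 3e-14, B_e = 20,
                        lam = 1e-16, w0 = 1e-15, A0 = 300, t_end = 1000)
    ),
    donnan_pump = list(
      scenario = "donnan",
      parameters = list(k = 0.05, A_e = 300, b = 3e-14, p = 0.5,
                        lam = 1e-16, w0 = 1e-15, A0 = 300, t_end = 1000)
    ),
    mixture_55M = list(
      scenario = "mixture",
      parameters = list(X_s = 0.01, v_w = v_w0_default, v_s = v_w0_default)
    )
  )
  paths <- character(0)
  for (nm in names(fx)) {
    path <- file.path(output_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(fx[[nm]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
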