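#' Scenario configuration files
#'
#' Configs are plain-text YAML with a strict schema: a top-level `scenario`
#' (one of `flux`, `profile`, `particles`, `donnan`, `mixture`), an optional
#' `seed`, an optional `units` block declaring the input units
#' (`concentration`: `mol/m3`, `M` or `mM`; `pressure`: `Pa` or `atm`), a
#' `parameters` block typed per scenario, and an optional `output` block
#' with `json` / `csv` paths.  Unknown keys anywhere are rejected with the
#' offending key path.  All quantities are normalized to SI on load and the
#' resolved parameters, seed and package version are logged.
#'
#' @name config_schema
NULL

.unit_choices <- list(concentration = c("mol/m3", "M", "mM"),
                      pressure = c("Pa", "atm"))

.schemas <- list(
  flux = list(
    temperature = TRUE,
    left = list(osmolarity = TRUE, pressure = TRUE),
    right = list(osmolarity = TRUE, pressure = TRUE),
    Lp = TRUE, Pd = TRUE, v_w0 = TRUE,
    K = TRUE, D = TRUE, h = TRUE
  ),
  profile = list(
    mode = TRUE, temperature = TRUE, Lp = TRUE,
    potential = list(shape = TRUE, U_max_rt = TRUE, U_max = TRUE,
                     h = TRUE, interface_width = TRUE),
    left = list(osmolarity = TRUE, pressure = TRUE),
    right = list(osmolarity = TRUE, pressure = TRUE),
    grid = list(n = TRUE, chamber_width_factor = TRUE)
  ),
  particles = list(
    reduced = TRUE, temperature = TRUE,
    potential = list(shape = TRUE, U_max_rt = TRUE, U_max = TRUE,
                     h = TRUE, interface_width = TRUE),
    n_particles = TRUE, D_s = TRUE, dt = TRUE, n_steps = TRUE,
    n_equilibration = TRUE, box = TRUE, cross_section_area = TRUE,
    n_bins = TRUE, n_blocks = TRUE
  ),
  donnan = list(
    k = TRUE, A_e = TRUE, b = TRUE, B_e = TRUE, p = TRUE, lam = TRUE,
    w0 = TRUE, A0 = TRUE, t_end = TRUE, n_out = TRUE
  ),
  mixture = list(
    X_s = TRUE, v_w = TRUE, v_s = TRUE, c_s = TRUE
  )
)

.top_schema <- function(scenario) {
  list(scenario = TRUE, seed = TRUE,
       units = list(concentration = TRUE, pressure = TRUE),
       parameters = .schemas[[scenario]],
       output = list(json = TRUE, csv = TRUE))
}

.validate_keys <- function(node, schema, path) {
  if (!is.list(node)) return(invisible(TRUE))
  nms <- names(node)
  if (length(node) && (is.null(nms) || any(!nzchar(nms))))
    stop(sprintf("config block `%s` must have named keys", path), call. = FALSE)
  for (nm in nms) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema))
      stop(sprintf("unknown config key `%s`", here), call. = FALSE)
    sub <- schema[[nm]]
    if (is.list(sub)) .validate_keys(node[[nm]], sub, here)
  }
  invisible(TRUE)
}

.conc_factor <- function(units) {
  switch(units$concentration, "mol/m3" = 1, "M" = 1000, "mM" = 1)
}
.pres_factor <- function(units) {
  switch(units$pressure, "Pa" = 1, "atm" = atm_Pa)
}

.require_keys <- function(block, keys, path) {
  for (k in keys)
    if (is.null(block[[k]]))
      stop(sprintf("required config key `%s.%s` is missing", path, k),
           call. = FALSE)
  invisible(TRUE)
}

#' Load and validate a scenario config
#'
#' Reads a YAML config, validates it against the strict per-scenario schema
#' (unknown keys are rejected with their key path), converts declared units
#' to SI, fills documented defaults (temperature 298.15 K when unspecified),
#' and logs the resolved SI parameters and seed.
#'
#' @param path path to a YAML config file.
#' @param quiet suppress the resolved-parameter log message.
#' @return an object of class `scenario_config`: a list with `scenario`,
#'   `parameters` (SI), `seed` (integer or `NA`), `output`.
#' @seealso [generate_fixtures()] for canonical example configs.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenario) ||
      !raw$scenario %in% names(.schemas))
    stop(sprintf("config must declare `scenario` as one of: %s",
                 paste(names(.schemas), collapse = ", ")), call. = FALSE)
  scenario <- raw$scenario
  .validate_keys(raw, .top_schema(scenario), "")

  units <- modifyList(list(concentration = "mol/m3", pressure = "Pa"),
                      if (is.null(raw$units)) list() else raw$units)
  if (!units$concentration %in% .unit_choices$concentration)
    stop(sprintf("units.concentration must be one of: %s",
                 paste(.unit_choices$concentration, collapse = ", ")),
         call. = FALSE)
  if (!units$pressure %in% .unit_choices$pressure)
    stop(sprintf("units.pressure must be one of: %s",
                 paste(.unit_choices$pressure, collapse = ", ")), call. = FALSE)
  cf <- .conc_factor(units); pf <- .pres_factor(units)

  p <- if (is.null(raw$parameters)) list() else raw$parameters
  conv_state <- function(st) {
    if (is.null(st)) return(NULL)
    st$osmolarity <- if (is.null(st$osmolarity)) 0 else st$osmolarity * cf
    st$pressure <- if (is.null(st$pressure)) 0 else st$pressure * pf
    st
  }
  p$left <- conv_state(p$left)
  p$right <- conv_state(p$right)
  for (k in c("A_e", "B_e", "A0", "c_s"))
    if (!is.null(p[[k]])) p[[k]] <- p[[k]] * cf

  reduced <- isTRUE(p$reduced)
  if (is.null(p$temperature))
    p$temperature <- if (reduced) 1 else default_temperature
  rt <- (if (reduced) 1 else R_gas) * p$temperature
  if (!is.null(p$potential)) {
    .require_keys(p$potential, c("shape", "h"), "parameters.potential")
    if (!is.null(p$potential[["U_max_rt"]]) && !is.null(p$potential[["U_max"]]))
      stop("give either `potential.U_max_rt` or `potential.U_max`, not both",
           call. = FALSE)
    if (!is.null(p$potential[["U_max_rt"]])) {
      p$potential[["U_max"]] <- p$potential[["U_max_rt"]] * rt
      p$potential[["U_max_rt"]] <- NULL
    }
    .require_keys(p$potential, "U_max", "parameters.potential")
  }

  seed <- if (is.null(raw$seed)) NA_integer_ else as.integer(raw$seed)
  cfg <- structure(
    list(scenario = scenario, parameters = p, seed = seed,
         output = raw$output),
    class = "scenario_config"
  )
  if (!quiet) .log_config(cfg)
  cfg
}

.flatten_params <- function(p, prefix = "") {
  out <- character(0)
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, .flatten_params(v, key))
    else out <- c(out, sprintf("%s=%s", key, paste(format(v), collapse = ",")))
  }
  out
}

.config_log_lines <- function(cfg) {
  c(sprintf("osmoflow %s | scenario=%s | seed=%s",
            as.character(packageVersion("osmoflow")), cfg$scenario,
            if (is.na(cfg$seed)) "unset" else cfg$seed),
    paste0("  ", .flatten_params(cfg$parameters)))
}

.log_config <- function(cfg) {
  message(paste(.config_log_lines(cfg), collapse = "\n"))
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(paste(.config_log_lines(x), collapse = "\n"), "\n")
  invisible(x)
}
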