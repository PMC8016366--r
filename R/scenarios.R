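# Scenario bundles: configuration schema, packaged fixtures for the worked
# experimental setups, and the run_* entry points the command-line wrapper
# binds to.

#' Scenario bundle
#'
#' A named bundle of electrolyte, particle, pore, drive conditions and
#' entrance model describing one capture experiment.
#'
#' @param electrolyte An [electrolyte()].
#' @param particle A [particle()].
#' @param pore A [pore()].
#' @param drive A [drive_conditions()].
#' @param entrance An [entrance_model()] (default: perfect absorption).
#' @param name Scenario name.
#' @param notes Free-text provenance note.
#' @param bd Optional [bd_config()].
#' @return An object of class `"pc_scenario"`.
#' @export
scenario <- function(electrolyte, particle, pore, drive,
                     entrance = entrance_model(model = "perfect"),
                     name = "scenario", notes = "", bd = NULL) {
  stopifnot(inherits(electrolyte, "electrolyte"),
            inherits(particle, "particle"),
            inherits(pore, "pore"),
            inherits(drive, "drive_conditions"),
            inherits(entrance, "entrance_model"))
  structure(
    list(name = name, notes = notes, electrolyte = electrolyte,
         particle = particle, pore = pore, drive = drive,
         entrance = entrance, bd = bd),
    class = "pc_scenario"
  )
}

# --- schema -----------------------------------------------------------------

.scenario_schema <- list(
  electrolyte = list(
    conductivity = "conductivity", debye_length = "length",
    viscosity = "viscosity", kinematic_viscosity = "kinematic",
    density = "density", temperature = "temperature"
  ),
  particle = list(
    radius = "length", charge = "charge", dipole = "dipole",
    n_residues = NA, mobility = NA, diffusion = "kinematic"
  ),
  pore = list(
    radius = "length", length = "length", entrance_radius = "length",
    surface_charge = "surface_charge", conductance = "conductance",
    eo_conductance = "eo_conductance", access_model = NA
  ),
  drive = list(voltage = "voltage", concentration = "concentration"),
  entrance = list(
    model = NA, dG0 = "energy_kBT", barrier_coupling = NA,
    s = NA, jump_length = "length", rate = "speed"
  ),
  bd = list(dt = "time", n_walkers = NA, seed = NA, r_start = "length",
            r_out = "length", absorption = NA, k = "speed")
)

parse_section <- function(cfg, section) {
  spec <- .scenario_schema[[section]]
  raw <- cfg[[section]]
  if (is.null(raw)) return(NULL)
  unknown <- setdiff(names(raw), c(names(spec), "note", "notes"))
  if (length(unknown)) {
    stop(sprintf("scenario section '%s': unknown keys: %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (key in names(raw)) {
    if (key %in% c("note", "notes")) next
    dim <- spec[[key]]
    val <- raw[[key]]
    # strip per-field note strings
    if (is.list(val) && !is.null(val$note)) val$note <- NULL
    out[[key]] <- if (is.na(dim[1]) || is.character(val)) {
      if (is.list(val)) val$value else val
    } else {
      parse_quantity(val, dimension = dim,
                     field = paste(section, key, sep = "."))
    }
  }
  out
}

#' Load a scenario from file or from the packaged fixtures
#'
#' Scenario files are YAML (or JSON) with sections `electrolyte`,
#' `particle`, `pore`, `drive`, and optionally `entrance` and `bd`; every
#' quantity is given as `{value, unit}` and converted to SI at the
#' boundary.  Unknown keys are rejected.  The packaged fixture library is
#' listed by [list_scenarios()].
#'
#' @param x A file path, or the name of a packaged fixture (e.g.
#'   `"fig3b_dep_eo"`).
#' @return A validated [scenario()].
#' @examples
#' sc <- load_scenario("sv28_dumbbell")
#' sc$particle$dipole / (pc_constants$e * 1e-9)  # 8 e nm
#' @export
load_scenario <- function(x) {
  path <- if (file.exists(x)) {
    x
  } else {
    p <- system.file("extdata", "scenarios", paste0(x, ".yaml"),
                     package = "porecapture")
    if (!nzchar(p)) {
      stop(sprintf("no such scenario file or fixture: '%s'", x),
           call. = FALSE)
    }
    p
  }
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), c("name", "notes", names(.scenario_schema)))
  if (length(unknown)) {
    stop(sprintf("scenario: unknown top-level keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (sec in c("electrolyte", "particle", "pore", "drive")) {
    if (is.null(cfg[[sec]])) {
      stop(sprintf("scenario: missing section '%s'", sec), call. = FALSE)
    }
  }
  el <- do.call(electrolyte, parse_section(cfg, "electrolyte"))
  pa <- do.call(particle, parse_section(cfg, "particle"))
  po <- do.call(pore, parse_section(cfg, "pore"))
  dr <- do.call(drive_conditions, parse_section(cfg, "drive"))
  en <- if (is.null(cfg$entrance)) {
    entrance_model(model = "perfect")
  } else {
    do.call(entrance_model, parse_section(cfg, "entrance"))
  }
  bd <- if (is.null(cfg$bd)) NULL else do.call(bd_config,
                                               parse_section(cfg, "bd"))
  scenario(el, pa, po, dr, en,
           name = if (is.null(cfg$name)) basename(path) else cfg$name,
           notes = if (is.null(cfg$notes)) "" else cfg$notes,
           bd = bd)
}

#' @rdname load_scenario
#' @return `list_scenarios()`: character vector of packaged fixture names.
#' @export
list_scenarios <- function() {
  dir_ <- system.file("extdata", "scenarios", package = "porecapture")
  sub("\\.yaml$", "", list.files(dir_, pattern = "\\.yaml$"))
}

#' Resolved SI parameter table of a scenario
#'
#' Flattens a scenario into the full SI parameter set actually used by the
#' computations (including derived mobility, diffusion, conductances).
#' Sufficient to re-run the computation bit-identically.
#'
#' @param sc A [scenario()].
#' @return A tibble with columns `parameter`, `value`, `unit`.
#' @export
scenario_parameters <- function(sc) {
  el <- sc$electrolyte; pa <- sc$particle; po <- sc$pore; dr <- sc$drive
  tr <- particle_transport(pa, el)
  pr <- pore_resistance(po, el)
  geo <- electroosmotic_conductance(po, el)
  em <- sc$entrance
  tibble::tribble(
    ~parameter, ~value, ~unit,
    "conductivity", el$conductivity, "S/m",
    "debye_length", el$debye_length, "m",
    "viscosity", el$viscosity, "Pa*s",
    "temperature", el$temperature, "K",
    "particle_radius", pa$radius, "m",
    "particle_charge", pa$charge, "C",
    "particle_dipole", pa$dipole, "C*m",
    "n_residues", if (is.null(pa$n_residues)) NA_real_ else pa$n_residues, "",
    "mobility", tr$mobility, "m/(N*s)",
    "diffusion", tr$diffusion, "m^2/s",
    "pore_radius", po$radius, "m",
    "pore_length", po$length, "m",
    "entrance_radius", po$entrance_radius, "m",
    "surface_charge", po$surface_charge, "C/m^2",
    "conductance", pr$G, "S",
    "eo_conductance", geo, "m^3/(s*V)",
    "voltage", dr$voltage, "V",
    "concentration", dr$concentration, "1/m^3",
    "entrance_dG0", if (identical(em$model, "perfect")) NA_real_ else em$dG0,
    "kBT",
    "entrance_s", em$s, "",
    "entrance_rate_override",
    if (is.null(em$rate)) NA_real_ else em$rate, "m/s"
  )
}

#' Write a scenario back to normalized YAML (SI units)
#'
#' @param sc A [scenario()].
#' @param path Output file.
#' @export
write_scenario <- function(sc, path) {
  qy <- function(v, u) list(value = v, unit = u)
  cfg <- list(
    name = sc$name, notes = sc$notes,
    electrolyte = list(
      conductivity = qy(sc$electrolyte$conductivity, "S/m"),
      debye_length = qy(sc$electrolyte$debye_length, "m"),
      viscosity = qy(sc$electrolyte$viscosity, "Pa*s"),
      temperature = qy(sc$electrolyte$temperature, "K")
    ),
    particle = list(
      radius = qy(sc$particle$radius, "m"),
      charge = qy(sc$particle$charge, "C"),
      dipole = qy(sc$particle$dipole, "C*m")
    ),
    pore = list(
      radius = qy(sc$pore$radius, "m"),
      length = qy(sc$pore$length, "m"),
      entrance_radius = qy(sc$pore$entrance_radius, "m"),
      surface_charge = qy(sc$pore$surface_charge, "C/m^2"),
      access_model = sc$pore$access_model
    ),
    drive = list(
      voltage = qy(sc$drive$voltage, "V"),
      concentration = qy(sc$drive$concentration, "1/m^3")
    ),
    entrance = list(
      model = sc$entrance$model,
      dG0 = qy(sc$entrance$dG0, "kBT"),
      barrier_coupling = sc$entrance$barrier_coupling,
      s = sc$entrance$s
    )
  )
  if (!is.null(sc$particle$n_residues)) {
    cfg$particle$n_residues <- sc$particle$n_residues
  }
  if (!is.null(sc$particle$mobility)) {
    cfg$particle$mobility <- sc$particle$mobility
  }
  if (!is.null(sc$pore$conductance)) {
    cfg$pore$conductance <- qy(sc$pore$conductance, "S")
  }
  if (!is.null(sc$pore$eo_conductance)) {
    cfg$pore$eo_conductance <- qy(sc$pore$eo_conductance, "m^3/(s*V)")
  }
  if (!is.null(sc$entrance$jump_length)) {
    cfg$entrance$jump_length <- qy(sc$entrance$jump_length, "m")
  }
  if (!is.null(sc$entrance$rate)) {
    cfg$entrance$rate <- qy(sc$entrance$rate, "m/s")
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# --- run layer (what the CLI wraps) -----------------------------------------

#' Run a scenario computation and write artifacts
#'
#' `run_compute()` evaluates the capture result, `run_sweep()` a voltage
#' sweep, `run_profile()` the stationary concentration profile.  Each
#' writes CSV/JSON plus a parameter log when `out_dir` is given; identical
#' inputs give identical outputs.
#'
#' @param sc A [scenario()] or a fixture name / path accepted by
#'   [load_scenario()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param ... Passed to [capture_frequency()].
#' @return `run_compute()`: the `"capture_result"`, invisibly when writing.
#' @export
run_compute <- function(sc, out_dir = NULL, ...) {
  if (is.character(sc)) sc <- load_scenario(sc)
  res <- capture_frequency(sc, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(res)[!vapply(unclass(res), is.null,
                                              logical(1))],
                         file.path(out_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(scenario_parameters(sc),
                     file.path(out_dir, "parameters.csv"), row.names = FALSE)
    writeLines(c(sprintf("porecapture %s",
                         as.character(utils::packageVersion("porecapture"))),
                 sprintf("scenario: %s", sc$name)),
               file.path(out_dir, "run.log"))
    return(invisible(res))
  }
  res
}

#' @rdname run_compute
#' @param voltages Voltages for the sweep, V.
#' @export
run_sweep <- function(sc, voltages, out_dir = NULL, ...) {
  if (is.character(sc)) sc <- load_scenario(sc)
  sw <- voltage_sweep(sc, voltages, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    utils::write.csv(scenario_parameters(sc),
                     file.path(out_dir, "parameters.csv"), row.names = FALSE)
    return(invisible(sw))
  }
  sw
}

#' @rdname run_compute
#' @param r Radial grid for the profile, m; default 200 log-spaced points
#'   over `[r_e, 50 r_e]`.
#' @export
run_profile <- function(sc, r = NULL, out_dir = NULL, ...) {
  if (is.character(sc)) sc <- load_scenario(sc)
  res <- capture_frequency(sc, ...)
  r_e <- sc$pore$entrance_radius
  if (is.null(r)) r <- exp(seq(log(r_e), log(50 * r_e), length.out = 200))
  pot <- effective_potential(res$a2, res$a3, res$diffusion)
  prof <- concentration_profile(pot, sc$drive$concentration, r_e, res$k, r)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(prof, file.path(out_dir, "profile.csv"),
                     row.names = FALSE)
    return(invisible(prof))
  }
  prof
}

#' @rdname run_compute
#' @export
run_bd <- function(sc, out_dir = NULL, ...) {
  if (is.character(sc)) sc <- load_scenario(sc)
  if (is.null(sc$bd)) stop("scenario has no 'bd' section", call. = FALSE)
  res <- capture_frequency(sc, ...)
  pot <- effective_potential(res$a2, res$a3, res$diffusion)
  bd <- simulate_capture_rate(pot, sc$pore$entrance_radius, res$k,
                              sc$drive$concentration, sc$bd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(bd), file.path(out_dir, "bd.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(bd))
  }
  bd
}
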