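# Run configuration: a single structured (YAML) text file describing
# geometry, materials, load schedule, solver settings and outputs.

#' Simulation run configuration
#'
#' Bundles everything needed to reproduce a joint creep run: the case,
#' geometry parameters, the four material presets, the ramp-hold load
#' schedule, solver settings, contact/penalty parameters and the output grid.
#' All defaults are embedded; [write_run_config()] dumps them to YAML and
#' [read_run_config()] restores them losslessly (unknown keys are rejected).
#'
#' @param case `"intact"` or `"meniscectomy"`.
#' @param geometry A [joint_geometry_params()]; its `variant` is forced to
#'   `case`.
#' @param materials Named list with entries `femoral_cartilage`,
#'   `tibial_cartilage`, `meniscus`, `meniscus_absent` (see
#'   [material_presets()]).
#' @param schedule A [load_schedule()].
#' @param solver A [solver_settings()].
#' @param contact List: `penalty_scale` (auto-penalty scale, default 100),
#'   `fluid_penalty` (pressure-jump penalty of sealed interfaces, default
#'   1000), `clip` (rigid-increment clip per iteration, mm, default 0.5).
#' @param n_hold_outputs Log-spaced output times across the hold (default 20).
#' @param drainage_switch Enable the moving sealed/free-draining partition
#'   (default TRUE; disabling it forces free draining on all contact faces, a
#'   deliberately wrong boundary condition kept for mechanism regression).
#' @param seed Integer seed recorded with the run (the solver itself is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(case = c("intact", "meniscectomy"),
                       geometry = joint_geometry_params(),
                       materials = material_presets(),
                       schedule = load_schedule(),
                       solver = solver_settings(),
                       contact = list(penalty_scale = 100,
                                      fluid_penalty = 1000, clip = 0.5),
                       n_hold_outputs = 20L,
                       drainage_switch = TRUE,
                       seed = 1L) {
  case <- match.arg(case)
  geometry$variant <- case
  need <- c("femoral_cartilage", "tibial_cartilage", "meniscus",
            "meniscus_absent")
  missing_mat <- setdiff(need, names(materials))
  if (length(missing_mat)) {
    abort(paste0("Missing material preset(s): ",
                 paste(missing_mat, collapse = ", "), "."),
          class = "poroknee_config_error")
  }
  condef <- list(penalty_scale = 100, fluid_penalty = 1000, clip = 0.5)
  bad <- setdiff(names(contact), names(condef))
  if (length(bad)) {
    abort(paste0("Unknown contact key(s): ", paste(bad, collapse = ", "), "."),
          class = "poroknee_config_error")
  }
  contact <- modifyList(condef, contact)
  structure(list(case = case, geometry = geometry, materials = materials,
                 schedule = schedule, solver = solver, contact = contact,
                 n_hold_outputs = as.integer(n_hold_outputs),
                 drainage_switch = isTRUE(drainage_switch),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_field_names <- list(
  top = c("case", "geometry", "materials", "schedule", "solver", "contact",
          "n_hold_outputs", "drainage_switch", "seed"),
  geometry = c("condyle_radius", "condyle_spacing",
               "femoral_cartilage_thickness", "tibial_cartilage_thickness",
               "meniscus_inner_height", "meniscus_outer_height",
               "meniscus_width", "out_of_plane_depth", "initial_gap",
               "central_clearance", "horn_free_length", "tip_relief",
               "mesh_size", "variant"),
  material = c("name", "matrix_modulus", "poisson_ratio", "fibril_moduli",
               "permeability"),
  schedule = c("total_force", "ramp_duration", "hold_duration",
               "medial_offset", "beyond"),
  solver = c("dt_initial", "dt_max", "dt_growth", "newton_tol_rel",
             "newton_max_iter", "damp_after", "retry_budget", "verbose"),
  contact = c("penalty_scale", "fluid_penalty", "clip")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(paste0("Unknown key(s) in ", where, ": ",
                 paste(bad, collapse = ", "), "."),
          class = "poroknee_config_error")
  }
  miss <- setdiff(allowed, names(x))
  if (length(miss)) {
    abort(paste0("Missing key(s) in ", where, ": ",
                 paste(miss, collapse = ", "), "."),
          class = "poroknee_config_error")
  }
  invisible(x)
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- list(
    case = config$case,
    geometry = unclass(config$geometry),
    materials = lapply(config$materials, function(m) {
      list(name = m$name, matrix_modulus = m$matrix_modulus,
           poisson_ratio = m$poisson_ratio,
           fibril_moduli = as.list(m$fibril_moduli),
           permeability = m$permeability)
    }),
    schedule = unclass(config$schedule),
    solver = unclass(config$solver),
    contact = config$contact,
    n_hold_outputs = config$n_hold_outputs,
    drainage_switch = config$drainage_switch,
    seed = config$seed
  )
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Strict inverse of [write_run_config()]: every key must be known and every
#' section complete; offending keys are named in the error.
#'
#' @param path YAML file written by [write_run_config()] (or by hand with the
#'   same schema).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_field_names$top, "config")
  check_keys(raw$geometry, config_field_names$geometry, "geometry")
  check_keys(raw$schedule, config_field_names$schedule, "schedule")
  check_keys(raw$solver, config_field_names$solver, "solver")
  check_keys(raw$contact, config_field_names$contact, "contact")
  mats <- lapply(raw$materials, function(m) {
    check_keys(m, config_field_names$material,
               paste0("material '", m$name %||% "?", "'"))
    tissue_material(m$name, m$matrix_modulus, m$poisson_ratio,
                    unlist(m$fibril_moduli) %||% numeric(),
                    m$permeability)
  })
  geo <- do.call(joint_geometry_params, raw$geometry)
  sched <- do.call(load_schedule, raw$schedule)
  solv <- do.call(solver_settings, raw$solver)
  run_config(case = raw$case, geometry = geo, materials = mats,
             schedule = sched, solver = solv, contact = raw$contact,
             n_hold_outputs = raw$n_hold_outputs,
             drainage_switch = raw$drainage_switch, seed = raw$seed)
}
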