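# Field snapshots (legacy VTK unstructured grids), CSV/JSON run outputs and
# the command-line pipeline entry point.

vtk_num <- function(x) formatC(x, format = "g", digits = 17)

#' Export a solved state as a VTK snapshot
#'
#' Writes the mesh and solution fields of one stored state as a legacy ASCII
#' VTK unstructured grid (biquadratic quad cells): nodal displacement and
#' fluid pressure as point data; region id, fibre direction, total stress
#' components and the minimum principal total stress as cell data. The file
#' is re-readable with [read_fields()]. Output is deterministic for a fixed
#' state.
#'
#' @param run A `creep_run` (or any object with `model` and `states`).
#' @param path Output file path (`.vtk`).
#' @param time Output time of the state to export (default: end of ramp).
#' @return `path`, invisibly.
#' @export
export_fields <- function(run, path, time = NULL) {
  st <- pick_state(run, time)
  model <- run$model
  mesh <- model$mesh
  pre <- model$pre
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)

  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("poroknee state t=", vtk_num(st$t), " s (units N-mm-s-MPa), format v1")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", nn, " double")
  writeLines(paste(vtk_num(mesh$nodes[, 1L]), vtk_num(mesh$nodes[, 2L]),
                   "0"), con)
  wl("CELLS ", ne, " ", ne * 10L)
  writeLines(paste(9L, apply(mesh$elems - 1L, 1L, paste, collapse = " ")),
             con)
  wl("CELL_TYPES ", ne)
  writeLines(rep("28", ne), con)  # VTK_BIQUADRATIC_QUAD

  # nodal pressure: midside/centre nodes get the element-local interpolation
  p_full <- rep(0, nn)
  p_full[pre$pnodes] <- st$p
  corner_mean <- function(cols) rowMeans(matrix(
    p_full[mesh$elems[, cols]], ne, length(cols)))
  p_full[mesh$elems[, 5L]] <- corner_mean(c(1L, 2L))
  p_full[mesh$elems[, 6L]] <- corner_mean(c(2L, 3L))
  p_full[mesh$elems[, 7L]] <- corner_mean(c(3L, 4L))
  p_full[mesh$elems[, 8L]] <- corner_mean(c(4L, 1L))
  p_full[mesh$elems[, 9L]] <- corner_mean(1:4)

  wl("POINT_DATA ", nn)
  wl("VECTORS displacement double")
  writeLines(paste(vtk_num(st$u[, 1L]), vtk_num(st$u[, 2L]), "0"), con)
  wl("SCALARS pressure double 1")
  wl("LOOKUP_TABLE default")
  writeLines(vtk_num(p_full), con)

  fields <- recover_gp_fields(model, st)
  cell_mean <- function(m) rowMeans(m)
  regs <- sort(unique(mesh$region))
  wl("CELL_DATA ", ne)
  wl("SCALARS region_id int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(match(mesh$region, regs)), con)
  wl("VECTORS fibre double")
  writeLines(paste(vtk_num(mesh$fibre[, 1L]), vtk_num(mesh$fibre[, 2L]),
                   "0"), con)
  for (nm in c("sxx_tot", "syy_tot", "sxy_eff", "szz_tot",
               "principal_min_tot", "pressure")) {
    wl("SCALARS ", nm, " double 1")
    wl("LOOKUP_TABLE default")
    writeLines(vtk_num(cell_mean(fields[[nm]])), con)
  }
  invisible(path)
}

#' Read a VTK snapshot written by [export_fields()]
#'
#' Minimal legacy-VTK reader for the package's own snapshot layout.
#'
#' @param path `.vtk` file path.
#' @return List with `points`, `cells`, `point_data`, `cell_data`.
#' @export
read_fields <- function(path) {
  lines <- readLines(path)
  i <- grep("^POINTS ", lines)[1L]
  nn <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  pts <- matrix(scan(text = lines[(i + 1L):(i + nn)], quiet = TRUE),
                nn, 3L, byrow = TRUE)[, 1:2, drop = FALSE]
  i <- grep("^CELLS ", lines)[1L]
  ne <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  cells <- matrix(scan(text = lines[(i + 1L):(i + ne)], quiet = TRUE),
                  ne, 10L, byrow = TRUE)[, -1L, drop = FALSE] + 1L
  parse_arrays <- function(start, n) {
    out <- list()
    j <- start
    while (j <= length(lines)) {
      ln <- lines[j]
      if (grepl("^(POINT_DATA|CELL_DATA) ", ln) && j > start) break
      if (grepl("^SCALARS ", ln)) {
        nm <- strsplit(ln, " ")[[1L]][2L]
        vals <- scan(text = lines[(j + 2L):(j + 1L + n)], quiet = TRUE)
        out[[nm]] <- vals
        j <- j + 1L + n
      } else if (grepl("^VECTORS ", ln)) {
        nm <- strsplit(ln, " ")[[1L]][2L]
        vals <- matrix(scan(text = lines[(j + 1L):(j + n)], quiet = TRUE),
                       n, 3L, byrow = TRUE)[, 1:2, drop = FALSE]
        out[[nm]] <- vals
        j <- j + n
      }
      j <- j + 1L
    }
    out
  }
  ip <- grep("^POINT_DATA ", lines)[1L]
  ic <- grep("^CELL_DATA ", lines)[1L]
  list(points = pts, cells = cells,
       point_data = parse_arrays(ip + 1L, nn),
       cell_data = parse_arrays(ic + 1L, ne))
}

write_csv_with_units <- function(df, path, units = "units: N, mm, s, MPa") {
  writeLines(paste0("# ", units), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write the CSV/JSON artifacts of a creep run
#'
#' One CSV per time-series family (`series.csv`, `probes.csv`, `pairs.csv`,
#' `solver_log.csv`), a JSON summary (`summary.json`), and VTK snapshots at
#' the end of the ramp and at 60, 600 and 1200 s of hold (nearest stored
#' states).
#'
#' @param run A `creep_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_with_units(run$series, file.path(dir, "series.csv"))
  write_csv_with_units(run$probes, file.path(dir, "probes.csv"))
  write_csv_with_units(run$pairs, file.path(dir, "pairs.csv"))
  write_csv_with_units(run$log, file.path(dir, "solver_log.csv"))
  jsonlite::write_json(as.list(glance(run)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- run$config$schedule$ramp_duration
  stored <- vapply(run$states, `[[`, numeric(1), "t")
  want <- tr + c(0, 60, 600, run$config$schedule$hold_duration)
  snaps <- unique(vapply(want, function(tt) {
    stored[which.min(abs(stored - tt))]
  }, numeric(1)))
  for (tt in snaps) {
    export_fields(run, file.path(dir, sprintf("fields_t%07.0fs.vtk", tt)),
                  time = tt)
  }
  invisible(dir)
}

#' Run the pipeline from a config file
#'
#' The command-line entry point: read a YAML [run_config()], run the requested
#' case(s), and write all artifacts (CSV series, JSON summaries, VTK
#' snapshots, a plain-text log with the package version and config hash).
#' `case = "both"` also writes the intact-vs-meniscectomy comparison report.
#'
#' @param config_path YAML config path (see [write_run_config()]).
#' @param out_dir Output directory.
#' @param case `"intact"`, `"meniscectomy"` or `"both"`.
#' @param medial_offset Optional override of the load offset, mm.
#' @return Named list of `creep_run` objects, invisibly.
#' @export
cli_run <- function(config_path, out_dir, case = "both",
                    medial_offset = NULL) {
  config <- read_run_config(config_path)
  if (!is.null(medial_offset)) {
    config$schedule$medial_offset <- medial_offset
  }
  cases <- if (case == "both") c("intact", "meniscectomy") else case
  if (!all(cases %in% c("intact", "meniscectomy"))) {
    abort("`case` must be 'intact', 'meniscectomy' or 'both'.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  t0 <- Sys.time()
  for (cs in cases) {
    runs[[cs]] <- run_creep(cs, config)
    write_run_outputs(runs[[cs]], file.path(out_dir, cs))
  }
  if (length(runs) == 2L) {
    cmp <- compare_cases(runs$intact, runs$meniscectomy)
    jsonlite::write_json(
      list(flags = cmp$flags, summary = cmp$summary,
           table = cmp$table),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  log <- c(
    paste0("poroknee ", as.character(packageVersion("poroknee"))),
    paste0("config: ", normalizePath(config_path)),
    paste0("config hash: ", rlang::hash(readLines(config_path))),
    paste0("cases: ", paste(cases, collapse = ", ")),
    paste0("elapsed: ", format(Sys.time() - t0)),
    vapply(names(runs), function(cs) {
      lg <- runs[[cs]]$log
      sprintf("%s: %d steps, max %d iterations, worst residual %.2e",
              cs, nrow(lg), max(lg$iterations), max(lg$residual))
    }, character(1))
  )
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(runs)
}
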