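# Joint creep analysis: run the protocol and reduce states to the reported
# metrics (displacement, contact areas, interface/compartment load partition,
# peak compressive stress, probe fluid pressures and fluid support ratios).

creep_output_times <- function(schedule, n_hold = 20L) {
  tr <- schedule$ramp_duration
  th <- schedule$hold_duration
  c(tr, tr + th^(seq_len(n_hold) / n_hold))
}

#' Run the creep protocol on a joint case
#'
#' The full pipeline for one case: generate the geometry, assemble materials
#' and contact pairs, march the ramp-hold schedule, and reduce every stored
#' state to the output metrics. Deterministic for a fixed config.
#'
#' @param case `"intact"` or `"meniscectomy"` (overrides the config case).
#' @param config A [run_config()].
#' @return A `creep_run` object with elements `series` (per-time metric
#'   tibble), `probes` (per-probe time series), `pairs` (per-contact-pair time
#'   series), `log` (solver log), `model`, `states`, `case`, `config`,
#'   `free_travel`.
#' @examples
#' \donttest{
#' cfg <- run_config("intact",
#'                   geometry = joint_geometry_params(mesh_size = 2))
#' run <- run_creep("intact", cfg)
#' glance(run)
#' }
#' @export
run_creep <- function(case = c("intact", "meniscectomy"),
                      config = run_config()) {
  case <- match.arg(case)
  config <- run_config(
    case = case, geometry = config$geometry, materials = config$materials,
    schedule = config$schedule, solver = config$solver,
    contact = config$contact, n_hold_outputs = config$n_hold_outputs,
    drainage_switch = config$drainage_switch, seed = config$seed
  )
  model <- build_joint_model(config)
  times <- creep_output_times(config$schedule, config$n_hold_outputs)
  march <- time_march(model, times, config$solver)
  reduce_creep_run(case, config, model, march)
}

reduce_creep_run <- function(case, config, model, march) {
  states <- march$states
  probes <- define_probes(model, states[[1L]])
  series <- dplyr::bind_rows(lapply(states, function(st) {
    state_metrics(model, st)
  }))
  probe_tbl <- dplyr::bind_rows(lapply(states, function(st) {
    probe_metrics(model, st, probes)
  }))
  pair_tbl <- dplyr::bind_rows(lapply(states, function(st) {
    pair_metrics(model, st)
  }))
  structure(
    list(case = case, config = config, model = model, states = states,
         log = march$log, series = series, probes = probe_tbl,
         pairs = pair_tbl, probe_defs = probes,
         free_travel = model$free_travel),
    class = "creep_run"
  )
}

pick_state <- function(run, time = NULL) {
  stopifnot(inherits(run, "creep_run"))
  tt <- vapply(run$states, `[[`, numeric(1), "t")
  if (is.null(time)) time <- tt[1L]
  i <- which.min(abs(tt - time))
  if (abs(tt[i] - time) > 1e-6 * max(1, time)) {
    warn(paste0("No stored state at t = ", time, " s; using nearest t = ",
                tt[i], " s."))
  }
  run$states[[i]]
}

pair_force_y <- function(ct) {
  act <- ct$active & is.finite(ct$ny)
  abs(sum(ct$traction[act] * ct$A[act] * ct$ny[act]))
}

pair_metrics <- function(model, st) {
  dep <- model$depth
  ct <- st$contact
  if (is.null(ct)) return(tibble())
  ct |>
    group_by(.data$pair, .data$type, .data$compartment) |>
    summarise(
      time = st$t,
      contact_length_mm = sum(.data$A[.data$active]),
      area_mm2 = sum(.data$A[.data$active]) * dep,
      force_N = pair_force_y(dplyr::pick(dplyr::everything())) * dep,
      max_traction_MPa = max(c(0, .data$traction)),
      sealed_fraction = sum(.data$A[.data$active]) / sum(.data$A),
      .groups = "drop"
    ) |>
    select("time", dplyr::everything())
}

state_metrics <- function(model, st) {
  dep <- model$depth
  pm <- pair_metrics(model, st)
  tot <- function(sel) if (nrow(pm)) sum(pm$force_N[sel]) else 0
  area_of <- function(sel) if (nrow(pm)) sum(pm$area_mm2[sel]) else 0
  tib_side <- pm$type %in% c("fem_tib", "men_tib")
  f_med <- tot(pm$compartment == "med" & pm$type %in% c("fem_tib", "fem_men"))
  f_lat <- tot(pm$compartment == "lat" & pm$type %in% c("fem_tib", "fem_men"))
  applied <- st$applied
  fields <- recover_gp_fields(model, st)
  tib <- fields$region == "tibial"
  peak_tib <- max(-fields$principal_min_tot[tib, ], 0)
  peak_all <- max(-fields$principal_min_tot, 0)
  tibble(
    time = st$t,
    hold_time = st$t - model$schedule$ramp_duration,
    applied_N = applied,
    displacement_mm = if (!is.null(st$rigid)) -unname(st$rigid["v"]) else NA_real_,
    rotation_rad = if (!is.null(st$rigid)) unname(st$rigid["theta"]) else NA_real_,
    area_total_mm2 = area_of(tib_side),
    area_medial_mm2 = area_of(tib_side & pm$compartment == "med"),
    area_lateral_mm2 = area_of(tib_side & pm$compartment == "lat"),
    area_fem_tib_mm2 = area_of(pm$type == "fem_tib"),
    area_men_tib_mm2 = area_of(pm$type == "men_tib"),
    area_fem_men_mm2 = area_of(pm$type == "fem_men"),
    force_meniscus_path_N = tot(pm$type == "fem_men"),
    force_direct_N = tot(pm$type == "fem_tib"),
    force_medial_N = f_med,
    force_lateral_N = f_lat,
    conservation_rel_err = if (applied > 0) {
      abs(f_med + f_lat - applied) / applied
    } else 0,
    peak_stress_tibial_MPa = peak_tib,
    peak_stress_MPa = peak_all,
    max_penetration_mm = st$max_pen
  )
}

# Probe material points: the condyle-centre probe of each compartment is the
# tibial-surface pressure node nearest the traction-weighted centroid of the
# direct (cartilage-cartilage) patch at the end of the ramp; the
# meniscus-interface probe uses the meniscus-tibial patch. Probes are then
# tracked as fixed material points.
define_probes <- function(model, ramp_state) {
  ct <- ramp_state$contact
  if (is.null(ct)) return(tibble())
  pn <- model$pre$pnodes
  defs <- list()
  for (comp in c("med", "lat")) {
    surf_nodes <- intersect(
      boundary_nodes(model$mesh, paste0("surf_tibial_", comp)), pn)
    sx <- model$mesh$nodes[surf_nodes, 1L]
    for (ty in c("fem_tib", "men_tib")) {
      rows <- ct[ct$type == ty & ct$compartment == comp & ct$active, ]
      if (!nrow(rows)) next
      px <- sum(rows$x * rows$traction * rows$A) /
        sum(rows$traction * rows$A)
      node <- surf_nodes[which.min(abs(sx - px))]
      nm <- if (ty == "fem_tib") paste0("condyle_centre_", comp)
            else paste0("meniscus_interface_", comp)
      defs[[nm]] <- tibble(probe = nm, compartment = comp, pair_type = ty,
                           node = node, x = model$mesh$nodes[node, 1L])
    }
  }
  dplyr::bind_rows(defs)
}

# Probe pressure and total contact traction are both read from the
# recovered field at the sub-surface Gauss points of the tibial layer
# (traction = -sigma_yy total at the flat articular surface): penalty
# tractions sampled point-wise carry node-to-segment checkerboard noise,
# while the Gauss-point fields of one consistent recovery are smooth and
# mutually compatible.
probe_metrics <- function(model, st, probes) {
  if (!nrow(probes)) return(tibble())
  fields <- recover_gp_fields(model, st)
  tib <- which(fields$region == "tibial")
  gx <- as.numeric(fields$gpx[tib, ])
  gy <- as.numeric(fields$gpy[tib, ])
  top <- gy > max(gy) - 0.3 * diff(range(gy))   # top Gauss row
  gx <- gx[top]
  pg <- as.numeric(fields$pressure[tib, ])[top]
  tg <- -as.numeric(fields$syy_tot[tib, ])[top]
  ord <- order(gx)
  gx <- gx[ord]; pg <- pg[ord]; tg <- tg[ord]
  out <- probes
  out$time <- st$t
  out$pressure_MPa <- approx(gx, pg, xout = probes$x, rule = 2,
                             ties = mean)$y
  out$traction_MPa <- approx(gx, tg, xout = probes$x, rule = 2,
                             ties = mean)$y
  out$fluid_support_ratio <- ifelse(
    !is.na(out$traction_MPa) & out$traction_MPa >= 0.01,
    out$pressure_MPa / out$traction_MPa, NA_real_)
  select(out, "time", "probe", "compartment", "node", "x",
         "pressure_MPa", "traction_MPa", "fluid_support_ratio")
}

#' Contact areas of a solved state
#'
#' Active contact length times the out-of-plane depth, per contact pair, per
#' interface type and per compartment. Compartment and total areas follow the
#' tibial-surface convention: the sum of the cartilage-cartilage and
#' meniscus-cartilage interfaces on the tibial articular surface.
#'
#' @param run A `creep_run`.
#' @param time Output time, s (default: end of ramp).
#' @return A tibble of areas, mm^2.
#' @export
contact_metrics <- function(run, time = NULL) {
  st <- pick_state(run, time)
  pair_metrics(run$model, st) |>
    select("time", "pair", "type", "compartment", "contact_length_mm",
           "area_mm2")
}

#' Interface and compartment load partition
#'
#' Vertical force transmitted across each interface family: the meniscus path
#' (femoral-meniscus pairs), the direct cartilage-cartilage path
#' (femoral-tibial pairs), and the medial/lateral compartment split. The
#' partition balances the applied load (conservation within the contact
#' penalty tolerance).
#'
#' @inheritParams contact_metrics
#' @return One-row tibble: forces in N, shares as fractions of applied load.
#' @export
interface_load_partition <- function(run, time = NULL) {
  st <- pick_state(run, time)
  m <- state_metrics(run$model, st)
  tibble(
    time = m$time,
    applied_N = m$applied_N,
    force_meniscus_path_N = m$force_meniscus_path_N,
    force_direct_N = m$force_direct_N,
    force_medial_N = m$force_medial_N,
    force_lateral_N = m$force_lateral_N,
    meniscus_share = m$force_meniscus_path_N /
      (m$force_meniscus_path_N + m$force_direct_N),
    medial_share = m$force_medial_N / (m$force_medial_N + m$force_lateral_N),
    conservation_rel_err = m$conservation_rel_err
  )
}

#' Fluid support ratio at a probe
#'
#' The fraction of the local contact pressure carried by pressurised
#' interstitial fluid: probe fluid pressure divided by the total normal
#' contact traction at the probe. Undefined (NA) when the probe is out of
#' contact or the traction falls below 0.01 MPa.
#'
#' @inheritParams contact_metrics
#' @param probe Probe name, e.g. `"condyle_centre_med"`.
#' @return Scalar ratio (dimensionless), or NA when undefined.
#' @export
fluid_support_ratio <- function(run, probe, time = NULL) {
  st <- pick_state(run, time)
  tb <- probe_metrics(run$model, st, run$probe_defs)
  row <- tb[tb$probe == probe, ]
  if (!nrow(row)) abort(paste0("Unknown probe '", probe, "'."))
  row$fluid_support_ratio
}

#' Peak compressive stress
#'
#' Magnitude of the most negative principal total stress (the third principal
#' stress) over a tissue region, reported as a positive number.
#'
#' @inheritParams contact_metrics
#' @param region Region label (default `"tibial"`); `"all"` scans every
#'   element.
#' @return Peak compressive stress, MPa.
#' @export
peak_compressive_stress <- function(run, time = NULL, region = "tibial") {
  st <- pick_state(run, time)
  fields <- recover_gp_fields(run$model, st)
  sel <- if (identical(region, "all")) {
    rep(TRUE, length(fields$region))
  } else {
    fields$region == region
  }
  if (!any(sel)) abort(paste0("Empty region '", region, "'."))
  max(-fields$principal_min_tot[sel, ], 0)
}

#' Compare intact and meniscectomy runs
#'
#' Joins the two metric series on the output-time grid (resampling with a
#' warning when the grids differ) and reports meniscectomy/intact ratios of
#' contact area and peak compressive stress, the displacement curves, the
#' probe fluid-support decay, and flags for the qualitative orderings
#' characteristic of meniscal (dys)function: reduced contact area, elevated
#' compressive stress, and faster fluid depressurisation at the
#' meniscus-covered interface than at the condyle centres.
#'
#' @param intact,menisc `creep_run` objects for the two cases.
#' @return A `case_comparison`: list with `table` (per-time tibble), `flags`
#'   (named logicals) and `summary`.
#' @export
compare_cases <- function(intact, menisc) {
  a <- intact$series
  b <- menisc$series
  if (!isTRUE(all.equal(a$time, b$time))) {
    warn("Output-time grids differ; resampling the meniscectomy series.")
    b <- tibble(time = a$time)
    for (cl in setdiff(names(menisc$series), "time")) {
      b[[cl]] <- approx(menisc$series$time, menisc$series[[cl]],
                        xout = a$time, rule = 2)$y
    }
  }
  tab <- tibble(
    time = a$time,
    displacement_intact_mm = a$displacement_mm,
    displacement_menisc_mm = b$displacement_mm,
    area_ratio = b$area_total_mm2 / a$area_total_mm2,
    stress_ratio = b$peak_stress_tibial_MPa / a$peak_stress_tibial_MPa,
    meniscus_share_intact = a$force_meniscus_path_N /
      pmax(a$force_meniscus_path_N + a$force_direct_N, 1e-12)
  )
  fsr_decay <- function(run, type_prefix) {
    pr <- run$probes
    pr <- pr[startsWith(pr$probe, type_prefix) &
               !is.na(pr$fluid_support_ratio), ]
    if (!nrow(pr)) return(NA_real_)
    byt <- pr |> group_by(.data$time) |>
      summarise(fsr = mean(.data$fluid_support_ratio), .groups = "drop")
    first(byt$fsr) - last(byt$fsr)
  }
  centre_drop <- fsr_decay(intact, "condyle_centre")
  men_drop <- fsr_decay(intact, "meniscus_interface")
  flags <- list(
    area_menisc_below_intact = all(tab$area_ratio < 1),
    stress_menisc_above_intact = all(tab$stress_ratio > 1),
    meniscus_share_decreasing =
      all(diff(tab$meniscus_share_intact) <= 0.01) &&
        last(tab$meniscus_share_intact) <
          first(tab$meniscus_share_intact) - 0.05,
    centre_fsr_decays_slower =
      is.finite(centre_drop) && is.finite(men_drop) &&
        centre_drop < men_drop
  )
  structure(list(
    table = tab, flags = flags,
    summary = list(
      stress_ratio_ramp = tab$stress_ratio[1L],
      stress_ratio_end = tab$stress_ratio[nrow(tab)],
      area_ratio_ramp = tab$area_ratio[1L],
      area_ratio_end = tab$area_ratio[nrow(tab)],
      centre_fsr_drop = centre_drop,
      meniscus_fsr_drop = men_drop
    )
  ), class = "case_comparison")
}

#' @export
print.creep_run <- function(x, ...) {
  cat("<creep_run> case:", x$case, "\n")
  cat("  ", nrow(x$series), " output times, ",
      nrow(x$model$mesh$elems), " elements, free travel ",
      signif(x$free_travel, 3), " mm\n", sep = "")
  rng <- range(x$series$time)
  cat("  t in [", rng[1], ", ", rng[2], "] s; final displacement ",
      signif(tail(x$series$displacement_mm, 1), 4), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.case_comparison <- function(x, ...) {
  cat("<case_comparison>\n")
  for (nm in names(x$flags)) {
    cat(sprintf("  %-32s %s\n", nm, x$flags[[nm]]))
  }
  cat("  stress ratio (menisc/intact): ramp",
      signif(x$summary$stress_ratio_ramp, 3), "-> end",
      signif(x$summary$stress_ratio_end, 3), "\n")
  invisible(x)
}
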