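# Assembled models: mesh + materials + constraints + load, ready for
# time_march().

new_fe_model <- function(...) {
  m <- list(...)
  defaults <- list(
    K_base = NULL,
    rigid = NULL, pairs = NULL, drainage_switch = TRUE,
    springs = tibble(dof = integer(), k = numeric()),
    pfix_always = integer(), fluid_penalty = 0, band = 0,
    depth = 1, clip = Inf, free_travel = 0, contact_eps = 0
  )
  for (nm in names(defaults)) {
    if (is.null(m[[nm]])) m[[nm]] <- defaults[[nm]]
  }
  if (is.null(m$K_base)) {
    m$K_base <- m$pre$K0
    if (nrow(m$springs)) {
      m$K_base <- m$K_base +
        sparseMatrix(i = m$springs$dof, j = m$springs$dof,
                     x = m$springs$k, dims = c(m$pre$ndu, m$pre$ndu))
    }
  }
  class(m) <- "fe_model"
  m
}

static_dirichlet <- function(dofs) {
  dofs <- unique(dofs)
  list(dofs = dofs, value = function(t) numeric(length(dofs)))
}

#' Confined-compression creep model
#'
#' The verification fixture for the consolidation oracle: a tissue column
#' loaded by a constant compressive surface stress applied as a step, laterally
#' confined and sealed, draining through the loaded top only.
#'
#' @param height Column height, mm.
#' @param n_elements Elements through the height.
#' @param material A [tissue_material()].
#' @param applied_stress Step stress, MPa (compression).
#' @param t_end Largest time the schedule must cover, s.
#' @return An `fe_model`.
#' @export
build_column_model <- function(height = 2, n_elements = 20,
                               material = material_presets("femoral_cartilage"),
                               applied_stress = 0.1, t_end = 2e4) {
  mesh <- make_confined_column(height, n_elements)
  mats <- list(column = material)
  mesh <- fibre_field(mesh, mats)
  pre <- fe_precompute(mesh, mats)
  base <- boundary_nodes(mesh, "fixed_base")
  roll <- setdiff(boundary_nodes(mesh, "roller_x"), base)
  dir <- static_dirichlet(c(2L * base - 1L, 2L * base, 2L * roll - 1L))
  f_unit <- edge_traction_vector(mesh, mesh$boundaries$loaded_top, pre$ndu)
  pfix <- intersect(boundary_nodes(mesh, "draining_top"), pre$pnodes)
  sched <- load_schedule(applied_stress, ramp_duration = 0,
                         hold_duration = t_end * 1.01, medial_offset = 0,
                         beyond = "clamp")
  new_fe_model(mesh = mesh, materials = mats, pre = pre, dirichlet = dir,
               load = list(type = "traction", f_unit = f_unit),
               pfix_always = pfix, schedule = sched)
}

#' Unconfined plane-strain strip model
#'
#' Displacement-controlled compression between rigid, frictionless,
#' impermeable platens with free-draining lateral edges. The apparent axial
#' stiffness interpolates between the instantaneous incompressible limit
#' `4 mu` and the drained plane-strain limit `E/(1-nu^2)`.
#'
#' @param width,height Strip dimensions, mm.
#' @param n Elements across the width.
#' @param material A [tissue_material()]; pass one without a `tangential`
#'   fibril family to test the matrix-only limits.
#' @param displacement Platen displacement magnitude, mm (applied as a step).
#' @param t_end Largest time the schedule must cover, s.
#' @return An `fe_model`.
#' @export
build_strip_model <- function(width = 4, height = 2, n = 8,
                              material = tissue_material(
                                "matrix_only", 0.64, 0.08,
                                numeric(), 0.00116),
                              displacement = 0.02, t_end = 2e4) {
  mesh <- make_unconfined_strip(width, height, n)
  mats <- list(strip = material)
  mesh <- fibre_field(mesh, mats)
  pre <- fe_precompute(mesh, mats)
  bot <- boundary_nodes(mesh, "platen_bottom")
  top <- boundary_nodes(mesh, "platen_top")
  mid <- which(abs(mesh$nodes[, 1L] - width / 2) < 1e-9)
  sched <- load_schedule(displacement, ramp_duration = 0,
                         hold_duration = t_end * 1.01, medial_offset = 0,
                         beyond = "clamp")
  fixed0 <- c(2L * bot, 2L * mid - 1L)
  top_dofs <- 2L * top
  dir <- list(
    dofs = c(fixed0, top_dofs),
    value = function(t) c(numeric(length(fixed0)),
                          rep(-ramp_hold(sched, t), length(top_dofs)))
  )
  pfix <- intersect(boundary_nodes(mesh, "peripheral_draining"), pre$pnodes)
  new_fe_model(mesh = mesh, materials = mats, pre = pre, dirichlet = dir,
               load = list(type = "none"), pfix_always = pfix,
               schedule = sched,
               monitor = list(top = top, bot = bot))
}

joint_region_materials <- function(mesh, materials) {
  key <- function(rg) switch(rg,
    femoral_med = , femoral_lat = "femoral_cartilage",
    tibial = "tibial_cartilage",
    meniscus_med = , meniscus_lat = "meniscus",
    rg)
  regs <- unique(mesh$region)
  setNames(lapply(regs, function(rg) materials[[key(rg)]]), regs)
}

joint_contact_pairs <- function(mesh, mats_by_region, penalty_scale) {
  mk <- function(name, type, comp, sec, pri) {
    contact_pair(mesh, name, type, comp, sec, pri,
                 penalty = auto_penalty(mesh, mats_by_region, sec, pri,
                                        scale = penalty_scale))
  }
  intact <- "meniscus_med" %in% mesh$region
  pairs <- list(
    mk("fem_tib_med", "fem_tib", "med", "surf_femoral_med", "surf_tibial_med"),
    mk("fem_tib_lat", "fem_tib", "lat", "surf_femoral_lat", "surf_tibial_lat")
  )
  if (intact) {
    pairs <- c(pairs, list(
      mk("fem_men_med", "fem_men", "med",
         "surf_femoral_med", "surf_meniscus_med_top"),
      mk("fem_men_lat", "fem_men", "lat",
         "surf_femoral_lat", "surf_meniscus_lat_top"),
      mk("men_tib_med", "men_tib", "med",
         "surf_tibial_med", "surf_meniscus_med_bot"),
      mk("men_tib_lat", "men_tib", "lat",
         "surf_tibial_lat", "surf_meniscus_lat_bot")
    ))
  }
  pairs
}

#' Assemble the coronal joint model
#'
#' Builds the full contact model for one case from a [run_config()]: mesh,
#' region materials, the six (intact) or two (meniscectomy) biphasic contact
#' pairs with auto-penalty factors, the rigid femur coupling (vertical
#' translation and varus-valgus rotation free, transverse translation fixed),
#' horn-anchor springs, peripheral drainage, and the load schedule. The femur
#' is first translated down to first contact (closing the unloaded clearance);
#' the closed distance is stored as `free_travel` and excluded from reported
#' displacements.
#'
#' @param config A [run_config()].
#' @return An `fe_model`.
#' @export
build_joint_model <- function(config = run_config()) {
  params <- config$geometry
  materials <- config$materials
  mesh <- make_coronal_joint(params, materials)
  mats_by_region <- joint_region_materials(mesh, materials)

  # close the unloaded clearance: translate the femur down to 5 um standoff
  pairs0 <- joint_contact_pairs(mesh, mats_by_region,
                                config$contact$penalty_scale)
  fem_pairs <- Filter(function(p) p$type %in% c("fem_tib", "fem_men"), pairs0)
  ev0 <- contact_eval(fem_pairs, mesh, mesh$nodes, band = 5)
  clear <- min(unlist(lapply(ev0, function(o) {
    v <- -o$g[o$indom & is.finite(o$g)]
    if (length(v)) min(v) else Inf
  })))
  shift <- max(0, clear - 0.005)
  fem_nodes <- sort(unique(as.integer(
    mesh$elems[startsWith(mesh$region, "femoral"), ])))
  mesh$nodes[fem_nodes, 2L] <- mesh$nodes[fem_nodes, 2L] - shift

  pairs <- joint_contact_pairs(mesh, mats_by_region,
                               config$contact$penalty_scale)
  pre <- fe_precompute(mesh, mats_by_region)

  base <- boundary_nodes(mesh, "fixed_base")
  dir <- static_dirichlet(c(2L * base - 1L, 2L * base))

  rig_nodes <- boundary_nodes(mesh, "rigid_femur_interface")
  rigid <- list(nodes = rig_nodes,
                centre = c(0, mesh$params$y_cen - shift),
                span = max(abs(mesh$nodes[rig_nodes, 1L])),
                k_reg = 0.01, k_reg_rot = 5)

  springs <- tibble(dof = integer(), k = numeric())
  if (nrow(mesh$springs)) {
    springs <- tibble(
      dof = ifelse(mesh$springs$dir == "x",
                   2L * mesh$springs$node - 1L, 2L * mesh$springs$node),
      k = mesh$springs$stiffness
    )
  }

  pfix <- intersect(boundary_nodes(mesh, "peripheral_draining"), pre$pnodes)

  new_fe_model(
    mesh = mesh, materials = mats_by_region, pre = pre, dirichlet = dir,
    load = list(type = "rigid"), schedule = config$schedule,
    rigid = rigid, springs = springs, pairs = pairs,
    drainage_switch = config$drainage_switch,
    pfix_always = pfix, fluid_penalty = config$contact$fluid_penalty,
    band = 2 * params$mesh_size, depth = params$out_of_plane_depth,
    clip = config$contact$clip, free_travel = shift,
    contact_eps = 2e-3
  )
}
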