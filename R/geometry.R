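# Synthetic geometries: verification fixtures (confined column, unconfined
# strip) and the parameterised 2-D coronal tibiofemoral cross-section.

#' Confined-compression column mesh
#'
#' A one-element-wide column of biphasic tissue for verification against the
#' closed-form consolidation solution: lateral edges on rollers and sealed,
#' bottom fixed and impermeable, top loaded and free-draining.
#'
#' @param height Column height, mm.
#' @param n_elements Number of stacked elements (>= 1).
#' @return A `region_mesh` with tags `fixed_base`, `roller_x`, `loaded_top`,
#'   `draining_top`.
#' @export
make_confined_column <- function(height, n_elements) {
  if (height <= 0) abort("`height` must be positive.")
  if (n_elements < 1) abort("`n_elements` must be >= 1.")
  w <- height / n_elements
  blk <- mesh_block(1L, as.integer(n_elements), function(xi, eta) {
    cbind(xi * w, eta * height)
  })
  mesh <- merge_blocks(list(list(
    block = blk, region = "column",
    tags = list(fixed_base = blk$sides$bottom,
                roller_x = rbind(blk$sides$left, blk$sides$right),
                loaded_top = blk$sides$top,
                draining_top = blk$sides$top)
  )))
  mesh$params <- list(height = height, n_elements = n_elements, width = w)
  mesh
}

#' Unconfined plane-strain strip mesh
#'
#' A rectangular strip compressed between rigid, frictionless, impermeable
#' platens, with traction-free, free-draining lateral edges. Used to verify
#' the instantaneous (incompressible, `4 mu`) and drained
#' (`E / (1 - nu^2)`) plane-strain stiffness limits.
#'
#' @param width,height Strip dimensions, mm.
#' @param n Elements across the width; rows scale with the aspect ratio.
#' @return A `region_mesh` with tags `platen_bottom`, `platen_top`,
#'   `peripheral_draining`.
#' @export
make_unconfined_strip <- function(width, height, n) {
  if (width <= 0 || height <= 0) abort("Dimensions must be positive.")
  nx <- as.integer(n)
  ny <- max(1L, as.integer(round(n * height / width)))
  blk <- mesh_block(nx, ny, function(xi, eta) cbind(xi * width, eta * height))
  mesh <- merge_blocks(list(list(
    block = blk, region = "strip",
    tags = list(platen_bottom = blk$sides$bottom,
                platen_top = blk$sides$top,
                peripheral_draining = rbind(blk$sides$left, blk$sides$right))
  )))
  mesh$params <- list(width = width, height = height, nx = nx, ny = ny)
  mesh
}

#' Joint geometry parameters
#'
#' Parameters of the synthetic 2-D coronal tibiofemoral cross-section: two
#' circular femoral condyle cartilage layers bonded to a rigid femur, a flat
#' tibial cartilage layer fixed to the tibia, and (intact variant) two
#' wedge-shaped menisci seated between condyle and tibial surfaces. The wedge
#' top follows the condyle arc at clearance `initial_gap` (the menisci render
#' the unloaded joint congruent) up to `meniscus_outer_height`; the direct
#' femoral-tibial gap at the condyle apex is `central_clearance` (unloaded
#' cartilage-cartilage apposition is slightly incongruent). All geometry
#' values are free model parameters, not literature measurements.
#'
#' @param condyle_radius Outer radius of the femoral cartilage arc, mm.
#' @param condyle_spacing Centre-to-centre distance of the condyles, mm.
#' @param femoral_cartilage_thickness,tibial_cartilage_thickness mm.
#' @param meniscus_inner_height,meniscus_outer_height Wedge heights at the
#'   inner tip and outer rim, mm (`outer > inner`).
#' @param meniscus_width Radial (medio-lateral) wedge width, mm.
#' @param out_of_plane_depth Effective depth used to map the joint force
#'   protocol (in N) to the plane-strain force-per-depth the 2-D model
#'   carries, mm. This is also the load-intensity scaling of the model's
#'   small-strain idealization: the default (125 mm) keeps drained-state
#'   compressive strains within the small-strain regime (about 15% intact,
#'   about 30% after meniscectomy) under the body-weight protocol.
#' @param initial_gap Clearance between condyle and meniscus top, mm.
#' @param central_clearance Unloaded condyle-tibia clearance at the apex, mm.
#' @param horn_free_length Effective free length of the horn attachment used
#'   in the hoop-spring stiffness `E_circ A_wedge / (R_ring L_horn)`, mm.
#'   The default (5 mm) keeps the radial meniscal extrusion under body weight
#'   in the physiological 1-3 mm range.
#' @param tip_relief Extra clearance of the wedge top at the inner rim, mm,
#'   fading quadratically over the inner quarter of the wedge width. The
#'   unloaded inner rim of a meniscus is not in compressive contact; the
#'   relief keeps the condyle off the thin feather edge until the body of the
#'   wedge is engaged.
#' @param mesh_size Target element size, mm.
#' @param variant `"intact"` or `"meniscectomy"` (double meniscectomy; same
#'   alignment as the intact joint).
#' @return A `joint_geometry_params` object.
#' @export
joint_geometry_params <- function(condyle_radius = 20,
                                  condyle_spacing = 45,
                                  femoral_cartilage_thickness = 2,
                                  tibial_cartilage_thickness = 2,
                                  meniscus_inner_height = 1.2,
                                  meniscus_outer_height = 4,
                                  meniscus_width = 8,
                                  out_of_plane_depth = 125,
                                  initial_gap = 0.02,
                                  central_clearance = 0.4,
                                  horn_free_length = 5,
                                  tip_relief = 0.3,
                                  mesh_size = 1.0,
                                  variant = c("intact", "meniscectomy")) {
  variant <- match.arg(variant)
  lens <- c(condyle_radius, condyle_spacing, femoral_cartilage_thickness,
            tibial_cartilage_thickness, meniscus_inner_height,
            meniscus_outer_height, meniscus_width, out_of_plane_depth,
            initial_gap, central_clearance, horn_free_length, mesh_size)
  if (tip_relief < 0) abort("`tip_relief` must be >= 0.")
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("All joint geometry lengths must be positive and finite.")
  }
  if (meniscus_outer_height <= meniscus_inner_height) {
    abort("`meniscus_outer_height` must exceed `meniscus_inner_height` (the wedge tapers inward).")
  }
  structure(list(
    condyle_radius = condyle_radius, condyle_spacing = condyle_spacing,
    femoral_cartilage_thickness = femoral_cartilage_thickness,
    tibial_cartilage_thickness = tibial_cartilage_thickness,
    meniscus_inner_height = meniscus_inner_height,
    meniscus_outer_height = meniscus_outer_height,
    meniscus_width = meniscus_width,
    out_of_plane_depth = out_of_plane_depth,
    initial_gap = initial_gap, central_clearance = central_clearance,
    horn_free_length = horn_free_length, tip_relief = tip_relief,
    mesh_size = mesh_size, variant = variant
  ), class = "joint_geometry_params")
}

#' Synthetic coronal tibiofemoral joint mesh
#'
#' Generates the 2-D coronal cross-section: tibial cartilage layer (bottom
#' fully fixed), two condylar femoral cartilage arcs (inner arc coupled to the
#' rigid femur), and for the intact variant two meniscal wedges resting on the
#' tibial surface with horn-attachment springs on their outer rim. The
#' meniscectomy variant omits the wedges and keeps every other coordinate
#' identical (the meniscectomized joint keeps the intact alignment). Fibre
#' directions and fibril moduli are assigned via [fibre_field()]. Generation
#' is deterministic: identical parameters give an identical mesh.
#'
#' @param params A [joint_geometry_params()].
#' @param materials Named list of [tissue_material()] presets used to assign
#'   fibril moduli (defaults to [material_presets()]).
#' @return A `region_mesh` with regions `femoral_med`, `femoral_lat`,
#'   `tibial` and, when intact, `meniscus_med`, `meniscus_lat`.
#' @export
make_coronal_joint <- function(params = joint_geometry_params(),
                               materials = material_presets()) {
  stopifnot(inherits(params, "joint_geometry_params"))
  R <- params$condyle_radius
  hf <- params$femoral_cartilage_thickness
  ht <- params$tibial_cartilage_thickness
  cc <- params$central_clearance
  g0 <- params$initial_gap
  s2 <- params$condyle_spacing / 2
  ms <- params$mesh_size
  y_cen <- cc + R

  gapf <- function(d) cc + R - sqrt(pmax(R^2 - d^2, 0))

  # wedge footprint: inner edge where the condyle-tibia gap (minus the
  # meniscal clearance) equals the inner wedge height
  q <- R + cc - g0 - params$meniscus_inner_height
  if (q >= R) {
    abort(paste0("Meniscal wedge does not fit the initial gap: the condyle-",
                 "tibia gap already exceeds `meniscus_inner_height` at the ",
                 "apex. Increase `meniscus_inner_height` or reduce ",
                 "`central_clearance`."))
  }
  if (q <= 0) abort("Wedge geometry degenerate: check condyle radius and heights.")
  d_in <- sqrt(R^2 - q^2)
  d_out <- d_in + params$meniscus_width
  if (d_out >= 0.97 * R) {
    abort(paste0("Meniscal wedge does not fit: its outer rim (", round(d_out, 2),
                 " mm from the condyle apex) extends past the condyle arc."))
  }
  # the inner quarter of the wedge top is relieved away from the condyle
  # (rounded inner rim): the feather edge must not take the first contact
  relief_len <- params$meniscus_width / 4
  wedge_top <- function(d) {
    relief <- params$tip_relief * pmax(0, (d_in + relief_len - d) /
                                         relief_len)^2
    pmin(gapf(d) - g0 - relief, params$meniscus_outer_height)
  }

  theta_max <- asin(min(0.98, (d_out + 0.5) / R))

  parts <- list()

  # tibial layer
  Wh <- s2 + d_out + 2
  nxt <- max(4L, as.integer(ceiling(2 * Wh / ms)))
  nyt <- max(2L, as.integer(ceiling(ht / ms)))
  tib <- mesh_block(nxt, nyt, function(xi, eta) {
    cbind(-Wh + xi * 2 * Wh, -ht + eta * ht)
  })
  midx <- (tib$nodes[tib$sides$top[, 1L], 1L] +
           tib$nodes[tib$sides$top[, 3L], 1L]) / 2
  parts[[length(parts) + 1L]] <- list(
    block = tib, region = "tibial",
    tags = list(
      fixed_base = tib$sides$bottom,
      peripheral_draining = rbind(tib$sides$left, tib$sides$right),
      surf_tibial_med = tib$sides$top[midx > 0, , drop = FALSE],
      surf_tibial_lat = tib$sides$top[midx < 0, , drop = FALSE]
    )
  )

  # femoral condyle arc (medial, then mirrored)
  nxf <- max(6L, as.integer(ceiling(2 * theta_max * R / ms)))
  nyf <- max(2L, as.integer(ceiling(hf / ms)))
  fem_map <- function(xc) {
    function(xi, eta) {
      th <- (2 * xi - 1) * theta_max
      r <- R - eta * hf
      cbind(xc + r * sin(th), y_cen - r * cos(th))
    }
  }
  fem_med <- mesh_block(nxf, nyf, fem_map(s2))
  fem_lat <- mirror_block(mesh_block(nxf, nyf, fem_map(s2)))
  parts[[length(parts) + 1L]] <- list(
    block = fem_med, region = "femoral_med",
    tags = list(surf_femoral_med = fem_med$sides$bottom,
                rigid_femur_interface = fem_med$sides$top,
                peripheral_draining = rbind(fem_med$sides$left,
                                            fem_med$sides$right))
  )
  parts[[length(parts) + 1L]] <- list(
    block = fem_lat, region = "femoral_lat",
    tags = list(surf_femoral_lat = fem_lat$sides$bottom,
                rigid_femur_interface = fem_lat$sides$top,
                peripheral_draining = rbind(fem_lat$sides$left,
                                            fem_lat$sides$right))
  )

  horn_sides <- list()
  if (params$variant == "intact") {
    nxm <- max(4L, as.integer(ceiling(params$meniscus_width / ms)))
    nym <- max(2L, as.integer(ceiling(
      (params$meniscus_inner_height + params$meniscus_outer_height) / 2 / ms)))
    men_map <- function(xi, eta) {
      d <- d_in + xi * params$meniscus_width
      cbind(s2 + d, eta * wedge_top(d))
    }
    men_med <- mesh_block(nxm, nym, men_map)
    men_lat <- mirror_block(mesh_block(nxm, nym, men_map))
    parts[[length(parts) + 1L]] <- list(
      block = men_med, region = "meniscus_med",
      tags = list(surf_meniscus_med_bot = men_med$sides$bottom,
                  surf_meniscus_med_top = men_med$sides$top,
                  peripheral_draining = rbind(men_med$sides$left,
                                              men_med$sides$right),
                  horn_outer_med = men_med$sides$right)
    )
    parts[[length(parts) + 1L]] <- list(
      block = men_lat, region = "meniscus_lat",
      tags = list(surf_meniscus_lat_bot = men_lat$sides$bottom,
                  surf_meniscus_lat_top = men_lat$sides$top,
                  peripheral_draining = rbind(men_lat$sides$left,
                                              men_lat$sides$right),
                  horn_outer_lat = men_lat$sides$right)
    )
  }

  mesh <- merge_blocks(parts)

  # horn/hoop anchoring: the out-of-plane circumferential fibre family (hoop
  # tension anchored at the horn attachments) acts on every material point of
  # the cross-section, so it is represented as a distributed horizontal
  # elastic foundation over the wedge, stiffness density
  # E_circ / (R_ring * L_horn) per unit cross-section area and unit depth
  # (total E_circ * A_wedge / (R_ring * L_horn)); a weak vertical foundation
  # (5% of the horizontal density) suppresses the rigid and rocking modes of
  # the unloaded, frictionally unrestrained wedge.
  if (params$variant == "intact") {
    e_circ <- materials$meniscus$fibril_moduli[["circumferential"]]
    r_ring <- params$condyle_spacing / 2
    k_dens <- e_circ / (r_ring * params$horn_free_length)  # N/mm^3 per depth
    springs <- list()
    for (rg in c("meniscus_med", "meniscus_lat")) {
      els <- which(mesh$region == rg)
      a_node <- numeric(nrow(mesh$nodes))
      for (e in els) {
        xc <- mesh$nodes[mesh$elems[e, 1:4], , drop = FALSE]
        a_e <- 0.5 * abs(sum(xc[, 1L] * xc[c(2:4, 1L), 2L] -
                             xc[c(2:4, 1L), 1L] * xc[, 2L]))
        a_node[mesh$elems[e, ]] <- a_node[mesh$elems[e, ]] + a_e / 9
      }
      nds <- which(a_node > 0)
      springs[[rg]] <- tibble(
        node = rep(nds, 2L),
        dir = rep(c("x", "y"), each = length(nds)),
        stiffness = c(k_dens * a_node[nds], 0.05 * k_dens * a_node[nds])
      )
    }
    mesh$springs <- dplyr::bind_rows(springs)
  }

  mesh$params <- c(unclass(params),
                   list(y_cen = y_cen, d_in = d_in, d_out = d_out,
                        condyle_centres = c(med = s2, lat = -s2),
                        theta_max = theta_max, half_width = Wh))
  fibre_field(mesh, materials)
}

#' Assign fibre directions and fibril moduli
#'
#' Cartilage elements receive a single in-plane fibril family tangent to the
#' nearest articular surface (horizontal in the flat tibial layer, arc-tangent
#' in the condylar layers); meniscal elements receive the radial
#' (medio-lateral) family. The circumferential (out-of-plane) meniscal family
#' cannot act in-plane and is represented by the horn-anchor hoop springs
#' instead.
#'
#' @param mesh A `region_mesh` with region labels.
#' @param materials Named list of [tissue_material()] used to look up the
#'   modulus of each element's family; regions missing a matching family get a
#'   zero modulus.
#' @return The mesh with `fibre` (unit vectors), `fibre_label` and `efib`
#'   (MPa) filled per element.
#' @export
fibre_field <- function(mesh, materials = material_presets()) {
  ne <- nrow(mesh$elems)
  cen <- (mesh$nodes[mesh$elems[, 1L], , drop = FALSE] +
          mesh$nodes[mesh$elems[, 2L], , drop = FALSE] +
          mesh$nodes[mesh$elems[, 3L], , drop = FALSE] +
          mesh$nodes[mesh$elems[, 4L], , drop = FALSE]) / 4
  fib <- matrix(0, ne, 2L)
  lab <- character(ne)
  for (e in seq_len(ne)) {
    rg <- mesh$region[e]
    if (is.na(rg) || !nzchar(rg)) abort("Unlabelled element in mesh.")
    if (startsWith(rg, "femoral")) {
      side <- if (endsWith(rg, "med")) "med" else "lat"
      xc <- mesh$params$condyle_centres[[side]]
      rvec <- c(cen[e, 1L] - xc, cen[e, 2L] - mesh$params$y_cen)
      rvec <- rvec / sqrt(sum(rvec^2))
      fib[e, ] <- c(-rvec[2L], rvec[1L])
      lab[e] <- "tangential"
    } else if (startsWith(rg, "meniscus")) {
      fib[e, ] <- c(1, 0)
      lab[e] <- "radial"
    } else {
      fib[e, ] <- c(1, 0)
      lab[e] <- "tangential"
    }
  }
  efib <- numeric(ne)
  matkey <- function(rg) {
    if (startsWith(rg, "femoral")) "femoral_cartilage"
    else if (rg == "tibial") "tibial_cartilage"
    else if (startsWith(rg, "meniscus")) "meniscus"
    else rg
  }
  for (e in seq_len(ne)) {
    m <- materials[[matkey(mesh$region[e])]]
    if (!is.null(m) && lab[e] %in% names(m$fibril_moduli)) {
      efib[e] <- m$fibril_moduli[[lab[e]]]
    }
  }
  mesh$fibre <- fib
  mesh$fibre_label <- lab
  mesh$efib <- efib
  mesh
}
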