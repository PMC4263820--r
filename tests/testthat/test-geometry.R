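test_that("confined column mesh has the documented structure", {
  m <- make_confined_column(2.0, 10)
  expect_s3_class(m, "region_mesh")
  expect_equal(nrow(m$elems), 10)
  expect_equal(max(m$nodes[, 2]), 2.0)
  # minimal case
  m1 <- make_confined_column(2.0, 1)
  expect_equal(nrow(m1$elems), 1)
  expect_gt(poroknee:::min_jacobian(m1), 0)
  # boundary tags partition the exterior: every exterior edge appears in
  # exactly one mechanical tag (draining_top doubles loaded_top by design)
  mech <- rbind(m$boundaries$fixed_base, m$boundaries$roller_x,
                m$boundaries$loaded_top)
  expect_equal(nrow(mech), 2 * 10 + 2)   # sides + top + bottom
  expect_equal(anyDuplicated(mech[, 1:3]), 0)
  expect_error(make_confined_column(2, 0), ">= 1")
})

test_that("unconfined strip mesh is structured with the stated tags", {
  m <- make_unconfined_strip(4, 2, 8)
  expect_equal(nrow(m$elems), 8 * 4)
  expect_setequal(
    names(m$boundaries),
    c("platen_bottom", "platen_top", "peripheral_draining")
  )
  drn <- boundary_nodes(m, "peripheral_draining")
  expect_true(all(m$nodes[drn, 1] %in% c(0, 4)))
  expect_gt(poroknee:::min_jacobian(m), 0)
})

test_that("coronal joint mesh has the expected regions and symmetry", {
  par <- joint_geometry_params(mesh_size = 1.5)
  m <- make_coronal_joint(par)
  expect_setequal(unique(m$region),
                  c("femoral_med", "femoral_lat", "tibial",
                    "meniscus_med", "meniscus_lat"))
  # mirror symmetry about the midline
  xs <- sort(m$nodes[, 1])
  expect_lt(max(abs(xs + rev(xs))), 1e-9)
  expect_gt(poroknee:::min_jacobian(m), 0)

  par2 <- joint_geometry_params(mesh_size = 1.5, variant = "meniscectomy")
  m2 <- make_coronal_joint(par2)
  expect_setequal(unique(m2$region),
                  c("femoral_med", "femoral_lat", "tibial"))
  # shared regions keep identical coordinates (same alignment as intact)
  for (rg in unique(m2$region)) {
    n1 <- sort(unique(as.integer(m$elems[m$region == rg, ])))
    n2 <- sort(unique(as.integer(m2$elems[m2$region == rg, ])))
    expect_equal(length(n1), length(n2))
  }
  tib1 <- m$nodes[sort(unique(as.integer(m$elems[m$region == "tibial", ]))), ]
  tib2 <- m2$nodes[sort(unique(as.integer(m2$elems[m2$region == "tibial", ]))), ]
  expect_equal(tib1, tib2)

  # regeneration is bit-identical
  m3 <- make_coronal_joint(par)
  expect_identical(m$nodes, m3$nodes)
  expect_identical(m$elems, m3$elems)
})

test_that("wedge-fit violations raise a geometry error", {
  expect_error(
    make_coronal_joint(joint_geometry_params(
      meniscus_inner_height = 0.05, central_clearance = 2,
      meniscus_outer_height = 4)),
    "does not fit"
  )
  expect_error(
    make_coronal_joint(joint_geometry_params(meniscus_width = 18)),
    "does not fit"
  )
})

test_that("fibre field is tangent to articular surfaces with unit norm", {
  m <- make_coronal_joint(joint_geometry_params(mesh_size = 1.5))
  expect_true(all(abs(rowSums(m$fibre^2) - 1) < 1e-12))
  # flat tibial surface: fibres horizontal
  tib <- m$region == "tibial"
  expect_true(all(abs(m$fibre[tib, 2]) < 1e-12))
  # meniscus carries the radial family modulus
  men <- startsWith(m$region, "meniscus")
  expect_true(all(m$efib[men] == 10.0))
  expect_true(all(m$fibre_label[men] == "radial"))
  # cartilage carries the tangential family
  expect_true(all(m$efib[startsWith(m$region, "femoral")] == 5.6))
  expect_true(all(m$efib[tib] == 5.6))
  # femoral fibres are perpendicular to the local radial direction
  fem <- which(m$region == "femoral_med")
  cen <- (m$nodes[m$elems[fem, 1], ] + m$nodes[m$elems[fem, 3], ]) / 2
  rad <- cbind(cen[, 1] - m$params$condyle_centres[["med"]],
               cen[, 2] - m$params$y_cen)
  rad <- rad / sqrt(rowSums(rad^2))
  expect_lt(max(abs(rowSums(rad * m$fibre[fem, ]))), 0.15)
})

test_that("pressure nodes are a strict subset of displacement nodes", {
  m <- make_coronal_joint(joint_geometry_params(mesh_size = 2))
  pn <- pressure_nodes(m)
  expect_true(all(pn %in% seq_len(nrow(m$nodes))))
  expect_lt(length(pn), nrow(m$nodes))
  expect_setequal(pn, sort(unique(as.integer(m$elems[, 1:4]))))
})
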