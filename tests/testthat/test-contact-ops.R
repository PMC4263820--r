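test_that("projection onto a flat surface measures signed gaps", {
  m <- make_unconfined_strip(4, 2, 4)
  surf <- poroknee:::contact_surface(m, "platen_top")
  # point above the top surface (y = 2): open contact, gap negative
  above <- project_and_gap(c(2, 2.1), surf, m)
  expect_equal(above$gap, -0.1, tolerance = 1e-9)
  expect_true(above$active_domain)
  # point below the surface: penetrating, outward normal +y
  below <- project_and_gap(c(2, 1.95), surf, m)
  expect_equal(below$gap, 0.05, tolerance = 1e-9)
  expect_equal(below$normal, c(0, 1), tolerance = 1e-9)
  # point beyond both ends projects outside the domain
  beyond <- project_and_gap(c(7.5, 2.1), surf, m)
  expect_false(beyond$active_domain)
})

test_that("penalty traction is the gap times the penalty factor", {
  expect_equal(penalty_traction(-0.1, 100), 0)
  expect_equal(penalty_traction(0, 100), 0)
  expect_equal(penalty_traction(0.01, 100), 1.0)
  g <- seq(-0.05, 0.05, by = 0.005)
  expect_true(all(diff(penalty_traction(g, 50)) >= 0))
  expect_error(penalty_traction(0.01, 0), "positive")
})

test_that("regularised law matches the sharp law outside the blend zone", {
  ge <- 2e-3
  for (g in c(-0.01, -ge - 1e-9, ge, 0.01, 0.1)) {
    rc <- poroknee:::reg_contact(g, 67, ge)
    expect_equal(rc$t, penalty_traction(g, 67), tolerance = 1e-12)
  }
  # continuous and continuously differentiable across the blend
  gs <- seq(-2 * ge, 2 * ge, length.out = 401)
  tv <- vapply(gs, function(g) poroknee:::reg_contact(g, 67, ge)$t, 1)
  kv <- vapply(gs, function(g) poroknee:::reg_contact(g, 67, ge)$k, 1)
  expect_true(all(diff(tv) >= 0))
  expect_lt(max(abs(diff(tv) / diff(gs) - kv[-1])), 67 * 0.02)
})

test_that("auto-penalty scales with aggregate modulus over element size", {
  par <- joint_geometry_params(mesh_size = 1.5)
  m <- make_coronal_joint(par)
  mats <- poroknee:::joint_region_materials(m, material_presets())
  pen <- auto_penalty(m, mats, "surf_femoral_med", "surf_tibial_med",
                      scale = 100)
  ed <- m$boundaries$surf_femoral_med
  lens <- sqrt(rowSums((m$nodes[ed[, 3], ] - m$nodes[ed[, 1], ])^2))
  expect_equal(pen, 100 * 0.6490 / mean(lens), tolerance = 1e-3)
  # doubling H_A doubles the factor
  stiff <- mats
  stiff$femoral_med <- tissue_material("f2", 2 * 0.64, 0.08,
                                       c(tangential = 5.6), 0.00116)
  stiff$femoral_lat <- stiff$femoral_med
  stiff$tibial <- tissue_material("t2", 2 * 0.84, 0.03,
                                  c(tangential = 5.6), 0.00326)
  pen2 <- auto_penalty(m, stiff, "surf_femoral_med", "surf_tibial_med",
                       scale = 100)
  expect_equal(pen2 / pen, 2, tolerance = 1e-9)
  # the scale is a plain multiplier
  expect_equal(auto_penalty(m, mats, "surf_femoral_med", "surf_tibial_med",
                            scale = 50) / pen, 0.5, tolerance = 1e-12)
})

test_that("intact joint defines six contact pairs, meniscectomy two", {
  cfg <- run_config("intact", geometry = joint_geometry_params(mesh_size = 2))
  mi <- build_joint_model(cfg)
  expect_length(mi$pairs, 6L)
  expect_setequal(vapply(mi$pairs, `[[`, "", "name"),
                  c("fem_tib_med", "fem_tib_lat", "fem_men_med",
                    "fem_men_lat", "men_tib_med", "men_tib_lat"))
  cfg2 <- run_config("meniscectomy",
                     geometry = joint_geometry_params(mesh_size = 2))
  mm <- build_joint_model(cfg2)
  expect_length(mm$pairs, 2L)
  expect_setequal(vapply(mm$pairs, `[[`, "", "type"), "fem_tib")
})
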