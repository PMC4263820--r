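# Property checks on the default joint runs beyond the headline acceptance
# mechanisms.

test_that("both joint runs satisfy basic state invariants", {
  for (case in c("intact", "meniscectomy")) {
    run <- default_run(case)
    s <- run$series
    # output grid strictly increasing, end of ramp present
    expect_true(all(diff(s$time) > 0))
    expect_true(any(abs(s$time - run$config$schedule$ramp_duration) < 1e-9))
    # applied load follows the schedule
    expect_equal(s$applied_N,
                 ramp_hold(run$config$schedule, s$time),
                 tolerance = 1e-9)
    # penetration stays far below the thinner contacting layer, or the run
    # would flag a penalty-too-low warning
    thin <- run$config$geometry$tibial_cartilage_thickness
    expect_true(all(s$max_penetration_mm < 0.02 * thin))
    # stress decomposition at every Gauss point of the final state
    st <- run$states[[length(run$states)]]
    f <- poroknee:::recover_gp_fields(run$model, st)
    expect_equal(f$sxx_tot, f$sxx_eff - f$pressure, tolerance = 1e-12)
    expect_equal(f$szz_tot, f$szz_eff - f$pressure, tolerance = 1e-12)
    # pressure is exactly zero on the peripheral free-draining boundary
    per <- intersect(boundary_nodes(run$model$mesh, "peripheral_draining"),
                     run$model$pre$pnodes)
    expect_equal(max(abs(st$p[run$model$pre$pmap[per]])), 0)
  }
})

test_that("fluid support is higher at the condyle centre than at the patch edge", {
  run <- default_run("intact")
  pr <- run$probes |> dplyr::filter(!is.na(fluid_support_ratio))
  wide <- pr |>
    dplyr::mutate(grp = sub("_(med|lat)$", "", probe)) |>
    dplyr::group_by(time, grp) |>
    dplyr::summarise(fsr = mean(fluid_support_ratio), .groups = "drop") |>
    tidyr::pivot_wider(names_from = grp, values_from = fsr)
  # after the ramp the covered centre stays better pressurised than the
  # meniscus-covered interface near the free-draining rim
  expect_true(all(wide$condyle_centre >= wide$meniscus_interface - 0.05))
  expect_gt(mean(wide$condyle_centre - wide$meniscus_interface), 0)
})

test_that("medial share grows with the load offset", {
  shares <- vapply(c(0, 2.5, 5), function(off) {
    run <- if (off == 5) {
      ramp_run("ramp_default", run_config("intact"))
    } else if (off == 0) {
      zero_offset_ramp()
    } else {
      offset_ramp(off)
    }
    interface_load_partition(run, 1)$medial_share
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("compare_cases of a run with itself gives unit ratios", {
  run <- default_run("intact")
  cmp <- compare_cases(run, run)
  expect_true(all(abs(cmp$table$area_ratio - 1) < 1e-12))
  expect_true(all(abs(cmp$table$stress_ratio - 1) < 1e-12))
})

test_that("mesh refinement changes the end-of-ramp peak fluid pressure by < 5%", {
  # the meniscectomy variant exercises the same mesh generator and contact
  # machinery at a fraction of the cost of the intact case
  peak_p <- function(ms) {
    cfg <- run_config("meniscectomy",
                      geometry = joint_geometry_params(mesh_size = ms))
    model <- build_joint_model(cfg)
    march <- time_march(model, 1, cfg$solver)
    f <- poroknee:::recover_gp_fields(model, march$states[[1]])
    max(f$pressure)
  }
  p1 <- peak_p(1.0)
  p2 <- peak_p(0.5)
  expect_lt(abs(p2 - p1) / p1, 0.05)
})

test_that("contact metric conventions hold on the intact run", {
  run <- default_run("intact")
  cm <- contact_metrics(run, 1)
  # compartment totals on the tibial surface add the two interface types
  s <- run$series[1, ]
  med <- sum(cm$area_mm2[cm$compartment == "med" &
                         cm$type %in% c("fem_tib", "men_tib")])
  lat <- sum(cm$area_mm2[cm$compartment == "lat" &
                         cm$type %in% c("fem_tib", "men_tib")])
  expect_equal(med, s$area_medial_mm2)
  expect_equal(lat, s$area_lateral_mm2)
  expect_equal(med + lat, s$area_total_mm2)
  # no contact, no area
  expect_true(all(cm$area_mm2 >= 0))
})

test_that("peak compressive stress reduces to principal-value formulas", {
  run <- default_run("intact")
  ps <- peak_compressive_stress(run, 1, region = "tibial")
  expect_gt(ps, 0)
  f <- poroknee:::recover_gp_fields(run$model, poroknee:::pick_state(run, 1))
  tib <- f$region == "tibial"
  expect_equal(ps, max(-f$principal_min_tot[tib, ]))
  expect_error(peak_compressive_stress(run, 1, region = "femur_of_oz"),
               "Empty region")
})
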