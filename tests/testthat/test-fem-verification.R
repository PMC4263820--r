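# Verification of the coupled displacement-pressure engine against the
# closed-form poroelastic oracles.

test_that("FE confined-compression creep matches the series solution", {
  mat <- material_presets("femoral_cartilage")
  ec <- derived_elastic_constants(mat$matrix_modulus, mat$poisson_ratio)
  tg <- gel_diffusion_time(2, ec$aggregate_modulus, mat$permeability)
  mdl <- build_column_model(height = 2, n_elements = 20, material = mat,
                            applied_stress = 0.1, t_end = 3.2 * tg)
  times <- exp(seq(log(0.01 * tg), log(3 * tg), length.out = 25))
  mm <- time_march(mdl, times,
                   solver_settings(dt_initial = 0.5, dt_max = 1e9,
                                   dt_growth = 1.25))
  top <- boundary_nodes(mdl$mesh, "loaded_top")
  u_fe <- vapply(mm$states, function(s) -mean(s$u[top, 2]), numeric(1))
  sp <- confined_creep_spec(0.1, 2, ec$aggregate_modulus, mat$permeability,
                            200)
  u_an <- confined_creep_displacement(sp, times)
  rel_l2 <- sqrt(sum((u_fe - u_an)^2) / sum(u_an^2))
  expect_lt(rel_l2, 0.02)
  # monotone creep
  expect_true(all(diff(u_fe) > 0))
  # drained equilibrium: pressures vanish at 10 gel-diffusion times
  late <- time_march(mdl, 10 * tg,
                     solver_settings(dt_initial = 5, dt_max = 1e9,
                                     dt_growth = 1.6))
  expect_lt(max(abs(late$states[[1]]$p)), 1e-3 * 0.1)
})

test_that("confined response is insensitive to surface-parallel fibrils", {
  # fibres parallel to the loaded surface never stretch in confined
  # compression, so the response must be identical with and without them
  mat_f <- material_presets("femoral_cartilage")      # tangential = 5.6
  mat_0 <- tissue_material("nofib", 0.64, 0.08, numeric(), 0.00116)
  tg <- gel_diffusion_time(2, 0.6490, 0.00116)
  times <- tg * c(0.05, 0.5)
  st <- solver_settings(dt_initial = 2, dt_max = 1e9, dt_growth = 1.5)
  u <- lapply(list(mat_f, mat_0), function(m) {
    mdl <- build_column_model(2, 8, m, 0.1, t_end = 0.6 * tg)
    mm <- time_march(mdl, times, st)
    top <- boundary_nodes(mdl$mesh, "loaded_top")
    vapply(mm$states, function(s) -mean(s$u[top, 2]), numeric(1))
  })
  expect_equal(u[[1]], u[[2]], tolerance = 1e-9)
})

test_that("unconfined strip reaches both plane-strain limit stiffnesses", {
  mat <- tissue_material("matrix_only", 0.64, 0.08, numeric(), 0.00116)
  lim <- unconfined_limit_moduli(0.64, 0.08)
  ec <- derived_elastic_constants(0.64, 0.08)
  w <- 4; h <- 2
  tg <- gel_diffusion_time(w / 2, ec$aggregate_modulus, mat$permeability)
  mdl <- build_strip_model(width = w, height = h, n = 8, material = mat,
                           displacement = 0.02, t_end = 12 * tg)
  mm <- time_march(mdl, c(5e-4 * tg, 10 * tg),
                   solver_settings(dt_initial = 5e-4 * tg, dt_max = 1e9,
                                   dt_growth = 1.4))
  mod <- vapply(mm$states, function(s) {
    R <- sum(s$resid_full[2 * mdl$monitor$top])
    abs(R) / w / (0.02 / h)
  }, numeric(1))
  expect_lt(abs(mod[1] - lim$instantaneous) / lim$instantaneous, 0.05)
  expect_lt(abs(mod[2] - lim$equilibrium) / lim$equilibrium, 0.02)
})

test_that("time discretisation is converged under step halving", {
  mat <- material_presets("tibial_cartilage")
  ec <- derived_elastic_constants(mat$matrix_modulus, mat$poisson_ratio)
  tg <- gel_diffusion_time(2, ec$aggregate_modulus, mat$permeability)
  tout <- 0.5 * tg
  u_of <- function(nstep) {
    dt <- tout / nstep
    mdl <- build_column_model(2, 10, mat, 0.1, t_end = 0.6 * tg)
    mm <- time_march(mdl, tout,
                     solver_settings(dt_initial = dt, dt_max = dt,
                                     dt_growth = 1))
    top <- boundary_nodes(mdl$mesh, "loaded_top")
    -mean(mm$states[[1]]$u[top, 2])
  }
  u_coarse <- u_of(160)
  u_fine <- u_of(320)
  expect_lt(abs(u_coarse - u_fine) / abs(u_fine), 1e-3)
})

test_that("an unloaded body stays in equilibrium at the zero state", {
  mat <- material_presets("femoral_cartilage")
  mdl <- build_column_model(2, 5, mat, applied_stress = 1e-12, t_end = 50)
  res <- poroknee:::solve_step(mdl, numeric(mdl$pre$ndu + mdl$pre$np),
                               t = 1, dt = 1, settings = solver_settings())
  expect_true(res$ok)
  expect_lt(max(abs(res$z)), 1e-6)
  expect_lt(res$residual, 1e-8)
})

test_that("assembled step system is symmetric", {
  mat <- material_presets("femoral_cartilage")
  mdl <- build_column_model(2, 4, mat, 0.1, t_end = 10)
  pre <- mdl$pre
  K <- pre$K0
  A <- rbind(cbind(K, -pre$C), cbind(-t(pre$C), -(0.1 * pre$H)))
  expect_lt(max(abs(A - t(A))), 1e-10)
})

test_that("pressure at free-draining tagged nodes is exactly zero", {
  mat <- material_presets("femoral_cartilage")
  ec <- derived_elastic_constants(mat$matrix_modulus, mat$poisson_ratio)
  tg <- gel_diffusion_time(2, ec$aggregate_modulus, mat$permeability)
  mdl <- build_column_model(2, 10, mat, 0.1, t_end = tg)
  mm <- time_march(mdl, tg * c(0.01, 0.2),
                   solver_settings(dt_initial = 1, dt_max = 1e9,
                                   dt_growth = 1.5))
  drn <- intersect(boundary_nodes(mdl$mesh, "draining_top"), mdl$pre$pnodes)
  for (s in mm$states) {
    expect_equal(max(abs(s$p[mdl$pre$pmap[drn]])), 0)
    # interior pressure is positive during consolidation
    expect_gt(max(s$p), 0)
  }
})
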