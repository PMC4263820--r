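test_that("Lame conversion reproduces hand-evaluated tissue constants", {
  fem <- derived_elastic_constants(0.64, 0.08)
  expect_equal(fem$lambda, 0.0564, tolerance = 1e-3)
  expect_equal(fem$mu, 0.2963, tolerance = 1e-3)
  expect_equal(fem$aggregate_modulus, 0.6490, tolerance = 1e-3)

  tib <- derived_elastic_constants(0.84, 0.03)
  expect_equal(tib$lambda, 0.0260, tolerance = 1e-2)
  expect_equal(tib$mu, 0.4078, tolerance = 1e-3)
  expect_equal(tib$aggregate_modulus, 0.8416, tolerance = 1e-3)

  # nu = 0 collapses lambda
  e0 <- derived_elastic_constants(1.7, 0)
  expect_equal(e0$lambda, 0)
  expect_equal(e0$mu, 1.7 / 2)
  expect_equal(e0$aggregate_modulus, 1.7)

  expect_error(derived_elastic_constants(0.64, 0.5), "compressible")
  expect_error(tissue_material("x", 1, 0.55, numeric(), 1e-3), "0.5")
})

test_that("matrix effective stress is the linear isotropic law", {
  fem <- derived_elastic_constants(0.64, 0.08)
  z <- matrix(0, 2, 2)
  expect_equal(matrix_effective_stress(z, fem$lambda, fem$mu), z)

  uni <- matrix(c(0, 0, 0, -0.1), 2, 2)
  s <- matrix_effective_stress(uni, fem$lambda, fem$mu)
  expect_equal(s[2, 2], -0.0649, tolerance = 1e-3)
  expect_equal(s[1, 1], -0.00564, tolerance = 1e-2)

  sh <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  ss <- matrix_effective_stress(sh, fem$lambda, fem$mu)
  expect_equal(ss[1, 2], 2 * fem$mu * 0.05)
  expect_equal(ss[1, 2], 0.0296, tolerance = 2e-3)
  expect_equal(ss[1, 1], 0)

  expect_error(matrix_effective_stress(matrix(c(0, 1, 0, 0), 2, 2), 1, 1),
               "symmetric")
})

test_that("fibril stress is tension-only and rank-one along the fibre", {
  ex <- c(1, 0)
  # fibre in compression: zero tensor
  comp <- matrix(c(-0.05, 0, 0, 0), 2, 2)
  expect_equal(fibril_stress(comp, ex, 40), matrix(0, 2, 2))
  # meniscus circumferential modulus under 1% stretch
  ten <- matrix(c(0.01, 0, 0, 0), 2, 2)
  s <- fibril_stress(ten, ex, 40)
  expect_equal(s[1, 1], 0.4)
  expect_equal(s[1, 2], 0)
  expect_equal(s[2, 2], 0)
  # degenerate modulus
  expect_equal(fibril_stress(ten, ex, 0), matrix(0, 2, 2))
  # rank-one along an oblique fibre
  d <- c(1, 1) / sqrt(2)
  so <- fibril_stress(ten, d, 10)
  expect_equal(so, 10 * as.numeric(t(d) %*% ten %*% d) * tcrossprod(d))
  expect_error(fibril_stress(ten, c(1, 1), 10), "unit")
})

test_that("total stress decomposition and Darcy law behave as stated", {
  expect_equal(total_stress(matrix(0, 2, 2), 0.5), -0.5 * diag(2))
  eff <- matrix(c(0.2, 0.05, 0.05, -0.1), 2, 2)
  expect_equal(total_stress(eff, 0), eff)
  # trace identity on random symmetric inputs
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(rnorm(4), 2, 2)
    sym <- (a + t(a)) / 2
    p <- rnorm(1)
    tot <- total_stress(sym, p)
    expect_equal(sum(diag(tot)), sum(diag(sym)) - 2 * p)
  }

  expect_equal(darcy_flux(c(1, 0), 0.00116), c(-0.00116, 0))
  expect_equal(darcy_flux(c(0, 0), 0.5), c(0, 0))
  expect_equal(darcy_flux(c(0.3, -0.2), 2 * 0.001),
               2 * darcy_flux(c(0.3, -0.2), 0.001))
  expect_error(darcy_flux(c(1, 0), 0), "positive")
})

test_that("material presets round-trip through config serialization", {
  cfg <- run_config("intact")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  for (nm in names(material_presets())) {
    expect_equal(back$materials[[nm]], cfg$materials[[nm]], ignore_attr = TRUE)
  }
  expect_equal(back$geometry, cfg$geometry, ignore_attr = TRUE)
  expect_equal(back$schedule, cfg$schedule, ignore_attr = TRUE)
})
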