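test_that("gel diffusion time scales as h^2 / (H_A k)", {
  expect_equal(gel_diffusion_time(2, 0.6490, 0.00116), 5313, tolerance = 1e-3)
  expect_equal(gel_diffusion_time(2, 0.8416, 0.00326), 1458, tolerance = 1e-3)
  expect_equal(gel_diffusion_time(4, 0.6490, 0.00116),
               4 * gel_diffusion_time(2, 0.6490, 0.00116))
})

test_that("confined creep series has the documented limits and shape", {
  sp <- confined_creep_spec(0.1, 2, 0.6490, 0.00116)
  # instantaneous incompressibility (up to series truncation: the tail of
  # the 50-term sum at t = 0 is ~0.4% of the drained limit)
  expect_lt(confined_creep_displacement(sp, 0), 0.01 * 0.308)
  expect_lt(confined_creep_displacement(
    confined_creep_spec(0.1, 2, 0.6490, 0.00116, 5000), 0), 1e-4 * 0.308)
  # drained limit sigma0 h / H_A
  expect_equal(confined_creep_displacement(sp, 1e9), 0.308, tolerance = 1e-3)
  # one gel-diffusion time reaches 93.1% of the drained limit
  tg <- gel_diffusion_time(2, 0.6490, 0.00116)
  expect_equal(confined_creep_displacement(sp, tg) / (0.1 * 2 / 0.6490),
               0.931, tolerance = 1e-3)
  # monotone increasing
  tt <- seq(0, 3 * tg, length.out = 40)
  expect_true(all(diff(confined_creep_displacement(sp, tt)) >= 0))
})

test_that("series truncation is converged at 20 terms", {
  tg <- gel_diffusion_time(2, 0.6490, 0.00116)
  sp20 <- confined_creep_spec(0.1, 2, 0.6490, 0.00116, series_terms = 20)
  sp200 <- confined_creep_spec(0.1, 2, 0.6490, 0.00116, series_terms = 200)
  tt <- tg * c(0.01, 0.1, 1, 3)
  expect_lt(max(abs(confined_creep_displacement(sp20, tt) -
                    confined_creep_displacement(sp200, tt))), 1e-10)
  # at one decade earlier the n = 20 tail is still visible but tiny
  expect_lt(abs(confined_creep_displacement(sp20, 0.001 * tg) -
                confined_creep_displacement(sp200, 0.001 * tg)), 1e-4)
})

test_that("unconfined plane-strain limit moduli", {
  lim <- unconfined_limit_moduli(0.64, 0.08)
  expect_equal(lim$instantaneous, 1.185, tolerance = 1e-3)
  expect_equal(lim$equilibrium, 0.644, tolerance = 1e-3)
  expect_equal(unconfined_limit_moduli(0.84, 0)$equilibrium, 0.84)
  # instantaneous stiffness dominates for every admissible nu
  for (nu in seq(0, 0.45, by = 0.05)) {
    l <- unconfined_limit_moduli(1, nu)
    expect_gte(l$instantaneous, l$equilibrium)
  }
})

test_that("load schedule ramps linearly then holds", {
  sched <- load_schedule(800, 1, 1200, 5)
  expect_equal(ramp_hold(sched, 0), 0)
  expect_equal(ramp_hold(sched, 0.5), 400)
  expect_equal(ramp_hold(sched, 600), 800)
  expect_equal(ramp_hold(sched, 1201), 800)
  expect_error(ramp_hold(sched, 1202), "beyond")
  expect_error(ramp_hold(sched, -1), ">= 0")
  clamped <- load_schedule(800, 1, 1200, 5, beyond = "clamp")
  expect_equal(ramp_hold(clamped, 5000), 800)
  # step load
  step <- load_schedule(0.1, 0, 100, 0)
  expect_equal(ramp_hold(step, 0), 0)
  expect_equal(ramp_hold(step, 1e-9), 0.1)
})

test_that("offset load is equivalent to a centred load plus adduction moment", {
  expect_equal(equivalent_adduction_moment(800, 5), 4)
  expect_equal(equivalent_adduction_moment(800, 0), 0)
  expect_equal(equivalent_adduction_moment(400, 10), 4)
})

test_that("creep increase percentage matches its definition", {
  expect_equal(creep_increase_pct(1, 2), 100)
  expect_equal(round(creep_increase_pct(0.95, 1.65)), 74)
  expect_error(creep_increase_pct(0, 1), "positive")
})
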