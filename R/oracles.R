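#' Gel diffusion time
#'
#' Characteristic poroelastic consolidation time of a layer of thickness `h`:
#' `t_g = h^2 / (H_A k)`. Creep transients play out over a few multiples of
#' `t_g`; it is the natural unit for choosing hold durations and output grids.
#'
#' @param h Drainage path length (layer thickness), mm.
#' @param H_A Aggregate modulus `lambda + 2 mu`, MPa.
#' @param k Permeability, mm^4/(N s).
#' @return Time constant, s.
#' @examples
#' gel_diffusion_time(2, 0.6490, 0.00116)
#' @export
gel_diffusion_time <- function(h, H_A, k) {
  if (any(c(h, H_A, k) <= 0)) abort("All arguments must be positive.")
  h^2 / (H_A * k)
}

#' Specification of a confined-compression creep problem
#'
#' Bundles the parameters of the one-dimensional confined-compression creep
#' benchmark: a tissue layer of thickness `thickness` on an impermeable rigid
#' base, loaded on its free-draining top surface by a constant applied stress.
#'
#' @param applied_stress Step stress magnitude (compression), MPa.
#' @param thickness Layer thickness, mm.
#' @param aggregate_modulus Confined modulus `H_A`, MPa.
#' @param permeability Permeability, mm^4/(N s).
#' @param series_terms Number of series terms (default 50, >= 20 recommended).
#' @return An object of class `confined_creep_spec`.
#' @export
confined_creep_spec <- function(applied_stress, thickness, aggregate_modulus,
                                permeability, series_terms = 50L) {
  vals <- c(applied_stress, thickness, aggregate_modulus, permeability,
            series_terms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All confined-creep parameters must be positive and finite.")
  }
  structure(
    list(applied_stress = applied_stress, thickness = thickness,
         aggregate_modulus = aggregate_modulus, permeability = permeability,
         series_terms = as.integer(series_terms)),
    class = "confined_creep_spec"
  )
}

#' Closed-form confined-compression creep displacement
#'
#' Series solution for the surface settlement of a biphasic layer under a
#' stress step in confined compression (one-dimensional consolidation):
#' \deqn{u(t) = \frac{\sigma_0 h}{H_A}\left[1 - 2\sum_{n\ge 0}
#'   \frac{\exp(-\pi^2 (n+1/2)^2\, t/t_g)}{\pi^2 (n+1/2)^2}\right]}
#' with `t_g = h^2/(H_A k)`. The surface displacement is zero at `t = 0`
#' (instantaneous incompressibility), rises monotonically, and approaches the
#' drained limit `sigma_0 h / H_A`. This is the primary analytic verification
#' oracle for the finite-element time marcher.
#'
#' @param spec A [confined_creep_spec()].
#' @param t Time(s), s (vectorised, all >= 0).
#' @return Surface displacement(s), mm (settlement positive).
#' @examples
#' sp <- confined_creep_spec(0.1, 2, 0.6490, 0.00116)
#' confined_creep_displacement(sp, c(0, 100, 1e5))
#' @export
confined_creep_displacement <- function(spec, t) {
  stopifnot(inherits(spec, "confined_creep_spec"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  u_inf <- spec$applied_stress * spec$thickness / spec$aggregate_modulus
  t_g <- gel_diffusion_time(spec$thickness, spec$aggregate_modulus,
                            spec$permeability)
  n <- seq_len(spec$series_terms) - 1L
  a_n <- pi^2 * (n + 0.5)^2
  vapply(t, function(ti) {
    u_inf * (1 - 2 * sum(exp(-a_n * ti / t_g) / a_n))
  }, numeric(1))
}

#' Limit stiffnesses of an unconfined plane-strain strip
#'
#' For a biphasic strip (no fibrils) compressed between rigid, frictionless,
#' impermeable platens with free-draining lateral edges, the apparent axial
#' stiffness has two analytic limits: the instantaneous response, where the
#' trapped fluid renders the tissue incompressible and the plane-strain
#' stiffness is `4 mu`, and the drained equilibrium response with plane-strain
#' modulus `E / (1 - nu^2)`.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return Named list with `instantaneous` and `equilibrium` stiffness, MPa.
#' @examples
#' unconfined_limit_moduli(0.64, 0.08)
#' @export
unconfined_limit_moduli <- function(E, nu) {
  ec <- derived_elastic_constants(E, nu)
  list(instantaneous = 4 * ec$mu, equilibrium = E / (1 - nu^2))
}

#' Percent increase of a creep displacement
#'
#' Relative growth of a creep displacement between the end of the load ramp
#' and the end of the hold, in percent: `100 (u_end - u_ramp) / u_ramp`.
#'
#' @param u_ramp Displacement at end of ramp, mm (> 0).
#' @param u_end Displacement at end of hold, mm.
#' @return Percent increase.
#' @examples
#' creep_increase_pct(0.95, 1.65)
#' @export
creep_increase_pct <- function(u_ramp, u_end) {
  if (u_ramp <= 0) abort("`u_ramp` must be positive.")
  100 * (u_end - u_ramp) / u_ramp
}

#' Equivalent adduction moment of an offset vertical load
#'
#' A vertical force applied at a point offset medially from the joint centre
#' is statically equivalent to the same force at the centre plus an adduction
#' (varus) moment `force x offset` loading the medial compartment.
#'
#' @param force Vertical force, N.
#' @param medial_offset Medial offset of the load application point, mm.
#' @return Moment in N m (note the unit conversion from N mm).
#' @examples
#' equivalent_adduction_moment(800, 5) # 4 N m
#' @export
equivalent_adduction_moment <- function(force, medial_offset) {
  force * medial_offset / 1000
}
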