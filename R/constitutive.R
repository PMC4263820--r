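#' Fibril-reinforced biphasic tissue material
#'
#' Constructs the material description used for cartilage and meniscus: an
#' isotropic, linear elastic non-fibrillar matrix (drained equilibrium
#' compressive modulus `matrix_modulus` and Poisson's ratio `poisson_ratio`),
#' one or more tension-only collagen fibril families (`fibril_moduli`, named by
#' direction label, e.g. `tangential`, `circumferential`, `radial`), and a
#' constant hydraulic permeability governing Darcy flow of the interstitial
#' fluid. Units are fixed to the N-mm-s-MPa system: moduli in MPa,
#' permeability in mm^4/(N s).
#'
#' @param name Tissue label (character scalar).
#' @param matrix_modulus Equilibrium compressive Young's modulus of the
#'   non-fibrillar matrix, MPa. Must be positive.
#' @param poisson_ratio Drained Poisson's ratio, in `[0, 0.5)`. Biphasic theory
#'   requires a compressible drained skeleton, so 0.5 is rejected.
#' @param fibril_moduli Named numeric vector of tensile fibril moduli (MPa),
#'   all non-negative. Fibrils carry load only in tension.
#' @param permeability Hydraulic permeability, mm^4/(N s). Must be positive.
#' @return An object of class `tissue_material`.
#' @examples
#' tissue_material("femoral_cartilage", 0.64, 0.08,
#'                 c(tangential = 5.6), 0.00116)
#' @export
tissue_material <- function(name, matrix_modulus, poisson_ratio,
                            fibril_moduli = numeric(), permeability) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(matrix_modulus) || length(matrix_modulus) != 1L ||
      matrix_modulus <= 0) {
    abort("`matrix_modulus` must be a positive scalar (MPa).")
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio >= 0.5) {
    abort(paste0(
      "`poisson_ratio` must lie in [0, 0.5): the drained solid matrix of a ",
      "biphasic tissue must be compressible (nu = 0.5 is incompressible)."
    ))
  }
  if (length(fibril_moduli)) {
    if (is.null(names(fibril_moduli)) || any(!nzchar(names(fibril_moduli)))) {
      abort("`fibril_moduli` must be a named numeric vector.")
    }
    if (any(fibril_moduli < 0)) abort("All `fibril_moduli` must be >= 0.")
  }
  if (!is.numeric(permeability) || length(permeability) != 1L ||
      permeability <= 0) {
    abort("`permeability` must be a positive scalar (mm^4/(N s)).")
  }
  structure(
    list(
      name = name,
      matrix_modulus = as.numeric(matrix_modulus),
      poisson_ratio = as.numeric(poisson_ratio),
      fibril_moduli = vapply(fibril_moduli, as.numeric, numeric(1)),
      permeability = as.numeric(permeability)
    ),
    class = "tissue_material"
  )
}

#' @export
print.tissue_material <- function(x, ...) {
  cat("<tissue_material> ", x$name, "\n", sep = "")
  cat("  matrix: E =", x$matrix_modulus, "MPa, nu =", x$poisson_ratio, "\n")
  if (length(x$fibril_moduli)) {
    cat("  fibrils (MPa):",
        paste(names(x$fibril_moduli), x$fibril_moduli,
              sep = " = ", collapse = ", "), "\n")
  } else {
    cat("  fibrils: none\n")
  }
  cat("  permeability:", x$permeability, "mm^4/(N s)\n")
  invisible(x)
}

#' Reference material presets
#'
#' The default material constants for the four tissue slots of the joint
#' model: femoral cartilage, tibial cartilage, meniscus, and the
#' `meniscus_absent` placeholder used by the double-meniscectomy variant (the
#' placeholder keeps the config schema identical between variants; no meniscus
#' elements are generated when it is selected). Values are typical
#' literature-derived constants for adult human tissue.
#'
#' @param name Optional preset name; with `NULL` the full named list is
#'   returned.
#' @return A `tissue_material`, or a named list of all presets.
#' @examples
#' material_presets("femoral_cartilage")
#' names(material_presets())
#' @export
material_presets <- function(name = NULL) {
  presets <- list(
    femoral_cartilage = tissue_material(
      "femoral_cartilage", matrix_modulus = 0.64, poisson_ratio = 0.08,
      fibril_moduli = c(tangential = 5.6), permeability = 0.00116
    ),
    tibial_cartilage = tissue_material(
      "tibial_cartilage", matrix_modulus = 0.84, poisson_ratio = 0.03,
      fibril_moduli = c(tangential = 5.6), permeability = 0.00326
    ),
    meniscus = tissue_material(
      "meniscus", matrix_modulus = 1.0, poisson_ratio = 0.03,
      fibril_moduli = c(circumferential = 40.0, radial = 10.0),
      permeability = 0.00100
    ),
    meniscus_absent = tissue_material(
      "meniscus_absent", matrix_modulus = 1.0, poisson_ratio = 0.03,
      fibril_moduli = c(circumferential = 40.0, radial = 10.0),
      permeability = 0.00100
    )
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(paste0("Unknown material preset '", name, "'. Available: ",
                 paste(names(presets), collapse = ", "), "."))
  }
  presets[[name]]
}

#' Lame constants and aggregate modulus from engineering constants
#'
#' Converts Young's modulus and Poisson's ratio of the drained matrix to the
#' Lame parameters and the confined-compression (aggregate) modulus
#' `H_A = lambda + 2 mu`, the stiffness that sets the poroelastic time scale.
#'
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return Named list with `lambda`, `mu`, `aggregate_modulus` (MPa).
#' @examples
#' derived_elastic_constants(0.64, 0.08)
#' @export
derived_elastic_constants <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) abort("`E` must be positive.")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5) {
    abort("`nu` must lie in [0, 0.5): biphasic theory requires a compressible drained matrix.")
  }
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  list(lambda = lambda, mu = mu, aggregate_modulus = lambda + 2 * mu)
}

check_symmetric2 <- function(strain, arg = "strain") {
  if (!is.matrix(strain) || !all(dim(strain) == c(2L, 2L))) {
    abort(paste0("`", arg, "` must be a 2x2 matrix."))
  }
  if (abs(strain[1, 2] - strain[2, 1]) > 1e-12 * max(1, max(abs(strain)))) {
    abort(paste0("`", arg, "` must be symmetric."))
  }
  invisible(strain)
}

#' Effective stress of the non-fibrillar matrix
#'
#' Linear isotropic (plane-strain) law for the drained solid matrix:
#' `sigma = lambda tr(eps) I + 2 mu eps`. Returns the in-plane 2x2 effective
#' stress; the out-of-plane normal component under plane strain is
#' `lambda tr(eps)`.
#'
#' @param strain Symmetric 2x2 in-plane small-strain tensor.
#' @param lambda,mu Lame constants, MPa.
#' @return 2x2 effective stress tensor, MPa (tension-positive).
#' @export
matrix_effective_stress <- function(strain, lambda, mu) {
  check_symmetric2(strain)
  tr <- strain[1, 1] + strain[2, 2]
  lambda * tr * diag(2) + 2 * mu * strain
}

#' Tension-only fibril stress
#'
#' Stress contribution of one collagen fibril family: the fibril strain is the
#' normal strain along the fibre, `eps_f = d' eps d`; if positive the family
#' contributes the rank-one stress `E_f eps_f (d x d)`, otherwise nothing
#' (fibrils buckle in compression).
#'
#' @param strain Symmetric 2x2 strain tensor.
#' @param fibre_dir Unit direction vector, length 2.
#' @param E_f Fibril tensile modulus, MPa (>= 0).
#' @return 2x2 stress tensor, MPa.
#' @export
fibril_stress <- function(strain, fibre_dir, E_f) {
  check_symmetric2(strain)
  if (length(fibre_dir) != 2L ||
      abs(sum(fibre_dir^2) - 1) > 1e-8) {
    abort("`fibre_dir` must be a unit 2-vector.")
  }
  if (E_f < 0) abort("`E_f` must be >= 0.")
  eps_f <- as.numeric(t(fibre_dir) %*% strain %*% fibre_dir)
  if (eps_f <= 0 || E_f == 0) return(matrix(0, 2, 2))
  E_f * eps_f * tcrossprod(fibre_dir)
}

#' Total stress of a biphasic point
#'
#' Biphasic stress split: the total (mixture) stress is the solid effective
#' stress minus the interstitial fluid pressure acting hydrostatically,
#' `sigma_total = sigma_eff - p I`. Stress is tension-positive, pressure
#' compression-positive.
#'
#' @param effective_stress Square stress tensor (2x2 or 3x3), MPa.
#' @param p Fluid pressure, MPa.
#' @return Total stress tensor of the same dimension.
#' @export
total_stress <- function(effective_stress, p) {
  if (!is.matrix(effective_stress) ||
      nrow(effective_stress) != ncol(effective_stress)) {
    abort("`effective_stress` must be a square matrix.")
  }
  if (!is.finite(p)) abort("`p` must be finite.")
  effective_stress - p * diag(nrow(effective_stress))
}

#' Darcy flux
#'
#' Relative fluid flux through the solid skeleton, `w = -k grad(p)`.
#'
#' @param grad_p Pressure gradient vector, MPa/mm.
#' @param k Permeability, mm^4/(N s) (> 0).
#' @return Flux vector, mm/s.
#' @export
darcy_flux <- function(grad_p, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    abort("`k` must be a positive scalar permeability.")
  }
  -k * as.numeric(grad_p)
}
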