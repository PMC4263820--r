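# Mixed displacement-pressure finite-element engine for the fibril-reinforced
# biphasic equations.
#
# Discretisation: 9-node biquadratic displacement / 4-node bilinear pressure
# (Taylor-Hood) quadrilaterals, 3x3 Gauss quadrature. Time integration is
# backward Euler on the coupled system
#   K u - C p = f(t)                 (solid momentum, quasi-static)
#   C' du/dt + H p = 0               (fluid continuity, Darcy flow)
# giving the symmetric indefinite step system
#   [ K  -C ] [u]   [ f        ]
#   [-C' -dt H ] [p] = [ -C' u_n ]
# Tension-only fibrils, penalty contact and the sealed/free drainage
# partition are handled by the per-step solver in solver.R: regularised
# (smooth) laws with the contact geometry frozen per step.

# ---- shape functions -------------------------------------------------------

q2_l <- function(x) cbind(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
q2_dl <- function(x) cbind(x - 0.5, -2 * x, x + 0.5)

# local coordinates of the 9 nodes (corners, midsides, centre)
q2_loc <- cbind(
  c(-1, 1, 1, -1, 0, 1, 0, -1, 0),
  c(-1, -1, 1, 1, -1, 0, 1, 0, 0)
)
# index (1,2,3) into the 1D basis for each local node
q2_ix <- c(1L, 3L, 3L, 1L, 2L, 3L, 2L, 1L, 2L)
q2_iy <- c(1L, 1L, 3L, 3L, 1L, 2L, 3L, 2L, 2L)

q2_shape <- function(xi, eta) {
  lx <- q2_l(xi); ly <- q2_l(eta)
  lx[q2_ix] * ly[q2_iy]
}

q2_dshape <- function(xi, eta) {
  lx <- q2_l(xi); ly <- q2_l(eta)
  dlx <- q2_dl(xi); dly <- q2_dl(eta)
  cbind(dlx[q2_ix] * ly[q2_iy], lx[q2_ix] * dly[q2_iy])
}

q1_shape <- function(xi, eta) {
  0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
}

q1_dshape <- function(xi, eta) {
  0.25 * cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
               c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

gauss9 <- function() {
  g <- sqrt(3 / 5)
  p1 <- c(-g, 0, g)
  w1 <- c(5, 8, 5) / 9
  pts <- as.matrix(expand.grid(xi = p1, eta = p1))
  w <- as.numeric(outer(w1, w1))
  list(pts = pts, w = w)
}

# quadratic edge shape functions at s in [-1,1], nodes ordered (end, mid, end)
edge_shape <- function(s) cbind(s * (s - 1) / 2, 1 - s^2, s * (s + 1) / 2)
edge_dshape <- function(s) cbind(s - 0.5, -2 * s, s + 0.5)

# ---- load schedule ---------------------------------------------------------

#' Ramp-hold load schedule
#'
#' The creep protocol: the load rises linearly from zero to `total_force` over
#' `ramp_duration`, then is held constant for `hold_duration`. With
#' `ramp_duration = 0` the load is a step. The load reference point sits
#' `medial_offset` mm medial of the joint centre, statically equivalent to a
#' centred load plus an adduction moment.
#'
#' @param total_force Peak vertical force, N (downward). For traction-driven
#'   fixtures this is the applied surface pressure in MPa; for
#'   displacement-driven fixtures the platen displacement in mm.
#' @param ramp_duration Ramp time, s (>= 0).
#' @param hold_duration Hold time, s (> 0).
#' @param medial_offset Medial offset of the load point, mm.
#' @param beyond `"error"` (default) or `"clamp"` for evaluation past the end
#'   of the protocol.
#' @return A `load_schedule` object.
#' @examples
#' sched <- load_schedule(800, 1, 1200, 5)
#' ramp_hold(sched, c(0, 0.5, 600))
#' @export
load_schedule <- function(total_force = 800, ramp_duration = 1,
                          hold_duration = 1200, medial_offset = 5,
                          beyond = c("error", "clamp")) {
  beyond <- match.arg(beyond)
  if (ramp_duration < 0 || hold_duration <= 0) {
    abort("`ramp_duration` must be >= 0 and `hold_duration` > 0.")
  }
  structure(list(total_force = total_force, ramp_duration = ramp_duration,
                 hold_duration = hold_duration, medial_offset = medial_offset,
                 beyond = beyond),
            class = "load_schedule")
}

#' Evaluate a ramp-hold schedule
#'
#' @param schedule A [load_schedule()].
#' @param t Time(s), s, all >= 0.
#' @return Force (or driven quantity) at `t`.
#' @export
ramp_hold <- function(schedule, t) {
  stopifnot(inherits(schedule, "load_schedule"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  t_end <- schedule$ramp_duration + schedule$hold_duration
  if (any(t > t_end + 1e-9)) {
    if (schedule$beyond == "error") {
      abort(paste0("t = ", max(t), " s lies beyond the end of the protocol (",
                   t_end, " s)."))
    }
    t <- pmin(t, t_end)
  }
  if (schedule$ramp_duration == 0) {
    ifelse(t > 0, schedule$total_force, 0)
  } else {
    schedule$total_force * pmin(t / schedule$ramp_duration, 1)
  }
}

#' Solver settings
#'
#' @param dt_initial Initial time step, s.
#' @param dt_max Maximum time step, s.
#' @param dt_growth Step growth factor after an accepted step.
#' @param newton_tol_rel Relative tolerance on the solution update across
#'   active-set iterations.
#' @param newton_max_iter Maximum nonlinear iterations per step.
#' @param damp_after Iteration after which updates are under-relaxed (factor
#'   0.5); the damped map shares the undamped fixed point but suppresses
#'   contact flip-flop cycles.
#' @param retry_budget Step-halving retries after a failed step.
#' @param verbose Print per-step progress (`2` traces the inner iteration).
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt_initial = 0.05, dt_max = 50, dt_growth = 1.6,
                            newton_tol_rel = 1e-6, newton_max_iter = 60L,
                            damp_after = 8L, retry_budget = 8L,
                            verbose = FALSE) {
  if (dt_initial <= 0) abort("`dt_initial` must be positive.")
  structure(list(dt_initial = dt_initial, dt_max = dt_max,
                 dt_growth = dt_growth, newton_tol_rel = newton_tol_rel,
                 newton_max_iter = as.integer(newton_max_iter),
                 damp_after = as.integer(damp_after),
                 retry_budget = as.integer(retry_budget), verbose = verbose),
            class = "solver_settings")
}

# ---- element precomputation and base matrices ------------------------------

# Per-element, per-Gauss-point kinematic data plus the constant sparse blocks
# K0 (isotropic matrix stiffness), C (div-pressure coupling) and H
# (permeability Laplacian). Units: N, mm, s, MPa; all quantities per unit
# out-of-plane depth.
fe_precompute <- function(mesh, materials) {
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  gp <- gauss9()
  ng <- 9L

  pnodes <- pressure_nodes(mesh)
  np <- length(pnodes)
  pmap <- integer(nn); pmap[pnodes] <- seq_len(np)

  edof <- matrix(0L, ne, 18L)
  for (i in 1:9) {
    edof[, 2L * i - 1L] <- 2L * mesh$elems[, i] - 1L
    edof[, 2L * i] <- 2L * mesh$elems[, i]
  }
  epid <- matrix(pmap[mesh$elems[, 1:4]], ne, 4L)

  Barr <- array(0, c(ne, ng, 3L, 18L))
  detJw <- matrix(0, ne, ng)
  dNparr <- array(0, c(ne, ng, 4L, 2L))
  gpxy <- array(0, c(ne, ng, 2L))
  Nparr <- matrix(0, ng, 4L)
  for (g in seq_len(ng)) Nparr[g, ] <- q1_shape(gp$pts[g, 1], gp$pts[g, 2])

  lam <- numeric(ne); mu <- numeric(ne); perm <- numeric(ne)
  for (e in seq_len(ne)) {
    m <- materials[[mesh$region[e]]]
    if (is.null(m)) abort(paste0("No material supplied for region '",
                                 mesh$region[e], "'."))
    ec <- derived_elastic_constants(m$matrix_modulus, m$poisson_ratio)
    lam[e] <- ec$lambda; mu[e] <- ec$mu; perm[e] <- m$permeability
  }

  for (e in seq_len(ne)) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (g in seq_len(ng)) {
      xi <- gp$pts[g, 1]; eta <- gp$pts[g, 2]
      dN <- q2_dshape(xi, eta)           # 9 x 2 (d/dxi, d/deta)
      J <- t(dN) %*% xe                  # 2 x 2
      dJ <- det(J)
      if (dJ <= 0) abort(paste0("Inverted element ", e, " (det J <= 0)."))
      dNx <- dN %*% solve(J)             # 9 x 2 physical gradients
      B <- matrix(0, 3, 18)
      B[1, seq(1, 17, 2)] <- dNx[, 1]
      B[2, seq(2, 18, 2)] <- dNx[, 2]
      B[3, seq(1, 17, 2)] <- dNx[, 2]
      B[3, seq(2, 18, 2)] <- dNx[, 1]
      Barr[e, g, , ] <- B
      detJw[e, g] <- dJ * gp$w[g]
      dNp <- q1_dshape(xi, eta) %*% solve(J)
      dNparr[e, g, , ] <- dNp
      gpxy[e, g, ] <- q2_shape(xi, eta) %*% xe
    }
  }

  # constant sparse blocks
  nK <- ne * 18L * 18L
  iK <- integer(nK); jK <- integer(nK); xK <- numeric(nK)
  iC <- integer(ne * 18L * 4L); jC <- integer(ne * 18L * 4L)
  xC <- numeric(ne * 18L * 4L)
  iH <- integer(ne * 16L); jH <- integer(ne * 16L); xH <- numeric(ne * 16L)
  kpos <- 0L; cpos <- 0L; hpos <- 0L
  for (e in seq_len(ne)) {
    D <- matrix(c(lam[e] + 2 * mu[e], lam[e], 0,
                  lam[e], lam[e] + 2 * mu[e], 0,
                  0, 0, mu[e]), 3, 3)
    Ke <- matrix(0, 18, 18)
    Ce <- matrix(0, 18, 4)
    He <- matrix(0, 4, 4)
    for (g in seq_len(ng)) {
      B <- matrix(Barr[e, g, , ], 3, 18)
      w <- detJw[e, g]
      Ke <- Ke + crossprod(B, D %*% B) * w
      divv <- B[1, ] + B[2, ]            # d/dx on x-dofs + d/dy on y-dofs
      Ce <- Ce + tcrossprod(divv, Nparr[g, ]) * w
      dNp <- matrix(dNparr[e, g, , ], 4, 2)
      He <- He + perm[e] * tcrossprod(dNp) * w
    }
    ed <- edof[e, ]
    pd <- epid[e, ]
    iK[kpos + 1:324] <- rep(ed, 18L); jK[kpos + 1:324] <- rep(ed, each = 18L)
    xK[kpos + 1:324] <- as.numeric(Ke); kpos <- kpos + 324L
    iC[cpos + 1:72] <- rep(ed, 4L); jC[cpos + 1:72] <- rep(pd, each = 18L)
    xC[cpos + 1:72] <- as.numeric(Ce); cpos <- cpos + 72L
    iH[hpos + 1:16] <- rep(pd, 4L); jH[hpos + 1:16] <- rep(pd, each = 4L)
    xH[hpos + 1:16] <- as.numeric(He); hpos <- hpos + 16L
  }
  ndu <- 2L * nn
  K0 <- sparseMatrix(i = iK, j = jK, x = xK, dims = c(ndu, ndu))
  C <- sparseMatrix(i = iC, j = jC, x = xC, dims = c(ndu, np))
  H <- sparseMatrix(i = iH, j = jH, x = xH, dims = c(np, np))

  # fibril data: rank-one vector b = B' m per Gauss point, factor Ef * w
  fibvec <- array(0, c(ne, ng, 18L))
  fibfac <- matrix(0, ne, ng)
  for (e in seq_len(ne)) {
    if (mesh$efib[e] <= 0 || any(is.na(mesh$fibre[e, ]))) next
    d <- mesh$fibre[e, ]
    m <- c(d[1]^2, d[2]^2, d[1] * d[2])
    for (g in seq_len(ng)) {
      fibvec[e, g, ] <- crossprod(matrix(Barr[e, g, , ], 3, 18), m)
      fibfac[e, g] <- mesh$efib[e] * detJw[e, g]
    }
  }
  # cache the fully-active (linear tension regime) element fibril blocks:
  # most loaded elements have every Gauss point well past the blend zone, so
  # their 18x18 contribution is constant and need not be rebuilt per
  # iteration
  fib_el <- which(mesh$efib > 0 & !is.na(mesh$fibre[, 1L]))
  fib_full_x <- matrix(0, length(fib_el), 324L)
  ii0 <- rep(1:18, times = 18L)
  jj0 <- rep(1:18, each = 18L)
  for (r in seq_along(fib_el)) {
    e <- fib_el[r]
    Ke <- matrix(0, 18, 18)
    for (g in seq_len(ng)) {
      bv <- fibvec[e, g, ]
      Ke <- Ke + fibfac[e, g] * tcrossprod(bv)
    }
    fib_full_x[r, ] <- as.numeric(Ke)
  }
  fib_full_i <- matrix(0L, length(fib_el), 324L)
  fib_full_j <- matrix(0L, length(fib_el), 324L)
  if (length(fib_el)) {
    fib_full_i <- edof[fib_el, ii0, drop = FALSE]
    fib_full_j <- edof[fib_el, jj0, drop = FALSE]
  }

  list(ne = ne, nn = nn, ng = ng, ndu = ndu, np = np,
       fib_el = fib_el, fib_full_x = fib_full_x,
       fib_full_i = fib_full_i, fib_full_j = fib_full_j,
       pnodes = pnodes, pmap = pmap, edof = edof, epid = epid,
       Barr = Barr, detJw = detJw, Nparr = Nparr, dNparr = dNparr,
       gpxy = gpxy, K0 = K0, C = C, H = H,
       fibvec = fibvec, fibfac = fibfac,
       lam = lam, mu = mu, perm = perm)
}

# fibre strain at every Gauss point for a displacement vector u
fibril_strains <- function(pre, u) {
  eps <- matrix(0, pre$ne, pre$ng)
  Ue <- matrix(u[pre$edof], pre$ne, 18L)
  for (g in seq_len(pre$ng)) {
    eps[, g] <- rowSums(Ue * pre$fibvec[, g, ])
  }
  eps
}

# Tension-only fibril contribution with a small quadratic blend around zero
# fibre strain (half-width eps0): stress E (e+eps0)^2 / (4 eps0) inside the
# blend, E e above, zero below. The blended law is continuously
# differentiable, so the Newton iteration sees a smooth system; the stress
# error relative to the sharp tension-only law is at most E eps0 / 4
# (~1e-4 MPa at the default eps0 = 1e-4). Returns the tangent stiffness
# triplets and the residual-correction right-hand side, linearised at the
# supplied fibre strains.
assemble_fibril <- function(pre, eps, eps0 = 1e-4) {
  out <- list(K = NULL, rhs = numeric(pre$ndu))
  if (!length(pre$fib_el)) {
    out$K <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                          dims = c(pre$ndu, pre$ndu))
    return(out)
  }
  eel <- eps[pre$fib_el, , drop = FALSE]
  full <- rowSums(eel >= eps0) == pre$ng   # every Gauss point linear-active
  mixed <- which(!full & rowSums(eel > -eps0) > 0)
  ii <- as.integer(pre$fib_full_i[full, , drop = FALSE])
  jj <- as.integer(pre$fib_full_j[full, , drop = FALSE])
  vv <- as.numeric(pre$fib_full_x[full, , drop = FALSE])
  if (length(mixed)) {
    els <- pre$fib_el[mixed]
    idx <- which(eps[els, , drop = FALSE] > -eps0, arr.ind = TRUE)
    nact <- nrow(idx)
    Bact <- matrix(0, nact, 18L)
    wdet <- numeric(nact)
    e <- numeric(nact)
    for (r in seq_len(nact)) {
      el <- els[idx[r, 1L]]
      Bact[r, ] <- pre$fibvec[el, idx[r, 2L], ]
      wdet[r] <- pre$fibfac[el, idx[r, 2L]]
      e[r] <- eps[el, idx[r, 2L]]
    }
    blend <- e < eps0
    kf <- ifelse(blend, (e + eps0) / (2 * eps0), 1)     # tangent / Ef
    tf <- ifelse(blend, (e + eps0)^2 / (4 * eps0), e)   # stress / Ef
    ii0 <- rep(1:18, times = 18L)
    jj0 <- rep(1:18, each = 18L)
    ed <- pre$edof[els[idx[, 1L]], , drop = FALSE]
    V <- (Bact[, ii0, drop = FALSE] * Bact[, jj0, drop = FALSE]) *
      (wdet * kf)
    ii <- c(ii, as.integer(ed[, ii0, drop = FALSE]))
    jj <- c(jj, as.integer(ed[, jj0, drop = FALSE]))
    vv <- c(vv, as.numeric(V))
    # rhs: -(t0 - k e0) * b per Gauss point (zero in the linear range)
    coef <- wdet * (tf - kf * e)
    nz <- which(abs(coef) > 0)
    for (r in nz) {
      out$rhs[ed[r, ]] <- out$rhs[ed[r, ]] - coef[r] * Bact[r, ]
    }
  }
  out$K <- sparseMatrix(i = ii, j = jj, x = vv, dims = c(pre$ndu, pre$ndu))
  out
}

# consistent nodal load vector for unit compressive pressure on tagged edges
edge_traction_vector <- function(mesh, edges, ndu) {
  f <- numeric(ndu)
  gs <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  for (r in seq_len(nrow(edges))) {
    nids <- edges[r, 1:3]
    xe <- mesh$nodes[nids, , drop = FALSE]
    for (g in 1:3) {
      N <- edge_shape(gs[g])[1, ]
      dN <- edge_dshape(gs[g])[1, ]
      tanv <- as.numeric(crossprod(xe, dN))
      len <- sqrt(sum(tanv^2))
      nrm <- c(-tanv[2], tanv[1]) / len    # outward
      for (i in 1:3) {
        dofs <- c(2L * nids[i] - 1L, 2L * nids[i])
        f[dofs] <- f[dofs] - N[i] * nrm * len * gw[g]  # unit pressure inward
      }
    }
  }
  f
}

# tributary (Simpson) lengths of the nodes of a surface edge list
node_tributary <- function(mesh, edges) {
  acc <- numeric(nrow(mesh$nodes))
  for (r in seq_len(nrow(edges))) {
    nids <- edges[r, 1:3]
    xe <- mesh$nodes[nids, , drop = FALSE]
    # arc length by 3-pt quadrature
    gs <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    gw <- c(5, 8, 5) / 9
    len <- 0
    for (g in 1:3) {
      dN <- edge_dshape(gs[g])[1, ]
      len <- len + sqrt(sum(as.numeric(crossprod(xe, dN))^2)) * gw[g]
    }
    acc[nids] <- acc[nids] + len * c(1, 4, 1) / 6
  }
  acc
}
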