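# Penalty contact between deformable biphasic surfaces, with automatic
# switching between pressure-continuous (sealed) conditions inside the contact
# patch and free-draining (p = 0) conditions outside it. Node-to-segment,
# single pass: the points of the secondary surface are projected onto the
# piecewise-quadratic primary surface.

# Build a contact surface from a boundary tag. Edges are oriented so that
# rot90ccw(tangent) is the outward normal of the owning body.
contact_surface <- function(mesh, tag) {
  edges <- mesh$boundaries[[tag]]
  if (is.null(edges) || !nrow(edges)) {
    abort(paste0("Boundary tag '", tag, "' is empty: a contact surface needs ",
                 "at least one segment."))
  }
  list(tag = tag, edges = edges,
       nodes = sort(unique(as.integer(edges[, 1:3]))))
}

# Closest-point projection of one point onto a quadratic edge.
# X: deformed coordinates; returns list(s, dist, g, n, xm) or NULL.
project_on_edge <- function(X, nids, xs) {
  xe <- X[nids, , drop = FALSE]
  a <- xe[1, ]; b <- xe[3, ]
  ch <- b - a
  l2 <- sum(ch^2)
  if (l2 < 1e-20) abort("Degenerate zero-length contact segment.")
  s <- 2 * sum((xs - a) * ch) / l2 - 1
  s <- max(-1.2, min(1.2, s))
  for (it in 1:4) {
    N <- edge_shape(s)[1, ]; dN <- edge_dshape(s)[1, ]
    xm <- as.numeric(crossprod(xe, N))
    tv <- as.numeric(crossprod(xe, dN))
    r <- xs - xm
    f <- sum(r * tv)
    # curvature x''(s) is constant for a quadratic edge
    xpp <- as.numeric(crossprod(xe, c(1, -2, 1)))
    fp <- sum(r * xpp) - sum(tv * tv)
    if (abs(fp) < 1e-14) break
    s <- s - f / fp
    s <- max(-1.2, min(1.2, s))
  }
  # evaluate at the clamped foot: distances compared across edges must be
  # true segment distances (extrapolated feet would undercut the correct
  # neighbouring edge near shared ends); the raw parameter decides whether
  # the projection falls within the surface
  s_raw <- s
  s <- max(-1, min(1, s))
  N <- edge_shape(s)[1, ]; dN <- edge_dshape(s)[1, ]
  xm <- as.numeric(crossprod(xe, N))
  tv <- as.numeric(crossprod(xe, dN))
  tl <- sqrt(sum(tv^2))
  n <- c(-tv[2], tv[1]) / tl
  g <- -sum((xs - xm) * n)           # penetration-positive
  list(s = s, s_raw = s_raw, dist = sqrt(sum((xs - xm)^2)), g = g, n = n,
       xm = xm, N = N)
}

#' Project a point onto a contact surface and measure the gap
#'
#' Closest-point projection of a point onto a piecewise-quadratic surface.
#' The returned gap uses the penetration-positive convention: positive when
#' the point lies inside the body owning the surface, negative when the
#' contact is open. Points whose closest-point projection falls beyond the
#' ends of the surface are reported inactive.
#'
#' @param point Numeric length-2 coordinates, mm.
#' @param surface A surface as built from a boundary tag (list with `edges`).
#' @param mesh The `region_mesh` owning the surface.
#' @param displacement Optional nodal displacement matrix (n x 2) to evaluate
#'   on the deformed geometry.
#' @return A list: `gap` (mm), `normal` (outward unit vector), `edge` (row
#'   index), `s` (local coordinate), `active_domain` (FALSE when the point
#'   projects beyond the surface ends).
#' @export
project_and_gap <- function(point, surface, mesh, displacement = NULL) {
  X <- mesh$nodes
  if (!is.null(displacement)) X <- X + displacement
  best <- NULL; best_row <- NA_integer_
  for (r in seq_len(nrow(surface$edges))) {
    pr <- project_on_edge(X, surface$edges[r, 1:3], point)
    if (is.null(best) || pr$dist < best$dist) {
      best <- pr; best_row <- r
    }
  }
  list(gap = best$g, normal = best$n, edge = best_row, s = best$s,
       active_domain = best$s_raw >= -1 - 1e-6 && best$s_raw <= 1 + 1e-6)
}

#' Penalty contact traction
#'
#' Normal contact traction of the penalty method: the penetration (normal
#' overlap) multiplied by the penalty factor, zero for open contact.
#'
#' @param gap Penetration, mm (positive when surfaces overlap).
#' @param penalty_factor Penalty factor, N/mm^3.
#' @return Normal traction, MPa.
#' @export
penalty_traction <- function(gap, penalty_factor) {
  if (any(penalty_factor <= 0)) abort("`penalty_factor` must be positive.")
  pmax(gap, 0) * penalty_factor
}

#' Automatic penalty factor for a contact pair
#'
#' Deterministic surrogate for solver auto-penalty heuristics: the stiffer the
#' adjacent tissue and the finer the surface mesh, the larger the factor.
#' `factor = scale * min(H_A of the two sides) / characteristic segment
#' length`, with the characteristic length taken as the mean secondary segment
#' length.
#'
#' @param mesh A `region_mesh`.
#' @param materials Named list of [tissue_material()] per region.
#' @param secondary_tag,primary_tag Boundary tags of the two surfaces.
#' @param scale Dimensionless scale, default 100.
#' @return Penalty factor, N/mm^3.
#' @export
auto_penalty <- function(mesh, materials, secondary_tag, primary_tag,
                         scale = 100) {
  ha_of <- function(tag) {
    ed <- mesh$boundaries[[tag]]
    if (is.null(ed) || !nrow(ed)) abort(paste0("Empty surface '", tag, "'."))
    regs <- unique(mesh$region[ed[, 4L]])
    min(vapply(regs, function(rg) {
      m <- materials[[rg]]
      derived_elastic_constants(m$matrix_modulus,
                                m$poisson_ratio)$aggregate_modulus
    }, numeric(1)))
  }
  ha <- min(ha_of(secondary_tag), ha_of(primary_tag))
  ed <- mesh$boundaries[[secondary_tag]]
  lens <- vapply(seq_len(nrow(ed)), function(r) {
    sqrt(sum((mesh$nodes[ed[r, 3L], ] - mesh$nodes[ed[r, 1L], ])^2))
  }, numeric(1))
  scale * ha / mean(lens)
}

# Regularised penalty law used by the solver: linear `pen * g` beyond a small
# blend half-width `g_eps`, quadratic inside `|g| <= g_eps`, zero below
# `-g_eps`. Continuously differentiable, so contact activation is decided by
# geometry (gap crossing -g_eps) rather than by a force-critical switch at
# zero, which suppresses active-set chattering. As g_eps -> 0 this reduces to
# the sharp law of penalty_traction().
reg_contact <- function(g, pen, g_eps) {
  if (g_eps <= 0) {
    return(list(t = pen * max(g, 0), k = if (g > 0) pen else 0))
  }
  if (g >= g_eps) {
    list(t = pen * g, k = pen)
  } else if (g > -g_eps) {
    list(t = pen * (g + g_eps)^2 / (4 * g_eps),
         k = pen * (g + g_eps) / (2 * g_eps))
  } else {
    list(t = 0, k = 0)
  }
}

# Define a contact pair. Secondary points are the nodes of the secondary
# surface with Simpson tributary lengths.
contact_pair <- function(mesh, name, type, compartment,
                         secondary_tag, primary_tag, penalty) {
  sec <- contact_surface(mesh, secondary_tag)
  pri <- contact_surface(mesh, primary_tag)
  trib <- node_tributary(mesh, sec$edges)
  list(name = name, type = type, compartment = compartment,
       secondary = sec, primary = pri, penalty = penalty,
       points = sec$nodes, A = trib[sec$nodes],
       primary_trib = node_tributary(mesh, pri$edges))
}

# Evaluate all pairs on the deformed geometry. Secondary surfaces shared by
# several pairs (the femoral arc sees both the meniscus and the tibial
# cartilage) assign each point to the pair with the deepest penetration /
# nearest surface, so a point belongs to at most one pair per search.
# Returns one row per (pair, point): chosen primary edge, local coordinate,
# normal, gap, activity. The search runs once per time step; within the step
# the feet, normals and pairing stay frozen and only the gaps evolve
# (linearly) with the solution, so the step system is smooth with an exact
# contact tangent.
contact_eval <- function(pairs, mesh, X, band, g_eps = 0) {
  res <- vector("list", length(pairs))
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    npt <- length(pr$points)
    out <- list(
      pair = rep(ip, npt), node = pr$points, A = pr$A,
      g = rep(-Inf, npt), s = rep(NA_real_, npt),
      nx = rep(NA_real_, npt), ny = rep(NA_real_, npt),
      e1 = rep(NA_integer_, npt), e2 = rep(NA_integer_, npt),
      e3 = rep(NA_integer_, npt),
      N1 = rep(NA_real_, npt), N2 = rep(NA_real_, npt), N3 = rep(NA_real_, npt),
      dist = rep(Inf, npt), indom = rep(FALSE, npt)
    )
    emid <- (X[pr$primary$edges[, 1L], , drop = FALSE] +
             X[pr$primary$edges[, 3L], , drop = FALSE]) / 2
    elen <- sqrt(rowSums((X[pr$primary$edges[, 3L], , drop = FALSE] -
                          X[pr$primary$edges[, 1L], , drop = FALSE])^2))
    for (q in seq_len(npt)) {
      xs <- X[pr$points[q], ]
      d2 <- (emid[, 1L] - xs[1])^2 + (emid[, 2L] - xs[2])^2
      cand <- which(d2 <= (elen + band)^2)
      if (!length(cand)) next
      best <- NULL; bi <- NA_integer_
      for (r in cand) {
        prj <- project_on_edge(X, pr$primary$edges[r, 1:3], xs)
        if (is.null(best) || prj$dist < best$dist) { best <- prj; bi <- r }
      }
      out$dist[q] <- best$dist
      # smooth end fade: a projection sliding past a surface end loses its
      # force linearly over 10% of the end segment, so corner contacts
      # appear and disappear continuously instead of popping
      fade <- min(1, max(0, (1.1 - abs(best$s_raw)) / 0.1))
      out$indom[q] <- fade > 0
      out$A[q] <- out$A[q] * fade
      out$g[q] <- best$g
      out$s[q] <- best$s
      out$nx[q] <- best$n[1]; out$ny[q] <- best$n[2]
      out$e1[q] <- pr$primary$edges[bi, 1L]
      out$e2[q] <- pr$primary$edges[bi, 2L]
      out$e3[q] <- pr$primary$edges[bi, 3L]
      out$N1[q] <- best$N[1]; out$N2[q] <- best$N[2]; out$N3[q] <- best$N[3]
    }
    res[[ip]] <- out
  }
  # resolve shared secondary points: keep, per node, the pair with the
  # largest penetration (deepest g) among in-domain projections
  all_nodes <- unlist(lapply(res, `[[`, "node"))
  if (anyDuplicated(all_nodes)) {
    keyg <- unlist(lapply(res, function(o) ifelse(o$indom, o$g, -Inf)))
    keyp <- unlist(lapply(res, `[[`, "pair"))
    ord <- order(all_nodes, -keyg)
    dupl <- duplicated(all_nodes[ord])
    drop_key <- paste(keyp[ord][dupl], all_nodes[ord][dupl])
    for (ip in seq_along(res)) {
      k <- paste(res[[ip]]$pair, res[[ip]]$node)
      off <- k %in% drop_key
      res[[ip]]$indom[off] <- FALSE
      res[[ip]]$g[off] <- -Inf
    }
  }
  for (ip in seq_along(res)) {
    res[[ip]]$active <- res[[ip]]$indom & res[[ip]]$g > -g_eps
  }
  res
}

#' Drainage partition of the contact faces
#'
#' For a stored state, reports which exterior contact-face pressure nodes are
#' sealed (inside the contact patch, pressure continuous across the
#' interface) and which are free-draining (p ~ 0). The partition follows the
#' contact patch and is re-established at every time step; nodes in the
#' narrow blend zone at the patch edge are partially sealed
#' (`0 < seal_level < 1`).
#'
#' @param run A `creep_run` (see [run_creep()]).
#' @param time Output time at which to inspect the partition, s.
#' @return A tibble with one row per contact-face pressure node: `node`,
#'   `seal_level` in `[0, 1]`, and `status` (`"sealed"` when
#'   `seal_level > 0.5`, else `"draining"`).
#' @export
drainage_partition <- function(run, time = NULL) {
  st <- pick_state(run, time)
  cls <- st$drainage
  nodes <- sort(unique(c(cls$sealed_nodes, cls$draining)))
  lev <- cls$seal_level[nodes]
  tibble(
    node = nodes,
    seal_level = lev,
    status = ifelse(lev > 0.5, "sealed", "draining")
  )
}

# Pressure-jump penalty (sealed interface) triplets in the pressure block.
assemble_pressure_ties <- function(ties, pre, kappa) {
  if (!length(ties$node)) {
    return(list(ii = integer(), jj = integer(), vv = numeric()))
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (q in seq_along(ties$node)) {
    ps <- pre$pmap[ties$node[q]]
    p1 <- pre$pmap[ties$e1[q]]
    p3 <- pre$pmap[ties$e3[q]]
    if (ps == 0L || p1 == 0L || p3 == 0L) next
    dofs <- c(ps, p1, p3)
    w <- c(1, -ties$N1[q], -ties$N3[q])
    ka <- kappa * ties$A[q]
    ii <- c(ii, rep(dofs, 3L)); jj <- c(jj, rep(dofs, each = 3L))
    vv <- c(vv, ka * as.numeric(tcrossprod(w)))
  }
  list(ii = ii, jj = jj, vv = vv)
}


# Per-step linearisation data of the contact state: for every point the
# frozen gap gradient w (8 dofs: secondary node + 3 primary-edge nodes) and
# the affine offset gint such that g(z) = w' z + gint.
contact_linearize <- function(pairs, ceval, z_ref) {
  lin <- vector("list", length(ceval))
  for (ip in seq_along(ceval)) {
    ev <- ceval[[ip]]
    npt <- length(ev$node)
    D <- matrix(0L, npt, 8L)
    W <- matrix(0, npt, 8L)
    sel <- which(ev$indom)
    for (q in sel) {
      n <- c(ev$nx[q], ev$ny[q])
      D[q, ] <- c(2L * ev$node[q] - 1L, 2L * ev$node[q],
                  2L * ev$e1[q] - 1L, 2L * ev$e1[q],
                  2L * ev$e2[q] - 1L, 2L * ev$e2[q],
                  2L * ev$e3[q] - 1L, 2L * ev$e3[q])
      W[q, ] <- c(-n, ev$N1[q] * n, ev$N2[q] * n, ev$N3[q] * n)
    }
    wzref <- numeric(npt)
    wzref[sel] <- rowSums(W[sel, , drop = FALSE] *
                          matrix(z_ref[D[sel, , drop = FALSE]],
                                 length(sel), 8L))
    ev$D <- D
    ev$W <- W
    ev$gint <- ifelse(ev$indom, ev$g - wzref, -Inf)
    lin[[ip]] <- ev
  }
  lin
}

# Current gaps of all linearised points for iterate z.
contact_gaps <- function(lin, z) {
  lapply(lin, function(ev) {
    g <- rep(-Inf, length(ev$node))
    sel <- which(ev$indom)
    if (length(sel)) {
      g[sel] <- ev$gint[sel] +
        rowSums(ev$W[sel, , drop = FALSE] *
                matrix(z[ev$D[sel, , drop = FALSE]], length(sel), 8L))
    }
    g
  })
}

# Contact tangent and residual linearisation for the frozen-geometry step
# system: internal force A t(g) w with g affine in z, so the tangent
# A k(g) w w' is exact. Returns triplets plus the constant right-hand side.
assemble_contact_lin <- function(pairs, lin, gaps, ndu, g_eps) {
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(ndu)
  for (ip in seq_along(pairs)) {
    ev <- lin[[ip]]
    g <- gaps[[ip]]
    pen <- pairs[[ip]]$penalty
    act <- which(ev$indom & g > -g_eps)
    if (!length(act)) next
    nact <- length(act)
    tg <- numeric(nact); kg <- numeric(nact)
    for (r in seq_len(nact)) {
      rc <- reg_contact(g[act[r]], pen, g_eps)
      tg[r] <- rc$t; kg[r] <- rc$k
    }
    A <- ev$A[act]
    W <- ev$W[act, , drop = FALSE]
    D <- ev$D[act, , drop = FALSE]
    ii0 <- rep(1:8, times = 8L)
    jj0 <- rep(1:8, each = 8L)
    V <- (W[, ii0, drop = FALSE] * W[, jj0, drop = FALSE]) * (A * kg)
    ii <- c(ii, as.integer(D[, ii0, drop = FALSE]))
    jj <- c(jj, as.integer(D[, jj0, drop = FALSE]))
    vv <- c(vv, as.numeric(V))
    # rhs: -(A (t - k g) + A k gint) w  per point, accumulated densely
    coef <- A * (tg - kg * g[act] + kg * ev$gint[act])
    for (r in seq_len(nact)) {
      rhs[D[r, ]] <- rhs[D[r, ]] - coef[r] * W[r, ]
    }
  }
  list(ii = ii, jj = jj, vv = vv, rhs = rhs)
}

# Drainage partition for the frozen-geometry step system, driven by the
# per-iteration gaps of the linearised points.
classify_drainage_lin <- function(pairs, lin, gaps, pre, switch_on = TRUE,
                                  g_eps = 0, seal_band = 0) {
  nn <- length(pre$pmap)
  ties <- list(node = integer(), e1 = integer(), e3 = integer(),
               N1 = numeric(), N3 = numeric(), A = numeric())
  wlev <- numeric(nn)
  aref <- numeric(nn)
  face <- integer()
  for (ip in seq_along(pairs)) {
    pr <- pairs[[ip]]
    ev <- lin[[ip]]
    g <- gaps[[ip]]
    face <- c(face, pr$secondary$nodes, pr$primary$nodes)
    aref[pr$primary$nodes] <- pmax(aref[pr$primary$nodes],
                                   pr$primary_trib[pr$primary$nodes])
    aref[ev$node] <- pmax(aref[ev$node], ev$A)
    if (!switch_on) next
    sel <- which(ev$indom & g > -g_eps)
    if (!length(sel)) next
    # seal weight ramps from 0 at the contact blend edge (-g_eps) to 1 at
    # touch (+seal_band, default 0): any point genuinely in contact is fully
    # sealed regardless of how lightly it is loaded, and only the blend-zone
    # fringe of the moving patch is partially drained
    w <- if (seal_band + g_eps > 0) {
      pmin(1, pmax(0, (g[sel] + g_eps) / (seal_band + g_eps)))
    } else {
      as.numeric(g[sel] > 0)
    }
    keep <- w > 0
    sel <- sel[keep]; w <- w[keep]
    if (!length(sel)) next
    nd <- ev$node[sel]
    isp <- pre$pmap[nd] > 0L
    ties$node <- c(ties$node, nd[isp])
    ties$e1 <- c(ties$e1, ev$e1[sel][isp])
    ties$e3 <- c(ties$e3, ev$e3[sel][isp])
    ties$N1 <- c(ties$N1, (1 - ev$s[sel][isp]) / 2)
    ties$N3 <- c(ties$N3, (1 + ev$s[sel][isp]) / 2)
    ties$A <- c(ties$A, ev$A[sel][isp] * w[isp])
    for (r in seq_along(sel)) {
      q <- sel[r]
      if (isp[r]) wlev[nd[r]] <- max(wlev[nd[r]], w[r])
      wlev[ev$e1[q]] <- max(wlev[ev$e1[q]],
                            w[r] * min(1, max(0, 1 - ev$s[q])))
      wlev[ev$e3[q]] <- max(wlev[ev$e3[q]],
                            w[r] * min(1, max(0, 1 + ev$s[q])))
    }
  }
  face <- unique(face)
  face <- face[pre$pmap[face] > 0L]
  open_frac <- 1 - wlev[face]
  sel <- open_frac > 0
  list(ties = ties,
       drain_node = face[sel],
       drain_coef = aref[face[sel]] * open_frac[sel],
       seal_level = wlev)
}
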