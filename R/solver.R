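# Time marching and the per-step nonlinear solver.
#
# Each backward-Euler step freezes the contact geometry (feet, normals,
# pairing) at the previous converged state, so that the gaps are affine in
# the solution and the regularised contact and fibril laws make the step
# system smooth with an exact tangent. The sealed/free-draining partition is
# refreshed between inner convergences until it is self-consistent with the
# accepted state.

solve_step <- function(model, z_prev, t, dt, settings,
                       rigid_prev = c(0, 0)) {
  pre <- model$pre
  ndu <- pre$ndu
  ndof <- ndu + pre$np
  u_n <- z_prev[seq_len(ndu)]

  sched <- model$schedule
  fval <- ramp_hold(sched, t)

  # external load vector (per unit depth)
  f_u <- numeric(ndu)
  if (model$load$type == "traction") {
    f_u <- f_u + fval * model$load$f_unit
  }

  dir_dofs <- model$dirichlet$dofs
  dir_vals <- model$dirichlet$value(t)

  rigid <- model$rigid
  rigid_dofs <- integer()
  if (!is.null(rigid)) {
    rigid_dofs <- c(2L * rigid$nodes - 1L, 2L * rigid$nodes)
  }

  z <- z_prev
  rig_cur <- rigid_prev
  increment_small <- FALSE
  last_full_dz <- Inf
  prev_full_dz <- Inf
  converged <- FALSE
  n_iter <- 0L
  lin <- NULL
  gaps <- NULL
  drain <- list(ties = list(node = integer()), drain_node = integer())

  # Contact search once per step, on the geometry of the previous converged
  # state: feet, normals, fades and pairing stay frozen through the step and
  # only the gaps evolve (affinely) with the solution. The step system is
  # then smooth with an exact contact tangent, and the geometric
  # nonlinearity enters through the step-to-step search updates.
  if (!is.null(model$pairs)) {
    X <- model$mesh$nodes +
      matrix(z_prev[seq_len(ndu)], ncol = 2L, byrow = TRUE)
    ceval0 <- contact_eval(model$pairs, model$mesh, X, model$band,
                           model$contact_eps)
    lin <- contact_linearize(model$pairs, ceval0, z_prev)
  }

  # The sealed/free-draining partition is refreshed whenever the mechanical
  # iteration has converged under the previous partition (its gap
  # sensitivity is deliberately kept out of the Jacobian); the step is
  # accepted once a refresh no longer moves the solution, so the partition
  # is self-consistent with the accepted state.
  drain_stage <- 0L
  z_at_refresh <- NULL
  for (iter in seq_len(settings$newton_max_iter)) {
    n_iter <- iter
    u_cur <- z[seq_len(ndu)]

    if (!is.null(lin)) {
      gaps <- contact_gaps(lin, z)
      if (drain_stage == 0L || (increment_small && drain_stage < 10L)) {
        if (increment_small && !is.null(z_at_refresh) &&
            max(abs(z - z_at_refresh)) < 1e-4) {
          # partition self-consistent: accept
        } else {
          drain <- classify_drainage_lin(model$pairs, lin, gaps, pre,
                                         switch_on = model$drainage_switch,
                                         g_eps = model$contact_eps)
          z_at_refresh <- z
          if (increment_small) increment_small <- FALSE
          drain_stage <- drain_stage + 1L
        }
      }
    }
    fib_eps <- NULL
    if (any(pre$fibfac > 0)) fib_eps <- fibril_strains(pre, u_cur)
    pfix_nodes <- model$pfix_always
    if (isTRUE(settings$verbose > 1)) {
      fc <- if (is.null(lin)) NA_real_ else
        sum(vapply(seq_along(lin), function(ip) {
          g <- gaps[[ip]]
          a <- lin[[ip]]$indom & g > 0
          sum(model$pairs[[ip]]$penalty * g[a] * lin[[ip]]$A[a] *
                lin[[ip]]$ny[a])
        }, numeric(1)))
      message(sprintf(
        "  it %2d: active %s | fib %d | dz %.2e | v %.4f th %.5f | Fc %.3f",
        iter,
        if (is.null(lin)) "-" else
          paste(vapply(seq_along(lin), function(ip) {
            sum(lin[[ip]]$indom & gaps[[ip]] > -model$contact_eps)
          }, 0L), collapse = "/"),
        if (is.null(fib_eps)) 0L else sum(fib_eps > 0),
        last_full_dz, rig_cur[1L], rig_cur[2L], fc))
    }
    if (increment_small) {
      converged <- TRUE
      break
    }

    # --- assemble (K_base = matrix stiffness + grounded springs is
    # constant and cached on the model)
    K <- model$K_base %||% pre$K0
    b_u <- f_u
    if (!is.null(fib_eps)) {
      fib <- assemble_fibril(pre, fib_eps)
      K <- K + fib$K
      b_u <- b_u + fib$rhs
    }
    if (!is.null(lin)) {
      con <- assemble_contact_lin(model$pairs, lin, gaps, ndu,
                                  model$contact_eps)
      if (length(con$ii)) {
        K <- K + sparseMatrix(i = con$ii, j = con$jj, x = con$vv,
                              dims = c(ndu, ndu))
        b_u <- b_u + con$rhs
      }
    }
    Hblk <- dt * pre$H
    if (length(drain$ties$node)) {
      tie <- assemble_pressure_ties(drain$ties, pre, model$fluid_penalty)
      if (length(tie$ii)) {
        Hblk <- Hblk + sparseMatrix(i = tie$ii, j = tie$jj, x = tie$vv,
                                    dims = c(pre$np, pre$np))
      }
    }
    if (length(drain$drain_node)) {
      # ambient-drainage conductance on the open fraction of contact faces
      dn <- pre$pmap[drain$drain_node]
      Hblk <- Hblk + sparseMatrix(i = dn, j = dn,
                                  x = model$fluid_penalty * drain$drain_coef,
                                  dims = c(pre$np, pre$np))
    }
    A <- rbind(cbind(K, -pre$C), cbind(-t(pre$C), -Hblk))
    b <- c(b_u, -as.numeric(crossprod(pre$C, u_n)))

    # --- constraint reduction
    pfix_dofs <- ndu + pre$pmap[pfix_nodes]
    drop <- c(dir_dofs, rigid_dofs, pfix_dofs)
    kept <- setdiff(seq_len(ndof), drop)
    nred <- length(kept) + if (is.null(rigid)) 0L else 2L
    Ti <- kept; Tj <- seq_along(kept); Tx <- rep(1, length(kept))
    if (!is.null(rigid)) {
      vcol <- length(kept) + 1L
      tcol <- length(kept) + 2L
      xn <- model$mesh$nodes[rigid$nodes, , drop = FALSE]
      Ti <- c(Ti, 2L * rigid$nodes, 2L * rigid$nodes - 1L, 2L * rigid$nodes)
      Tj <- c(Tj, rep(vcol, length(rigid$nodes)),
              rep(tcol, 2L * length(rigid$nodes)))
      Tx <- c(Tx, rep(1, length(rigid$nodes)),
              -(xn[, 2L] - rigid$centre[2L]), xn[, 1L] - rigid$centre[1L])
    }
    T <- sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(ndof, nred))
    zD <- numeric(ndof)
    zD[dir_dofs] <- dir_vals
    A_red <- t(T) %*% A %*% T
    b_red <- as.numeric(t(T) %*% (b - A %*% zD))
    if (!is.null(rigid)) {
      A_red[vcol, vcol] <- A_red[vcol, vcol] + rigid$k_reg
      A_red[tcol, tcol] <- A_red[tcol, tcol] + rigid$k_reg_rot
      Fd <- fval / model$depth
      b_red[vcol] <- b_red[vcol] - Fd
      b_red[tcol] <- b_red[tcol] - Fd * sched$medial_offset
    }
    z_red <- tryCatch(as.numeric(solve(A_red, b_red)),
                      error = function(e) NULL)
    if (is.null(z_red) || any(!is.finite(z_red))) {
      return(list(ok = FALSE, reason = "singular or non-finite linear solve"))
    }
    z_new <- as.numeric(T %*% z_red) + zD

    # Clip large rigid-body increments (translation and rotation) so the
    # contact search stays local, and under-relax when the increments have
    # stopped contracting: the damped map has the same fixed point but
    # breaks the small-amplitude flip-flops that full Newton steps can
    # sustain across blend-zone boundaries, while quick full steps are kept
    # whenever the iteration is already converging.
    stalling <- is.finite(prev_full_dz) && last_full_dz >= 0.7 * prev_full_dz
    alpha <- if (iter > settings$damp_after && stalling) 0.5 else 1
    if (!is.null(rigid)) {
      dv <- z_red[vcol] - rig_cur[1L]
      dth <- z_red[tcol] - rig_cur[2L]
      move <- max(abs(dv), abs(dth) * rigid$span)
      if (is.finite(move) && alpha * move > model$clip) {
        alpha <- model$clip / move
      }
      rig_cur <- rig_cur + alpha * c(dv, dth)
    }
    full_dz <- max(abs(z_new - z))   # undamped Newton increment
    prev_full_dz <- last_full_dz
    last_full_dz <- full_dz
    z <- z + alpha * (z_new - z)
    zscale <- max(max(abs(z)), 1e-6)
    # absolute floor: increments below 1e-7 mm are far inside the contact
    # penetration scale and the blend widths
    increment_small <- full_dz <
      max(settings$newton_tol_rel * zscale, 1e-7)
  }

  if (!converged) {
    return(list(ok = FALSE, reason = "nonlinear iteration failed to converge"))
  }

  # reactions / residual bookkeeping at the accepted solution
  resid <- as.numeric(A %*% z - b)
  resid[seq_len(ndu)] <- resid[seq_len(ndu)]  # u rows: f_int - f_ext
  free_res <- sqrt(sum(resid[kept]^2)) / max(1, sqrt(sum(b[kept]^2)))

  ceval <- NULL
  max_pen <- 0
  if (!is.null(lin)) {
    gaps <- contact_gaps(lin, z)
    ceval <- lin
    for (ip in seq_along(ceval)) {
      ceval[[ip]]$g <- gaps[[ip]]
      ceval[[ip]]$active <- ceval[[ip]]$indom &
        gaps[[ip]] > -model$contact_eps
    }
    gall <- unlist(lapply(ceval, function(o) o$g[o$active]))
    if (length(gall)) max_pen <- max(gall)
  }

  rigid_state <- NULL
  if (!is.null(rigid)) rigid_state <- c(v = rig_cur[1L], theta = rig_cur[2L])

  list(ok = TRUE, z = z, iterations = n_iter, residual = free_res,
       ceval = ceval, drain = drain, resid_full = resid,
       rigid = rigid_state, applied = fval, max_pen = max_pen, t = t, dt = dt)
}


#' March a model through a ramp-hold protocol
#'
#' Advances the coupled biphasic system with backward Euler and adaptive step
#' growth, hitting every requested output time exactly (steps are clipped to
#' the output grid, which always includes the end of the load ramp). A step
#' whose active-set iteration fails is retried with half the step until the
#' retry budget is exhausted; the last good state is preserved in the error.
#'
#' @param model An assembled model (see [build_column_model()],
#'   [build_strip_model()], [build_joint_model()]).
#' @param output_times Strictly increasing times, s, at which converged states
#'   are stored.
#' @param settings A [solver_settings()].
#' @return A `fe_march` object: list with `states` (one per output time) and
#'   `log` (per-step tibble: time, dt, iterations, residual, penetration).
#' @export
time_march <- function(model, output_times, settings = solver_settings()) {
  output_times <- sort(unique(output_times))
  if (any(output_times <= 0)) abort("`output_times` must be positive.")
  must <- sort(unique(c(model$schedule$ramp_duration, output_times)))
  must <- must[must > 0]

  ndof <- model$pre$ndu + model$pre$np
  z <- numeric(ndof)
  rig <- c(0, 0)
  t <- 0
  dt <- settings$dt_initial
  states <- list()
  log <- list()
  t_end <- max(output_times)
  step_id <- 0L

  while (t < t_end - 1e-9) {
    t_next <- t + dt
    upcoming <- must[must > t + 1e-9]
    if (length(upcoming) && t_next > upcoming[1] - 1e-9) {
      t_next <- upcoming[1]
    }
    attempt <- 0L
    res <- NULL
    repeat {
      res <- solve_step(model, z, t_next, t_next - t, settings, rig)
      if (res$ok) break
      attempt <- attempt + 1L
      if (attempt > settings$retry_budget) {
        abort(paste0("Time step at t = ", signif(t_next, 6),
                     " s failed after ", attempt - 1L, " halvings: ",
                     res$reason, ". Last good state at t = ", t, " s."),
              class = "poroknee_march_error",
              states = states, solver_log = dplyr::bind_rows(log),
              last_z = z, last_t = t, last_rigid = rig)
      }
      t_next <- t + (t_next - t) / 2
    }
    step_id <- step_id + 1L
    log[[step_id]] <- tibble(
      step = step_id, time = t_next, dt = t_next - t,
      iterations = res$iterations, residual = res$residual,
      max_penetration = res$max_pen, applied = res$applied
    )
    if (settings$verbose) {
      message(sprintf("step %3d  t=%9.3f  dt=%8.3f  it=%2d  pen=%.2e",
                      step_id, t_next, t_next - t, res$iterations,
                      res$max_pen))
    }
    dt_taken <- t_next - t
    z <- res$z
    if (!is.null(res$rigid)) rig <- unname(res$rigid)
    t <- t_next
    if (any(abs(output_times - t) < 1e-8)) {
      states[[length(states) + 1L]] <- make_state(model, res)
    }
    # grow from the attempted step when it was merely clipped to an output
    # time, but from the achieved step after convergence failures
    dt <- if (attempt > 0L) dt_taken * settings$dt_growth
          else min(max(dt_taken, dt) * settings$dt_growth, settings$dt_max)
    dt <- min(dt, settings$dt_max)
  }
  structure(list(states = states, log = dplyr::bind_rows(log), model = model),
            class = "fe_march")
}

# condense a converged step into a stored state
make_state <- function(model, res) {
  pre <- model$pre
  u <- matrix(res$z[seq_len(pre$ndu)], ncol = 2L, byrow = TRUE)
  p <- res$z[pre$ndu + seq_len(pre$np)]
  contact <- NULL
  sealed_nodes <- integer()
  if (!is.null(res$ceval)) {
    rows <- list()
    for (ip in seq_along(model$pairs)) {
      pr <- model$pairs[[ip]]
      ev <- res$ceval[[ip]]
      rows[[ip]] <- tibble(
        pair = pr$name, type = pr$type, compartment = pr$compartment,
        node = ev$node,
        x = model$mesh$nodes[ev$node, 1L],
        gap = ev$g, A = ev$A,
        nx = ev$nx, ny = ev$ny,
        active = ev$active,
        traction = vapply(seq_along(ev$node), function(q) {
          if (!ev$active[q]) return(0)
          reg_contact(ev$g[q], pr$penalty, model$contact_eps)$t
        }, numeric(1))
      )
    }
    contact <- dplyr::bind_rows(rows)
    sealed_nodes <- unique(res$drain$ties$node[res$drain$ties$A > 0])
  }
  list(t = res$t, z = res$z, u = u, p = p, rigid = res$rigid,
       applied = res$applied, contact = contact,
       drainage = list(draining = res$drain$drain_node,
                       sealed_nodes = sealed_nodes,
                       seal_level = res$drain$seal_level),
       resid_full = res$resid_full, max_pen = res$max_pen)
}

# Gauss-point strain/stress/pressure recovery for one state.
# Returns matrices (ne x 9) of field values plus element region labels.
recover_gp_fields <- function(model, state) {
  pre <- model$pre
  u <- state$z[seq_len(pre$ndu)]
  p <- state$z[pre$ndu + seq_len(pre$np)]
  ne <- pre$ne; ng <- pre$ng
  Ue <- matrix(u[pre$edof], ne, 18L)
  Pe <- matrix(p[pre$epid], ne, 4L)
  exx <- eyy <- gxy <- pgp <- matrix(0, ne, ng)
  for (g in seq_len(ng)) {
    exx[, g] <- rowSums(Ue * pre$Barr[, g, 1L, ])
    eyy[, g] <- rowSums(Ue * pre$Barr[, g, 2L, ])
    gxy[, g] <- rowSums(Ue * pre$Barr[, g, 3L, ])
    pgp[, g] <- as.numeric(Pe %*% pre$Nparr[g, ])
  }
  lam <- pre$lam; mu <- pre$mu
  tr <- exx + eyy
  sxx <- lam * tr + 2 * mu * exx
  syy <- lam * tr + 2 * mu * eyy
  sxy <- mu * gxy
  szz <- lam * tr
  # fibril contribution (tension-only)
  fib <- model$mesh$efib > 0 & !is.na(model$mesh$fibre[, 1L])
  if (any(fib)) {
    dx <- model$mesh$fibre[, 1L]; dy <- model$mesh$fibre[, 2L]
    epsf <- dx^2 * exx + dy^2 * eyy + dx * dy * gxy
    sf <- (model$mesh$efib * (epsf > 0) * epsf)
    sf[!fib, ] <- 0
    sxx <- sxx + sf * dx^2
    syy <- syy + sf * dy^2
    sxy <- sxy + sf * dx * dy
  }
  # total stress and principal values
  sxxt <- sxx - pgp; syyt <- syy - pgp; szzt <- szz - pgp
  cen <- (sxxt + syyt) / 2
  rad <- sqrt(((sxxt - syyt) / 2)^2 + sxy^2)
  s3 <- pmin(cen - rad, szzt)
  list(exx = exx, eyy = eyy, gxy = gxy, pressure = pgp,
       sxx_eff = sxx, syy_eff = syy, sxy_eff = sxy, szz_eff = szz,
       sxx_tot = sxxt, syy_tot = syyt, szz_tot = szzt,
       principal_min_tot = s3, region = model$mesh$region,
       gpx = pre$gpxy[, , 1L], gpy = pre$gpxy[, , 2L])
}
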