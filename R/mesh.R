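# Structured 9-node quadrilateral mesh blocks and the region_mesh container.
#
# Elements are 9-node Lagrange quads (biquadratic displacement); the 4 corner
# nodes double as the bilinear pressure nodes of the Taylor-Hood mixed pair.
# Local node ordering: corners 1-4 counter-clockwise from (-1,-1), midsides
# 5-8 (bottom, right, top, left), centre 9.

# Generate one structured block by mapping the unit square through `mapfun`.
# mapfun(xi, eta) with xi, eta in [0,1] (vectorised) -> cbind(x, y).
mesh_block <- function(nx, ny, mapfun) {
  stopifnot(nx >= 1, ny >= 1)
  gx <- 2L * nx + 1L
  gy <- 2L * ny + 1L
  xi <- rep(seq(0, 1, length.out = gx), times = gy)
  eta <- rep(seq(0, 1, length.out = gy), each = gx)
  nodes <- mapfun(xi, eta)
  idx <- function(i, j) (j) * gx + i + 1L  # i, j zero-based half-step indices

  elems <- matrix(0L, nx * ny, 9L)
  e <- 0L
  for (ej in seq_len(ny) - 1L) {
    for (ei in seq_len(nx) - 1L) {
      e <- e + 1L
      i0 <- 2L * ei
      j0 <- 2L * ej
      elems[e, ] <- c(
        idx(i0, j0), idx(i0 + 2L, j0), idx(i0 + 2L, j0 + 2L), idx(i0, j0 + 2L),
        idx(i0 + 1L, j0), idx(i0 + 2L, j0 + 1L), idx(i0 + 1L, j0 + 2L),
        idx(i0, j0 + 1L), idx(i0 + 1L, j0 + 1L)
      )
    }
  }

  side_edges <- function(side) {
    out <- matrix(0L, switch(side, bottom = nx, top = nx, left = ny,
                             right = ny), 4L)
    for (s in seq_len(nrow(out))) {
      i0 <- 2L * (s - 1L)
      out[s, ] <- switch(side,
        bottom = c(idx(i0, 0L), idx(i0 + 1L, 0L), idx(i0 + 2L, 0L),
                   s),
        top    = c(idx(i0, 2L * ny), idx(i0 + 1L, 2L * ny),
                   idx(i0 + 2L, 2L * ny), (ny - 1L) * nx + s),
        left   = c(idx(0L, i0), idx(0L, i0 + 1L), idx(0L, i0 + 2L),
                   (s - 1L) * nx + 1L),
        right  = c(idx(2L * nx, i0), idx(2L * nx, i0 + 1L),
                   idx(2L * nx, i0 + 2L), s * nx)
      )
    }
    colnames(out) <- c("n1", "n2", "n3", "elem")
    out
  }

  list(nodes = nodes, elems = elems,
       sides = list(bottom = side_edges("bottom"), right = side_edges("right"),
                    top = side_edges("top"), left = side_edges("left")))
}

# Orient boundary edges so the outward normal convention holds:
# n = rot90ccw(x3 - x1) points away from the owning element's centre node.
orient_edges <- function(edges, nodes, elems) {
  if (!nrow(edges)) return(edges)
  for (r in seq_len(nrow(edges))) {
    a <- nodes[edges[r, 1L], ]
    b <- nodes[edges[r, 3L], ]
    cen <- nodes[elems[edges[r, 4L], 9L], ]
    tan <- b - a
    nrm <- c(-tan[2L], tan[1L])
    mid <- nodes[edges[r, 2L], ]
    if (sum(nrm * (mid - cen)) < 0) {
      edges[r, c(1L, 3L)] <- edges[r, c(3L, 1L)]
    }
  }
  edges
}

new_region_mesh <- function(nodes, elems, region, boundaries,
                            fibre = NULL, fibre_label = NULL, efib = NULL,
                            springs = NULL, params = list()) {
  structure(
    list(
      nodes = nodes, elems = elems, region = region,
      boundaries = boundaries,
      fibre = fibre %||% matrix(NA_real_, nrow(elems), 2L),
      fibre_label = fibre_label %||% rep(NA_character_, nrow(elems)),
      efib = efib %||% rep(0, nrow(elems)),
      springs = springs %||%
        tibble(node = integer(), dir = character(), stiffness = numeric()),
      params = params
    ),
    class = "region_mesh"
  )
}

# Merge disjoint bodies (no shared nodes; bodies interact through contact).
merge_blocks <- function(parts) {
  offset <- 0L
  nodes <- NULL; elems <- NULL; region <- character()
  boundaries <- list()
  for (p in parts) {
    nn <- nrow(p$block$nodes)
    ne <- nrow(p$block$elems)
    nodes <- rbind(nodes, p$block$nodes)
    el <- p$block$elems + offset
    eoff <- if (is.null(elems)) 0L else nrow(elems)
    elems <- rbind(elems, el)
    region <- c(region, rep(p$region, ne))
    for (tag in names(p$tags)) {
      ed <- p$tags[[tag]]
      if (!nrow(ed)) next
      ed[, 1:3] <- ed[, 1:3] + offset
      ed[, 4L] <- ed[, 4L] + eoff
      boundaries[[tag]] <- rbind(boundaries[[tag]], ed)
    }
    offset <- offset + nn
  }
  for (tag in names(boundaries)) {
    boundaries[[tag]] <- orient_edges(boundaries[[tag]], nodes, elems)
  }
  new_region_mesh(nodes, elems, region, boundaries)
}

# Mirror a block about x = 0, restoring counter-clockwise element orientation.
mirror_block <- function(block) {
  perm <- c(2L, 1L, 4L, 3L, 5L, 8L, 7L, 6L, 9L)
  block$nodes[, 1L] <- -block$nodes[, 1L]
  block$elems <- block$elems[, perm, drop = FALSE]
  # edge orientation is re-derived later by orient_edges
  block
}

#' Nodes belonging to a boundary tag
#'
#' @param mesh A `region_mesh`.
#' @param tag Boundary tag name.
#' @return Sorted integer vector of node ids.
#' @export
boundary_nodes <- function(mesh, tag) {
  ed <- mesh$boundaries[[tag]]
  if (is.null(ed)) abort(paste0("Unknown boundary tag '", tag, "'."))
  sort(unique(as.integer(ed[, 1:3])))
}

#' Pressure (corner) nodes of a mixed-order mesh
#'
#' The bilinear pressure field lives on the element corner nodes, a strict
#' subset of the biquadratic displacement nodes.
#'
#' @param mesh A `region_mesh`.
#' @return Sorted integer vector of node ids carrying pressure DOFs.
#' @export
pressure_nodes <- function(mesh) {
  sort(unique(as.integer(mesh$elems[, 1:4])))
}

#' @export
print.region_mesh <- function(x, ...) {
  cat("<region_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elems),
      " biquadratic elements\n", sep = "")
  cat("  regions:", paste(sort(unique(x$region)), collapse = ", "), "\n")
  cat("  boundary tags:", paste(names(x$boundaries), collapse = ", "), "\n")
  invisible(x)
}

# Minimum Jacobian determinant over all Gauss points (mesh validity check).
min_jacobian <- function(mesh) {
  gp <- gauss9()
  mn <- Inf
  for (e in seq_len(nrow(mesh$elems))) {
    xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (g in seq_len(9L)) {
      dN <- q2_dshape(gp$pts[g, 1L], gp$pts[g, 2L])
      J <- t(dN) %*% xe
      mn <- min(mn, det(J))
    }
  }
  mn
}
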