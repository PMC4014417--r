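#' @keywords internal
#' Force matrices are (2 * n_nodes - 1) x 2 over bodies (nodes 1..n, then
#' spacers 1..n-1); spacer torques ride along as the "torque" attribute
#' (length n - 1, pN um).
zero_forces <- function(params) {
  f <- matrix(0, nrow = 2L * params$n_nodes - 1L, ncol = 2L)
  attr(f, "torque") <- rep(0, params$n_nodes - 1L)
  f
}

spacer_endpoints <- function(state, params) {
  u <- cbind(cos(state$sp_angle), sin(state$sp_angle))
  h <- params$spacer_length / 2
  list(lead = state$sp_pos + h * u, trail = state$sp_pos - h * u, u = u)
}

#' Joint-spring forces
#'
#' Each rotational joint is a zero-rest-length linear spring between a node
#' centre and the coincident spacer endpoint (spacer `j` joins node `j` at
#' its leading end and node `j + 1` at its trailing end). Hooke's law gives
#' equal-and-opposite forces of magnitude `k_joint * |displacement|`; forces
#' applied at spacer endpoints also exert torque about the spacer centre.
#'
#' @param state A `cell_state`.
#' @param params A [mech_params()] object.
#' @return Per-body force matrix (pN) with a `"torque"` attribute for the
#'   spacers (pN um).
#' @export
joint_forces <- function(state, params) {
  if (!all(is.finite(state$nodes)) || !all(is.finite(state$sp_pos)) ||
      !all(is.finite(state$sp_angle))) {
    stop("joint_forces: non-finite state (numerical blow-up)", call. = FALSE)
  }
  n <- params$n_nodes
  f <- zero_forces(params)
  tq <- attr(f, "torque")
  ep <- spacer_endpoints(state, params)
  for (j in seq_len(n - 1L)) {
    for (side in c("lead", "trail")) {
      node <- if (side == "lead") j else j + 1L
      p <- ep[[side]][j, ]           # spacer endpoint
      q <- state$nodes[node, ]       # node centre
      fn <- params$k_joint * (p - q) # force on the node, toward the endpoint
      f[node, ] <- f[node, ] + fn
      f[n + j, ] <- f[n + j, ] - fn
      arm <- p - state$sp_pos[j, ]
      tq[j] <- tq[j] + arm[1] * (-fn[2]) - arm[2] * (-fn[1])
    }
  }
  attr(f, "torque") <- tq
  f
}

#' Angular-spring bending forces
#'
#' An angular spring spans every three consecutive nodes and resists bending
#' away from the straight (rest angle pi) configuration with bending energy
#' `E = k_bend / 2 * (theta - pi)^2` per triple. Forces are the exact
#' negative gradient of E: perpendicular to the arms on the flanking nodes,
#' with the centre-node force cancelling their sum (zero net force and zero
#' axial component per triple).
#'
#' @inheritParams joint_forces
#' @return Per-body force matrix (pN); spacers receive zero.
#' @export
bending_forces <- function(state, params) {
  n <- params$n_nodes
  f <- zero_forces(params)
  for (i in seq(2L, n - 1L)) {
    a <- state$nodes[i - 1L, ]; b <- state$nodes[i, ]; c <- state$nodes[i + 1L, ]
    u <- a - b; v <- c - b
    lu2 <- sum(u^2); lv2 <- sum(v^2)
    if (lu2 == 0 || lv2 == 0) {
      stop("bending_forces: degenerate (zero-length) arm at node ", i,
           call. = FALSE)
    }
    cr <- u[1] * v[2] - u[2] * v[1]
    dt <- sum(u * v)
    theta <- atan2(cr, dt)
    # gradient of theta = atan2(u x v, u . v) wrt u and v
    den <- cr^2 + dt^2
    dth_du <- (dt * c(v[2], -v[1]) - cr * v) / den
    dth_dv <- (dt * c(-u[2], u[1]) - cr * u) / den
    # E uses the unsigned opening angle |theta| with rest value pi
    s <- if (theta < 0) -1 else 1
    coef <- -params$k_bend * (s * theta - pi) * s
    fa <- coef * dth_du
    fc <- coef * dth_dv
    f[i - 1L, ] <- f[i - 1L, ] + fa
    f[i + 1L, ] <- f[i + 1L, ] + fc
    f[i, ] <- f[i, ] - fa - fc
  }
  f
}

#' Bending energy of a cell (used as the finite-difference oracle target)
#'
#' @inheritParams joint_forces
#' @return Total bending energy, pN um.
#' @export
bending_energy <- function(state, params) {
  n <- params$n_nodes
  e <- 0
  for (i in seq(2L, n - 1L)) {
    u <- state$nodes[i - 1L, ] - state$nodes[i, ]
    v <- state$nodes[i + 1L, ] - state$nodes[i, ]
    theta <- abs(atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)))
    e <- e + params$k_bend / 2 * (theta - pi)^2
  }
  e
}

#' Gliding propulsion forces
#'
#' A constant-magnitude motility force `f_prop` acts at every interior node
#' (the poles are force-free), directed along the segment toward the next
#' node in the travel direction, i.e. the unit vector from node `i` to node
#' `i - 1`.
#'
#' @inheritParams joint_forces
#' @return Per-body force matrix (pN).
#' @export
propulsion_forces <- function(state, params) {
  n <- params$n_nodes
  f <- zero_forces(params)
  for (i in seq(2L, n - 1L)) {
    d <- state$nodes[i - 1L, ] - state$nodes[i, ]
    f[i, ] <- params$f_prop * d / sqrt(sum(d^2))
  }
  f
}

#' Stokes drag forces
#'
#' Every body experiences `-gamma_node * velocity`; spacers additionally
#' experience rotational drag `-gamma_rot * omega` with
#' `gamma_rot = gamma_node * (spacer_length^2 + cell_width^2) / 12`, the
#' drag distributed over the spacer's extent (so the rotational and
#' translational relaxation rates coincide).
#'
#' @inheritParams joint_forces
#' @return Per-body force matrix (pN) with rotational drag in the `"torque"`
#'   attribute.
#' @export
drag_forces <- function(state, params) {
  n <- params$n_nodes
  f <- zero_forces(params)
  f[seq_len(n), ] <- -params$gamma_node * state$node_vel
  f[seq(n + 1L, 2L * n - 1L), ] <- -params$gamma_node * state$sp_vel
  attr(f, "torque") <- -gamma_rot(params) * state$sp_omega
  f
}

gamma_rot <- function(params) {
  params$gamma_node * (params$spacer_length^2 + params$cell_width^2) / 12
}

spacer_inertia <- function(params) {
  params$body_mass * (params$spacer_length^2 + params$cell_width^2) / 12
}

#' Substrate adhesion forces and bond bookkeeping
#'
#' For each intact bond the node's displacement from its anchor is split
#' into axial and lateral components relative to the bond axis — the
#' cell's local axis at the moment the bond formed, frozen thereafter. The
#' anchor slides freely along this line (it is advanced by the axial
#' component each call), so motors can translocate the cell along its axis
#' against stationary adhesions, while displacement perpendicular to the
#' line is loaded: `F = -kappa * lateral`. A lateral stretch beyond
#' `d_break` breaks the bond (zero force) and schedules reformation after
#' an exponential waiting time with mean `1 / reform_rate`; a broken bond
#' whose time has come re-anchors at the node's current position with the
#' current local axis.
#'
#' Uses R's RNG stream for waiting times; seed the session for reproducible
#' runs.
#'
#' @inheritParams joint_forces
#' @param bonds Bond table as produced by [init_bonds()].
#' @param aparams An [adhesion_params()] object with `mode = "ECM"`.
#' @param now Current simulation time, min.
#' @return `list(forces = per-body force matrix, bonds = updated bond table)`.
#' @export
adhesion_forces <- function(state, bonds, aparams, params, now = 0) {
  if (aparams$mode == "VCM") {
    stop("adhesion_forces: no bonds exist under viscous coupling (VCM)",
         call. = FALSE)
  }
  f <- zero_forces(params)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$node[k]
    if (!bonds$intact[k]) {
      if (bonds$reform_at[k] <= now) {
        bonds$intact[k] <- TRUE
        bonds$ax[k] <- state$nodes[i, 1]
        bonds$ay[k] <- state$nodes[i, 2]
        axis <- state$nodes[i - 1L, ] - state$nodes[i + 1L, ]
        axis <- axis / sqrt(sum(axis^2))
        bonds$ux[k] <- axis[1]  # bond axis frozen at formation
        bonds$uy[k] <- axis[2]
      }
      next
    }
    axis <- c(bonds$ux[k], bonds$uy[k])  # frozen at bond formation
    disp <- state$nodes[i, ] - c(bonds$ax[k], bonds$ay[k])
    ax_comp <- sum(disp * axis)
    # anchor slides along the bond line: axial motion is free
    bonds$ax[k] <- bonds$ax[k] + ax_comp * axis[1]
    bonds$ay[k] <- bonds$ay[k] + ax_comp * axis[2]
    bonds$slid[k] <- bonds$slid[k] + ax_comp
    lateral <- disp - ax_comp * axis
    stretch <- sqrt(sum(lateral^2))
    if (stretch > aparams$d_break) {
      bonds$intact[k] <- FALSE
      bonds$reform_at[k] <- now + stats::rexp(1, rate = aparams$reform_rate)
      bonds$slid[k] <- 0
    } else {
      f[i, ] <- f[i, ] - aparams$kappa * lateral
      # adhesion turnover: after one node spacing of axial travel the load
      # is handed to a fresh site at the node's current position
      if (abs(bonds$slid[k]) >= params$spacer_length) {
        bonds$ax[k] <- state$nodes[i, 1]
        bonds$ay[k] <- state$nodes[i, 2]
        axis <- state$nodes[i - 1L, ] - state$nodes[i + 1L, ]
        axis <- axis / sqrt(sum(axis^2))
        bonds$ux[k] <- axis[1]
        bonds$uy[k] <- axis[2]
        bonds$slid[k] <- 0
      }
    }
  }
  list(forces = f, bonds = bonds)
}

#' Detect contacts between bodies of different cells
#'
#' All-pairs circle-circle and circle-rectangle overlap tests between bodies
#' belonging to different cells (intra-cell contacts are never reported).
#' The contact normal is the unit vector from body `a` into body `b`.
#'
#' @param world A `glider_world`.
#' @return Tibble with one row per overlap: `cell_a`, `body_a`, `cell_b`,
#'   `body_b` (body index: nodes `1..n`, spacers `n+1..2n-1`), `depth` (um),
#'   `nx`, `ny` (unit normal), `px`, `py` (contact point, um).
#' @export
detect_contacts <- function(world) {
  p <- world$params
  out <- list()
  nc <- length(world$cells)
  for (ia in seq_len(nc)) for (ib in seq_len(nc)) {
    if (ib <= ia) next
    for (a in seq_len(2L * p$n_nodes - 1L)) {
      for (b in seq_len(2L * p$n_nodes - 1L)) {
        ev <- body_contact(world$cells[[ia]], a, world$cells[[ib]], b, p)
        if (!is.null(ev)) {
          out[[length(out) + 1L]] <- c(cell_a = ia, body_a = a,
                                       cell_b = ib, body_b = b, ev)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(cell_a = integer(), body_a = integer(),
                          cell_b = integer(), body_b = integer(),
                          depth = double(), nx = double(), ny = double(),
                          px = double(), py = double()))
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, out)))
}

# circle-circle, circle-rectangle and spacer-spacer (capsule) primitives;
# the capsule test is required because obliquely crossing cells can
# otherwise tunnel between the node circles
body_contact <- function(ca, a, cb, b, p) {
  n <- p$n_nodes
  a_circ <- a <= n; b_circ <- b <= n
  if (!a_circ && !b_circ) {
    ja <- a - n; jb <- b - n
    return(capsule_capsule(ca$sp_pos[ja, ], ca$sp_angle[ja],
                           cb$sp_pos[jb, ], cb$sp_angle[jb],
                           p$spacer_length, p$cell_width))
  }
  if (a_circ && b_circ) {
    return(circle_circle(ca$nodes[a, ], cb$nodes[b, ], p$node_radius))
  }
  if (a_circ && !b_circ) {
    j <- b - n
    ev <- circle_rect(ca$nodes[a, ], p$node_radius,
                      cb$sp_pos[j, ], cb$sp_angle[j],
                      p$spacer_length, p$cell_width)
    return(ev)
  }
  if (!a_circ && b_circ) {
    j <- a - n
    ev <- circle_rect(cb$nodes[b, ], p$node_radius,
                      ca$sp_pos[j, ], ca$sp_angle[j],
                      p$spacer_length, p$cell_width)
    if (is.null(ev)) return(NULL)
    # normal must point from a into b: flip the circle-into-rect normal
    ev[c("nx", "ny")] <- -ev[c("nx", "ny")]
    return(ev)
  }
  NULL
}

# closest points between two segments, clamped parametric solution
seg_seg_closest <- function(a0, a1, b0, b1) {
  da <- a1 - a0; db <- b1 - b0; r <- a0 - b0
  A <- sum(da^2); B <- sum(da * db); C <- sum(db^2)
  D <- sum(da * r); E <- sum(db * r)
  den <- A * C - B^2
  s <- if (den > 1e-14) (B * E - C * D) / den else 0
  s <- min(1, max(0, s))
  t <- if (C > 1e-14) (B * s + E) / C else 0
  t <- min(1, max(0, t))
  s <- if (A > 1e-14) (B * t - D) / A else 0
  s <- min(1, max(0, s))
  list(pa = a0 + s * da, pb = b0 + t * db)
}

capsule_capsule <- function(pa, anga, pb, angb, len, width) {
  h <- len / 2
  ua <- c(cos(anga), sin(anga)); ub <- c(cos(angb), sin(angb))
  cp <- seg_seg_closest(pa - h * ua, pa + h * ua, pb - h * ub, pb + h * ub)
  d <- cp$pb - cp$pa
  dist <- sqrt(sum(d^2))
  if (dist >= width || dist == 0) return(NULL)
  nrm <- d / dist
  mid <- (cp$pa + cp$pb) / 2
  c(depth = width - dist, nx = nrm[1], ny = nrm[2], px = mid[1], py = mid[2])
}

circle_circle <- function(xa, xb, r) {
  d <- xb - xa
  dist <- sqrt(sum(d^2))
  if (dist >= 2 * r || dist == 0) return(NULL)
  nrm <- d / dist
  mid <- (xa + xb) / 2
  c(depth = 2 * r - dist, nx = nrm[1], ny = nrm[2], px = mid[1], py = mid[2])
}

# overlap of a circle with an oriented rectangle; normal points from the
# circle into the rectangle
circle_rect <- function(xc, r, rp, rang, rl, rw) {
  ca <- cos(rang); sa <- sin(rang)
  d <- xc - rp
  lx <- ca * d[1] + sa * d[2]   # circle centre in the rect frame
  ly <- -sa * d[1] + ca * d[2]
  hx <- rl / 2; hy <- rw / 2
  qx <- max(-hx, min(hx, lx)); qy <- max(-hy, min(hy, ly))
  if (qx == lx && qy == ly) {
    # centre inside: push out along the axis of least penetration
    dx <- hx - abs(lx); dy <- hy - abs(ly)
    if (dx < dy) { qx <- if (lx >= 0) hx else -hx } else {
      qy <- if (ly >= 0) hy else -hy
    }
  }
  gx <- lx - qx; gy <- ly - qy
  dist <- sqrt(gx^2 + gy^2)
  if (dist >= r || dist == 0) return(NULL)
  # local normal from circle toward the rectangle surface point
  nlx <- -gx / dist; nly <- -gy / dist
  nx <- ca * nlx - sa * nly
  ny <- sa * nlx + ca * nly
  px <- rp[1] + ca * qx - sa * qy
  py <- rp[2] + sa * qx + ca * qy
  c(depth = r - dist, nx = nx, ny = ny, px = px, py = py)
}

#' Penalty contact forces
#'
#' Each contact event contributes equal-and-opposite normal forces of
#' magnitude `k_contact * depth` along the contact normal, plus a
#' regularized Coulomb friction force `mu * |F_n| * tanh(v_slip / 0.5)`
#' opposing the tangential slip velocity at the contact point (disabled
#' when `friction_mu = 0`). Forces on spacers also exert torque about the
#' spacer centre.
#'
#' @param events Contact table from [detect_contacts()].
#' @param world The `glider_world` the events came from.
#' @return List of per-body force matrices (one per cell), each with a
#'   `"torque"` attribute.
#' @export
contact_forces <- function(events, world) {
  p <- world$params
  n <- p$n_nodes
  out <- lapply(world$cells, function(...) zero_forces(p))
  body_vel <- function(ci, bi, pt) {
    cl <- world$cells[[ci]]
    if (bi <= n) return(cl$node_vel[bi, ])
    j <- bi - n
    arm <- pt - cl$sp_pos[j, ]
    cl$sp_vel[j, ] + cl$sp_omega[j] * c(-arm[2], arm[1])
  }
  for (k in seq_len(nrow(events))) {
    fmag <- p$k_contact * events$depth[k]
    fa <- -fmag * c(events$nx[k], events$ny[k])  # pushes a away from b
    if (p$friction_mu > 0) {
      tangent <- c(-events$ny[k], events$nx[k])
      pt <- c(events$px[k], events$py[k])
      vs <- sum((body_vel(events$cell_a[k], events$body_a[k], pt) -
                   body_vel(events$cell_b[k], events$body_b[k], pt)) * tangent)
      fa <- fa - p$friction_mu * fmag * tanh(vs / 0.5) * tangent
    }
    for (side in 1:2) {
      ci <- if (side == 1) events$cell_a[k] else events$cell_b[k]
      bi <- if (side == 1) events$body_a[k] else events$body_b[k]
      fv <- if (side == 1) fa else -fa
      fmat <- out[[ci]]
      fmat[bi, ] <- fmat[bi, ] + fv
      if (bi > n) {
        j <- bi - n
        arm <- c(events$px[k], events$py[k]) - world$cells[[ci]]$sp_pos[j, ]
        tq <- attr(fmat, "torque")
        tq[j] <- tq[j] + arm[1] * fv[2] - arm[2] * fv[1]
        attr(fmat, "torque") <- tq
      }
      out[[ci]] <- fmat
    }
  }
  out
}

#' Sample bond-reformation waiting times
#'
#' Draws from the same exponential generator the simulation engine uses for
#' broken-bond reformation (mean `1 / reform_rate`).
#'
#' @param n Number of waiting times.
#' @param aparams An [adhesion_params()] object.
#' @return Numeric vector of waiting times, min.
#' @export
sample_reform_times <- function(n, aparams = adhesion_params()) {
  draw_reform_waits_cpp(as.integer(n), aparams$reform_rate)
}
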