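# Marshalling between the list-of-cells world representation and the flat
# arrays the compiled stepper uses.

world_to_flat <- function(world) {
  p <- world$params
  n <- p$n_nodes
  pos <- do.call(rbind, lapply(world$cells, function(cl) {
    rbind(cl$nodes, cl$sp_pos)
  }))
  vel <- do.call(rbind, lapply(world$cells, function(cl) {
    rbind(cl$node_vel, cl$sp_vel)
  }))
  ang <- unlist(lapply(world$cells, `[[`, "sp_angle"), use.names = FALSE)
  omega <- unlist(lapply(world$cells, `[[`, "sp_omega"), use.names = FALSE)
  bl <- lapply(seq_along(world$bonds), function(ci) {
    b <- world$bonds[[ci]]
    if (!nrow(b)) return(NULL)
    cbind(ci, b$node, b$ax, b$ay, b$ux, b$uy, as.numeric(b$intact),
          b$reform_at, b$slid)
  })
  bl <- bl[!vapply(bl, is.null, logical(1))]
  bonds <- if (length(bl)) do.call(rbind, bl) else matrix(0, 0, 9)
  list(pos = pos, vel = vel, ang = ang, omega = omega, bonds = bonds)
}

flat_to_world <- function(world, res) {
  p <- world$params
  n <- p$n_nodes
  nb <- 2L * n - 1L
  nsp <- n - 1L
  for (ci in seq_along(world$cells)) {
    o <- (ci - 1L) * nb
    os <- (ci - 1L) * nsp
    world$cells[[ci]]$nodes <- res$pos[o + seq_len(n), , drop = FALSE]
    world$cells[[ci]]$node_vel <- res$vel[o + seq_len(n), , drop = FALSE]
    world$cells[[ci]]$sp_pos <- res$pos[o + n + seq_len(nsp), , drop = FALSE]
    world$cells[[ci]]$sp_vel <- res$vel[o + n + seq_len(nsp), , drop = FALSE]
    world$cells[[ci]]$sp_angle <- res$ang[os + seq_len(nsp)]
    world$cells[[ci]]$sp_omega <- res$omega[os + seq_len(nsp)]
  }
  if (nrow(res$bonds)) {
    for (ci in seq_along(world$bonds)) {
      sel <- res$bonds[, 1] == ci
      if (!any(sel)) next
      b <- res$bonds[sel, , drop = FALSE]
      world$bonds[[ci]] <- tibble::tibble(
        node = as.integer(b[, 2]), ax = b[, 3], ay = b[, 4],
        ux = b[, 5], uy = b[, 6], intact = b[, 7] != 0, reform_at = b[, 8],
        slid = b[, 9]
      )
    }
  }
  world$time <- res$time
  world
}

engine_pars <- function(world) {
  p <- world$params
  a <- world$aparams
  list(n_nodes = p$n_nodes, node_radius = p$node_radius,
       spacer_length = p$spacer_length, cell_width = p$cell_width,
       body_mass = p$body_mass, k_joint = p$k_joint, k_bend = p$k_bend,
       f_prop = p$f_prop, gamma_node = p$gamma_node,
       k_contact = p$k_contact, friction_mu = p$friction_mu, dt = p$dt,
       kappa = a$kappa, d_break = a$d_break, reform_rate = a$reform_rate,
       ecm = as.integer(a$mode == "ECM"))
}

#' Advance the world by time steps
#'
#' Performs `n_steps` semi-implicit Euler steps of length `params$dt`. For
#' every body the total force (joints + bending + propulsion + adhesion in
#' ECM mode + contacts) is computed, the velocity updated with the Stokes
#' drag term treated implicitly, and the position advanced with the updated
#' velocity. Bond breakage and reformation are processed within the step.
#'
#' @param world A `glider_world`.
#' @param n_steps Number of steps (default 1).
#' @return The advanced world. Attributes `first_contact` (time of first
#'   inter-cell contact within this call, or `NA`) and `max_depth` (largest
#'   contact overlap, um) report contact activity.
#' @export
step_world <- function(world, n_steps = 1L) {
  fl <- world_to_flat(world)
  res <- advance_cpp(fl$pos, fl$vel, fl$ang, fl$omega, fl$bonds,
                     engine_pars(world), length(world$cells),
                     as.integer(n_steps), 0L, world$time)
  out <- flat_to_world(world, res)
  attr(out, "first_contact") <- res$first_contact
  attr(out, "max_depth") <- res$max_depth
  out
}

#' Run a simulation and record a trajectory
#'
#' Steps the world for `duration` minutes, sampling node positions every
#' `sample_interval` minutes. Deterministic for a fixed RNG seed (bond
#' reformation times are the only stochastic element).
#'
#' @param world A `glider_world`.
#' @param duration Simulated time, min (> 0; `duration = 0` returns the
#'   initial sample only).
#' @param sample_interval Sampling interval, min (rounded to a whole number
#'   of steps, at least one).
#' @return A `trajectory_record`: tidy tibble of node positions with columns
#'   `time_min`, `cell_id`, `node_id`, `x_um`, `y_um`, plus attributes
#'   `world` (final state), `first_contact`, `orientation` (wide matrix of
#'   unwrapped cell orientations, degrees).
#' @export
run_world <- function(world, duration, sample_interval = 0.01) {
  p <- world$params
  n <- p$n_nodes
  nc <- length(world$cells)
  init <- tibble::tibble(
    time_min = world$time,
    cell_id = rep(seq_len(nc), each = n),
    node_id = rep(seq_len(n), nc),
    x_um = unlist(lapply(world$cells, function(cl) cl$nodes[, 1])),
    y_um = unlist(lapply(world$cells, function(cl) cl$nodes[, 2]))
  )
  if (duration <= 0) {
    return(new_trajectory(init, world, NA_real_))
  }
  every <- max(1L, as.integer(round(sample_interval / p$dt)))
  n_steps <- as.integer(ceiling(duration / p$dt))
  n_steps <- as.integer(ceiling(n_steps / every)) * every
  fl <- world_to_flat(world)
  res <- advance_cpp(fl$pos, fl$vel, fl$ang, fl$omega, fl$bonds,
                     engine_pars(world), nc, n_steps, every, world$time)
  world <- flat_to_world(world, res)
  samp <- tibble::tibble(
    time_min = rep(res$sample_t, each = nc * n),
    cell_id = rep(rep(seq_len(nc), each = n), length(res$sample_t)),
    node_id = rep(seq_len(n), nc * length(res$sample_t)),
    x_um = as.vector(t(res$sample_x)),
    y_um = as.vector(t(res$sample_y))
  )
  new_trajectory(dplyr::bind_rows(init, samp), world, res$first_contact)
}

new_trajectory <- function(tbl, world, first_contact) {
  attr(tbl, "world") <- world
  attr(tbl, "first_contact") <- first_contact
  attr(tbl, "orientation") <- trajectory_orientations(tbl, world$params)
  class(tbl) <- c("trajectory_record", class(tbl))
  tbl
}

# unwrapped per-cell orientation (degrees) at each sample time
trajectory_orientations <- function(tbl, params) {
  n <- params$n_nodes
  times <- unique(tbl$time_min)
  cells <- sort(unique(tbl$cell_id))
  lead <- tbl[tbl$node_id == 1L, ]
  lag <- tbl[tbl$node_id == n, ]
  out <- matrix(NA_real_, length(times), length(cells),
                dimnames = list(NULL, paste0("cell", cells)))
  for (ci in seq_along(cells)) {
    li <- lead[lead$cell_id == cells[ci], ]
    gi <- lag[lag$cell_id == cells[ci], ]
    th <- atan2(li$y_um - gi$y_um, li$x_um - gi$x_um) * 180 / pi
    out[, ci] <- unwrap_deg(th)
  }
  attr(out, "time_min") <- times
  out
}

#' Unwrap an angle series in degrees
#'
#' Removes the +/-360 degree jumps that occur when an angle series crosses
#' the +/-180 boundary, making the series continuous.
#'
#' @param theta Numeric vector of angles, degrees.
#' @return Unwrapped series, degrees.
#' @export
unwrap_deg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jumps <- cumsum(round(d / 360)) * 360
  theta - c(0, jumps)
}

#' Serialize a trajectory to CSV and a JSON summary
#'
#' @param traj A `trajectory_record`.
#' @param csv_path Path for the tidy node-position CSV.
#' @param json_path Optional path for a JSON summary (final orientations and
#'   bond states).
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, json_path = NULL) {
  readr::write_csv(tibble::as_tibble(traj), csv_path)
  if (!is.null(json_path)) {
    w <- attr(traj, "world")
    orient <- attr(traj, "orientation")
    summ <- list(
      time_min = w$time,
      orientation_deg = as.list(stats::setNames(
        orient[nrow(orient), ], colnames(orient))),
      bonds = lapply(w$bonds, function(b) {
        list(n_total = nrow(b), n_intact = sum(b$intact))
      })
    )
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
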