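# Small fixtures shared across test files. Fast parameter sets use a short
# cell and a larger dt so dynamics tests stay quick; physics tests that
# check exact force arithmetic use the defaults.

fast_params <- function(...) {
  mech_params(dt = 2e-5, ...)
}

# a reproducibly bent single cell: nodes perturbed off the straight line
bent_cell <- function(params, amplitude = 0.05, seed = 42) {
  set.seed(seed)
  cl <- make_cell(params, head = c(0, 0))
  n <- params$n_nodes
  cl$nodes[, 2] <- cl$nodes[, 2] + amplitude * sin(seq_len(n)) +
    stats::rnorm(n, sd = amplitude / 5)
  cl$sp_pos <- (cl$nodes[-n, , drop = FALSE] + cl$nodes[-1, , drop = FALSE]) / 2
  d <- cl$nodes[-n, , drop = FALSE] - cl$nodes[-1, , drop = FALSE]
  cl$sp_angle <- atan2(d[, 2], d[, 1])
  cl
}

# total force over all bodies of a force matrix
force_sum <- function(f) colSums(f)

# pure-R semi-implicit Euler step mirroring the compiled integrator
# (implicit Stokes drag), used as the dual-route check on step_world()
r_reference_step <- function(world) {
  p <- world$params
  n <- p$n_nodes
  events <- detect_contacts(world)
  cf <- contact_forces(events, world)
  new_cells <- world$cells
  for (ci in seq_along(world$cells)) {
    cl <- world$cells[[ci]]
    f <- joint_forces(cl, p) + bending_forces(cl, p) +
      propulsion_forces(cl, p) + cf[[ci]]
    tq <- attr(joint_forces(cl, p), "torque") + attr(cf[[ci]], "torque")
    if (world$aparams$mode == "ECM") {
      ad <- adhesion_forces(cl, world$bonds[[ci]], world$aparams, p,
                            now = world$time)
      f <- f + ad$forces
      world$bonds[[ci]] <- ad$bonds
    }
    m <- p$body_mass
    lam <- 1 + p$gamma_node * p$dt / m
    isp <- p$body_mass * (p$spacer_length^2 + p$cell_width^2) / 12
    grot <- p$gamma_node * (p$spacer_length^2 + p$cell_width^2) / 12
    lam_rot <- 1 + grot * p$dt / isp
    vel <- rbind(cl$node_vel, cl$sp_vel)
    vel <- (vel + f * p$dt / m) / lam
    posm <- rbind(cl$nodes, cl$sp_pos) + vel * p$dt
    omega <- (cl$sp_omega + tq * p$dt / isp) / lam_rot
    cl$nodes <- posm[seq_len(n), , drop = FALSE]
    cl$sp_pos <- posm[n + seq_len(n - 1L), , drop = FALSE]
    cl$node_vel <- vel[seq_len(n), , drop = FALSE]
    cl$sp_vel <- vel[n + seq_len(n - 1L), , drop = FALSE]
    cl$sp_omega <- omega
    cl$sp_angle <- cl$sp_angle + omega * p$dt
    new_cells[[ci]] <- cl
  }
  world$cells <- new_cells
  world$time <- world$time + p$dt
  world
}
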