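#' Mechanical parameters of the node-and-spring cell model
#'
#' A gliding cell is represented as a chain of `n_nodes` circular nodes (rigid
#' bodies of radius `node_radius`) kept apart by `n_nodes - 1` rectangular
#' spacers, connected by stiff zero-rest-length joint springs and angular
#' springs that resist bending away from the straight configuration.
#' Propulsion acts at every interior node, directed toward the leading pole;
#' Stokes drag acts on every body. All quantities are in real units
#' (micrometres, piconewtons, minutes).
#'
#' @param n_nodes Number of circular nodes (>= 3).
#' @param cell_length Total cell length, um.
#' @param cell_width Cell width, um. Node radius defaults to `cell_width / 2`.
#' @param node_radius Radius of the circular nodes, um.
#' @param spacer_length Length of the rectangular spacers, um. Defaults to the
#'   value that makes `(n_nodes - 1) * spacer_length + 2 * node_radius`
#'   equal `cell_length`.
#' @param body_mass Mass per body, pN min^2/um. Chosen so the inertial
#'   relaxation time `body_mass / gamma_node` is well below `dt` (the
#'   quasi-overdamped regime); results are insensitive to its exact value.
#' @param k_joint Linear joint-spring stiffness, pN/um. Stiff but finite:
#'   the default keeps joint-length fluctuations below 1% of `spacer_length`
#'   at the force scales of the model.
#' @param k_bend Angular spring constant, pN um/rad. Sets the flexural
#'   rigidity of the cell (`k_bend ~ EI / spacer_length` for a discretised
#'   rod). Cell flexibility is a tuned quantity in this model class; the
#'   default (EI ~ 8.5e-23 N m^2, within published estimates for
#'   M. xanthus) is calibrated so an unadhered cell's maximal collision
#'   response reproduces the ~40 degree orientation change of the pure
#'   viscous-coupling regime.
#' @param f_prop Propulsion force per interior node, pN.
#' @param gamma_node Drag coefficient per body, pN min/um. `NULL` (default)
#'   means calibrate with [calibrate_drag()] so the terminal speed of a
#'   straight unloaded cell equals `target_speed`.
#' @param k_contact Contact penalty stiffness, pN/um (>= 10 * k_joint).
#' @param friction_mu Coulomb friction coefficient of cell-cell contacts
#'   (dimensionless; 0 gives purely normal penalty forces). The default 0.2
#'   is the customary rigid-body-engine value; the tangential coupling at
#'   sliding contacts is what allows a colliding cell to rotate into
#'   alignment instead of raking along its partner indefinitely.
#' @param dt Integration time step, min.
#' @param target_speed Unloaded gliding speed used for drag calibration,
#'   um/min.
#'
#' @return An object of class `mech_params` (a named list).
#' @examples
#' p <- mech_params()
#' p$gamma_node * n_bodies(p) * p$target_speed  # total drag at terminal speed
#' @export
mech_params <- function(n_nodes = 7L,
                        cell_length = 7,
                        cell_width = 0.5,
                        node_radius = cell_width / 2,
                        spacer_length = (cell_length - 2 * node_radius) / (n_nodes - 1),
                        body_mass = 1e-6,
                        k_joint = 2000,
                        k_bend = 90,
                        f_prop = 12,
                        gamma_node = NULL,
                        k_contact = 20000,
                        friction_mu = 0.2,
                        dt = 2e-5,
                        target_speed = 4) {
  p <- list(
    n_nodes = as.integer(n_nodes), cell_length = cell_length,
    cell_width = cell_width, node_radius = node_radius,
    spacer_length = spacer_length, body_mass = body_mass,
    k_joint = k_joint, k_bend = k_bend, f_prop = f_prop,
    gamma_node = gamma_node, k_contact = k_contact,
    friction_mu = friction_mu, dt = dt,
    target_speed = target_speed
  )
  class(p) <- "mech_params"
  if (is.null(p$gamma_node)) p$gamma_node <- calibrate_drag(p)
  validate_mech_params(p)
}

#' @rdname mech_params
#' @param p A `mech_params` object.
#' @export
n_bodies <- function(p) 2L * p$n_nodes - 1L

validate_mech_params <- function(p) {
  if (!is.numeric(p$n_nodes) || p$n_nodes < 3L) {
    stop("mech_params: `n_nodes` must be >= 3", call. = FALSE)
  }
  num <- c("cell_length", "cell_width", "node_radius", "spacer_length",
           "body_mass", "k_joint", "k_bend", "f_prop", "gamma_node",
           "k_contact", "dt", "target_speed")
  for (key in num) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("mech_params: `", key, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$friction_mu) || length(p$friction_mu) != 1L ||
      !is.finite(p$friction_mu) || p$friction_mu < 0) {
    stop("mech_params: `friction_mu` must be a single finite number >= 0",
         call. = FALSE)
  }
  geom <- (p$n_nodes - 1L) * p$spacer_length + 2 * p$node_radius
  if (abs(geom - p$cell_length) > 0.01 * p$cell_length) {
    stop("mech_params: geometry inconsistent; (n_nodes - 1) * spacer_length + ",
         "2 * node_radius = ", signif(geom, 4), " but cell_length = ",
         p$cell_length, call. = FALSE)
  }
  p
}

#' Calibrate the per-body drag coefficient to the target gliding speed
#'
#' At terminal speed the total Stokes drag over all bodies balances the total
#' propulsion `(n_nodes - 2) * f_prop`, so the summed drag coefficient is
#' total propulsion / target speed, distributed uniformly over the
#' `2 * n_nodes - 1` bodies (nodes and spacers).
#'
#' @param p A `mech_params` object (`gamma_node` may be unset).
#' @return Drag coefficient per body, pN min/um.
#' @export
calibrate_drag <- function(p) {
  if (!is.numeric(p$f_prop) || p$f_prop <= 0) {
    stop("calibrate_drag: propulsion force must be positive", call. = FALSE)
  }
  if (!is.numeric(p$target_speed) || p$target_speed <= 0) {
    stop("calibrate_drag: target_speed must be positive", call. = FALSE)
  }
  total_prop <- (p$n_nodes - 2L) * p$f_prop
  (total_prop / p$target_speed) / (2L * p$n_nodes - 1L)
}

#' Substrate adhesion parameters
#'
#' Under elastic coupling (`mode = "ECM"`) every adhesion node carries a bond
#' to the substrate modelled as a linear spring of stiffness `kappa` acting on
#' the component of the node's displacement perpendicular to the local cell
#' axis (axial sliding is free, so motors can translocate the cell along its
#' axis against stationary adhesions). A bond stretched laterally beyond
#' `d_break` breaks and reforms at the node's current position after an
#' exponentially distributed waiting time with mean `1 / reform_rate`.
#' Under viscous coupling (`mode = "VCM"`) no bonds are ever formed and the
#' only substrate interaction is Stokes drag.
#'
#' @param kappa Bond stiffness, pN/um (>= 0). The default 2000 pN/um together
#'   with `d_break = 0.025` um gives a 50 pN bond-breaking force.
#' @param d_break Lateral stretch at which a bond breaks, um.
#' @param reform_rate Bond reformation rate, 1/min.
#' @param mode `"ECM"` (elastic coupling) or `"VCM"` (viscous coupling).
#' @param adhesion_nodes Node indices carrying bonds; defaults to the interior
#'   nodes `2:(n_nodes - 1)` (the leading pole never adheres, which preserves
#'   the cell's ability to change direction).
#' @param n_nodes Number of nodes, used for the `adhesion_nodes` default.
#'
#' @return An object of class `adhesion_params`.
#' @export
adhesion_params <- function(kappa = 2000,
                            d_break = 0.025,
                            reform_rate = 8,
                            mode = c("ECM", "VCM"),
                            n_nodes = 7L,
                            adhesion_nodes = seq(2L, n_nodes - 1L)) {
  mode <- match.arg(mode)
  a <- list(kappa = kappa, d_break = d_break, reform_rate = reform_rate,
            mode = mode, adhesion_nodes = as.integer(adhesion_nodes))
  class(a) <- "adhesion_params"
  validate_adhesion_params(a, n_nodes = as.integer(n_nodes))
}

validate_adhesion_params <- function(a, n_nodes = NULL) {
  if (!is.numeric(a$kappa) || length(a$kappa) != 1L || !is.finite(a$kappa) ||
      a$kappa < 0) {
    stop("adhesion_params: `kappa` must be a single finite number >= 0",
         call. = FALSE)
  }
  if (!is.numeric(a$d_break) || a$d_break <= 0) {
    stop("adhesion_params: `d_break` must be > 0", call. = FALSE)
  }
  if (!is.numeric(a$reform_rate) || a$reform_rate <= 0) {
    stop("adhesion_params: `reform_rate` must be > 0", call. = FALSE)
  }
  if (!a$mode %in% c("ECM", "VCM")) {
    stop("adhesion_params: `mode` must be \"ECM\" or \"VCM\"", call. = FALSE)
  }
  if (1L %in% a$adhesion_nodes) {
    stop("adhesion_params: node 1 (the leading pole) never carries a bond",
         call. = FALSE)
  }
  if (!is.null(n_nodes) && length(a$adhesion_nodes) &&
      any(a$adhesion_nodes < 2L | a$adhesion_nodes > n_nodes - 1L)) {
    stop("adhesion_params: `adhesion_nodes` must lie in 2:(n_nodes - 1)",
         call. = FALSE)
  }
  a
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params>", x$n_nodes, "nodes,",
      signif(x$cell_length, 3), "um x", signif(x$cell_width, 3), "um\n")
  cat("  f_prop", x$f_prop, "pN/node, gamma_node",
      signif(x$gamma_node, 4), "pN min/um, target", x$target_speed, "um/min\n")
  cat("  k_joint", x$k_joint, " k_bend", x$k_bend, " k_contact", x$k_contact,
      " dt", x$dt, "min\n")
  invisible(x)
}

#' @export
print.adhesion_params <- function(x, ...) {
  cat("<adhesion_params>", x$mode, "\n")
  if (x$mode == "ECM") {
    cat("  kappa", x$kappa, "pN/um, d_break", x$d_break,
        "um (breaking force", signif(x$kappa * x$d_break, 4), "pN)\n")
    cat("  reform_rate", x$reform_rate, "1/min, nodes",
        paste(x$adhesion_nodes, collapse = ","), "\n")
  }
  invisible(x)
}
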