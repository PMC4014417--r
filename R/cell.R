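#' Construct a straight cell state
#'
#' Bodies are ordered nodes first (1 = leading pole, `n_nodes` = lagging
#' pole), then spacers (spacer `j` sits between nodes `j` and `j + 1`).
#' Spacer headings point from the trailing node toward the leading node, so
#' a spacer's endpoints are `pos +/- (spacer_length / 2) * (cos a, sin a)`.
#'
#' @param params A [mech_params()] object.
#' @param head Position of the leading node (um), length-2 numeric.
#' @param angle_deg Orientation of the cell's travel direction, degrees CCW
#'   from the +x axis.
#' @param speed Initial speed along the travel direction, um/min (all bodies;
#'   default the calibrated terminal speed, so there is no start-up transient).
#' @return A `cell_state` list with node and spacer positions, velocities,
#'   spacer headings and angular velocities.
#' @export
make_cell <- function(params, head = c(0, 0), angle_deg = 0,
                      speed = params$target_speed) {
  n <- params$n_nodes
  a <- angle_deg * pi / 180
  u <- c(cos(a), sin(a))
  idx <- seq_len(n) - 1L
  nodes <- cbind(head[1] - idx * params$spacer_length * u[1],
                 head[2] - idx * params$spacer_length * u[2])
  sp_pos <- (nodes[-n, , drop = FALSE] + nodes[-1, , drop = FALSE]) / 2
  state <- list(
    nodes = nodes,
    node_vel = matrix(rep(speed * u, each = n), ncol = 2),
    sp_pos = sp_pos,
    sp_angle = rep(a, n - 1L),
    sp_vel = matrix(rep(speed * u, each = n - 1L), ncol = 2),
    sp_omega = rep(0, n - 1L)
  )
  class(state) <- "cell_state"
  state
}

#' Travel direction of a cell
#'
#' Unit vector pointing from the lagging node to the leading node.
#'
#' @param state A `cell_state`.
#' @return Length-2 unit vector.
#' @export
travel_direction <- function(state) {
  d <- state$nodes[1, ] - state$nodes[nrow(state$nodes), ]
  d / sqrt(sum(d^2))
}

#' Cell orientation in degrees
#'
#' Counter-clockwise angle between the travel direction and the +x axis.
#'
#' @param state A `cell_state`.
#' @return Angle in degrees in (-180, 180].
#' @export
cell_orientation <- function(state) {
  d <- travel_direction(state)
  atan2(d[2], d[1]) * 180 / pi
}

validate_cell_state <- function(state, params, tol = 0.05) {
  ok <- all(is.finite(state$nodes)) && all(is.finite(state$node_vel)) &&
    all(is.finite(state$sp_pos)) && all(is.finite(state$sp_angle))
  if (!ok) stop("cell_state contains non-finite values", call. = FALSE)
  d <- sqrt(rowSums((diff(state$nodes))^2))
  if (any(abs(d - params$spacer_length) > tol * params$spacer_length)) {
    stop("cell_state: adjacent node distances deviate by more than ",
         tol * 100, "% from spacer_length", call. = FALSE)
  }
  invisible(state)
}

#' Initial adhesion bonds for a cell
#'
#' One intact bond per adhesion node, anchored at the node's current
#' position with the bond axis frozen to the local cell axis at formation
#' (the anchor slides freely along this line; only displacement
#' perpendicular to it is loaded). Once the node has slid one node spacing
#' along the bond line the load is handed to a fresh adhesion site
#' (deterministic re-anchoring at the node with the current axis),
#' mirroring the turnover of focal adhesion complexes as the cell
#' advances. Returns a zero-row table in VCM mode (no bonds are ever
#' formed).
#'
#' @param state A `cell_state`.
#' @param aparams An [adhesion_params()] object.
#' @return A tibble with columns `node`, `ax`, `ay` (anchor, um), `ux`,
#'   `uy` (unit bond axis), `intact`, `reform_at`.
#' @export
init_bonds <- function(state, aparams) {
  if (aparams$mode == "VCM") {
    return(tibble::tibble(node = integer(), ax = double(), ay = double(),
                          ux = double(), uy = double(),
                          intact = logical(), reform_at = double(),
                          slid = double()))
  }
  nodes <- aparams$adhesion_nodes
  u <- t(vapply(nodes, function(i) {
    d <- state$nodes[i - 1L, ] - state$nodes[i + 1L, ]
    d / sqrt(sum(d^2))
  }, numeric(2)))
  tibble::tibble(
    node = nodes,
    ax = state$nodes[nodes, 1],
    ay = state$nodes[nodes, 2],
    ux = u[, 1],
    uy = u[, 2],
    intact = TRUE,
    reform_at = 0,
    slid = 0
  )
}

#' Assemble a simulation world
#'
#' @param cells List of `cell_state` objects (all sharing `params`).
#' @param params A [mech_params()] object.
#' @param aparams An [adhesion_params()] object.
#' @param time Simulation clock, min.
#' @return A `glider_world` object: cells, per-cell bond tables, parameters
#'   and clock.
#' @export
make_world <- function(cells, params,
                       aparams = adhesion_params(mode = "VCM",
                                                 n_nodes = params$n_nodes),
                       time = 0) {
  if (inherits(cells, "cell_state")) cells <- list(cells)
  validate_adhesion_params(aparams, n_nodes = params$n_nodes)
  w <- list(
    cells = cells,
    bonds = lapply(cells, init_bonds, aparams = aparams),
    params = params,
    aparams = aparams,
    time = time
  )
  class(w) <- "glider_world"
  w
}

#' @export
print.glider_world <- function(x, ...) {
  cat("<glider_world>", length(x$cells), "cell(s), t =",
      signif(x$time, 4), "min,", x$aparams$mode, "coupling\n")
  invisible(x)
}
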