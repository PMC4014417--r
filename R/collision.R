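#' Build the two-cell head-to-side collision world
#'
#' The primary cell glides along +x; the secondary cell's travel direction
#' makes `collision_angle` degrees with the primary axis (positive angles
#' approach from below). Both cells start at the calibrated terminal speed
#' and are positioned so the secondary's leading node and the primary's
#' `collision_node` reach the impact point (the origin) simultaneously, with
#' the secondary's leading node starting at least one cell length away.
#'
#' @param collision_node Node index on the primary cell taking the hit
#'   (interior: `2:(n_nodes - 1)`).
#' @param collision_angle Angle between the travel directions at contact,
#'   degrees, in (5, 175) (a ~0 or ~180 degree "side" impact is geometrically
#'   impossible).
#' @param params A [mech_params()] object.
#' @param aparams An [adhesion_params()] object.
#' @param approach Distance from the secondary's leading node to the impact
#'   point at t = 0, um (>= cell_length).
#' @return A `glider_world` with cells `1` (primary) and `2` (secondary).
#' @export
setup_collision <- function(collision_node = 4L, collision_angle = 90,
                            params = mech_params(),
                            aparams = adhesion_params(mode = "VCM",
                                                      n_nodes = params$n_nodes),
                            approach = params$cell_length + 1) {
  n <- params$n_nodes
  if (collision_node < 2L || collision_node > n - 1L) {
    stop("setup_collision: `collision_node` must be an interior node ",
         "(2:", n - 1L, ")", call. = FALSE)
  }
  aa <- abs(collision_angle)
  if (aa <= 5 || aa >= 175) {
    stop("setup_collision: collision_angle ", collision_angle,
         " deg cannot produce a side impact", call. = FALSE)
  }
  if (approach < params$cell_length) {
    stop("setup_collision: `approach` must be >= one cell length",
         call. = FALSE)
  }
  v <- params$target_speed
  t_star <- approach / v
  # primary: head at x such that collision_node reaches the origin at t_star
  head_x <- -v * t_star + (collision_node - 1L) * params$spacer_length
  primary <- make_cell(params, head = c(head_x, 0), angle_deg = 0, speed = v)
  # secondary: leading node `approach` um from the origin along -direction
  a <- collision_angle * pi / 180
  s <- c(cos(a), sin(a))
  secondary <- make_cell(params, head = -approach * s,
                         angle_deg = collision_angle, speed = v)
  make_world(list(primary, secondary), params, aparams)
}

#' Run a head-to-side collision and measure the orientation change
#'
#' Advances the world until both cells' orientation rates drop below
#' `settle_rate` degrees/min over a trailing `settle_window` minute window
#' (checked only after first contact), or until `post_window` minutes have
#' passed since first contact — the measurement window matched to the mean
#' duration of experimentally observed collisions — or until `max_duration`
#' minutes without any contact. Pre-collision orientations are taken at the
#' last sample before first contact; post-collision orientations at settling
#' or at the end of the measurement window, whichever comes first.
#'
#' @param world A two-cell world from [setup_collision()], or `NULL` to build
#'   one from the remaining arguments.
#' @inheritParams setup_collision
#' @param max_duration Hard cap on simulated time, min.
#' @param post_window Measurement window after first contact, min (default
#'   2.9, the mean experimental collision duration).
#' @param settle_rate,settle_window Settling criterion (deg/min over min).
#' @param sample_interval Orientation sampling interval, min.
#' @param seed Optional RNG seed (bond reformation is the only stochastic
#'   element).
#' @return A `collision_outcome` list: `delta_theta_primary`,
#'   `delta_theta_secondary` (absolute orientation changes, degrees),
#'   `aligned` (travel directions within 5 degrees at the end), `theta_pre`,
#'   `theta_post`, `first_contact`, `settled`, `trajectory`.
#' @export
run_collision <- function(world = NULL, collision_node = 4L,
                          collision_angle = 90,
                          params = mech_params(),
                          aparams = adhesion_params(mode = "VCM",
                                                    n_nodes = params$n_nodes),
                          max_duration = 10, post_window = 2.9,
                          settle_rate = 0.5,
                          settle_window = 0.5, sample_interval = 0.01,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(world)) {
    world <- setup_collision(collision_node, collision_angle, params, aparams)
  }
  params <- world$params
  chunk <- 0.25
  elapsed <- 0
  pieces <- list()
  first_contact <- NA_real_
  settled <- FALSE
  w <- world
  while (elapsed < max_duration) {
    d <- min(chunk, max_duration - elapsed)
    if (!is.na(first_contact)) {
      d <- min(d, max(first_contact + post_window - elapsed, sample_interval))
    }
    traj <- run_world(w, d, sample_interval)
    w <- attr(traj, "world")
    if (is.na(first_contact)) first_contact <- attr(traj, "first_contact")
    pieces[[length(pieces) + 1L]] <- tibble::as_tibble(traj)
    elapsed <- w$time
    if (!is.na(first_contact)) {
      orient <- combined_orientations(pieces, params)
      tt <- attr(orient, "time_min")
      if (max(tt) - first_contact >= settle_window &&
          settled_now(orient, tt, settle_rate, settle_window)) {
        settled <- TRUE
        break
      }
      if (elapsed >= first_contact + post_window) break
    }
  }
  tbl <- dplyr::bind_rows(pieces)
  tbl <- tbl[!duplicated(tbl[, c("time_min", "cell_id", "node_id")]), ]
  traj <- new_trajectory(tbl, w, first_contact)
  orient <- attr(traj, "orientation")
  tt <- attr(orient, "time_min")
  if (is.na(first_contact)) {
    theta_pre <- orient[nrow(orient), ]
  } else {
    pre_i <- if (any(tt < first_contact)) max(which(tt < first_contact)) else 1L
    theta_pre <- orient[pre_i, ]
  }
  theta_post <- orient[nrow(orient), ]
  dth <- abs(theta_post - theta_pre)
  dirs <- vapply(w$cells, travel_direction, numeric(2))
  ddeg <- acos(pmin(1, pmax(-1, sum(dirs[, 1] * dirs[, 2])))) * 180 / pi
  out <- list(
    delta_theta_primary = unname(dth[1]),
    delta_theta_secondary = unname(dth[2]),
    aligned = !is.na(first_contact) && ddeg < 5,
    theta_pre = theta_pre,
    theta_post = theta_post,
    first_contact = first_contact,
    settled = settled || is.na(first_contact),
    trajectory = traj
  )
  class(out) <- "collision_outcome"
  out
}

combined_orientations <- function(pieces, params) {
  tbl <- dplyr::bind_rows(pieces)
  tbl <- tbl[!duplicated(tbl[, c("time_min", "cell_id", "node_id")]), ]
  trajectory_orientations(tbl, params)
}

settled_now <- function(orient, tt, settle_rate, settle_window) {
  t_end <- max(tt)
  i0 <- which.min(abs(tt - (t_end - settle_window)))
  rate <- abs(orient[nrow(orient), ] - orient[i0, ]) / (t_end - tt[i0])
  all(rate < settle_rate)
}

#' @export
print.collision_outcome <- function(x, ...) {
  cat("<collision_outcome> dtheta primary",
      signif(x$delta_theta_primary, 4), "deg, secondary",
      signif(x$delta_theta_secondary, 4), "deg;",
      if (x$aligned) "aligned" else "not aligned",
      if (x$settled) "(settled)\n" else "(max duration reached)\n")
  invisible(x)
}

#' Maximum primary-cell orientation change over collision positions
#'
#' Runs [run_collision()] for every interior collision node at a fixed
#' collision angle and returns the largest per-node primary-cell
#' orientation change — the collision metric used throughout the sweeps.
#' Because bond reformation times are stochastic, each elastic-coupling
#' collision is repeated `n_rep` times (drawing fresh reformation times
#' from one seeded stream) and summarized by its median; viscous-coupling
#' runs contain no randomness and are run once.
#'
#' @inheritParams run_collision
#' @param nodes Collision nodes to scan (default all interior nodes).
#' @param n_rep Reformation-time replicates per node in ECM mode.
#' @param ... Passed on to [run_collision()].
#' @return Scalar, degrees, with the per-node results as attribute
#'   `"by_node"` (tibble `collision_node`, `delta_theta_primary`,
#'   `delta_theta_secondary`, `sd_rep`).
#' @export
delta_theta_max <- function(collision_angle = 90, params = mech_params(),
                            aparams = adhesion_params(mode = "VCM",
                                                      n_nodes = params$n_nodes),
                            nodes = seq(2L, params$n_nodes - 1L),
                            seed = 1L, n_rep = 5L, ...) {
  if (!is.null(seed)) set.seed(seed)
  # kappa = 0 bonds exert no force, so those runs are also deterministic
  reps <- if (aparams$mode == "ECM" && aparams$kappa > 0) n_rep else 1L
  rows <- purrr::map_dfr(nodes, function(nd) {
    outs <- lapply(seq_len(reps), function(r) {
      run_collision(collision_node = nd, collision_angle = collision_angle,
                    params = params, aparams = aparams, seed = NULL, ...)
    })
    dp <- vapply(outs, `[[`, numeric(1), "delta_theta_primary")
    ds <- vapply(outs, `[[`, numeric(1), "delta_theta_secondary")
    tibble::tibble(collision_node = nd,
                   delta_theta_primary = stats::median(dp),
                   delta_theta_secondary = stats::median(ds),
                   sd_rep = if (reps > 1L) stats::sd(dp) else 0)
  })
  res <- max(rows$delta_theta_primary)
  attr(res, "by_node") <- rows
  res
}

#' Sweep the substrate bond stiffness
#'
#' Computes [delta_theta_max()] for each bond stiffness value; `kappa = 0`
#' means no effective bonds (the viscous-coupling limit).
#'
#' @param kappas Stiffness grid, pN/um, sorted ascending (should include 0).
#' @inheritParams delta_theta_max
#' @param d_break Bond-breaking stretch held fixed across the sweep, um.
#' @return Tibble `kappa`, `delta_theta_max`.
#' @export
sweep_kappa <- function(kappas = c(0, 50, 100, 200, 500, 1000, 2000),
                        collision_angle = 90, params = mech_params(),
                        d_break = 0.025, seed = 1L, ...) {
  purrr::map_dfr(kappas, function(kp) {
    ap <- adhesion_params(kappa = kp, d_break = d_break, mode = "ECM",
                          n_nodes = params$n_nodes)
    tibble::tibble(
      kappa = kp,
      delta_theta_max = as.numeric(delta_theta_max(
        collision_angle = collision_angle, params = params, aparams = ap,
        seed = seed, ...))
    )
  })
}

#' Smallest bond stiffness matching the experimental band
#'
#' @param sweep Result of [sweep_kappa()].
#' @param band_mean,band_sd Experimental net orientation-change band,
#'   degrees (mean +/- one SD); defaults to the wild-type collision data
#'   summary (15 +/- 15 deg).
#' @return The smallest `kappa` whose `delta_theta_max` lies within one SD of
#'   the mean, or `NA` if none does.
#' @export
min_matching_kappa <- function(sweep, band_mean = 15, band_sd = 15) {
  ok <- abs(sweep$delta_theta_max - band_mean) <= band_sd
  if (!any(ok)) return(NA_real_)
  min(sweep$kappa[ok])
}

#' Orientation change as a function of collision position
#'
#' @inheritParams sweep_kappa
#' @param kappa_ecm Bond stiffness used for the elastic-coupling curve,
#'   pN/um.
#' @return Tibble `mode`, `collision_node`, `delta_theta_primary`.
#' @export
sweep_position <- function(collision_angle = 90, params = mech_params(),
                           kappa_ecm = 2000, seed = 1L, ...) {
  modes <- list(
    VCM = adhesion_params(mode = "VCM", n_nodes = params$n_nodes),
    ECM = adhesion_params(kappa = kappa_ecm, mode = "ECM",
                          n_nodes = params$n_nodes)
  )
  purrr::map_dfr(names(modes), function(m) {
    dtm <- delta_theta_max(collision_angle = collision_angle, params = params,
                           aparams = modes[[m]], seed = seed, ...)
    dplyr::mutate(attr(dtm, "by_node"), mode = m, .before = 1)
  })
}

#' Orientation change as a function of collision angle
#'
#' @inheritParams sweep_position
#' @param angles Collision angles to scan, degrees.
#' @return Tibble `mode`, `angle`, `delta_theta_max`.
#' @export
sweep_angle <- function(angles = seq(15, 165, by = 15),
                        params = mech_params(), kappa_ecm = 2000,
                        seed = 1L, ...) {
  modes <- list(
    VCM = adhesion_params(mode = "VCM", n_nodes = params$n_nodes),
    ECM = adhesion_params(kappa = kappa_ecm, mode = "ECM",
                          n_nodes = params$n_nodes)
  )
  grid <- tidyr::expand_grid(mode = names(modes), angle = angles)
  purrr::pmap_dfr(grid, function(mode, angle) {
    tibble::tibble(
      mode = mode, angle = angle,
      delta_theta_max = as.numeric(delta_theta_max(
        collision_angle = angle, params = params, aparams = modes[[mode]],
        seed = seed, ...))
    )
  })
}

#' Robustness of the stiffness sweep to mechanical parameter variation
#'
#' Varies one mechanical parameter at a time by the given factors and
#' recomputes [delta_theta_max()] per bond stiffness; unstable runs are
#' excluded and counted.
#'
#' @inheritParams sweep_kappa
#' @param factors Multiplicative factors applied to each parameter (must
#'   include 1).
#' @param vary Names of `mech_params` fields to vary.
#' @return Tibble `kappa`, `mean_dtheta`, `sd_dtheta`, `n_ok`, `n_failed`,
#'   with the per-variation results in attribute `"detail"`.
#' @export
robustness_sweep <- function(kappas = c(0, 2000),
                             factors = c(0.1, 1, 10),
                             vary = c("k_bend", "k_joint", "gamma_node",
                                      "f_prop", "body_mass"),
                             collision_angle = 90,
                             base_params = mech_params(), seed = 1L, ...) {
  stopifnot(1 %in% factors)
  grid <- dplyr::bind_rows(
    tibble::tibble(param = "base", factor = 1),
    tidyr::expand_grid(param = vary, factor = factors[factors != 1])
  )
  detail <- purrr::pmap_dfr(grid, function(param, factor) {
    p <- base_params
    if (param != "base") p[[param]] <- p[[param]] * factor
    purrr::map_dfr(kappas, function(kp) {
      ap <- adhesion_params(kappa = kp, mode = "ECM",
                            n_nodes = p$n_nodes)
      val <- tryCatch(
        as.numeric(delta_theta_max(collision_angle = collision_angle,
                                   params = p, aparams = ap,
                                   seed = seed, ...)),
        error = function(e) NA_real_
      )
      tibble::tibble(param = param, factor = factor, kappa = kp,
                     delta_theta_max = val)
    })
  })
  agg <- detail |>
    dplyr::group_by(.data$kappa) |>
    dplyr::summarise(
      mean_dtheta = mean(.data$delta_theta_max, na.rm = TRUE),
      sd_dtheta = stats::sd(.data$delta_theta_max, na.rm = TRUE),
      n_ok = sum(!is.na(.data$delta_theta_max)),
      n_failed = sum(is.na(.data$delta_theta_max)),
      .groups = "drop"
    )
  attr(agg, "detail") <- detail
  agg
}

#' Minimum adhesion strength matching experiment vs propulsion force
#'
#' For each propulsion force, bisects the bond stiffness (at fixed breaking
#' stretch) for the smallest value whose [delta_theta_max()] enters the
#' experimental band, and reports the corresponding bond-breaking force
#' `kappa * d_break`.
#'
#' @param f_props Per-node propulsion forces to scan, pN.
#' @inheritParams sweep_kappa
#' @param band_mean,band_sd Experimental comparison band, degrees.
#' @param kappa_max Upper bracket for the bisection, pN/um.
#' @param rel_tol Relative bisection tolerance on kappa.
#' @return Tibble `f_prop`, `total_propulsion`, `min_kappa`,
#'   `min_adhesion_force` (pN; `NA` when the band is never reached),
#'   `force_ratio` (adhesion force / total propulsion).
#' @export
min_adhesion_strength <- function(f_props = c(6, 12, 24),
                                  band_mean = 15, band_sd = 15,
                                  d_break = 0.025, collision_angle = 90,
                                  base_params = mech_params(),
                                  kappa_max = 8000, rel_tol = 0.1,
                                  seed = 1L, ...) {
  purrr::map_dfr(f_props, function(fp) {
    p <- mech_params(
      n_nodes = base_params$n_nodes, cell_length = base_params$cell_length,
      cell_width = base_params$cell_width, body_mass = base_params$body_mass,
      k_joint = base_params$k_joint, k_bend = base_params$k_bend,
      f_prop = fp, k_contact = base_params$k_contact, dt = base_params$dt,
      target_speed = base_params$target_speed
    )
    dtm <- function(kp) {
      ap <- adhesion_params(kappa = kp, d_break = d_break, mode = "ECM",
                            n_nodes = p$n_nodes)
      as.numeric(delta_theta_max(collision_angle = collision_angle,
                                 params = p, aparams = ap, seed = seed, ...))
    }
    in_band <- function(v) abs(v - band_mean) <= band_sd
    total_prop <- (p$n_nodes - 2L) * fp
    if (!in_band(dtm(kappa_max))) {
      return(tibble::tibble(f_prop = fp, total_propulsion = total_prop,
                            min_kappa = NA_real_,
                            min_adhesion_force = NA_real_,
                            force_ratio = NA_real_))
    }
    lo <- 0; hi <- kappa_max
    if (in_band(dtm(lo))) {
      hi <- lo
    } else {
      while ((hi - lo) > rel_tol * hi) {
        mid <- (lo + hi) / 2
        if (in_band(dtm(mid))) hi <- mid else lo <- mid
      }
    }
    tibble::tibble(f_prop = fp, total_propulsion = total_prop,
                   min_kappa = hi, min_adhesion_force = hi * d_break,
                   force_ratio = hi * d_break / total_prop)
  })
}
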