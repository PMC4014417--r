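#' Read tracked cell-pole coordinates
#'
#' Consumes MTrackJ-style exports: a CSV with columns `cell_id`, `frame`,
#' `end` (`"head"` or `"tail"`), `x_px`, `y_px`. Pixel size and frame
#' interval may be given as arguments or as `# key: value` comment lines at
#' the top of the file (`pixel_size_um`, `frame_interval_min`). Frames
#' missing one pole are dropped with a warning reporting the count.
#'
#' @param file Path to the CSV file.
#' @param pixel_size_um Pixel size, um/px (overrides any file header).
#' @param frame_interval_min Frame interval, min (overrides any file header).
#' @return A list of `pole_track` objects, one per cell: tibbles with columns
#'   `time_min`, `head_x`, `head_y`, `tail_x`, `tail_y` (um) and attributes
#'   `cell_id` and `frame_interval_min`.
#' @export
read_tracks <- function(file, pixel_size_um = NULL, frame_interval_min = NULL) {
  if (!file.exists(file)) stop("read_tracks: no such file: ", file,
                               call. = FALSE)
  hdr <- parse_track_header(file)
  if (is.null(pixel_size_um)) pixel_size_um <- hdr$pixel_size_um
  if (is.null(frame_interval_min)) frame_interval_min <- hdr$frame_interval_min
  if (is.null(pixel_size_um) || is.null(frame_interval_min)) {
    stop("read_tracks: pixel_size_um and frame_interval_min must be given ",
         "as arguments or `# key: value` header lines", call. = FALSE)
  }
  raw <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "end", "x_px", "y_px")
  if (!all(need %in% names(raw))) {
    stop("read_tracks: missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!raw$end %in% c("head", "tail") | !is.finite(raw$x_px) |
                 !is.finite(raw$y_px))
  if (length(bad)) {
    stop("read_tracks: malformed row(s) at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dropped <- 0L
  tracks <- lapply(split(raw, raw$cell_id), function(d) {
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(d), id_cols = "frame", names_from = "end",
      values_from = c("x_px", "y_px")
    )
    complete <- !is.na(wide$x_px_head) & !is.na(wide$x_px_tail)
    dropped <<- dropped + sum(!complete)
    wide <- wide[complete, ]
    if (!nrow(wide)) return(NULL)
    wide <- wide[order(wide$frame), ]
    out <- tibble::tibble(
      time_min = wide$frame * frame_interval_min,
      head_x = wide$x_px_head * pixel_size_um,
      head_y = wide$y_px_head * pixel_size_um,
      tail_x = wide$x_px_tail * pixel_size_um,
      tail_y = wide$y_px_tail * pixel_size_um
    )
    attr(out, "cell_id") <- d$cell_id[1]
    attr(out, "frame_interval_min") <- frame_interval_min
    class(out) <- c("pole_track", class(out))
    out
  })
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  if (dropped > 0L) {
    warning("read_tracks: dropped ", dropped,
            " frame(s) missing one pole", call. = FALSE)
  }
  if (!length(tracks)) stop("read_tracks: no complete frames", call. = FALSE)
  tracks
}

parse_track_header <- function(file) {
  lines <- readLines(file, n = 10L)
  lines <- lines[startsWith(lines, "#")]
  out <- list(pixel_size_um = NULL, frame_interval_min = NULL)
  for (ln in lines) {
    m <- regmatches(ln, regexec("#\\s*([a-z_]+)\\s*:\\s*([0-9.eE+-]+)", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(out)) out[[m[2]]] <- as.numeric(m[3])
  }
  out
}

#' Write pole tracks to CSV
#'
#' Inverse of [read_tracks()] (round-trip exact up to float printing).
#'
#' @param tracks List of `pole_track` objects.
#' @param file Output path.
#' @param pixel_size_um Pixel size used to convert back to pixels.
#' @param frame_interval_min Frame interval written to the header.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(tracks, file, pixel_size_um = 1,
                         frame_interval_min = NULL) {
  if (inherits(tracks, "pole_track")) tracks <- list(tracks)
  if (is.null(frame_interval_min)) {
    frame_interval_min <- attr(tracks[[1]], "frame_interval_min")
  }
  rows <- purrr::map_dfr(tracks, function(tr) {
    id <- attr(tr, "cell_id")
    frame <- round(tr$time_min / frame_interval_min)
    dplyr::bind_rows(
      tibble::tibble(cell_id = id, frame = frame, end = "head",
                     x_px = tr$head_x / pixel_size_um,
                     y_px = tr$head_y / pixel_size_um),
      tibble::tibble(cell_id = id, frame = frame, end = "tail",
                     x_px = tr$tail_x / pixel_size_um,
                     y_px = tr$tail_y / pixel_size_um)
    )
  })
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pixel_size_um: ", format(pixel_size_um, digits = 15)),
               paste0("# frame_interval_min: ",
                      format(frame_interval_min, digits = 15))), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Orientation time series of a tracked cell
#'
#' The cell orientation at each frame is the counter-clockwise angle between
#' the travel-direction vector (head minus tail) and the +x axis, unwrapped
#' to be continuous across the +/-180 degree boundary.
#'
#' @param track A `pole_track`.
#' @return Tibble `time_min`, `theta_deg` (unwrapped).
#' @export
orientation_series <- function(track) {
  dx <- track$head_x - track$tail_x
  dy <- track$head_y - track$tail_y
  if (any(dx == 0 & dy == 0)) {
    stop("orientation_series: coincident head and tail at frame(s) ",
         paste(utils::head(which(dx == 0 & dy == 0), 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(time_min = track$time_min,
                 theta_deg = unwrap_deg(atan2(dy, dx) * 180 / pi))
}

#' Mean spontaneous turning of isolated cells
#'
#' For each cell the absolute orientation change is measured over
#' non-overlapping windows of length `tau_c` (the mean collision duration)
#' and averaged; the statistic is the mean of these per-cell means:
#' `delta_theta_s = (1/M) sum_i (1/n_i) sum_j |theta_i(t_j + tau_c) -
#' theta_i(t_j)|` with `n_i = floor(T_i / tau_c)` windows per cell.
#'
#' @param tracks List of `pole_track` objects.
#' @param tau_c Window length, min (default 2.9, the mean collision time).
#' @param overlapping Use sliding (every-frame) windows instead of
#'   non-overlapping ones (sensitivity analysis; default `FALSE`).
#' @return A `turning_stat` list: `delta_theta_s` (degrees), `tau_c`, `M`
#'   (number of cells used), `n_i` (windows per cell), `per_cell` (tibble).
#' @export
spontaneous_turning <- function(tracks, tau_c = 2.9, overlapping = FALSE) {
  if (inherits(tracks, "pole_track")) tracks <- list(tracks)
  per_cell <- purrr::map_dfr(tracks, function(tr) {
    os <- orientation_series(tr)
    dur <- max(os$time_min) - min(os$time_min)
    if (dur < tau_c) {
      return(tibble::tibble(cell_id = as.character(attr(tr, "cell_id")),
                            n_windows = 0L, mean_abs_change = NA_real_))
    }
    th <- stats::approxfun(os$time_min, os$theta_deg)
    t0 <- min(os$time_min)
    if (overlapping) {
      starts <- os$time_min[os$time_min + tau_c <= max(os$time_min)]
    } else {
      n_i <- floor(dur / tau_c)
      starts <- t0 + (seq_len(n_i) - 1L) * tau_c
    }
    tibble::tibble(
      cell_id = as.character(attr(tr, "cell_id")),
      n_windows = length(starts),
      mean_abs_change = mean(abs(th(starts + tau_c) - th(starts)))
    )
  })
  used <- per_cell[per_cell$n_windows > 0L, ]
  if (!nrow(used)) {
    stop("spontaneous_turning: every track is shorter than tau_c = ", tau_c,
         " min", call. = FALSE)
  }
  out <- list(delta_theta_s = mean(used$mean_abs_change), tau_c = tau_c,
              M = nrow(used), n_i = used$n_windows, per_cell = per_cell)
  class(out) <- "turning_stat"
  out
}

#' @export
print.turning_stat <- function(x, ...) {
  cat("<turning_stat> delta_theta_s =", signif(x$delta_theta_s, 4),
      "deg over tau_c =", x$tau_c, "min (", x$M, "cells )\n")
  invisible(x)
}

#' Net collision orientation change
#'
#' The observed change is `|theta(t_post) - theta(t_contact)|`; the net
#' change subtracts the mean spontaneous turning and is floored at zero
#' (a negative net turn is not meaningful).
#'
#' @param series Orientation series from [orientation_series()] (or any
#'   tibble with `time_min`, `theta_deg`).
#' @param t_contact,t_post Measurement times, min (within the series range,
#'   `t_contact < t_post`).
#' @param turning A `turning_stat`, or a number (degrees) used directly as
#'   the spontaneous-turning correction.
#' @return A `collision_measurement` list: `delta_theta_obs`,
#'   `delta_theta_net` (degrees), `t_contact`, `t_post`.
#' @export
collision_delta_theta <- function(series, t_contact, t_post, turning = 0) {
  rng <- range(series$time_min)
  if (t_contact >= t_post) {
    stop("collision_delta_theta: t_contact must precede t_post", call. = FALSE)
  }
  if (t_contact < rng[1] || t_post > rng[2]) {
    stop("collision_delta_theta: times outside the tracked range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "] min", call. = FALSE)
  }
  dts <- if (inherits(turning, "turning_stat")) turning$delta_theta_s
         else turning
  th <- stats::approxfun(series$time_min, series$theta_deg)
  obs <- abs(th(t_post) - th(t_contact))
  out <- list(delta_theta_obs = obs,
              delta_theta_net = max(obs - dts, 0),
              t_contact = t_contact, t_post = t_post,
              delta_theta_s = dts)
  class(out) <- "collision_measurement"
  out
}

#' @export
print.collision_measurement <- function(x, ...) {
  cat("<collision_measurement> observed", signif(x$delta_theta_obs, 4),
      "deg, net", signif(x$delta_theta_net, 4), "deg\n")
  invisible(x)
}

#' Convert a simulated trajectory to pole tracks
#'
#' Lets simulated collisions flow through the same quantification pipeline as
#' experimental tracks (head = leading node, tail = lagging node).
#'
#' @param traj A `trajectory_record`.
#' @param params The `mech_params` used in the simulation.
#' @return List of `pole_track` objects, one per cell.
#' @export
trajectory_to_tracks <- function(traj, params) {
  n <- params$n_nodes
  tbl <- tibble::as_tibble(traj)
  lapply(sort(unique(tbl$cell_id)), function(ci) {
    h <- tbl[tbl$cell_id == ci & tbl$node_id == 1L, ]
    t <- tbl[tbl$cell_id == ci & tbl$node_id == n, ]
    out <- tibble::tibble(time_min = h$time_min,
                          head_x = h$x_um, head_y = h$y_um,
                          tail_x = t$x_um, tail_y = t$y_um)
    attr(out, "cell_id") <- ci
    dt <- diff(out$time_min)
    attr(out, "frame_interval_min") <- if (length(dt)) stats::median(dt) else NA
    class(out) <- c("pole_track", class(out))
    out
  })
}
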