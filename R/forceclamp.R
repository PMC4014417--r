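#' Force-clamp protocol parameters
#'
#' A transient force clamp: the trap is armed until the bead makes a
#' motor-driven displacement of `trigger_displacement` within
#' `trigger_window`, then applies the constant `preset_force` opposing the
#' motion for `clamp_duration`, after which the trap shuts off.
#'
#' @param trigger_displacement Trigger displacement, nm.
#' @param trigger_window Maximum time allowed for the trigger displacement, s.
#' @param clamp_duration Duration of constant-force application, s.
#' @param preset_force Clamp force, pN (0-20 pN scan range).
#' @return A `clamp_protocol` list.
#' @export
clamp_protocol <- function(trigger_displacement = 63, trigger_window = 3,
                           clamp_duration = 8, preset_force = 6) {
  stopifnot(trigger_displacement > 0, trigger_window > 0, clamp_duration > 0,
            preset_force >= 0)
  structure(list(trigger_displacement = trigger_displacement,
                 trigger_window = trigger_window,
                 clamp_duration = clamp_duration,
                 preset_force = preset_force),
            class = "clamp_protocol")
}

#' Motor model for synthetic bead traces
#'
#' The motor alternates runs and pauses and occasionally reverses direction
#' on resuming. Under load F opposing the motion, run velocity follows
#' `v0 * exp(-F / f_c)` for elastic motor-substrate coupling (never
#' negative: the bead stays put above stall) or `v0 * (1 - F / f_stall)`
#' for viscous coupling (crosses zero at the stall force and is negative
#' above it, i.e. the bead is dragged backwards).
#'
#' @param v0 Unloaded run velocity, nm/s. The default matches the gliding
#'   speed scale of the cell model (4 um/min ~ 67 nm/s).
#' @param f_c Characteristic decay force of the elastic law, pN.
#' @param f_stall Stall force of the viscous law, pN (default 12, where the
#'   two laws both reach (near) zero velocity).
#' @param coupling `"ELASTIC"` or `"VISCOUS"`.
#' @param pause_rate Rate of entering a pause while running, 1/s.
#' @param pause_mean Mean pause duration, s.
#' @param reversal_prob Probability of reversing direction when resuming.
#' @param noise_sd Gaussian positional noise SD per sample, nm.
#' @return A `motor_model` list.
#' @export
motor_model <- function(v0 = 67, f_c = 2.3, f_stall = 12,
                        coupling = c("ELASTIC", "VISCOUS"),
                        pause_rate = 0.06, pause_mean = 2,
                        reversal_prob = 0.3, noise_sd = 5) {
  coupling <- match.arg(coupling)
  stopifnot(v0 > 0, f_c > 0, f_stall > 0, pause_rate >= 0, pause_mean > 0,
            reversal_prob >= 0, reversal_prob <= 1, noise_sd >= 0)
  structure(list(v0 = v0, f_c = f_c, f_stall = f_stall, coupling = coupling,
                 pause_rate = pause_rate, pause_mean = pause_mean,
                 reversal_prob = reversal_prob, noise_sd = noise_sd),
            class = "motor_model")
}

#' Run velocity under load
#'
#' @param motor A [motor_model()].
#' @param force Opposing load, pN.
#' @return Velocity, nm/s (signed relative to the run direction).
#' @export
motor_velocity <- function(motor, force) {
  if (motor$coupling == "ELASTIC") {
    motor$v0 * exp(-force / motor$f_c)
  } else {
    motor$v0 * (1 - force / motor$f_stall)
  }
}

#' Simulate a force-clamp bead trace
#'
#' Piecewise run/pause/reversal bead motion with Gaussian positional noise,
#' sampled at `fs` Hz. When the trigger rule fires (net displacement of at
#' least the trigger threshold within the trigger window, in one direction),
#' the preset force is applied for the clamp duration and the run velocity
#' drops to the loaded value given by [motor_velocity()]; pauses and
#' reversals continue to occur inside clamps (such events are what segment
#' validation later rejects). Deterministic for a fixed seed.
#'
#' @param motor A [motor_model()].
#' @param protocol A [clamp_protocol()].
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @param seed Optional RNG seed.
#' @return A `bead_trace` tibble with columns `time_s`, `pos_nm`,
#'   `force_pN`, and attributes `events` (tibble of clamp windows), `motor`,
#'   `protocol`.
#' @export
simulate_bead_trace <- function(motor, protocol = clamp_protocol(),
                                duration = 120, fs = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs
  nsamp <- ceiling(duration * fs)
  time_s <- seq_len(nsamp) * dt
  pos <- numeric(nsamp)
  force <- numeric(nsamp)
  x <- 0
  dir <- 1
  running <- TRUE
  state_until <- 0         # pause end time when paused
  clamp_until <- -Inf
  rearm_at <- 0            # trap armed again after refractory
  events <- list()
  win <- as.integer(protocol$trigger_window * fs)
  for (k in seq_len(nsamp)) {
    t <- time_s[k]
    # run/pause state machine
    if (running) {
      if (motor$pause_rate > 0 &&
          stats::runif(1) < 1 - exp(-motor$pause_rate * dt)) {
        running <- FALSE
        state_until <- t + stats::rexp(1, rate = 1 / motor$pause_mean)
      }
    } else if (t >= state_until) {
      running <- TRUE
      if (stats::runif(1) < motor$reversal_prob) dir <- -dir
    }
    in_clamp <- t < clamp_until
    f_now <- if (in_clamp) protocol$preset_force else 0
    v <- if (running) dir * motor_velocity(motor, f_now) else 0
    x <- x + v * dt
    pos[k] <- x + stats::rnorm(1, sd = motor$noise_sd)
    force[k] <- f_now
    # trigger rule: net one-direction displacement within the window
    if (!in_clamp && t >= rearm_at && k > win) {
      disp <- pos[k] - pos[k - win]
      if (abs(disp) >= protocol$trigger_displacement) {
        clamp_until <- t + protocol$clamp_duration
        rearm_at <- clamp_until + 2
        events[[length(events) + 1L]] <-
          tibble::tibble(clamp_id = length(events) + 1L, t_start = t,
                         t_end = clamp_until, force = protocol$preset_force)
      }
    }
  }
  out <- tibble::tibble(time_s = time_s, pos_nm = pos, force_pN = force)
  attr(out, "events") <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(clamp_id = integer(), t_start = double(),
                   t_end = double(), force = double())
  attr(out, "motor") <- motor
  attr(out, "protocol") <- protocol
  class(out) <- c("bead_trace", class(out))
  out
}

#' Fit the linear velocity of a trace segment
#'
#' Ordinary least-squares slope of position versus time.
#'
#' @param segment Tibble with `time_s` and `pos_nm` (>= 10 samples).
#' @return Named list `v` (nm/s) and `se` (standard error of the slope).
#' @export
fit_linear_velocity <- function(segment) {
  if (nrow(segment) < 10L) {
    stop("fit_linear_velocity: need at least 10 samples, got ",
         nrow(segment), call. = FALSE)
  }
  fit <- stats::lm(pos_nm ~ time_s, data = segment)
  sm <- summary(fit)$coefficients
  list(v = unname(sm["time_s", "Estimate"]),
       se = unname(sm["time_s", "Std. Error"]))
}

#' Stall classification
#'
#' A segment is stalled when its linear velocity is zero within twice the
#' standard error of the velocity measurement.
#'
#' @param v Velocity, nm/s.
#' @param se Standard error of the velocity, nm/s (>= 0).
#' @return Logical.
#' @export
classify_stall <- function(v, se) {
  stopifnot(se >= 0)
  abs(v) <= 2 * se
}

#' Validate clamp segments of a bead trace
#'
#' A clamp segment reflects a single uninterrupted motor run only if the
#' bead's velocity before and after force application is nearly the same:
#' equal sign and a difference within twice the combined standard error.
#' Segments failing the rule (the motor paused or reversed) are rejected
#' with a reason code.
#'
#' @param trace A `bead_trace`.
#' @param protocol The [clamp_protocol()] used (defaults to the trace's).
#' @param flank Length of the pre/post comparison windows, s.
#' @return Tibble per clamp event: `clamp_id`, `force`, `v_pre`, `v_post`,
#'   `v_clamp`, `se_clamp`, `stalled`, `accepted`, `reason`.
#' @export
detect_runs_and_validate <- function(trace, protocol = attr(trace, "protocol"),
                                     flank = 3) {
  events <- attr(trace, "events")
  purrr::map_dfr(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    pre <- trace[trace$time_s >= ev$t_start - flank &
                   trace$time_s < ev$t_start, ]
    post <- trace[trace$time_s > ev$t_end &
                    trace$time_s <= ev$t_end + flank, ]
    mid <- trace[trace$time_s >= ev$t_start & trace$time_s <= ev$t_end, ]
    base <- tibble::tibble(clamp_id = ev$clamp_id, force = ev$force,
                           v_pre = NA_real_, v_post = NA_real_,
                           v_clamp = NA_real_, se_clamp = NA_real_,
                           stalled = NA, accepted = FALSE,
                           reason = "insufficient_samples")
    if (nrow(pre) < 10L || nrow(post) < 10L || nrow(mid) < 10L) return(base)
    fp <- fit_linear_velocity(pre)
    fq <- fit_linear_velocity(post)
    fm <- fit_linear_velocity(mid)
    base$v_pre <- fp$v; base$v_post <- fq$v
    base$v_clamp <- fm$v; base$se_clamp <- fm$se
    base$stalled <- classify_stall(fm$v, fm$se)
    if (sign(fp$v) != sign(fq$v)) {
      base$reason <- "sign_change"
    } else if (abs(fp$v - fq$v) > 2 * sqrt(fp$se^2 + fq$se^2)) {
      base$reason <- "velocity_mismatch"
    } else {
      base$accepted <- TRUE
      base$reason <- "accepted"
    }
    base
  })
}

#' Generate a synthetic force-velocity dataset
#'
#' Draws trial velocities from the exponential force-velocity law
#' `v = v0 * exp(-F / f_c)` with Gaussian noise of the given coefficient of
#' variation.
#'
#' @param v0 Unloaded velocity, nm/s.
#' @param f_c Ground-truth characteristic decay force, pN.
#' @param forces Force grid, pN.
#' @param trials Trials per force.
#' @param cv Coefficient of variation of the noise (SD relative to `v0`).
#' @param group Group label attached to every row.
#' @param seed Optional RNG seed.
#' @return Tibble `force`, `velocity`, `group`.
#' @export
simulate_fv_dataset <- function(v0 = 67, f_c = 2.3,
                                forces = seq(0, 20, by = 2), trials = 8,
                                cv = 0.2, group = "g1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tidyr::expand_grid(force = forces, trial = seq_len(trials)) |>
    dplyr::mutate(
      velocity = v0 * exp(-.data$force / f_c) +
        stats::rnorm(dplyr::n(), sd = cv * v0 * exp(-.data$force / f_c)),
      group = group
    ) |>
    dplyr::select("force", "velocity", "group")
}

#' Fit the exponential force-velocity relation
#'
#' Nonlinear least squares for `v = v0 * exp(-F / f_c)` (which never
#' predicts negative velocity). Starting values come from a log-domain
#' linear fit to the positive velocities. By default the fit is iteratively
#' reweighted with weights proportional to `1 / predicted^2`, matching the
#' constant-coefficient-of-variation error structure of bead velocimetry,
#' which keeps the parameter standard errors honest; pass explicit
#' `weights` (e.g. all 1 for an unweighted fit) to override.
#'
#' @param dataset Tibble with `force` (pN) and `velocity` (nm/s).
#' @param weights Optional per-row weights for weighted least squares;
#'   `NULL` (default) uses the iteratively reweighted scheme.
#' @return An `fv_fit` object with elements `v0`, `f_c`, `se_v0`, `se_f_c`,
#'   `fit` (the nls object) and `data`; supports [generics::tidy()],
#'   [generics::glance()], [predict()] and [ggplot2::autoplot()].
#' @export
fit_force_velocity <- function(dataset, weights = NULL) {
  forces <- unique(dataset$force)
  if (length(forces) < 2L) {
    stop("fit_force_velocity: need at least 2 distinct forces (degenerate ",
         "data)", call. = FALSE)
  }
  posd <- dataset[dataset$velocity > 0, ]
  ll <- stats::lm(log(velocity) ~ force, data = posd)
  start <- list(v0 = unname(exp(stats::coef(ll)[1])),
                f_c = unname(max(1e-3, -1 / stats::coef(ll)[2])))
  do_fit <- function(w, st) {
    minpack.lm::nlsLM(
      velocity ~ v0 * exp(-force / f_c), data = dataset, start = st,
      weights = w, lower = c(v0 = 1e-12, f_c = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  if (is.null(weights)) {
    fit <- do_fit(rep(1, nrow(dataset)), start)
    for (it in 1:2) {  # reweight by the fitted mean (constant-CV errors)
      pred <- pmax(predict(fit), 1e-8 * max(abs(dataset$velocity)))
      st <- as.list(stats::coef(fit))
      fit <- do_fit(1 / pred^2, st)
    }
  } else {
    fit <- do_fit(weights, start)
  }
  sm <- summary(fit)$coefficients
  out <- list(v0 = sm["v0", "Estimate"], f_c = sm["f_c", "Estimate"],
              se_v0 = sm["v0", "Std. Error"], se_f_c = sm["f_c", "Std. Error"],
              fit = fit, data = dataset, n = nrow(dataset))
  class(out) <- "fv_fit"
  out
}

#' @export
print.fv_fit <- function(x, ...) {
  cat("<fv_fit> v = v0 exp(-F / f_c)\n")
  cat("  v0 =", signif(x$v0, 4), "+/-", signif(x$se_v0, 3), "nm/s\n")
  cat("  f_c =", signif(x$f_c, 4), "+/-", signif(x$se_f_c, 3), "pN  (n =",
      x$n, ")\n")
  invisible(x)
}

#' @export
predict.fv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  object$v0 * exp(-newdata$force / object$f_c)
}

#' @importFrom generics tidy
#' @export
tidy.fv_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std.error = sm[, "Std. Error"],
                 statistic = sm[, "t value"], p.value = sm[, "Pr(>|t|)"])
}

#' @importFrom generics glance
#' @export
glance.fv_fit <- function(x, ...) {
  tibble::tibble(v0 = x$v0, f_c = x$f_c, sigma = summary(x$fit)$sigma,
                 df.residual = stats::df.residual(x$fit), nobs = x$n)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Normalize force-velocity curves and fit a common decay force
#'
#' Each group's velocities are divided by its own fitted unloaded velocity;
#' if the exponential law holds with a shared characteristic force, the
#' normalized curves collapse onto `exp(-F / f_c)`, which is then fitted to
#' the pooled data.
#'
#' @param dataset Tibble with `force`, `velocity`, `group`.
#' @param anchor_force Maximum allowed lowest force per group, pN: a group
#'   with no data at or below this load has no unloaded-velocity anchor and
#'   is an error.
#' @return An `fv_collapse` list: `collapsed` (tibble with
#'   `velocity_normalized`), `f_c`, `se_f_c` (pooled fit), `per_group`
#'   (tibble of per-group `v0` and `f_c`).
#' @export
normalize_collapse <- function(dataset, anchor_force = 2) {
  groups <- split(dataset, dataset$group)
  low <- vapply(groups, function(g) min(g$force), numeric(1))
  if (any(low > anchor_force)) {
    stop("normalize_collapse: group(s) without low-force data: ",
         paste(names(groups)[low > anchor_force], collapse = ", "),
         call. = FALSE)
  }
  per_group <- purrr::map_dfr(names(groups), function(g) {
    f <- fit_force_velocity(groups[[g]])
    tibble::tibble(group = g, v0 = f$v0, f_c = f$f_c, se_f_c = f$se_f_c)
  })
  collapsed <- purrr::map_dfr(names(groups), function(g) {
    dplyr::mutate(groups[[g]],
                  velocity_normalized = .data$velocity /
                    per_group$v0[per_group$group == g])
  })
  pooled <- minpack.lm::nlsLM(
    velocity_normalized ~ exp(-force / f_c), data = collapsed,
    start = list(f_c = mean(per_group$f_c)), lower = c(f_c = 1e-12)
  )
  sm <- summary(pooled)$coefficients
  out <- list(collapsed = collapsed, f_c = sm["f_c", "Estimate"],
              se_f_c = sm["f_c", "Std. Error"], per_group = per_group,
              fit = pooled)
  class(out) <- "fv_collapse"
  out
}

#' @export
print.fv_collapse <- function(x, ...) {
  cat("<fv_collapse> pooled f_c =", signif(x$f_c, 4), "+/-",
      signif(x$se_f_c, 3), "pN over", nrow(x$per_group), "groups\n")
  invisible(x)
}
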