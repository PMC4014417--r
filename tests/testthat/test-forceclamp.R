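# Synthetic force-clamp assay: trigger rule, segment validation, linear and
# exponential fits, stall classification, and the normalized collapse.

test_that("the trigger never fires for a motor too slow to reach the
           threshold", {
  # 63 nm in 3 s needs 21 nm/s; a 10 nm/s motor with no pauses stays below
  motor <- motor_model(v0 = 10, pause_rate = 0, reversal_prob = 0,
                       noise_sd = 0)
  tr <- simulate_bead_trace(motor, clamp_protocol(preset_force = 6),
                            duration = 60, seed = 1)
  expect_equal(nrow(attr(tr, "events")), 0)

  # a fast motor fires and the clamp window carries the preset force
  fast <- motor_model(v0 = 67, pause_rate = 0, reversal_prob = 0,
                      noise_sd = 1)
  tr2 <- simulate_bead_trace(fast, clamp_protocol(preset_force = 6),
                             duration = 60, seed = 1)
  ev <- attr(tr2, "events")
  expect_gt(nrow(ev), 0)
  expect_true(all(tr2$force_pN[tr2$time_s > ev$t_start[1] &
                                 tr2$time_s < ev$t_end[1]] == 6))
})

test_that("elastic coupling stops but never reverses beads under high load;
           viscous coupling drags them backwards", {
  el <- motor_model(v0 = 67, coupling = "ELASTIC", pause_rate = 0,
                    reversal_prob = 0, noise_sd = 1)
  tr <- simulate_bead_trace(el, clamp_protocol(preset_force = 18),
                            duration = 120, seed = 2)
  ev <- attr(tr, "events")
  expect_gt(nrow(ev), 0)
  for (k in seq_len(nrow(ev))) {
    seg <- tr[tr$time_s >= ev$t_start[k] & tr$time_s <= ev$t_end[k], ]
    v <- fit_linear_velocity(seg)
    expect_gte(v$v, -2 * v$se)   # indistinguishable from or above zero
    expect_lt(abs(v$v), 2)       # 18 pN >> f_c: essentially stalled
  }

  vi <- motor_model(v0 = 67, coupling = "VISCOUS", f_stall = 12,
                    pause_rate = 0, reversal_prob = 0, noise_sd = 1)
  tr2 <- simulate_bead_trace(vi, clamp_protocol(preset_force = 18),
                             duration = 120, seed = 2)
  ev2 <- attr(tr2, "events")
  expect_gt(nrow(ev2), 0)
  for (k in seq_len(nrow(ev2))) {
    seg <- tr2[tr2$time_s >= ev2$t_start[k] & tr2$time_s <= ev2$t_end[k], ]
    disp <- seg$pos_nm[nrow(seg)] - seg$pos_nm[1]
    expect_lt(disp, 0)           # backwards motion above stall
  }
})

test_that("linear velocity fit matches closed-form least squares", {
  seg <- tibble::tibble(time_s = seq(0, 1.1, by = 0.1),
                        pos_nm = 5 * seq(0, 1.1, by = 0.1) + 3)
  v <- fit_linear_velocity(seg)
  expect_equal(v$v, 5, tolerance = 1e-9)
  expect_lt(v$se, 1e-9)

  # 12-point fixture with noise: slope and SE from the closed-form formulas
  set.seed(9)
  x <- seq_len(12)
  y <- 2.5 * x + rnorm(12, sd = 3)
  seg2 <- tibble::tibble(time_s = x, pos_nm = y)
  v2 <- fit_linear_velocity(seg2)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (x - mean(x))
  se <- sqrt(sum(resid^2) / (12 - 2) / sxx)
  expect_equal(v2$v, beta, tolerance = 1e-9)
  expect_equal(v2$se, se, tolerance = 1e-9)

  expect_error(fit_linear_velocity(seg2[1:5, ]), "at least 10")
})

test_that("stall classification uses the two-standard-error rule", {
  expect_true(classify_stall(1.0, 0.6))
  expect_false(classify_stall(1.0, 0.4))
  expect_true(classify_stall(0, 0))
  expect_error(classify_stall(1, -0.1))
})

test_that("segment validation accepts clean runs and rejects reversals and
           pauses, matching a hand-built oracle", {
  # construct a trace with three clamp events by hand: (1) clean constant
  # velocity throughout, (2) reversal inside the clamp so the post velocity
  # flips sign, (3) pause after the clamp (post velocity ~ 0, mismatched)
  fs <- 10; dt <- 1 / fs
  t <- seq(dt, 60, by = dt)
  v <- rep(30, length(t))
  v[t > 20 & t <= 40] <- 30            # segment 2 pre
  v[t > 26 & t <= 40] <- -30           # reversal during clamp 2
  v[t > 46] <- 0                       # pause after clamp 3
  pos <- cumsum(v * dt)
  set.seed(4)
  pos <- pos + rnorm(length(pos), sd = 1)
  tr <- tibble::tibble(time_s = t, pos_nm = pos, force_pN = 0)
  ev <- tibble::tibble(clamp_id = 1:3,
                       t_start = c(5, 25, 42), t_end = c(13, 33, 50),
                       force = 6)
  attr(tr, "events") <- ev
  res <- detect_runs_and_validate(tr, clamp_protocol(preset_force = 6))
  expect_equal(res$accepted, c(TRUE, FALSE, FALSE))
  expect_equal(res$reason[2], "sign_change")
  expect_false(res$reason[3] == "accepted")
})

test_that("the exponential force-velocity fit recovers parameters exactly on
           noiseless data and is scale-equivariant", {
  d <- simulate_fv_dataset(v0 = 60, f_c = 2.5, forces = seq(0, 12, by = 3),
                           trials = 2, cv = 0, seed = 1)
  fit <- fit_force_velocity(d)
  expect_equal(fit$v0, 60, tolerance = 1e-6)
  expect_equal(fit$f_c, 2.5, tolerance = 1e-6)
  expect_true(all(predict(fit) >= 0))

  d2 <- dplyr::mutate(d, velocity = velocity * 3)
  fit2 <- fit_force_velocity(d2)
  expect_equal(fit2$v0, 3 * fit$v0, tolerance = 1e-6)
  expect_equal(fit2$f_c, fit$f_c, tolerance = 1e-6)

  expect_error(fit_force_velocity(d[d$force == 0, ]), "distinct forces")
})

test_that("noisy recovery agrees with a log-domain linear fit and stays
           within joint errors", {
  d <- simulate_fv_dataset(v0 = 67, f_c = 2.3, forces = seq(0, 8, by = 1),
                           trials = 10, cv = 0.1, seed = 5)
  fit <- fit_force_velocity(d)
  posd <- d[d$velocity > 0, ]
  ll <- stats::lm(log(velocity) ~ force, data = posd)
  fc_log <- -1 / coef(ll)[2]
  se_log <- abs(fc_log^2 * summary(ll)$coefficients["force", "Std. Error"])
  expect_lt(abs(fit$f_c - fc_log), 2 * sqrt(fit$se_f_c^2 + se_log^2))
})

test_that("tidy and glance return one row per term and per model", {
  d <- simulate_fv_dataset(seed = 8)
  fit <- fit_force_velocity(d)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("v0", "f_c"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nobs, nrow(d))
})

test_that("estimator calibration: small bias and near-nominal coverage over
           replicated synthetic datasets", {
  set.seed(2024)
  truth <- 2.3
  ests <- ses <- numeric(100)
  for (i in seq_along(ests)) {
    d <- simulate_fv_dataset(v0 = 67, f_c = truth,
                             forces = seq(0, 20, by = 2), trials = 6,
                             cv = 0.2)
    fit <- fit_force_velocity(d)
    ests[i] <- fit$f_c
    ses[i] <- fit$se_f_c
  }
  expect_lt(abs(mean(ests) - truth) / truth, 0.05)       # bias < 5%
  coverage <- mean(abs(ests - truth) <= 2 * ses)
  expect_gte(coverage, 0.9)                              # 2-SE coverage
})

test_that("normalized force-velocity curves collapse onto a common decay
           force and genuinely different decay forces are detected", {
  set.seed(31)
  groups <- dplyr::bind_rows(
    simulate_fv_dataset(v0 = 80, f_c = 2.3, trials = 8, cv = 0.1,
                        group = "n0"),
    simulate_fv_dataset(v0 = 40, f_c = 2.3, trials = 8, cv = 0.1,
                        group = "n10"),
    simulate_fv_dataset(v0 = 20, f_c = 2.3, trials = 8, cv = 0.1,
                        group = "n20")
  )
  col <- normalize_collapse(groups)
  expect_equal(col$f_c, 2.3, tolerance = 0.15)
  # per-group decay forces agree within a few pooled SEs
  expect_lt(diff(range(col$per_group$f_c)), 8 * col$se_f_c + 0.5)
  # normalized velocity at zero force is ~1 in every group
  at0 <- col$collapsed[col$collapsed$force == 0, ]
  means <- tapply(at0$velocity_normalized, at0$group, mean)
  expect_true(all(abs(means - 1) < 0.15))

  diff_groups <- dplyr::bind_rows(
    simulate_fv_dataset(v0 = 60, f_c = 1.2, trials = 8, cv = 0.05,
                        group = "a"),
    simulate_fv_dataset(v0 = 60, f_c = 4.5, trials = 8, cv = 0.05,
                        group = "b")
  )
  col2 <- normalize_collapse(diff_groups)
  expect_gt(diff(range(col2$per_group$f_c)),
            4 * max(col2$per_group$se_f_c))  # collapse detectably fails

  high_only <- simulate_fv_dataset(forces = seq(10, 20, 2), group = "hi",
                                   seed = 3)
  expect_error(normalize_collapse(high_only), "low-force")
})
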