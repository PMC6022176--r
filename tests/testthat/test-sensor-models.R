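test_that("body potential reduces to q_b/c_f while standing", {
  sched <- gait_events(c(0, 0.6), c("IC", "SE"))
  traj <- synthesize_trajectory(sched, fs = 500) # no swing: h == 0
  cfg <- electrostatics_config()
  u <- body_potential(traj, cfg)
  expect_equal(u$u_b, rep(cfg$q_b / cfg$c_f, nrow(traj)))
})

test_that("body potential matches the closed form for constant kinematics", {
  cfg <- electrostatics_config(q_b = 2e-8, c_f = 1.5e-10)
  h0 <- 0.08
  s0 <- 0.004
  traj <- tibble::tibble(
    time = seq(0, 0.1, by = 1e-3),
    h = h0, s_s = s0
  )
  u <- body_potential(traj, cfg)
  expect_equal(
    u$u_b,
    rep(cfg$q_b * (1 / cfg$c_f + h0 / (cfg$eps_a * s0)), nrow(traj))
  )
  # linear in the body charge
  cfg2 <- electrostatics_config(q_b = 2 * cfg$q_b, c_f = cfg$c_f)
  expect_equal(body_potential(traj, cfg2)$u_b, 2 * u$u_b)
  # non-positive area is a domain error
  traj$s_s[3] <- 0
  expect_error(body_potential(traj, cfg), class = "efsgait_domain_error")
})

test_that("induced current is the scaled derivative of the potential", {
  cfg <- electrostatics_config()
  t <- seq(0, 1, by = 1e-3)
  const <- tibble::tibble(time = t, u_b = 5)
  expect_equal(induced_current(const, cfg)$current, rep(0, length(t)))
  a <- 3.7
  ramp <- tibble::tibble(time = t, u_b = a * t)
  i <- induced_current(ramp, cfg, fs = 1000)
  interior <- 2:(length(t) - 1)
  expect_equal(i$current[interior], rep(cfg$c_couple * a, length(interior)))
  expect_error(induced_current(ramp[1, ], cfg), "2 samples")
})

test_that("current follows dh/dt in sign and, for constant area, in value", {
  # constant-area trajectory: I = c_couple * q_b/(eps_a * s0) * dh/dt
  sched <- zero_variance_schedule(2)
  fs <- 20000
  lift <- 0.1
  traj <- synthesize_trajectory(sched,
    fs = fs, lift_s = lift, land_s = lift,
    s_min = 0.002, s_max = 0.025
  )
  s0 <- 0.004
  traj$s_s <- s0
  cfg <- electrostatics_config()
  i <- induced_current(body_potential(traj, cfg), cfg)$current
  scale <- cfg$c_couple * cfg$q_b / (cfg$eps_a * s0)

  # analytic dh/dt of the piecewise-cosine bump, derived by hand
  iv <- efsgait:::schedule_intervals(sched)
  h_max <- 0.15
  a1 <- 0.85 * h_max
  dh <- numeric(nrow(traj))
  boundary <- rep(FALSE, nrow(traj))
  for (k in seq_len(nrow(iv$swing))) {
    a <- iv$swing[k, 1]
    b <- iv$swing[k, 2]
    tw <- b - a
    r1 <- min(lift / tw, 0.4)
    r2 <- min(lift / tw, 0.4)
    idx <- which(traj$time >= a & traj$time <= b)
    u <- (traj$time[idx] - a) / tw
    d <- numeric(length(u))
    rise <- u < r1
    fall <- u > 1 - r2
    mid <- !rise & !fall
    d[rise] <- a1 * pi / (2 * r1) * sin(pi * u[rise] / r1) / tw
    d[fall] <- -a1 * pi / (2 * r2) * sin(pi * (1 - u[fall]) / r2) / tw
    L <- 1 - r1 - r2
    d[mid] <- (h_max - a1) * pi / L * sin(2 * pi * (u[mid] - r1) / L) / tw
    dh[idx] <- d
    # segment joins and interval ends, where the finite difference straddles
    # a derivative kink
    for (tb in c(a, a + r1 * tw, b - r2 * tw, b)) {
      boundary <- boundary | abs(traj$time - tb) <= 3 / fs
    }
  }
  check <- !boundary & abs(dh) > 0.05 * max(abs(dh))
  expect_gt(sum(check), 100)
  rel <- abs(i[check] - scale * dh[check]) / (scale * max(abs(dh)))
  expect_lt(max(rel), 1e-6)
  # sign agreement: current positive while the foot lifts, negative lowering
  away <- !boundary & abs(dh) > 0.01 * max(abs(dh))
  expect_true(all(sign(i[away]) == sign(dh[away])))
})

test_that("the I-V stage converts 1 pA to 10 mV through the 10 GOhm resistor", {
  t <- seq(0, 1, by = 2.5e-4)
  i <- tibble::tibble(time = t, current = 1e-12)
  tr <- front_end(i, quiet_front_end())
  expect_equal(trace_fs(tr), 1000)
  mid <- tr$value[tr$time > 0.2 & tr$time < 0.8]
  expect_equal(mid, rep(0.01, length(mid)), tolerance = 1e-6)
})

test_that("the 20 Hz low-pass rejects mains-band input but passes gait band", {
  t <- seq(0, 4, by = 2.5e-4)
  fe <- quiet_front_end()
  out_rms <- function(freq) {
    i <- tibble::tibble(time = t, current = 1e-12 * sin(2 * pi * freq * t))
    v <- front_end(i, fe)$value
    v <- v[seq(1000, length(v) - 1000)] # ignore filter edge transients
    sqrt(mean(v^2))
  }
  passband <- out_rms(2)
  expect_gt(passband, 0.9 * 0.01 / sqrt(2)) # ~unity gain at 2 Hz
  expect_lt(out_rms(50) / passband, 0.1) # >= 20 dB down at 50 Hz
})

test_that("front end is linear, deterministic under a seed, and zero-preserving", {
  t <- seq(0, 1, by = 2.5e-4)
  i <- tibble::tibble(time = t, current = 1e-12 * sin(2 * pi * 3 * t))
  fe <- quiet_front_end()
  a <- 3.2
  ia <- tibble::tibble(time = t, current = a * i$current)
  expect_equal(front_end(ia, fe)$value, a * front_end(i, fe)$value,
    tolerance = 1e-9
  )
  zero <- tibble::tibble(time = t, current = 0)
  expect_equal(front_end(zero, fe)$value, rep(0, 1 + length(t) %/% 4))
  fe_noisy <- front_end_config()
  expect_identical(front_end(i, fe_noisy, seed = 11), front_end(i, fe_noisy, seed = 11))
  expect_false(identical(
    front_end(i, fe_noisy, seed = 11)$value,
    front_end(i, fe_noisy, seed = 12)$value
  ))
})

test_that("front-end configuration is validated", {
  expect_error(front_end_config(cutoff = 600, fs = 1000),
    class = "efsgait_config_error"
  )
  t <- seq(0, 1, by = 1e-2) # 100 Hz grid, coarser than the 1 kHz target
  i <- tibble::tibble(time = t, current = 0)
  expect_error(front_end(i, quiet_front_end()), "fine")
})

test_that("noiseless EFS extrema align with the schedule's SE and IC events", {
  sched <- sample_event_schedule(pace_profile("normal"), 10, seed = 4)
  tr <- simulate_efs(sched, fe = quiet_front_end())
  ev <- detect_efs_events(tr)
  for (kind in c("IC", "SE")) {
    det <- event_times(ev, kind)
    truth <- event_times(sched, kind)
    for (d in det) {
      expect_lt(min(abs(d - truth)) * 1000, 30)
    }
  }
})

test_that("pressure simulation produces the specified trapezoid", {
  sched <- gait_events(c(1.0, 1.7), c("IC", "SE"))
  tr <- simulate_pressure(sched,
    v_full = 2.5, ramp_s = 0.1, baseline = 0,
    drift_amp = 0, noise_sd = 0, fs = 1000
  )
  v_at <- function(tt) tr$value[which.min(abs(tr$time - tt))]
  expect_equal(v_at(0.9), 0)
  expect_equal(v_at(1.05), 1.25, tolerance = 0.026) # mid-ramp
  expect_true(all(abs(tr$value[tr$time >= 1.1 & tr$time <= 1.6] - 2.5) < 1e-9))
  expect_equal(v_at(1.8), 0)
})

test_that("pressure output respects the 0-2.5 V conditioning range", {
  sched <- zero_variance_schedule(3)
  tr <- simulate_pressure(sched, noise_sd = 0.5, drift_amp = 0.3, seed = 9)
  expect_true(all(tr$value >= 0 & tr$value <= 2.5))
  expect_identical(
    simulate_pressure(sched, seed = 5),
    simulate_pressure(sched, seed = 5)
  )
})

test_that("overlong pressure ramps are rejected", {
  sched <- zero_variance_schedule(2) # stance 0.6 s
  expect_error(simulate_pressure(sched, ramp_s = 0.35), "ramp")
  expect_error(simulate_pressure(sched, v_full = 2.6), "2.5")
})
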