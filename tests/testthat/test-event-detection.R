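test_that("pressure detector recovers trapezoid events to ramp-crossing accuracy", {
  # closed-form oracle: on a linear ramp from baseline 0 to v_full, the
  # corrected contact lies offset_frac * ramp_s after the true IC, and the
  # separation the same interval before the true SE
  sched <- zero_variance_schedule(3)
  ramp <- 0.05
  tr <- simulate_pressure(sched,
    baseline = 0, drift_amp = 0, noise_sd = 0,
    ramp_s = ramp, v_full = 2.5
  )
  ev <- detect_pressure_events(tr)
  shift <- 0.03 * ramp
  expect_equal(event_times(ev, "IC"), c(0, 1, 2) + shift, tolerance = 2e-3)
  expect_equal(event_times(ev, "SE"), c(0.6, 1.6, 2.6) - shift,
    tolerance = 2e-3
  )
})

test_that("the worked ramp-crossing example holds at 1 kHz", {
  # single stance, rise 1.0 -> 1.1 s: corrected IC = 1.0 + 0.1 * 0.03 = 1.003
  sched <- gait_events(c(1.0, 1.7), c("IC", "SE"))
  tr <- simulate_pressure(sched,
    baseline = 0, drift_amp = 0, noise_sd = 0,
    ramp_s = 0.1, v_full = 2.5
  )
  ev <- detect_pressure_events(tr)
  expect_equal(event_times(ev, "IC"), 1.003, tolerance = 1.5e-3)
  expect_equal(event_times(ev, "SE"), 1.697, tolerance = 1.5e-3)
})

test_that("a trace that never crosses threshold yields no events, with warning", {
  t <- seq(0, 5, by = 1e-3)
  tr <- signal_trace(t, rep(0, length(t)), channel = "pressure")
  expect_warning(ev <- detect_pressure_events(tr), "threshold")
  expect_equal(nrow(ev), 0)
})

test_that("pressure detection survives drift and noise", {
  sched <- sample_event_schedule(pace_profile("slow"), 10, seed = 21)
  tr <- simulate_pressure(sched, seed = 22)
  ev <- detect_pressure_events(tr)
  m_ic <- match_events(ev, sched, "IC")
  m_se <- match_events(ev, sched, "SE")
  expect_gte(nrow(m_ic), 9)
  expect_gte(nrow(m_se), 9)
  expect_lt(max(abs(c(m_ic$delta_ms, m_se$delta_ms))), 20)
})

test_that("both detectors are translation-equivariant", {
  sched <- zero_variance_schedule(3)
  dt <- 7.25
  pr <- simulate_pressure(sched,
    baseline = 0, drift_amp = 0, noise_sd = 0,
    ramp_s = 0.05
  )
  pr_shift <- signal_trace(pr$time + dt, pr$value,
    channel = "pressure",
    fs = trace_fs(pr)
  )
  expect_equal(
    detect_pressure_events(pr_shift)$time,
    detect_pressure_events(pr)$time + dt
  )
  ef <- simulate_efs(sched, fe = quiet_front_end())
  ef_shift <- signal_trace(ef$time + dt, ef$value,
    channel = "efs",
    fs = trace_fs(ef)
  )
  expect_equal(
    detect_efs_events(ef_shift)$time,
    detect_efs_events(ef)$time + dt
  )
})

test_that("pressure events are insensitive to amplitude scaling", {
  sched <- zero_variance_schedule(3)
  tr <- simulate_pressure(sched,
    baseline = 0, drift_amp = 0, noise_sd = 0,
    ramp_s = 0.05
  )
  scaled <- signal_trace(tr$time, 0.8 * tr$value,
    channel = "pressure",
    fs = trace_fs(tr)
  )
  a <- detect_pressure_events(tr)
  b <- detect_pressure_events(scaled)
  expect_equal(b$time, a$time, tolerance = 2e-3)
})

test_that("EFS detector labels foot-off at peaks and contact at troughs", {
  sched <- sample_event_schedule(pace_profile("normal"), 10, seed = 4)
  tr <- simulate_efs(sched, fe = quiet_front_end())
  ev <- detect_efs_events(tr)
  m_se <- match_events(ev, sched, "SE", window = 40)
  m_ic <- match_events(ev, sched, "IC", window = 40)
  expect_gte(nrow(m_se), 9)
  expect_gte(nrow(m_ic), 9)
  expect_true(all(m_se$delta_ms > 0)) # peak trails the true foot-off
  expect_true(all(m_ic$delta_ms < 0)) # trough leads the true contact
})

test_that("alternation always holds in detector output", {
  for (seed in 1:4) {
    sched <- sample_event_schedule(pace_profile("fast"), 8, seed = seed)
    ev <- detect_efs_events(simulate_efs(sched, seed = seed + 100))
    expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
    evp <- detect_pressure_events(simulate_pressure(sched, seed = seed + 200))
    expect_true(all(evp$kind[-1] != evp$kind[-nrow(evp)]))
  }
})

test_that("a featureless EFS trace raises an insufficient-signal error", {
  t <- seq(0, 5, by = 1e-3)
  tr <- signal_trace(t, rep(0.3, length(t)), channel = "efs")
  expect_error(detect_efs_events(tr), class = "efsgait_insufficient_signal")
})

test_that("negating the trace swaps the event labels exactly", {
  sched <- zero_variance_schedule(4)
  tr <- simulate_efs(sched, fe = quiet_front_end())
  neg <- signal_trace(tr$time, -tr$value, channel = "efs", fs = trace_fs(tr))
  a <- detect_efs_events(tr)
  b <- detect_efs_events(neg)
  expect_equal(b$time, a$time)
  expect_equal(b$kind, ifelse(a$kind == "SE", "IC", "SE"))
})

test_that("polarity auto-detection restores labels on a flipped electrode", {
  sched <- sample_event_schedule(pace_profile("normal"), 10, seed = 6)
  tr <- simulate_efs(sched, fe = quiet_front_end())
  neg <- signal_trace(tr$time, -tr$value, channel = "efs", fs = trace_fs(tr))
  cfg <- detector_config(detect_polarity = TRUE)
  a <- detect_efs_events(tr, cfg)
  b <- detect_efs_events(neg, cfg)
  expect_equal(b$kind, a$kind)
  # and with correct polarity auto-detection changes nothing
  expect_equal(a$kind, detect_efs_events(tr)$kind)
})

test_that("channel tags are enforced", {
  t <- seq(0, 1, by = 1e-3)
  efs <- signal_trace(t, sin(t), channel = "efs")
  pressure <- signal_trace(t, abs(sin(t)), channel = "pressure")
  expect_error(detect_pressure_events(efs), "pressure")
  expect_error(detect_efs_events(pressure), "efs")
})
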