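#' Electrostatic body/environment configuration
#'
#' Constants of the equivalent-capacitance model of a charged walking body.
#' The body carries a quasi-static charge `q_b`; its capacitance to the
#' environment is the foot--ground capacitance `c_f` (two soles acting as
#' plate capacitors, `c_f = 2 * eps_s * s / d_e`) in parallel with the
#' residual body--environment capacitances `c_r_total`; `c_couple` couples
#' the body to the sensing electrode. Absolute charge and coupling values
#' are not measurable in practice, so the absolute amplitude of the
#' simulated signal is uncalibrated -- only its timing structure is
#' physically meaningful.
#'
#' @param q_b Body charge (C).
#' @param eps_a Air permittivity (F/m).
#' @param eps_s Sole dielectric permittivity (F/m).
#' @param d_e Sole thickness (m).
#' @param c_f Foot--ground capacitance (F); by default derived as
#'   `2 * eps_s * s_ref / d_e`.
#' @param s_ref Reference flat-foot area used in the `c_f` derivation (m^2).
#' @param c_r_total Summed residual body--environment capacitance (F).
#' @param c_couple Body--electrode coupling capacitance (F).
#' @return A list of class `electrostatics_config`.
#' @export
#' @examples
#' electrostatics_config()
electrostatics_config <- function(q_b = 1e-8,
                                  eps_a = 8.85e-12,
                                  eps_s = 2.2 * 8.85e-12,
                                  d_e = 0.01,
                                  c_f = NULL,
                                  s_ref = 0.025,
                                  c_r_total = 5e-11,
                                  c_couple = 1e-12) {
  c_f <- c_f %||% (2 * eps_s * s_ref / d_e)
  check_positive_scalar(c_f, "c_f")
  check_positive_scalar(c_couple, "c_couple")
  check_positive_scalar(eps_a, "eps_a")
  if (!is.finite(q_b)) abort("`q_b` must be finite")
  structure(
    list(
      q_b = q_b, eps_a = eps_a, eps_s = eps_s, d_e = d_e, c_f = c_f,
      c_r_total = c_r_total, c_couple = c_couple
    ),
    class = "electrostatics_config"
  )
}

#' Analog front-end configuration
#'
#' The electrode current is converted to a voltage across a 10 GOhm
#' sampling resistor (10 mV per pA), low-pass filtered at 20 Hz to reject
#' mains and other high-frequency fields, and digitized at 1 kHz. Noise is
#' injected input-referred: wideband current noise of standard deviation
#' `noise_sd` plus a mains sinusoid of amplitude `mains_amp` at
#' `mains_freq`.
#'
#' @param r_s Sampling resistance (Ohm); sets the I--V gain (`1e10` Ohm
#'   gives 10 mV/pA).
#' @param cutoff Low-pass corner frequency (Hz).
#' @param filter_order Butterworth order (the filter is applied
#'   forward-backward, so the effective attenuation is doubled and the
#'   phase is zero).
#' @param fs Output sampling rate (Hz).
#' @param noise_sd Input-referred white current-noise sd (A).
#' @param mains_freq,mains_amp Mains interference frequency (Hz) and
#'   amplitude (A).
#' @return A list of class `front_end_config`.
#' @export
#' @examples
#' front_end_config()
front_end_config <- function(r_s = 1e10, cutoff = 20, filter_order = 4,
                             fs = 1000, noise_sd = 1e-7, mains_freq = 50,
                             mains_amp = 5e-8) {
  check_positive_scalar(r_s, "r_s")
  check_positive_scalar(fs, "fs")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    abort("`cutoff` must lie in (0, fs/2)", class = "efsgait_config_error")
  }
  structure(
    list(
      r_s = r_s, cutoff = cutoff, filter_order = as.integer(filter_order),
      fs = fs, noise_sd = noise_sd, mains_freq = mains_freq,
      mains_amp = mains_amp
    ),
    class = "front_end_config"
  )
}

#' Induced body potential from foot kinematics
#'
#' Evaluates the body potential of the plate-capacitor walking model,
#' `U_B(t) = q_b * (eps_a * s_s(t) + h(t) * c_f) / (c_f * eps_a * s_s(t))`,
#' equivalently `q_b * (1/c_f + h(t) / (eps_a * s_s(t)))`: a constant
#' standing potential plus a term that grows as the airborne foot opens a
#' series air gap under the sole.
#'
#' @param traj A [synthesize_trajectory()] result (columns `time`, `h`,
#'   `s_s`).
#' @param cfg An [electrostatics_config()].
#' @return A tibble with columns `time` and `u_b` (V), carrying `fs`.
#' @export
body_potential <- function(traj, cfg = electrostatics_config()) {
  stopifnot(is.data.frame(traj), all(c("time", "h", "s_s") %in% names(traj)))
  if (any(traj$s_s <= 0)) {
    abort("`s_s` must be strictly positive everywhere",
      class = "efsgait_domain_error"
    )
  }
  u <- cfg$q_b * (1 / cfg$c_f + traj$h / (cfg$eps_a * traj$s_s))
  out <- tibble(time = traj$time, u_b = u)
  attr(out, "fs") <- attr(traj, "fs") %||% (1 / median(diff(traj$time)))
  out
}

#' Displacement current through the sensing electrode
#'
#' The electrode current is the time derivative of the induced charge,
#' `I(t) = c_couple * dU_B/dt`, computed by central differences (one-sided
#' at the ends). The electrode's own potential is neglected relative to the
#' body potential: the electrode sits at virtual ground behind the sampling
#' resistor.
#'
#' @param u_b Tibble with columns `time`, `u_b` (from [body_potential()]).
#' @param cfg An [electrostatics_config()].
#' @param fs Sampling rate (Hz); inferred from `u_b` when `NULL`.
#' @return A tibble with columns `time` and `current` (A), carrying `fs`.
#' @export
induced_current <- function(u_b, cfg = electrostatics_config(), fs = NULL) {
  stopifnot(is.data.frame(u_b), all(c("time", "u_b") %in% names(u_b)))
  if (nrow(u_b) < 2L) abort("need at least 2 samples of the potential")
  fs <- fs %||% attr(u_b, "fs") %||% (1 / median(diff(u_b$time)))
  i <- cfg$c_couple * central_diff(u_b$u_b, fs)
  out <- tibble(time = u_b$time, current = i)
  attr(out, "fs") <- fs
  out
}

#' Analog front end: noise, I--V conversion, filtering, decimation
#'
#' Applies the acquisition chain to an electrode-current series simulated
#' on a fine grid: adds input-referred white noise and a mains sinusoid,
#' converts to volts across the sampling resistor, low-pass filters with a
#' zero-phase Butterworth (applied forward-backward so event timing is
#' never shifted), and decimates to the target rate. The fine simulation
#' grid keeps the numerical derivative clean before filtering; its rate
#' must be an integer multiple of `cfg$fs`.
#'
#' @param current Tibble with columns `time`, `current` (A) on a grid at
#'   `>= cfg$fs` Hz.
#' @param cfg A [front_end_config()].
#' @param seed Integer seed for the noise draws; `NULL` leaves the RNG
#'   state alone.
#' @return A [signal_trace()] on the `efs` channel at `cfg$fs` Hz.
#' @export
#' @examples
#' # a steady 1 pA current reads 10 mV through the 10 GOhm resistor
#' i <- tibble::tibble(time = seq(0, 1, by = 2.5e-4), current = 1e-12)
#' fe <- front_end_config(noise_sd = 0, mains_amp = 0)
#' tr <- front_end(i, fe)
#' round(median(tr$value), 6)
front_end <- function(current, cfg = front_end_config(), seed = NULL) {
  stopifnot(is.data.frame(current),
    all(c("time", "current") %in% names(current)))
  fs_in <- attr(current, "fs") %||% (1 / median(diff(current$time)))
  if (fs_in + 1e-6 < cfg$fs) {
    abort("simulate on a grid at least as fine as the output rate")
  }
  if (cfg$cutoff >= cfg$fs / 2) {
    abort("`cutoff` must be below the output Nyquist frequency",
      class = "efsgait_config_error"
    )
  }
  factor <- round(fs_in / cfg$fs)
  if (abs(fs_in / cfg$fs - factor) > 1e-6) {
    abort("simulation rate must be an integer multiple of `cfg$fs`")
  }
  i <- current$current
  n <- length(i)
  add_noise <- function(i) {
    if (cfg$noise_sd > 0) i <- i + rnorm(n, 0, cfg$noise_sd)
    if (cfg$mains_amp > 0) {
      i <- i + cfg$mains_amp * sin(2 * pi * cfg$mains_freq * current$time)
    }
    i
  }
  i <- if (is.null(seed)) add_noise(i) else withr::with_seed(seed, add_noise(i))
  v <- i * cfg$r_s
  bf <- signal::butter(cfg$filter_order, cfg$cutoff / (fs_in / 2),
    type = "low"
  )
  # odd-reflection padding suppresses the filter's edge transients (a DC
  # input then passes exactly at the DC gain)
  pad <- min(n - 1L, 3L * ceiling(fs_in / cfg$cutoff))
  if (pad > 0L) {
    front <- 2 * v[1L] - v[seq(pad + 1L, 2L)]
    back <- 2 * v[n] - v[seq(n - 1L, n - pad)]
    vp <- signal::filtfilt(bf, c(front, v, back))
    v <- vp[pad + seq_len(n)]
  } else {
    v <- signal::filtfilt(bf, v)
  }
  keep <- seq(1L, n, by = factor)
  signal_trace(current$time[keep], v[keep], channel = "efs", fs = cfg$fs)
}

#' Simulate the electrostatic channel from a schedule
#'
#' Convenience wrapper chaining [synthesize_trajectory()],
#' [body_potential()], [induced_current()] and [front_end()]. The forward
#' model runs on an internal grid of `sim_fs` Hz and the front end
#' decimates to `fe$fs`.
#'
#' @param schedule A [gait_events()] schedule.
#' @param cfg An [electrostatics_config()].
#' @param fe A [front_end_config()].
#' @param sim_fs Internal simulation rate (Hz); must be an integer
#'   multiple of `fe$fs`.
#' @param seed Integer seed for the front-end noise.
#' @param ... Passed to [synthesize_trajectory()].
#' @return A [signal_trace()] on the `efs` channel.
#' @export
simulate_efs <- function(schedule, cfg = electrostatics_config(),
                         fe = front_end_config(), sim_fs = 4 * fe$fs,
                         seed = NULL, ...) {
  traj <- synthesize_trajectory(schedule, fs = sim_fs, ...)
  traj |>
    body_potential(cfg) |>
    induced_current(cfg) |>
    front_end(fe, seed = seed)
}

#' Simulate the FSR insole pressure channel
#'
#' The insole voltage follows the foot load: per stance interval a
#' trapezoid rising from the baseline to `v_full` over `ramp_s` seconds
#' starting at IC and falling back over `ramp_s` seconds ending at SE. A
#' slow sinusoidal baseline drift (unloaded-sensor drift during movement)
#' and Gaussian noise are added, and the output is clipped to the
#' conditioning circuit's 0--2.5 V range.
#'
#' @param schedule A [gait_events()] schedule.
#' @param v_full Loaded plateau voltage (V, at most 2.5).
#' @param ramp_s Loading/unloading ramp duration (s); the two ramps must
#'   fit inside the shortest stance.
#' @param baseline Unloaded output voltage (V).
#' @param drift_amp,drift_period Baseline drift amplitude (V) and period
#'   (s); the period is much longer than a gait cycle.
#' @param noise_sd Additive Gaussian noise sd (V).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed for drift phase and noise.
#' @param pad_s Recording padding before the first and after the final
#'   event (s).
#' @return A [signal_trace()] on the `pressure` channel.
#' @export
#' @examples
#' sched <- gait_events(c(0, 0.6, 1.0), c("IC", "SE", "IC"))
#' tr <- simulate_pressure(sched,
#'   baseline = 0, drift_amp = 0, noise_sd = 0,
#'   ramp_s = 0.05
#' )
#' range(tr$value)
simulate_pressure <- function(schedule, v_full = 2.5, ramp_s = 0.08,
                              baseline = 0.1, drift_amp = 0.05,
                              drift_period = 20, noise_sd = 0.01,
                              fs = 1000, seed = NULL, pad_s = 0.5) {
  stopifnot(inherits(schedule, "gait_events"))
  if (v_full > 2.5) abort("`v_full` must not exceed the 2.5 V output range")
  check_positive_scalar(ramp_s, "ramp_s")
  iv <- schedule_intervals(schedule)
  if (nrow(iv$stance) > 0L) {
    min_stance <- min(iv$stance[, 2L] - iv$stance[, 1L])
    if (2 * ramp_s > min_stance) {
      abort("`ramp_s` too long: loading and unloading ramps overlap in the shortest stance")
    }
  }
  t <- seq(min(schedule$time) - pad_s, max(schedule$time) + pad_s, by = 1 / fs)
  v <- rep(baseline, length(t))
  for (k in seq_len(nrow(iv$stance))) {
    a <- iv$stance[k, 1L]
    b <- iv$stance[k, 2L]
    idx <- which(t >= a & t <= b)
    tt <- t[idx]
    vv <- rep(v_full, length(tt))
    rise <- tt < a + ramp_s
    fall <- tt > b - ramp_s
    vv[rise] <- baseline + (v_full - baseline) * (tt[rise] - a) / ramp_s
    vv[fall] <- baseline + (v_full - baseline) * (b - tt[fall]) / ramp_s
    v[idx] <- vv
  }
  # a final IC with no closing SE leaves the foot loaded to the end
  ic <- event_times(schedule, "IC")
  se <- event_times(schedule, "SE")
  if (length(ic) > 0L && (length(se) == 0L || max(ic) > max(se))) {
    a <- max(ic)
    idx <- which(t >= a)
    tt <- t[idx]
    vv <- rep(v_full, length(tt))
    rise <- tt < a + ramp_s
    vv[rise] <- baseline + (v_full - baseline) * (tt[rise] - a) / ramp_s
    v[idx] <- vv
  }
  apply_noise <- function(v) {
    if (drift_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      v <- v + drift_amp * sin(2 * pi * t / drift_period + phase)
    }
    if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
    v
  }
  v <- if (is.null(seed)) apply_noise(v) else {
    withr::with_seed(seed, apply_noise(v))
  }
  v <- pmin(pmax(v, 0), 2.5)
  signal_trace(t, v, channel = "pressure", fs = fs)
}
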