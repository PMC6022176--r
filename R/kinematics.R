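#' Pace profiles for the gait-timing sampler
#'
#' A pace profile describes the distribution of gait-cycle durations at one
#' walking speed. Cycle durations are drawn from a truncated normal with the
#' given mean and standard deviation, clipped to `[tg_min, tg_max]`; the
#' stance phase occupies a fraction of each cycle drawn from its own
#' truncated normal (clipped to (0.4, 0.8)). The built-in profiles reproduce
#' metronome-paced walking at three speeds:
#' fast 990 +/- 120 ms (870--1153 ms), normal 1198 +/- 110 ms
#' (1088--1398 ms), slow 1498 +/- 75 ms (1358--1697 ms), with a stance
#' fraction of about 60% of the cycle, as in healthy adult gait.
#'
#' @param name `"slow"`, `"normal"` or `"fast"`.
#' @param tg_mean,tg_sd Mean and sd of the cycle duration (ms).
#' @param tg_min,tg_max Clip bounds for the cycle duration (ms).
#' @param stance_fraction_mean,stance_fraction_sd Mean and sd of the stance
#'   fraction (dimensionless, in (0, 1)).
#' @return A list of class `pace_profile`.
#' @export
#' @examples
#' pace_profile("normal")
#' pace_profile("normal", tg_sd = 0, stance_fraction_sd = 0) # deterministic
pace_profile <- function(name = c("normal", "slow", "fast"),
                         tg_mean = NULL, tg_sd = NULL,
                         tg_min = NULL, tg_max = NULL,
                         stance_fraction_mean = 0.6,
                         stance_fraction_sd = 0.025) {
  name <- match.arg(name)
  defaults <- list(
    fast   = c(tg_mean = 990, tg_sd = 120, tg_min = 870, tg_max = 1153),
    normal = c(tg_mean = 1198, tg_sd = 110, tg_min = 1088, tg_max = 1398),
    slow   = c(tg_mean = 1498, tg_sd = 75, tg_min = 1358, tg_max = 1697)
  )[[name]]
  custom <- !is.null(tg_mean) || !is.null(tg_sd)
  tg_mean <- tg_mean %||% defaults[["tg_mean"]]
  tg_sd <- tg_sd %||% defaults[["tg_sd"]]
  # the stock bounds are the printed per-pace ranges; once the mean or sd is
  # overridden they no longer apply, so fall back to mean +/- 3 sd
  tg_min <- tg_min %||% if (custom) tg_mean - 3 * tg_sd else defaults[["tg_min"]]
  tg_max <- tg_max %||% if (custom) tg_mean + 3 * tg_sd else defaults[["tg_max"]]
  if (tg_sd < 0 || stance_fraction_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  if (!(tg_min <= tg_mean && tg_mean <= tg_max)) {
    abort("`tg_min <= tg_mean <= tg_max` is required")
  }
  if (stance_fraction_mean <= 0 || stance_fraction_mean >= 1) {
    abort("`stance_fraction_mean` must lie in (0, 1)")
  }
  structure(
    list(
      name = name, tg_mean = tg_mean, tg_sd = tg_sd,
      tg_min = tg_min, tg_max = tg_max,
      stance_fraction_mean = stance_fraction_mean,
      stance_fraction_sd = stance_fraction_sd
    ),
    class = "pace_profile"
  )
}

#' @export
print.pace_profile <- function(x, ...) {
  cat(sprintf(
    "<pace_profile: %s> Tg %g +/- %g ms [%g, %g], stance %.1f%% +/- %.1f%%\n",
    x$name, x$tg_mean, x$tg_sd, x$tg_min, x$tg_max,
    100 * x$stance_fraction_mean, 100 * x$stance_fraction_sd
  ))
  invisible(x)
}

# Truncated-normal draws by rejection; degenerates to the mean when sd = 0.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a ground-truth gait event schedule
#'
#' Draws `n_cycles` gait cycles from a pace profile and lays them out on the
#' time axis: initial contacts at the cumulative cycle boundaries
#' (`n_cycles + 1` IC events, the last one closing the final cycle) and one
#' foot-off (SE) inside each cycle at the sampled stance fraction. The
#' result is the simulator's hidden truth against which detectors are
#' scored.
#'
#' @param profile A [pace_profile()].
#' @param n_cycles Number of gait cycles (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical schedules.
#'   `NULL` leaves the RNG state alone.
#' @return A [gait_events()] tibble (source `"truth"`) with
#'   `2 * n_cycles + 1` rows, plus attributes `tg_ms` and `stance_fraction`
#'   holding the per-cycle draws.
#' @export
#' @examples
#' sched <- sample_event_schedule(pace_profile("normal"), n_cycles = 5, seed = 1)
#' sched
#' attr(sched, "tg_ms")
sample_event_schedule <- function(profile, n_cycles, seed = NULL) {
  stopifnot(inherits(profile, "pace_profile"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
    n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be a positive integer")
  }
  n_cycles <- as.integer(n_cycles)
  draw <- function() {
    tg <- rtrunc_norm(
      n_cycles, profile$tg_mean, profile$tg_sd,
      profile$tg_min, profile$tg_max
    )
    frac <- rtrunc_norm(
      n_cycles, profile$stance_fraction_mean, profile$stance_fraction_sd,
      0.4, 0.8
    )
    list(tg = tg, frac = frac)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ic <- c(0, cumsum(d$tg)) / 1000
  se <- ic[seq_len(n_cycles)] + d$tg * d$frac / 1000
  times <- c(ic, se)
  kinds <- c(rep("IC", n_cycles + 1L), rep("SE", n_cycles))
  ord <- order(times)
  out <- gait_events(times[ord], kinds[ord], source = "truth")
  attr(out, "tg_ms") <- d$tg
  attr(out, "stance_fraction") <- d$frac
  out
}

#' Contralateral (left-foot) schedule
#'
#' Only the right foot is instrumented and modelled by default; a left-foot
#' schedule can be derived by shifting each cycle by half its duration,
#' keeping the same stance durations. It is useful to enrich the simulated
#' electrostatic waveform with the second foot's contribution.
#'
#' @param schedule A right-foot [sample_event_schedule()] result.
#' @return A [gait_events()] schedule for the opposite foot (one cycle
#'   fewer, since the shifted final cycle has no closing contact).
#' @export
contralateral_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "gait_events"))
  ic <- event_times(schedule, "IC")
  se <- event_times(schedule, "SE")
  n <- length(se)
  if (n < 2L) abort("need at least 2 cycles to derive the opposite foot")
  tg <- diff(ic)
  stance <- se - ic[seq_len(n)]
  ic_l <- ic[seq_len(n)] + tg / 2
  se_l <- ic_l + stance
  # drop any trailing partial structure beyond the last shifted contact
  keep <- se_l < ic_l[n]
  times <- c(ic_l, se_l[keep])
  kinds <- c(rep("IC", n), rep("SE", sum(keep)))
  ord <- order(times)
  gait_events(times[ord], kinds[ord], source = "truth")
}

# Stance intervals (IC -> SE) and swing intervals (SE -> next IC) of an
# alternating event sequence, as two-column matrices.
schedule_intervals <- function(events) {
  ic <- event_times(events, "IC")
  se <- event_times(events, "SE")
  stance <- swing <- matrix(numeric(), ncol = 2)
  if (length(se) > 0L) {
    # pair each SE with the IC immediately before / the IC immediately after
    prev_ic <- vapply(se, function(s) {
      cand <- ic[ic < s]
      if (length(cand)) max(cand) else NA_real_
    }, numeric(1))
    next_ic <- vapply(se, function(s) {
      cand <- ic[ic > s]
      if (length(cand)) min(cand) else NA_real_
    }, numeric(1))
    stance <- cbind(prev_ic, se)[!is.na(prev_ic), , drop = FALSE]
    swing <- cbind(se, next_ic)[!is.na(next_ic), , drop = FALSE]
  }
  list(stance = stance, swing = swing)
}

#' Synthesize foot kinematics from an event schedule
#'
#' Builds the two kinematic series the electrostatic forward model needs:
#' the foot height above ground `h(t)` and the equivalent sole--ground plate
#' area `s_s(t)`, on a uniform grid at `fs` Hz spanning the schedule.
#'
#' The height is zero throughout stance. Over each swing it is a piecewise
#' raised-cosine bump: a fast lift over `lift_s` seconds up to 85% of
#' `h_max`, a gentle dome peaking at `h_max` at mid-swing, and a fast
#' landing over `land_s` seconds. The fast lift and landing reflect that in
#' human gait the vertical foot velocity peaks just after toe-off and just
#' before heel strike; this is what places the extrema of the induced
#' current at the foot-off and contact instants.
#'
#' The area is `s_max` while the foot is flat, rolls off smoothly to
#' `s_min` over the last `roll_fraction` of stance (toe roll-off before
#' foot-off), ramps back from `s_min` to `s_max` over the first
#' `roll_fraction` of stance after contact (heel-to-flat loading), and
#' stays at `s_min` during swing. Both series are continuous with bounded
#' derivatives.
#'
#' @param schedule A [gait_events()] schedule (alternating IC/SE).
#' @param h_max Peak swing foot clearance (m).
#' @param s_max,s_min Flat-foot and minimal (toe/heel point contact)
#'   equivalent plate areas (m^2); `s_min > 0` keeps the downstream
#'   potential finite.
#' @param roll_fraction Fraction of each stance spent in the heel-loading /
#'   toe roll-off ramps, in (0, 0.5).
#' @param fs Sampling rate of the kinematic grid (Hz).
#' @param lift_s,land_s Durations of the fast lift after foot-off and the
#'   fast landing before contact (s); each is capped at 40% of the swing.
#' @param pad_s Quiet padding prepended before the first and appended
#'   after the final event (s).
#' @return A tibble of class `foot_trajectory` with columns `time`, `h`,
#'   `s_s`, carrying `fs` and the generating schedule as attributes.
#' @export
#' @examples
#' sched <- sample_event_schedule(pace_profile("normal", tg_sd = 0,
#'   stance_fraction_sd = 0
#' ), 2, seed = 1)
#' traj <- synthesize_trajectory(sched, fs = 500)
#' max(traj$h)
synthesize_trajectory <- function(schedule, h_max = 0.15, s_max = 0.025,
                                  s_min = 0.002, roll_fraction = 0.15,
                                  fs = 4000, lift_s = 0.05, land_s = 0.05,
                                  pad_s = 0.5) {
  stopifnot(inherits(schedule, "gait_events"))
  check_positive_scalar(fs, "fs")
  check_positive_scalar(s_min, "s_min")
  if (s_min >= s_max) abort("`s_min` must be smaller than `s_max`")
  if (roll_fraction <= 0 || roll_fraction >= 0.5) {
    abort("`roll_fraction` must lie in (0, 0.5)")
  }
  t_end <- max(schedule$time) + pad_s
  t <- seq(min(schedule$time) - pad_s, t_end, by = 1 / fs)
  h <- numeric(length(t))
  s_s <- rep(s_min, length(t))

  iv <- schedule_intervals(schedule)
  plateau <- 0.85 # height reached by the end of the fast lift, as a fraction

  for (k in seq_len(nrow(iv$swing))) {
    a <- iv$swing[k, 1L]
    b <- iv$swing[k, 2L]
    tw <- b - a
    idx <- which(t >= a & t <= b)
    u <- (t[idx] - a) / tw
    r1 <- min(lift_s / tw, 0.4)
    r2 <- min(land_s / tw, 0.4)
    a1 <- plateau * h_max
    hh <- numeric(length(u))
    rise <- u < r1
    fall <- u > 1 - r2
    mid <- !rise & !fall
    hh[rise] <- a1 * (1 - cos(pi * u[rise] / r1)) / 2
    hh[fall] <- a1 * (1 - cos(pi * (1 - u[fall]) / r2)) / 2
    hh[mid] <- a1 + (h_max - a1) *
      (1 - cos(2 * pi * (u[mid] - r1) / (1 - r1 - r2))) / 2
    h[idx] <- hh
  }

  stance <- iv$stance
  # the final IC opens a stance with no closing SE: treat the padded tail as
  # flat stance with a heel-loading ramp of typical length
  ic <- event_times(schedule, "IC")
  se <- event_times(schedule, "SE")
  if (length(ic) > 0L && (length(se) == 0L || max(ic) > max(se))) {
    typical <- if (nrow(stance) > 0L) {
      median(stance[, 2L] - stance[, 1L])
    } else {
      t_end - max(ic)
    }
    stance <- rbind(stance, c(max(ic), max(ic) + typical))
  }
  for (k in seq_len(nrow(stance))) {
    a <- stance[k, 1L]
    b <- min(stance[k, 2L], t_end)
    ts <- stance[k, 2L] - stance[k, 1L]
    idx <- which(t >= a & t <= b)
    u <- (t[idx] - a) / ts
    ss <- rep(s_max, length(u))
    load <- u < roll_fraction
    roll <- u > 1 - roll_fraction
    ss[load] <- s_min + (s_max - s_min) *
      (1 - cos(pi * u[load] / roll_fraction)) / 2
    ss[roll] <- s_min + (s_max - s_min) *
      (1 - cos(pi * (1 - u[roll]) / roll_fraction)) / 2
    s_s[idx] <- ss
  }
  # before the first IC the foot is treated as just landing out of swing
  # (h = 0, s_s = s_min), which keeps both series continuous at the first
  # contact

  out <- new_tibble(
    list(time = t, h = h, s_s = s_s),
    nrow = length(t),
    class = "foot_trajectory"
  )
  attr(out, "fs") <- fs
  attr(out, "schedule") <- schedule
  out
}
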