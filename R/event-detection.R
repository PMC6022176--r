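#' Detector configuration
#'
#' Tuning constants for the two foot-event detectors. The pressure
#' detector thresholds the insole voltage at `pressure_threshold` (1 V sits
#' well between the unloaded output and the fully loaded plateau) and
#' corrects the contact/separation instants by an offset of `offset_frac`
#' (3%) of the cycle's local max-to-min signal excursion. The EFS detector
#' smooths the trace over `efs_smooth_window` seconds and extracts peaks
#' and troughs with a prominence of at least `efs_min_prominence_frac` of
#' the trace's peak-to-peak amplitude, separated by at least
#' `min_event_gap` seconds within each kind.
#'
#' @param pressure_threshold Stance-detection threshold (V).
#' @param offset_frac Correction offset as a fraction of the local
#'   max-to-min excursion.
#' @param min_event_gap Minimum separation between same-kind events (s).
#' @param efs_smooth_window Moving-average width for the EFS trace (s).
#' @param efs_min_prominence_frac Minimum peak prominence as a fraction of
#'   the EFS trace's peak-to-peak amplitude.
#' @param pressure_smooth_window Moving-average width used for edge and
#'   derivative finding on the pressure trace (s).
#' @param detect_polarity If `TRUE`, the EFS detector checks whether the
#'   electrode polarity is flipped (troughs leading peaks within cycles)
#'   and swaps the IC/SE labels if so.
#' @return A list of class `detector_config`.
#' @export
#' @examples
#' detector_config()
detector_config <- function(pressure_threshold = 1.0, offset_frac = 0.03,
                            min_event_gap = 0.3, efs_smooth_window = 0.05,
                            efs_min_prominence_frac = 0.2,
                            pressure_smooth_window = 0.02,
                            detect_polarity = FALSE) {
  if (offset_frac <= 0 || offset_frac >= 1) {
    abort("`offset_frac` must lie in (0, 1)")
  }
  check_positive_scalar(min_event_gap, "min_event_gap")
  structure(
    list(
      pressure_threshold = pressure_threshold, offset_frac = offset_frac,
      min_event_gap = min_event_gap, efs_smooth_window = efs_smooth_window,
      efs_min_prominence_frac = efs_min_prominence_frac,
      pressure_smooth_window = pressure_smooth_window,
      detect_polarity = detect_polarity
    ),
    class = "detector_config"
  )
}

#' Detect foot events in the insole pressure signal
#'
#' Three-step segmentation of the FSR voltage:
#' \enumerate{
#'   \item Locate the stance time zones from the rising and falling edges
#'     of the signal: a monotonically increasing run crossing the fixed
#'     threshold upward opens a stance, a decreasing run crossing downward
#'     closes it.
#'   \item For each edge find the adjacent local minimum of the signal
#'     (the unloaded level drifts, so a fixed level cannot be used):
#'     differentiate the smoothed signal and walk from the derivative's
#'     peak back (rising edge) or forward (falling edge) to its zero
#'     crossing.
#'   \item Correct the contact and separation instants by an offset of
#'     `offset_frac` of the local max-to-min excursion of the cycle:
#'     initial contact is the first instant after the pre-rise minimum at
#'     which the signal exceeds `min + offset`; the separate event is the
#'     last instant before the post-fall minimum at which it still does.
#' }
#'
#' @param trace A [signal_trace()] on the `pressure` channel.
#' @param cfg A [detector_config()].
#' @return A [gait_events()] tibble (source `"pressure"`). A trace that
#'   never crosses the threshold yields an empty result with a warning.
#' @export
detect_pressure_events <- function(trace, cfg = detector_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace_channel(trace) != "pressure") {
    abort("`trace` must be a pressure-channel signal_trace")
  }
  fs <- trace_fs(trace)
  x <- trace$value
  t <- trace$time
  n <- length(x)
  win <- max(1L, round(cfg$pressure_smooth_window * fs))
  xs <- moving_average(x, win)
  thr <- cfg$pressure_threshold

  above <- xs > thr
  rises <- which(above[-1L] & !above[-n]) + 1L
  falls <- which(!above[-1L] & above[-n]) + 1L
  if (length(rises) == 0L && length(falls) == 0L) {
    warn("pressure trace never crosses the threshold; no events detected")
    return(gait_events(numeric(), character(), source = "pressure"))
  }
  cross <- tibble(
    index = c(rises, falls),
    type = rep(c("rise", "fall"), c(length(rises), length(falls)))
  ) |> arrange(.data$index)
  # de-chatter: a crossing pair closer than the minimum event gap is a noise
  # excursion through the threshold, not a gait phase
  gap <- round(cfg$min_event_gap * fs)
  repeat {
    d <- diff(cross$index)
    bad <- which(d < gap)
    if (length(bad) == 0L) break
    cross <- cross[-c(bad[1L], bad[1L] + 1L), ]
  }
  if (nrow(cross) > 1L &&
    any(cross$type[-1L] == cross$type[-nrow(cross)])) {
    k <- which(cross$type[-1L] == cross$type[-nrow(cross)])[1L] + 1L
    abort(
      sprintf(
        "malformed pressure signal: consecutive %s edges near sample %d",
        cross$type[k], cross$index[k]
      ),
      class = "efsgait_malformed_signal"
    )
  }
  # keep complete stance zones only
  if (nrow(cross) > 0L && cross$type[1L] == "fall") cross <- cross[-1L, ]
  if (nrow(cross) > 0L && cross$type[nrow(cross)] == "rise") {
    cross <- cross[-nrow(cross), ]
  }
  if (nrow(cross) == 0L) {
    warn("no complete stance zone in the pressure trace; no events detected")
    return(gait_events(numeric(), character(), source = "pressure"))
  }
  rises <- cross$index[cross$type == "rise"]
  falls <- cross$index[cross$type == "fall"]

  ds <- moving_average(central_diff(xs, fs), win)
  half <- max(1L, round(cfg$min_event_gap * fs / 2))

  ic_idx <- se_idx <- integer(length(rises))
  min_pre <- min_post <- numeric(length(rises))
  for (m in seq_along(rises)) {
    ri <- rises[m]
    fi <- falls[m]
    lo <- if (m > 1L) falls[m - 1L] else 1L
    hi <- if (m < length(rises)) rises[m + 1L] else n
    # step 2: local minima adjacent to the edges, via the derivative
    wpk <- max(lo, ri - half):min(ri + half, fi)
    dpk <- wpk[which.max(ds[wpk])]
    j <- dpk
    while (j > lo && ds[j] > 0) j <- j - 1L
    jmin <- j
    wtr <- max(ri, fi - half):min(fi + half, hi)
    dtr <- wtr[which.min(ds[wtr])]
    j <- dtr
    while (j < hi && ds[j] < 0) j <- j + 1L
    jpost <- j
    # step 3: offset correction from the cycle's local excursion
    local_max <- max(xs[jmin:jpost])
    ic_level <- xs[jmin] + cfg$offset_frac * (local_max - xs[jmin])
    k <- jmin
    while (k < fi && x[k] <= ic_level) k <- k + 1L
    ic_idx[m] <- k
    se_level <- xs[jpost] + cfg$offset_frac * (local_max - xs[jpost])
    k <- jpost
    while (k > ri && x[k] <= se_level) k <- k - 1L
    se_idx[m] <- k
    min_pre[m] <- xs[jmin]
    min_post[m] <- xs[jpost]
  }
  keep <- ic_idx < se_idx
  gait_events(
    time = as.vector(rbind(t[ic_idx[keep]], t[se_idx[keep]])),
    kind = rep(c("IC", "SE"), sum(keep)),
    source = "pressure"
  )
}

#' Detect foot events in the electrostatic signal
#'
#' The induced current peaks when the foot-lift velocity is maximal --
#' right as the foot leaves the ground -- and dips most sharply as the
#' growing sole--ground contact collapses the body potential at heel
#' strike. The detector therefore smooths the trace with a short moving
#' average, extracts positive peaks (foot-off, SE) and negative troughs
#' (initial contact, IC) with a prominence of at least
#' `efs_min_prominence_frac` of the trace's peak-to-peak amplitude and a
#' mutual separation of `min_event_gap` within each kind, merges them in
#' time order, and enforces IC/SE alternation by dropping the
#' lower-prominence member of any same-kind adjacent pair (ties keep the
#' earlier event).
#'
#' With `detect_polarity = TRUE` the detector checks the cycle phase
#' structure: foot-off to the next contact spans the swing (about 40% of
#' the cycle), contact to the next foot-off the stance (about 60%), so if
#' the median peak-to-trough gap exceeds the trough-to-peak gap the
#' electrode polarity is deemed flipped and the labels are swapped.
#'
#' @param trace A [signal_trace()] on the `efs` channel.
#' @param cfg A [detector_config()].
#' @return A [gait_events()] tibble (source `"efs"`).
#' @export
detect_efs_events <- function(trace, cfg = detector_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace_channel(trace) != "efs") {
    abort("`trace` must be an efs-channel signal_trace")
  }
  fs <- trace_fs(trace)
  win <- max(1L, round(cfg$efs_smooth_window * fs))
  xs <- moving_average(trace$value, win)
  ptp <- diff(range(xs))
  flat <- !is.finite(ptp) || ptp <= 0 ||
    diff(range(trace$value)) == 0 ||
    ptp <= 1e-12 * max(1, max(abs(xs)))
  if (flat) {
    abort("EFS trace has no amplitude; cannot extract events",
      class = "efsgait_insufficient_signal"
    )
  }
  prom <- cfg$efs_min_prominence_frac * ptp
  dist <- max(1L, round(cfg$min_event_gap * fs))
  pk <- find_peaks(xs, prom, dist)
  tr <- find_peaks(-xs, prom, dist)
  ev <- bind_rows(
    mutate(pk, kind = "SE"),
    mutate(tr, kind = "IC")
  ) |> arrange(.data$index)
  if (nrow(ev) < 2L) {
    abort("fewer than 2 prominent extrema in the EFS trace",
      class = "efsgait_insufficient_signal"
    )
  }
  # enforce alternation: among adjacent same-kind events keep the more
  # prominent (ties: the earlier)
  repeat {
    same <- which(ev$kind[-1L] == ev$kind[-nrow(ev)])
    if (length(same) == 0L) break
    k <- same[1L]
    drop <- if (ev$prominence[k + 1L] > ev$prominence[k]) k else k + 1L
    ev <- ev[-drop, ]
  }
  if (isTRUE(cfg$detect_polarity) && nrow(ev) >= 4L) {
    gaps <- diff(ev$index)
    first_kind <- ev$kind[-nrow(ev)]
    se_to_ic <- median(gaps[first_kind == "SE"])
    ic_to_se <- median(gaps[first_kind == "IC"])
    if (is.finite(se_to_ic) && is.finite(ic_to_se) && se_to_ic > ic_to_se) {
      ev$kind <- ifelse(ev$kind == "SE", "IC", "SE")
    }
  }
  gait_events(trace$time[ev$index], ev$kind, source = "efs")
}
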