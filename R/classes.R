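#' Construct a signal trace
#'
#' A signal trace is a tibble with columns `time` (seconds) and `value`
#' (volts), uniformly sampled, carrying the channel name (`"efs"` or
#' `"pressure"`) and sampling rate as attributes. The EFS channel is the
#' voltage across the current-sampling resistor of the electrostatic
#' front end; the pressure channel is the FSR insole output, constrained to
#' 0--2.5 V.
#'
#' @param time Numeric vector of sample times in seconds (uniform grid).
#' @param value Numeric vector of sample values in volts.
#' @param channel `"efs"` or `"pressure"`.
#' @param fs Sampling rate in Hz; inferred from `time` when `NULL`.
#' @return A tibble of class `signal_trace` with columns `time`, `value`.
#' @export
#' @examples
#' tr <- signal_trace(seq(0, 1, by = 1e-3), sin(2 * pi * seq(0, 1, by = 1e-3)),
#'   channel = "efs"
#' )
#' trace_fs(tr)
signal_trace <- function(time, value, channel = c("efs", "pressure"),
                         fs = NULL) {
  channel <- match.arg(channel)
  if (length(time) != length(value)) {
    abort("`time` and `value` must have equal length")
  }
  if (anyNA(value) || any(!is.finite(value))) {
    abort("signal values must be finite")
  }
  if (is.null(fs)) {
    if (length(time) < 2L) abort("cannot infer `fs` from fewer than 2 samples")
    fs <- 1 / median(diff(time))
  }
  if (channel == "pressure" &&
    (any(value < -1e-9) || any(value > 2.5 + 1e-9))) {
    abort("pressure samples must lie within [0, 2.5] V")
  }
  out <- new_tibble(
    list(time = as.numeric(time), value = as.numeric(value)),
    nrow = length(time),
    class = "signal_trace"
  )
  attr(out, "channel") <- channel
  attr(out, "fs") <- fs
  out
}

#' @rdname signal_trace
#' @param x A `signal_trace`.
#' @export
trace_channel <- function(x) attr(x, "channel")

#' @rdname signal_trace
#' @export
trace_fs <- function(x) attr(x, "fs")

#' Construct a gait event sequence
#'
#' Gait events are the instants that segment the gait cycle: initial contact
#' (IC, heel strike) and the separate event (SE, foot-off). They are stored
#' as a tibble with columns `time` (seconds) and `kind` (`"IC"` or `"SE"`),
#' strictly increasing in time and strictly alternating in kind.
#'
#' @param time Numeric vector of event times in seconds.
#' @param kind Character vector of `"IC"` / `"SE"` labels, same length.
#' @param source Where the events came from: simulator ground truth
#'   (`"truth"`), the pressure detector, or the EFS detector.
#' @return A tibble of class `gait_events` with columns `time`, `kind`.
#' @export
#' @examples
#' gait_events(c(0, 0.6, 1.0), c("IC", "SE", "IC"))
gait_events <- function(time, kind, source = c("truth", "pressure", "efs")) {
  source <- match.arg(source)
  kind <- as.character(kind)
  if (length(time) != length(kind)) {
    abort("`time` and `kind` must have equal length")
  }
  if (!all(kind %in% c("IC", "SE"))) {
    abort("event `kind` must be \"IC\" or \"SE\"")
  }
  if (length(time) > 1L) {
    if (any(diff(time) <= 0)) {
      abort("event times must be strictly increasing")
    }
    if (any(kind[-1L] == kind[-length(kind)])) {
      abort("event kinds must strictly alternate (IC, SE, IC, ...)")
    }
  }
  out <- new_tibble(
    list(time = as.numeric(time), kind = kind),
    nrow = length(time),
    class = "gait_events"
  )
  attr(out, "source") <- source
  out
}

#' @rdname gait_events
#' @param x A `gait_events` object.
#' @export
events_source <- function(x) attr(x, "source")

# Subset a gait_events to one kind, returning times.
event_times <- function(x, kind) x$time[x$kind == kind]

# Keep tibble subsetting but preserve class/attributes where cheap to do so.
#' @export
`[.signal_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("time", "value") %in% names(out))) {
    attr(out, "channel") <- attr(x, "channel")
    attr(out, "fs") <- attr(x, "fs")
    class(out) <- class(x)
  }
  out
}
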