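# CSV interchange: signal traces (time_s,value_v) and event lists
# (time_s,kind). Times are serialized with full double precision so
# round-trips are lossless.

#' Read and write signal CSV files
#'
#' The signal dialect is a two-column CSV with header `time_s,value_v`,
#' uniformly sampled; the sampling rate is inferred from the median sample
#' interval and the grid is checked for uniformity (relative jitter below
#' `1e-6`).
#'
#' @param path File path.
#' @param channel Channel to tag the trace with on read.
#' @return `read_signal_csv()` returns a [signal_trace()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path, channel = c("efs", "pressure")) {
  channel <- match.arg(channel)
  df <- readr::read_csv(path,
    col_types = readr::cols(
      time_s = readr::col_double(), value_v = readr::col_double()
    )
  )
  if (!all(c("time_s", "value_v") %in% names(df))) {
    abort("signal CSV must have columns `time_s,value_v`",
      class = "efsgait_format_error"
    )
  }
  if (nrow(df) == 0L) {
    abort("signal CSV has no samples", class = "efsgait_format_error")
  }
  if (nrow(df) < 2L) {
    abort("signal CSV needs at least 2 samples to infer the rate",
      class = "efsgait_format_error"
    )
  }
  dt <- diff(df$time_s)
  med <- median(dt)
  if (med <= 0) {
    bad <- which(dt <= 0)[1L] + 1L
    abort(sprintf("non-increasing time at row %d", bad),
      class = "efsgait_format_error"
    )
  }
  jitter <- abs(dt - med) / med
  if (any(jitter > 1e-6)) {
    bad <- which(jitter > 1e-6)[1L] + 1L
    abort(sprintf("non-uniform sampling at row %d", bad),
      class = "efsgait_format_error"
    )
  }
  signal_trace(df$time_s, df$value_v, channel = channel, fs = 1 / med)
}

#' @rdname read_signal_csv
#' @param trace A [signal_trace()].
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  readr::write_csv(
    tibble(time_s = trace$time, value_v = trace$value),
    path
  )
  invisible(path)
}

#' Read and write gait-event CSV files
#'
#' The event dialect has columns `time_s,kind` with `kind` one of
#' `IC`/`SE`; ordering and alternation are validated on read.
#'
#' @param path File path.
#' @param source Source tag for the events on read.
#' @return `read_events_csv()` returns a [gait_events()];
#'   `write_events_csv()` returns `path` invisibly.
#' @export
read_events_csv <- function(path, source = c("truth", "pressure", "efs")) {
  source <- match.arg(source)
  df <- readr::read_csv(path,
    col_types = readr::cols(
      time_s = readr::col_double(), kind = readr::col_character()
    )
  )
  if (!all(c("time_s", "kind") %in% names(df))) {
    abort("events CSV must have columns `time_s,kind`",
      class = "efsgait_format_error"
    )
  }
  if (nrow(df) > 0L && !all(df$kind %in% c("IC", "SE"))) {
    abort(
      sprintf(
        "unknown event kind %s",
        paste(unique(setdiff(df$kind, c("IC", "SE"))), collapse = ", ")
      ),
      class = "efsgait_format_error"
    )
  }
  ev <- tryCatch(
    gait_events(df$time_s, df$kind, source = source),
    error = function(e) {
      abort(conditionMessage(e), class = "efsgait_format_error")
    }
  )
  ev
}

#' @rdname read_events_csv
#' @param events A [gait_events()].
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  readr::write_csv(tibble(time_s = events$time, kind = events$kind), path)
  invisible(path)
}

#' Trim the unsteady ends of a recording
#'
#' Walkers need an adjustment period before settling into a steady gait,
#' so the first and last seconds of each recording are discarded before
#' analysis (2 s at each end by default).
#'
#' @param x A [signal_trace()] or [gait_events()].
#' @param head,tail Durations removed from the start and end (s).
#' @param t_range For event sequences, the recording's `c(start, end)`
#'   times the trim is measured from; defaults to the event range.
#' @return The trimmed object; event times are never altered, only events
#'   inside the trimmed windows are dropped (for events sequences the
#'   result is additionally cut to start on the first IC and end on an IC
#'   so it stays alternating and analysis-ready).
#' @export
trim_recording <- function(x, head = 2, tail = 2, t_range = NULL) {
  UseMethod("trim_recording")
}

#' @export
trim_recording.signal_trace <- function(x, head = 2, tail = 2,
                                        t_range = NULL) {
  t0 <- min(x$time)
  t1 <- max(x$time)
  if (head + tail >= t1 - t0) {
    abort("trim windows longer than the recording")
  }
  keep <- x$time >= t0 + head & x$time <= t1 - tail
  signal_trace(x$time[keep], x$value[keep],
    channel = trace_channel(x), fs = trace_fs(x)
  )
}

#' @export
trim_recording.gait_events <- function(x, head = 2, tail = 2,
                                       t_range = NULL) {
  if (nrow(x) == 0L) {
    return(x)
  }
  t_range <- t_range %||% range(x$time)
  t0 <- t_range[1L]
  t1 <- t_range[2L]
  keep <- x$time >= t0 + head & x$time <= t1 - tail
  tt <- x$time[keep]
  kk <- x$kind[keep]
  # start at the first IC, end at the last IC
  first_ic <- match("IC", kk)
  if (is.na(first_ic)) {
    return(gait_events(numeric(), character(), source = events_source(x)))
  }
  last_ic <- max(which(kk == "IC"))
  idx <- first_ic:last_ic
  gait_events(tt[idx], kk[idx], source = events_source(x))
}
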