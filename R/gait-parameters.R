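#' Per-cycle temporal gait parameters
#'
#' For each consecutive pair of initial contacts `IC(m), IC(m+1)` with the
#' foot-off `SE(n)` between them, computes the gait cycle
#' `Tg = IC(m+1) - IC(m)`, stance duration `Ts = SE(n) - IC(m)`, swing
#' duration `Tw = IC(m+1) - SE(n) = Tg - Ts`, cadence
#' `C = (60 / Tg[s]) * 2` steps/min (two steps per cycle), and the stance
#' and swing ratios `RS = Ts/Tg`, `RW = Tw/Tg`. A leading SE before the
#' first IC and any events after the last IC are discarded; partial cycles
#' are never extrapolated.
#'
#' @param events A [gait_events()] sequence with at least 2 IC events.
#' @return A tibble of class `cycle_params` with one row per cycle and
#'   columns `cycle`, `ic_time` (s, cycle start), `tg_ms`, `ts_ms`,
#'   `tw_ms`, `cadence`, `rs`, `rw`. Fewer than 2 IC events yield an empty
#'   table with a warning.
#' @export
#' @examples
#' ev <- gait_events(c(0, 0.6, 1.0), c("IC", "SE", "IC"))
#' compute_cycle_params(ev)
compute_cycle_params <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  ic <- event_times(events, "IC")
  if (length(ic) < 2L) {
    warn("fewer than 2 IC events; no complete gait cycle")
    return(empty_cycle_params())
  }
  n <- length(ic) - 1L
  se_all <- event_times(events, "SE")
  tg <- ts <- numeric(n)
  for (m in seq_len(n)) {
    se <- se_all[se_all > ic[m] & se_all < ic[m + 1L]]
    if (length(se) != 1L) {
      abort(
        sprintf("cycle %d: expected exactly one SE between its IC events", m),
        class = "efsgait_inconsistent_events"
      )
    }
    tg[m] <- (ic[m + 1L] - ic[m]) * 1000
    ts[m] <- (se - ic[m]) * 1000
  }
  if (any(tg <= 0) || any(ts <= 0)) {
    abort(
      sprintf(
        "cycle %d: non-positive duration",
        which(tg <= 0 | ts <= 0)[1L]
      ),
      class = "efsgait_inconsistent_events"
    )
  }
  tw <- tg - ts
  out <- tibble(
    cycle = seq_len(n),
    ic_time = ic[seq_len(n)],
    tg_ms = tg,
    ts_ms = ts,
    tw_ms = tw,
    cadence = 120000 / tg,
    rs = ts / tg,
    rw = tw / tg
  )
  class(out) <- c("cycle_params", class(out))
  out
}

empty_cycle_params <- function() {
  out <- tibble(
    cycle = integer(), ic_time = numeric(), tg_ms = numeric(),
    ts_ms = numeric(), tw_ms = numeric(), cadence = numeric(),
    rs = numeric(), rw = numeric()
  )
  class(out) <- c("cycle_params", class(out))
  out
}

#' Summary statistics of a gait-parameter table
#'
#' Per-parameter arithmetic mean, sample (n-1) standard deviation, and
#' range, in long form. A single-cycle table reports `sd = 0` and is
#' flagged as degenerate.
#'
#' @param params A [compute_cycle_params()] table (non-empty).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `min`, `max`,
#'   `n` and attribute `degenerate_n` (TRUE when n = 1).
#' @export
#' @examples
#' ev <- gait_events(c(0, 0.6, 1.0, 1.55, 1.9), c("IC", "SE", "IC", "SE", "IC"))
#' summarize_params(compute_cycle_params(ev))
summarize_params <- function(params) {
  if (!is.data.frame(params) || nrow(params) == 0L) {
    abort("`params` must be a non-empty cycle-parameter table")
  }
  cols <- c("tg_ms", "ts_ms", "tw_ms", "cadence", "rs", "rw")
  cols <- intersect(cols, names(params))
  out <- params |>
    select(all_of(cols)) |>
    tidyr::pivot_longer(everything(),
      names_to = "parameter",
      values_to = "value"
    ) |>
    group_by(.data$parameter) |>
    summarise(
      mean = mean(.data$value),
      sd = if (n() > 1L) sd(.data$value) else 0,
      min = min(.data$value),
      max = max(.data$value),
      n = n(),
      .groups = "drop"
    ) |>
    mutate(parameter = factor(.data$parameter, levels = cols)) |>
    arrange(.data$parameter) |>
    mutate(parameter = as.character(.data$parameter))
  attr(out, "degenerate_n") <- nrow(params) == 1L
  out
}
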