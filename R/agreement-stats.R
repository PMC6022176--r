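#' Match detected events to a reference sequence
#'
#' Greedy nearest-neighbour pairing of same-kind events: candidate pairs
#' within `window` ms are accepted in order of increasing absolute time
#' difference, each event on either side used at most once.
#'
#' @param est,ref [gait_events()] sequences (estimated and reference).
#' @param kind `"IC"` or `"SE"`; only events of this kind are matched.
#' @param window Matching window (ms).
#' @return A tibble with columns `est_time`, `ref_time` (s) and `delta_ms`
#'   (signed, est - ref), plus attributes `n_unmatched_est` and
#'   `n_unmatched_ref`.
#' @export
#' @examples
#' truth <- gait_events(c(0, 0.6, 1.0), c("IC", "SE", "IC"))
#' est <- gait_events(c(0.01, 0.59, 1.02), c("IC", "SE", "IC"), source = "efs")
#' match_events(est, truth, kind = "IC")
match_events <- function(est, ref, kind = c("IC", "SE"), window = 100) {
  kind <- match.arg(kind)
  te <- event_times(est, kind)
  tr <- event_times(ref, kind)
  if (length(te) == 0L || length(tr) == 0L) {
    out <- tibble(
      est_time = numeric(), ref_time = numeric(),
      delta_ms = numeric()
    )
    attr(out, "n_unmatched_est") <- length(te)
    attr(out, "n_unmatched_ref") <- length(tr)
    return(out)
  }
  pairs <- tidyr::expand_grid(i = seq_along(te), j = seq_along(tr)) |>
    mutate(delta_ms = (te[.data$i] - tr[.data$j]) * 1000) |>
    filter(abs(.data$delta_ms) <= window) |>
    arrange(abs(.data$delta_ms), .data$i)
  used_e <- logical(length(te))
  used_r <- logical(length(tr))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    if (!used_e[i] && !used_r[j]) {
      keep[k] <- TRUE
      used_e[i] <- TRUE
      used_r[j] <- TRUE
    }
  }
  matched <- pairs[keep, ] |> arrange(.data$i)
  out <- tibble(
    est_time = te[matched$i],
    ref_time = tr[matched$j],
    delta_ms = matched$delta_ms
  )
  attr(out, "n_unmatched_est") <- sum(!used_e)
  attr(out, "n_unmatched_ref") <- sum(!used_r)
  out
}

#' Event-timing error statistics
#'
#' Mean, sample standard deviation and range of signed timing errors, with
#' a fixed-width histogram for error-distribution plots.
#'
#' @param deltas Numeric vector of signed errors (ms), or a
#'   [match_events()] result (its `delta_ms` column is used and the
#'   unmatched counts are carried over).
#' @param bin_width Histogram bin width (ms).
#' @param span Histogram half-range (ms); bins cover `[-span, span]`,
#'   widened if errors fall outside.
#' @return A list of class `event_error_stats` with elements `n_matched`,
#'   `n_unmatched`, `mean`, `sd`, `min`, `max`, `histogram` (tibble of bin
#'   edges and counts).
#' @export
#' @examples
#' error_stats(c(-3, 1, 2))
error_stats <- function(deltas, bin_width = 5, span = 50) {
  n_unmatched <- 0L
  if (is.data.frame(deltas)) {
    n_unmatched <- (attr(deltas, "n_unmatched_est") %||% 0L) +
      (attr(deltas, "n_unmatched_ref") %||% 0L)
    deltas <- deltas$delta_ms
  }
  n <- length(deltas)
  if (n == 0L) {
    out <- list(
      n_matched = 0L, n_unmatched = n_unmatched,
      mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
      histogram = tibble(lower = numeric(), upper = numeric(), count = integer())
    )
    class(out) <- "event_error_stats"
    return(out)
  }
  span <- max(span, ceiling(max(abs(deltas)) / bin_width) * bin_width)
  edges <- seq(-span, span, by = bin_width)
  counts <- as.integer(table(cut(deltas, edges, include.lowest = TRUE)))
  out <- list(
    n_matched = n,
    n_unmatched = n_unmatched,
    mean = mean(deltas),
    sd = if (n > 1L) sd(deltas) else 0,
    min = min(deltas),
    max = max(deltas),
    histogram = tibble(
      lower = edges[-length(edges)], upper = edges[-1L], count = counts
    )
  )
  class(out) <- "event_error_stats"
  out
}

#' @export
print.event_error_stats <- function(x, ...) {
  cat(sprintf(
    "<event_error_stats> n = %d matched (%d unmatched), %.2f +/- %.2f ms, range [%.1f, %.1f] ms\n",
    x$n_matched, x$n_unmatched, x$mean, x$sd, x$min, x$max
  ))
  invisible(x)
}

#' Gait-cycle estimation accuracy
#'
#' Per-cycle error of an estimated cycle-duration series against a
#' pairwise-corresponding reference, and the headline accuracy
#' `100 - mean(|percentage error|)`.
#'
#' @param est_tg,ref_tg Equal-length numeric vectors of cycle durations
#'   (ms), cycle-for-cycle corresponding.
#' @return A list of class `cycle_accuracy` with `errors` (tibble of
#'   per-cycle `error_ms` and `pct_error`) and `accuracy` (%).
#' @export
#' @examples
#' cycle_accuracy(c(970, 1010), c(1000, 1000))$accuracy
cycle_accuracy <- function(est_tg, ref_tg) {
  if (length(est_tg) != length(ref_tg)) {
    abort("`est_tg` and `ref_tg` must have equal length")
  }
  if (length(est_tg) == 0L) abort("no cycles to compare")
  err <- est_tg - ref_tg
  pct <- 100 * err / ref_tg
  out <- list(
    errors = tibble(
      cycle = seq_along(err), error_ms = err,
      pct_error = pct
    ),
    accuracy = 100 - mean(abs(pct)),
    n = length(err)
  )
  class(out) <- "cycle_accuracy"
  out
}

#' @export
print.cycle_accuracy <- function(x, ...) {
  cat(sprintf(
    "<cycle_accuracy> n = %d cycles, error %.2f +/- %.2f ms, accuracy %.2f%%\n",
    x$n, mean(x$errors$error_ms),
    if (x$n > 1) sd(x$errors$error_ms) else 0, x$accuracy
  ))
  invisible(x)
}

grade_pearson <- function(r) {
  if (r > 0.90) "excellent" else if (r >= 0.80) "good" else if (r >= 0.70) "fair" else "poor"
}

grade_icc <- function(icc) {
  if (icc > 0.90) "excellent" else if (icc >= 0.75) "good" else if (icc >= 0.50) "moderate" else "poor"
}

#' Pearson correlation with qualitative grading
#'
#' Product-moment correlation between two measurement series, the
#' two-sided p-value from the t transform with n - 2 degrees of freedom,
#' and the conventional qualitative grade: excellent (r > 0.90), good
#' (0.80--0.89), fair (0.70--0.79), poor (< 0.70).
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return A list of class `gait_pearson` with `r`, `p`, `grade`, `n`.
#' @export
#' @examples
#' pearson_agreement(1:10, 2 * (1:10) + 1)
pearson_agreement <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for zero-variance input",
      class = "efsgait_undefined_correlation"
    )
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tv), df = n - 2)
  }
  out <- list(r = r, p = p, grade = grade_pearson(r), n = n)
  class(out) <- "gait_pearson"
  out
}

#' @export
print.gait_pearson <- function(x, ...) {
  cat(sprintf(
    "<gait_pearson> r = %.4f (p = %.3g, n = %d): %s\n",
    x$r, x$p, x$n, x$grade
  ))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measures, absolute-agreement intraclass correlation under the
#' two-way random-effects model (Shrout--Fleiss ICC(2,1)), used for
#' test-retest reliability across sessions. From the two-way ANOVA mean
#' squares (rows = subjects, columns = sessions),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' Significance is assessed by the F test `MSR/MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom. Grades: excellent (> 0.90),
#' good (0.75--0.90), moderate (0.50--0.75), poor (< 0.50).
#'
#' @param data Numeric matrix or data frame, `n` subjects by `k >= 2`
#'   sessions, no missing cells.
#' @return A list of class `gait_icc` with `icc`, `p`, `grade`, `n`, `k`
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
#' @examples
#' icc_2_1(cbind(c(1, 2, 3), c(1.1, 2.2, 2.9)))
icc_2_1 <- function(data) {
  m <- as.matrix(data)
  if (anyNA(m)) abort("no missing cells allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 sessions")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) {
    abort("ICC undefined: no variance in the data",
      class = "efsgait_undefined_icc"
    )
  }
  icc <- (msr - mse) / denom
  p <- if (mse == 0) {
    if (msr == 0) {
      abort("ICC undefined: zero between- and within-subject variance",
        class = "efsgait_undefined_icc"
      )
    }
    0
  } else {
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  out <- list(
    icc = icc, p = p, grade = grade_icc(icc), n = n, k = k,
    msr = msr, msc = msc, mse = mse
  )
  class(out) <- "gait_icc"
  out
}

#' @export
print.gait_icc <- function(x, ...) {
  cat(sprintf(
    "<gait_icc> ICC(2,1) = %.4f (p = %.3g, n = %d, k = %d): %s\n",
    x$icc, x$p, x$n, x$k, x$grade
  ))
  invisible(x)
}

#' Combined concurrent-validity report
#'
#' Bundles the Pearson correlation between two paired measurement series
#' with an optional ICC(2,1) reliability matrix into one report.
#'
#' @param x,y Paired measurements of the same quantity by two methods.
#' @param sessions Optional subjects-by-sessions matrix for test-retest
#'   reliability.
#' @return A list of class `agreement_report` with elements `pearson` and
#'   (optionally) `icc`.
#' @export
agreement_report <- function(x, y, sessions = NULL) {
  out <- list(pearson = pearson_agreement(x, y))
  if (!is.null(sessions)) out$icc <- icc_2_1(sessions)
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$pearson)
  if (!is.null(x$icc)) print(x$icc)
  invisible(x)
}
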