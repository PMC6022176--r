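# broom-style tidiers for the statistics objects.

#' @export
tidy.gait_pearson <- function(x, ...) {
  tibble(
    estimate = x$r, p.value = x$p, grade = x$grade, n = x$n,
    method = "Pearson product-moment correlation"
  )
}

#' @export
glance.gait_pearson <- function(x, ...) tidy(x)

#' @export
tidy.gait_icc <- function(x, ...) {
  tibble(
    estimate = x$icc, p.value = x$p, grade = x$grade,
    n = x$n, k = x$k, msr = x$msr, msc = x$msc, mse = x$mse,
    method = "ICC(2,1) two-way random, single measures, absolute agreement"
  )
}

#' @export
glance.gait_icc <- function(x, ...) {
  tibble(estimate = x$icc, p.value = x$p, grade = x$grade, n = x$n, k = x$k)
}

#' @export
tidy.event_error_stats <- function(x, ...) {
  tibble(
    n_matched = x$n_matched, n_unmatched = x$n_unmatched,
    mean = x$mean, sd = x$sd, min = x$min, max = x$max
  )
}

#' @export
tidy.cycle_accuracy <- function(x, ...) x$errors

#' @export
glance.cycle_accuracy <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, n = x$n,
    mean_error_ms = mean(x$errors$error_ms),
    sd_error_ms = if (x$n > 1) sd(x$errors$error_ms) else 0
  )
}

#' @export
tidy.agreement_report <- function(x, ...) {
  out <- mutate(tidy(x$pearson), statistic = "pearson_r", .before = 1)
  if (!is.null(x$icc)) {
    out <- bind_rows(
      out,
      mutate(glance(x$icc), statistic = "icc_2_1", .before = 1)
    )
  }
  out
}
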