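# Internal numeric helpers shared by the simulator and the detectors.

# Centered moving average with edge shrinkage (window truncated at the ends so
# the filter stays zero-phase everywhere). `width` is in samples and is forced
# odd.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 3L) {
    return(x)
  }
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Central-difference derivative (one-sided at the ends); `fs` converts sample
# differences to per-second rates.
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2L) {
    abort("need at least 2 samples to differentiate")
  }
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (x[i + 1L] - x[i - 1L]) * fs / 2
  }
  d
}

# Local maxima of a series with a prominence floor and a minimum mutual
# separation (in samples). Prominence follows the usual topographic
# definition: height above the higher of the two minima separating the peak
# from the nearest higher terrain on each side. Peaks are kept greedily in
# order of decreasing prominence (ties: earlier peak wins).
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  dx <- diff(x)
  # rising-then-falling sign change, with plateaus resolved to their first
  # sample
  sgn <- sign(dx)
  nz <- sgn != 0
  idx <- which(nz)
  if (length(idx) < 2L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  peaks <- integer()
  for (k in seq_len(length(idx) - 1L)) {
    if (sgn[idx[k]] > 0 && sgn[idx[k + 1L]] < 0) {
      peaks <- c(peaks, idx[k] + 1L)
    }
  }
  if (length(peaks) == 0L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  prom <- vapply(peaks, function(p) {
    v <- x[p]
    # walk left to the nearest strictly higher sample, tracking the minimum
    left <- if (p > 1L) x[seq_len(p - 1L)] else numeric()
    higher_l <- which(left > v)
    min_l <- if (length(higher_l)) {
      min(left[(max(higher_l)):(p - 1L)])
    } else if (length(left)) {
      min(left)
    } else {
      v
    }
    right <- if (p < n) x[(p + 1L):n] else numeric()
    higher_r <- which(right > v)
    min_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r))])
    } else if (length(right)) {
      min(right)
    } else {
      v
    }
    v - max(min_l, min_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) == 0L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  # enforce minimum separation, strongest (then earliest) first
  ord <- order(-prom, peaks)
  sel <- logical(length(peaks))
  taken <- integer()
  for (k in ord) {
    if (all(abs(peaks[k] - taken) >= min_distance)) {
      sel[k] <- TRUE
      taken <- c(taken, peaks[k])
    }
  }
  out <- tibble(
    index = peaks[sel], value = x[peaks[sel]], prominence = prom[sel]
  )
  arrange(out, .data$index)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
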