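# Shared fixtures: all built in code at test time.

# Deterministic schedule: cycles of exactly tg_ms with a fixed stance
# fraction, so event times are known in closed form.
zero_variance_schedule <- function(n_cycles = 3, tg_ms = 1000, stance = 0.6) {
  sample_event_schedule(
    pace_profile("normal",
      tg_mean = tg_ms, tg_sd = 0,
      stance_fraction_mean = stance, stance_fraction_sd = 0
    ),
    n_cycles = n_cycles, seed = 1
  )
}

# Noise-free front end (keeps the I-V gain, filtering and decimation).
quiet_front_end <- function(...) {
  front_end_config(noise_sd = 0, mains_amp = 0, ...)
}

# Mean of a normal truncated to [lo, hi], by numerical integration -- the
# independent oracle for the sampler's moments.
truncnorm_mean <- function(mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi)$value / z
}

# ICC(2,1) from mean squares obtained via stats::aov -- an independent
# route to the ANOVA decomposition.
icc21_aov_oracle <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    sess = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
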