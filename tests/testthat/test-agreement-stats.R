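test_that("event matching pairs identical and shifted sequences exactly", {
  truth <- zero_variance_schedule(4)
  m <- match_events(truth, truth, "IC")
  expect_equal(m$delta_ms, rep(0, 5))
  expect_equal(attr(m, "n_unmatched_est"), 0L)
  shifted <- gait_events(truth$time + 0.010, truth$kind, source = "efs")
  m2 <- match_events(shifted, truth, "IC")
  expect_equal(m2$delta_ms, rep(10, 5), tolerance = 1e-9)
})

test_that("a missing event leaves exactly one reference unmatched", {
  ref <- gait_events(
    c(0, 0.6, 1.0, 1.6, 2.0), c("IC", "SE", "IC", "SE", "IC")
  )
  est <- gait_events(c(0.01, 0.61, 2.01), c("IC", "SE", "IC"),
    source = "efs"
  )
  m <- match_events(est, ref, "IC")
  expect_equal(nrow(m), 2)
  expect_equal(attr(m, "n_unmatched_ref"), 1L)
  expect_equal(attr(m, "n_unmatched_est"), 0L)
  # empty inputs give empty deltas, no error
  empty <- gait_events(numeric(), character(), source = "efs")
  expect_equal(nrow(match_events(empty, ref, "IC")), 0)
})

test_that("matching respects the window and pairs nearest neighbours first", {
  ref <- gait_events(c(1.0), c("IC"))
  est <- gait_events(c(0.95, 1.02), c("IC", "SE"), source = "efs")
  m <- match_events(est, ref, "IC", window = 100)
  expect_equal(m$delta_ms, -50)
  expect_equal(nrow(match_events(est, ref, "IC", window = 30)), 0)
})

test_that("error statistics match hand computation", {
  s <- error_stats(c(-3, 1, 2))
  expect_equal(s$mean, 0)
  expect_equal(s$sd, sqrt(7))
  expect_equal(round(s$sd, 4), 2.6458)
  expect_equal(c(s$min, s$max), c(-3, 2))
  expect_equal(sum(s$histogram$count), s$n_matched)
  z <- error_stats(rep(0, 10))
  expect_equal(c(z$mean, z$sd), c(0, 0))
  d <- error_stats(numeric())
  expect_equal(d$n_matched, 0L)
  expect_true(is.na(d$mean))
})

test_that("matched deltas never exceed the matching window", {
  sched <- sample_event_schedule(pace_profile("normal"), 50, seed = 31)
  ev <- detect_efs_events(simulate_efs(sched, seed = 32))
  m <- match_events(ev, sched, "SE", window = 100)
  s <- error_stats(m)
  expect_lte(max(abs(m$delta_ms)), 100)
  expect_true(s$min <= s$mean && s$mean <= s$max)
})

test_that("cycle accuracy follows its defining formula", {
  expect_equal(cycle_accuracy(c(1000), c(1000))$accuracy, 100)
  ca <- cycle_accuracy(c(970), c(1000))
  expect_equal(ca$errors$pct_error, -3)
  expect_equal(ca$accuracy, 97)
  expect_error(cycle_accuracy(1:3, 1:2), "equal length")
  # accuracy is 100 only for elementwise equality, and never above 100
  set.seed(1)
  est <- 1000 + rnorm(50, 0, 10)
  ref <- 1000 + rnorm(50, 0, 10)
  acc <- cycle_accuracy(est, ref)$accuracy
  expect_lt(acc, 100)
})

test_that("pearson agreement matches its defining formula and cor.test", {
  x <- 1:10
  expect_equal(pearson_agreement(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_agreement(x, 2 * x + 1)$grade, "excellent")
  p <- pearson_agreement(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(p$r, 0.6)
  expect_equal(p$grade, "poor")
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- 0.5 * a + rnorm(30)
    got <- pearson_agreement(a, b)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    ct <- stats::cor.test(a, b)
    expect_equal(got$p, ct$p.value, tolerance = 1e-9)
    # symmetry and affine invariance
    expect_equal(pearson_agreement(b, a)$r, got$r)
    expect_equal(pearson_agreement(3 * a + 2, b)$r, got$r, tolerance = 1e-12)
  }
  expect_error(pearson_agreement(rep(1, 5), 1:5),
    class = "efsgait_undefined_correlation"
  )
  expect_error(pearson_agreement(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) is exact on perfect agreement and penalizes session effects", {
  perfect <- cbind(c(1, 2, 3), c(1, 2, 3))
  r <- icc_2_1(perfect)
  expect_equal(r$icc, 1)
  expect_equal(r$grade, "excellent")
  # a systematic session effect caps the absolute-agreement ICC below 1
  m <- cbind(c(1, 2, 3), c(2, 4, 6))
  got <- icc_2_1(m)
  expect_lt(got$icc, 1)
  # explicit-sums oracle on this 3 x 2 matrix
  expect_equal(got$icc, icc21_aov_oracle(m), tolerance = 1e-12)
})

test_that("ICC(2,1) equals the ANOVA oracle and obeys its invariances", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rnorm(20, mean = 5), nrow = 10, ncol = 2)
    got <- icc_2_1(m)
    expect_equal(got$icc, icc21_aov_oracle(m), tolerance = 1e-10)
    expect_lte(got$icc, 1)
    # invariant to adding a constant to all cells
    expect_equal(icc_2_1(m + 3.21)$icc, got$icc, tolerance = 1e-9)
  }
  expect_error(icc_2_1(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(icc_2_1(matrix(1, 2, 2)), class = "efsgait_undefined_icc")
})

test_that("tidiers return one-row tibbles with grades", {
  p <- pearson_agreement(1:10, (1:10) + rnorm(10, 0, 0.1))
  tp <- tidy(p)
  expect_s3_class(tp, "tbl_df")
  expect_named(tp, c("estimate", "p.value", "grade", "n", "method"))
  r <- icc_2_1(matrix(rnorm(20), 10, 2))
  expect_equal(glance(r)$estimate, r$icc)
  rep <- agreement_report(1:10, (1:10) * 1.01, sessions = matrix(rnorm(20), 10, 2))
  tr <- tidy(rep)
  expect_equal(tr$statistic, c("pearson_r", "icc_2_1"))
})
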