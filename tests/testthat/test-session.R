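# Session orchestration: pre/post deltas, cohort comparisons, and the
# dose-response regression.

test_that("deltas vanish without habituation or treatment and track injected effects", {
  s0 <- simulate_session(habituation = 0, habituation_sd = 0, effect = 0,
                         session_sd = 0, seed = 21)
  r0 <- run_session(s0)
  expect_lt(abs(r0$delta), 0.02)

  sh <- simulate_session(habituation = -0.06, habituation_sd = 0, effect = 0,
                         session_sd = 0, seed = 22)
  rh <- run_session(sh)
  expect_lt(abs(rh$delta + 0.06), 0.02)

  st <- simulate_session(habituation = -0.06, habituation_sd = 0,
                         effect = 0.08, session_sd = 0, seed = 23)
  rt <- run_session(st)
  expect_lt(abs(rt$delta - 0.02), 0.02)
})

test_that("delta is antisymmetric and recomputable from stored pre/post", {
  s <- simulate_session(habituation = -0.05, seed = 31)
  r <- run_session(s)
  expect_equal(r$delta, r$post - r$pre)
  # reversing the roles of the phases flips the sign
  s_rev <- s
  s_rev$pre <- s$post
  s_rev$post <- s$pre
  r_rev <- run_session(s_rev)
  expect_equal(r_rev$delta, -r$delta, tolerance = 1e-9)
})

test_that("the pooled t statistic matches stats::t.test and the summary formula", {
  set.seed(5)
  df <- data.frame(measure = "gain",
                   treatment = rep(c("saline", "drug_systemic"), c(10, 15)),
                   delta = c(rnorm(10, -0.06, 0.06), rnorm(15, 0.019, 0.076)),
                   pre = NA, post = NA)
  cmp <- compare_groups(df, "gain", grouping = "treatment")
  ref <- stats::t.test(delta ~ treatment, df, var.equal = TRUE)
  expect_equal(abs(cmp$t), abs(unname(ref$statistic)), tolerance = 1e-10)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-10)

  # summary-statistic route agrees with the per-observation route
  x1 <- df$delta[df$treatment == "saline"]
  x2 <- df$delta[df$treatment == "drug_systemic"]
  ts <- t_from_summary(mean(x1), sd(x1), 10, mean(x2), sd(x2), 15)
  expect_equal(ts$t, cmp$t, tolerance = 1e-12)
  expect_equal(ts$p, cmp$p, tolerance = 1e-12)
})

test_that("group comparison agrees with a permutation reference on small samples", {
  set.seed(9)
  df <- data.frame(measure = "gain",
                   treatment = rep(c("a", "b"), each = 6),
                   delta = c(rnorm(6, 0, 0.05), rnorm(6, 0.09, 0.05)),
                   pre = NA, post = NA)
  cmp <- compare_groups(df, "gain", grouping = "treatment")
  obs <- abs(diff(tapply(df$delta, df$treatment, mean)))
  perm <- replicate(2000, {
    sh <- sample(df$treatment)
    abs(diff(tapply(df$delta, sh, mean)))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(cmp$p - p_perm), 0.1)
  expect_equal(cmp$p < 0.05, p_perm < 0.05)
})

test_that("degenerate variance is reported, not fatal", {
  df <- data.frame(measure = "gain", treatment = rep(c("a", "b"), each = 3),
                   delta = rep(0.1, 6), pre = NA, post = NA)
  cmp <- compare_groups(df, "gain", grouping = "treatment")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)

  # paired test with a constant shift
  dfp <- data.frame(measure = "gain", treatment = "saline",
                    pre = c(0.5, 0.6, 0.7), post = c(0.55, 0.65, 0.75),
                    delta = 0.05)
  cmpp <- compare_groups(dfp, "gain", test = "paired")
  expect_true(cmpp$degenerate)
  expect_equal(cmpp$p, 0)
})

test_that("dose-response regression is exact on an exact line and guards degeneracy", {
  df <- data.frame(measure = "resting_v",
                   injection_volume = c(10, 100, 300, 600, 900),
                   delta = 0.001 * c(10, 100, 300, 600, 900) - 1)
  # summary.lm warns about the perfect fit; that is the point of the case
  dr <- suppressWarnings(dose_response(df))
  expect_equal(dr$slope, 0.001, tolerance = 1e-12)
  expect_equal(dr$r_squared, 1, tolerance = 1e-12)

  df_bad <- df
  df_bad$injection_volume <- 300
  expect_error(dose_response(df_bad), "degenerate")
  expect_error(dose_response(df[1:2, ]), ">= 3 sessions")
})

test_that("the saline reference band is the control mean +/- 2 SD", {
  set.seed(3)
  ctrl <- data.frame(measure = "resting_v", injection_volume = NA,
                     delta = rnorm(20, -1, 2))
  inj <- data.frame(measure = "resting_v",
                    injection_volume = c(10, 200, 500, 900),
                    delta = c(-1, 0, 1, 2.5))
  dr <- dose_response(inj, controls = ctrl)
  expect_equal(dr$reference_band$mean, mean(ctrl$delta))
  expect_equal(dr$reference_band$upper - dr$reference_band$mean,
               2 * sd(ctrl$delta))
})

test_that("session pipelines are deterministic for identical inputs", {
  s1 <- run_session(simulate_session(seed = 77))
  s2 <- run_session(simulate_session(seed = 77))
  expect_identical(s1, s2)
})
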