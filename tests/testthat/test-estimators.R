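test_that("OLS recovers the generating line exactly from noiseless triples", {
  fr <- noiseless_frame(50, b = 0.65, c = -0.15)
  fit <- suppressWarnings(fit_sensitivity(fr))
  expect_equal(fit$slope, -0.15, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.65, tolerance = 1e-10)
  expect_equal(fit$n, 200)
  # scoped fits partition the frame
  fp <- suppressWarnings(fit_sensitivity(fr, "positive"))
  fn <- suppressWarnings(fit_sensitivity(fr, "negative"))
  expect_equal(fp$n + fn$n, fit$n)
  expect_equal(fp$slope, -0.15, tolerance = 1e-10)
  expect_equal(fn$intercept, 0.65, tolerance = 1e-10)
})

test_that("zero-sensitivity responses give a zero line", {
  fr <- noiseless_frame(30, b = 0, c = 0)
  fit <- suppressWarnings(fit_sensitivity(fr))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
})

test_that("fit errors are informative", {
  fr <- noiseless_frame(2)
  expect_error(fit_sensitivity(fr[1:2, ]), "at least 3")
  df <- as.data.frame(noiseless_frame(3))
  df$a_t <- 50
  df$f_t <- df$a_t + df$sign * df$delta_t
  df$a_next <- df$a_t + 0.5 * (df$f_t - df$a_t)
  expect_error(fit_sensitivity(sample_frame(df)), "variance")
})

test_that("mixed-model slope equals OLS when between-participant variance is zero", {
  fr <- noiseless_frame(60, b = 0.6, c = -0.1)
  ols <- suppressWarnings(fit_sensitivity(fr))
  mix <- suppressWarnings(fit_sensitivity_mixed(fr))
  expect_lt(abs(ols$slope - mix$slope), 1e-6)
  expect_true(is.na(mix$p_slope))
  expect_equal(mix$method, "lmer")
})

test_that("mixed model needs at least three time steps", {
  fr <- noiseless_frame(20)
  expect_error(fit_sensitivity_mixed(subset_frame(fr, timesteps = 1:2)),
               "not applicable")
})

test_that("mixed model recovers the slope under participant heterogeneity", {
  co <- simulate_cohort(recovery_config(n = 1500, c = -0.12,
                                        participant_sd = 0.1), seed = 5)
  fr <- cohort_frame(co)
  ols <- fit_sensitivity(fr)
  mix <- fit_sensitivity_mixed(fr)
  expect_lt(abs(mix$slope - (-0.12)), 0.03)
  # pooled and mixed slopes are close (clustering has a weak effect)
  expect_lt(abs(mix$slope - ols$slope), 0.02)
})

test_that("total bias is the normalized net change over complete series", {
  expect_equal(total_bias(tiny_frame()), 2.0)
  # everyone ends where they started
  fr <- tiny_frame()
  fr$a_next[4] <- 50
  expect_equal(total_bias(fr), 0)
  # incomplete series are refused, naming the offender
  co <- simulate_cohort(cohort_config(n_participants = 10), seed = 1)
  fr <- sample_frame(co$triples, co$participants)
  expect_error(total_bias(fr[-2, ]), "participant")
})

test_that("enhancement bias follows the fitted asymmetry", {
  fr <- noiseless_frame(40)
  fit <- suppressWarnings(fit_sensitivity(fr, "positive"))
  fit_n <- fit
  fit_n$scope <- "negative"
  expect_equal(enhancement_bias(fr, fit, fit_n), 0)
  # direct arithmetic: cp-cn = 0.2, bp-bn = -0.1, mean a_t = 50
  df <- as.data.frame(noiseless_frame(10))
  df$a_t <- rep(c(40, 60), 20)
  fp <- structure(list(slope = 0.1, intercept = 0.3, scope = "positive"),
                  class = "sensitivity_fit")
  fn <- structure(list(slope = -0.1, intercept = 0.4, scope = "negative"),
                  class = "sensitivity_fit")
  expect_equal(enhancement_bias(sample_frame(df), fp, fn), 0)
})

test_that("theoretical sensitivity bias matches the model-core prediction", {
  # single triple: a=50, delta=13, c_m=-0.1, b_m=0.55 -> 0.65
  df <- data.frame(participant_id = 1L, t = 1L, a_t = 50, f_t = 63,
                   a_next = 56, delta_t = 13, sign = 1L)
  fp <- structure(list(slope = -0.1, intercept = 0.55, scope = "positive"),
                  class = "sensitivity_fit")
  fn <- structure(list(slope = -0.1, intercept = 0.55, scope = "negative"),
                  class = "sensitivity_fit")
  expect_equal(sensitivity_bias_theoretical(sample_frame(df), fp, fn), 0.65)
  # c_m = 0 gives 0
  f0 <- structure(list(slope = 0, intercept = 0.55, scope = "positive"),
                  class = "sensitivity_fit")
  f0n <- f0; f0n$scope <- "negative"
  expect_equal(sensitivity_bias_theoretical(sample_frame(df), f0, f0n), 0)

  # cross-module consistency: per-triple mean of avg_pair_bias * 100/delta
  fr <- noiseless_frame(60, b = 0.7, c = -0.2)
  fitp <- suppressWarnings(fit_sensitivity(fr, "positive"))
  fitn <- suppressWarnings(fit_sensitivity(fr, "negative"))
  sp <- sensitivity_bias_theoretical(fr, fitp, fitn)
  hp <- fit_curve(fitp)
  hn <- fit_curve(fitn)
  oracle <- mean(vapply(seq_len(nrow(fr)), function(i) {
    avg_pair_bias(fr$a_t[i], hp, hn, fr$delta_t[i])$raw * 100 / fr$delta_t[i]
  }, numeric(1)))
  expect_equal(sp, oracle, tolerance = 1e-10)
})

test_that("the decomposition ties the four measures together", {
  # exact intensities (no +/-1 jitter): the only S vs S" discrepancy left
  # is the higher-order trajectory effect, which must be small at
  # delta = 13 and shrink as delta is reduced
  fr <- noiseless_frame(200, b = 0.7, c = -0.2, jitter = 0)
  est <- suppressWarnings(decompose_bias(fr))
  expect_equal(est$S_measured, est$B - est$E)
  expect_equal(est$units, "percent of delta")
  # symmetric noiseless generation: E = 0 (fits are exact), S ~ S",
  # both positive; agreement within 15% relative at delta = 13
  expect_lt(abs(est$E), 1e-8)
  expect_gt(est$S_measured, 0)
  expect_gt(est$S_theoretical, 0)
  expect_lt(abs(est$S_measured - est$S_theoretical),
            0.15 * est$S_theoretical)
  fr_small <- noiseless_frame(200, b = 0.7, c = -0.2, delta = 6.5,
                              jitter = 0)
  est_small <- suppressWarnings(decompose_bias(fr_small))
  rel <- function(e) abs(e$S_measured - e$S_theoretical) / e$S_theoretical
  expect_lt(rel(est_small), rel(est))
  # constant equal curves (exact intensities): everything 0
  fr0 <- noiseless_frame(40, b = 0.5, c = 0, jitter = 0)
  est0 <- suppressWarnings(decompose_bias(fr0))
  expect_equal(est0$B, 0, tolerance = 1e-10)
  expect_equal(est0$E, 0, tolerance = 1e-10)
  expect_equal(est0$S_measured, 0, tolerance = 1e-10)
  expect_equal(est0$S_theoretical, 0, tolerance = 1e-10)
})

test_that("slope sign is recovered reliably at the design sample size", {
  # |c| >= 0.1 with ~1100 triples: fitted slope negative and significant
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(recovery_config(n = 280, c = -0.12), seed = s)
    fit <- fit_sensitivity(cohort_frame(co))
    fit$slope < 0 && fit$p_slope < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
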