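test_that("sensitivity curves evaluate, clip and reject out-of-domain input", {
  h <- linear_curve(0.65, -0.15)
  expect_equal(eval_sensitivity(h, 50), 0.575)
  expect_equal(eval_sensitivity(h, 0), 0.65)
  expect_equal(eval_sensitivity(h, c(0, 50, 100)), c(0.65, 0.575, 0.5))
  expect_equal(eval_sensitivity(linear_curve(0.5, -2, clip = TRUE), 100), 0)
  expect_equal(eval_sensitivity(linear_curve(0.5, -2, clip = FALSE), 100), -1.5)
  expect_error(eval_sensitivity(h, 101), "0, 100")
  expect_error(eval_sensitivity(h, -1), "0, 100")
  # decreasing on the unclipped region when c < 0
  a <- seq(0, 100, by = 5)
  expect_true(all(diff(eval_sensitivity(h, a)) < 0))
})

test_that("curves serialize to and from plain key-value lists", {
  for (cv in list(linear_curve(0.6, -0.1, clip = TRUE), constant_curve(0.4),
                  logistic_curve(0.1, 0.9, 0.4, 5))) {
    back <- curve_from_list(as.list(cv))
    expect_equal(back, cv)
  }
  expect_error(curve_from_list(list(family = "spline")), "unknown")
})

test_that("mean_curve averages linear curves coefficient-wise", {
  hm <- mean_curve(linear_curve(0.7, -0.2), linear_curve(0.6, -0.1))
  expect_equal(hm$b, 0.65)
  expect_equal(hm$c, -0.15)
  # mixture fallback agrees pointwise for non-linear members
  mix <- mean_curve(logistic_curve(0.2, 0.8, 0.5, 6), linear_curve(0.6, -0.1))
  a <- c(10, 50, 90)
  expect_equal(eval_sensitivity(mix, a),
               (eval_sensitivity(logistic_curve(0.2, 0.8, 0.5, 6), a) +
                  eval_sensitivity(linear_curve(0.6, -0.1), a)) / 2)
})

test_that("apply_feedback moves a fraction of the gap and stays bounded", {
  expect_equal(apply_feedback(50, 63, 0.5), 56.5)
  expect_equal(apply_feedback(50, 63, 0), 50)
  expect_equal(apply_feedback(50, 37, 1), 37)
  expect_error(apply_feedback(50, 63, 1.2), "\\[0, 1\\]")
  set.seed(4)
  a <- runif(500, 1, 100)
  f <- a + sample(c(-1, 1), 500, TRUE) * runif(500, 1, 14)
  h <- runif(500)
  out <- apply_feedback(a, f, h)
  expect_true(all(out >= pmin(a, f) & out <= pmax(a, f)))
})

test_that("pair bias: exact and first-order agree exactly for linear curves", {
  cv <- linear_curve(0.8, -0.4)
  expect_equal(pair_bias_exact(50, cv, 13, "+-")$raw, 0.4056)
  expect_equal(pair_bias_exact(50, cv, 13, "-+")$raw, 0.4056)
  expect_equal(pair_bias_first_order(50, cv, 13)$raw, 0.4056)
  expect_equal(pair_bias_exact(50, linear_curve(0.6, 0), 13, "+-")$raw, 0)
  # exactness across random linear curves and both orders (regimes where
  # the bias itself is not vanishingly small relative to the updates)
  set.seed(11)
  for (k in 1:25) {
    b <- runif(1, 0.5, 0.9); c <- runif(1, -0.4, -0.1)
    a1 <- runif(1, 30, 70); delta <- runif(1, 5, 14)
    cv <- linear_curve(b, c)
    if (eval_sensitivity(cv, min(100, a1 + delta)) < 0.05) next
    fo <- pair_bias_first_order(a1, cv, delta)$raw
    for (ord in c("+-", "-+")) {
      ex <- pair_bias_exact(a1, cv, delta, ord)$raw
      expect_gt(ex, 0)
      expect_lt(abs(ex - fo), 1e-12 * abs(ex))
    }
  }
})

test_that("bias predictions carry coherent units", {
  p <- pair_bias_exact(50, linear_curve(0.8, -0.4), 13, "+-")
  expect_equal(p$percent, 100 * p$fraction)
  expect_equal(p$fraction, p$raw / 13)
})

test_that("first-order error is O(delta^3) for a logistic curve", {
  cv <- logistic_curve(0.2, 0.8, 0.5, 6)
  # away from the inflection point, where the cubic term does not vanish
  d <- function(delta) {
    abs(pair_bias_exact(65, cv, delta, "+-")$raw -
          pair_bias_first_order(65, cv, delta)$raw)
  }
  ratio <- d(8) / d(4)
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)
})

test_that("invalid curve trajectories are rejected", {
  # sensitivity goes negative along the way
  expect_error(pair_bias_exact(95, linear_curve(0.1, -0.11), 13, "+-"),
               "negative")
})

test_that("enhancement_at measures the reaction asymmetry", {
  e <- enhancement_at(50, linear_curve(0.7, -0.2), linear_curve(0.6, -0.2), 13)
  expect_equal(e$fraction, 0.1)
  expect_equal(e$raw, 1.3)
  same <- linear_curve(0.5, -0.3)
  for (a in c(10, 50, 90)) {
    expect_equal(enhancement_at(a, same, same, 13)$raw, 0)
  }
  # curves crossing at a = 50
  e <- enhancement_at(50, linear_curve(0.5, 0.2), linear_curve(0.6, 0), 13)
  expect_equal(e$fraction, 0)
})

test_that("avg_pair_bias matches the order-averaged cross terms", {
  hp <- linear_curve(0.7, -0.25)
  hn <- linear_curve(0.55, -0.1)
  delta <- 13
  for (a in c(30, 50, 70)) {
    # independent oracle: average the four order-specific second-order
    # terms -hn'hp, -hp'hn, -hp'hp, -hn'hn
    terms <- c(
      -sensitivity_deriv(hn, a) * eval_sensitivity(hp, a),
      -sensitivity_deriv(hp, a) * eval_sensitivity(hn, a),
      -sensitivity_deriv(hp, a) * eval_sensitivity(hp, a),
      -sensitivity_deriv(hn, a) * eval_sensitivity(hn, a)
    )
    expect_equal(avg_pair_bias(a, hp, hn, delta)$raw,
                 mean(terms) * delta^2)
  }
  # symmetric case reduces to the single-curve pair bias
  cv <- linear_curve(0.8, -0.4)
  expect_equal(avg_pair_bias(50, cv, cv, 13)$raw, 0.4056)
  expect_equal(avg_pair_bias(50, cv, cv, 13)$percent, 3.12)
  expect_equal(avg_pair_bias(40, constant_curve(0.5), constant_curve(0.7),
                             13)$raw, 0)
})

test_that("avg_pair_bias increases strictly as the slope steepens", {
  slopes <- seq(-0.05, -0.45, by = -0.1)
  vals <- vapply(slopes, function(c) {
    avg_pair_bias(50, linear_curve(0.8, c), linear_curve(0.8, c), 13)$raw
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("random_bias_theory matches formula, sign rules and Monte Carlo", {
  cv <- linear_curve(0.8, -0.4)
  expect_equal(random_bias_theory(50, cv, 25)$raw, 0.036)
  expect_equal(random_bias_theory(50, linear_curve(0.6, 0), 25)$raw, 0)
  expect_equal(random_bias_theory(50, cv, 0)$raw, 0)
  for (c in c(-0.4, -0.1, 0)) {
    v <- random_bias_theory(50, linear_curve(0.7, c), 16)$raw
    if (c == 0) expect_equal(v, 0) else expect_gt(v, 0)
  }
  # brute-force oracle: two noisy feedbacks drawn around a1
  mc <- simulate_random_feedback_series(50, cv, sd_theta = 5, n_steps = 2,
                                        n_reps = 2e5, seed = 42)
  expect_lt(abs(mc$mean_bias - 0.036), 3 * mc$se)
})

test_that("random feedback series simulation is seeded and unbiased for constant curves", {
  cv <- constant_curve(0.5)
  a <- simulate_random_feedback_series(50, cv, 5, 4, 5e4, seed = 7)
  b <- simulate_random_feedback_series(50, cv, 5, 4, 5e4, seed = 7)
  expect_identical(a, b)
  expect_lt(abs(a$mean_bias), 3 * a$se)
  # discard policy drops out-of-bounds trajectories
  d <- simulate_random_feedback_series(95, linear_curve(0.9, 0), 10, 3,
                                       1e4, seed = 1, bounds = "discard")
  expect_gt(d$n_out_of_bounds, 0)
  expect_equal(d$n_reps, 1e4 - d$n_out_of_bounds)
})
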