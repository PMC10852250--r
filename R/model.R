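#' Bias predictions
#'
#' Closed-form predictions of self-evaluation drift are returned as a
#' `bias_prediction`: the raw change in self-evaluation units (0--100
#' scale), the same change as a fraction of the feedback intensity
#' `delta`, and as a percent of `delta`.
#'
#' @param raw Raw change in self-evaluation units.
#' @param delta Feedback intensity used to normalize.
#' @return A `bias_prediction` with fields `raw`, `fraction`
#'   (`raw / delta`) and `percent` (`100 * fraction`).
#' @keywords internal
bias_prediction <- function(raw, delta) {
  structure(list(raw = raw, fraction = raw / delta,
                 percent = 100 * raw / delta, delta = delta),
            class = "bias_prediction")
}

#' @export
print.bias_prediction <- function(x, ...) {
  cat(sprintf("<bias_prediction> raw = %.6g (%.4g%% of delta = %.4g)\n",
              x$raw, x$percent, x$delta))
  invisible(x)
}

#' Single feedback update
#'
#' The elementary update of the agent model: on receiving feedback `f`
#' while holding self-evaluation `a`, the agent moves a fraction `h_value`
#' of the way towards the feedback,
#' \eqn{a' = a + h (f - a)}.
#' With `h_value` in \[0, 1\] the result always lies in the closed interval
#' between `a` and `f`.
#'
#' @param a Current self-evaluation.
#' @param f Feedback value.
#' @param h_value Sensitivity fraction in \[0, 1\].
#' @return Updated self-evaluation (not rounded).
#' @export
apply_feedback <- function(a, f, h_value) {
  if (any(h_value < 0 | h_value > 1)) {
    stop("sensitivity must lie in [0, 1]")
  }
  a + h_value * (f - a)
}

# Sequentially applies the two opposite feedbacks of a +/- delta pair,
# erroring if the (unclipped) sensitivity goes negative along the way.
# The net change is accumulated from the per-step increments (rather than
# differencing the endpoints) to avoid cancellation when the bias is tiny.
pair_trajectory <- function(a1, curve_p, curve_n, signs, delta) {
  a <- a1
  change <- 0
  for (s in signs) {
    curve <- if (s > 0) curve_p else curve_n
    h <- eval_sensitivity(curve, a)
    if (any(h < 0)) {
      stop("sensitivity curve evaluates negative along the trajectory")
    }
    step <- h * s * delta
    change <- change + step
    a <- a + step
    if (any(a < 0 | a > 100)) {
      stop("trajectory leaves the [0, 100] self-evaluation range")
    }
  }
  change
}

#' Exact drift after a balanced pair of feedbacks
#'
#' Applies a positive and a negative feedback of equal intensity `delta`
#' sequentially and returns the exact net change `a3 - a1`. For a strictly
#' decreasing positive curve the net change is positive for both orders:
#' the downward step is taken at a higher self-evaluation where the
#' sensitivity is lower, so it does not fully undo the upward step.
#'
#' @param a1 Initial self-evaluation.
#' @param curve A [sensitivity_curve][linear_curve]; the analytic
#'   (unclipped) curve is used.
#' @param delta Feedback intensity (> 0).
#' @param order `"+-"` (positive then negative) or `"-+"`.
#' @return A [bias_prediction].
#' @examples
#' pair_bias_exact(50, linear_curve(0.8, -0.4), 13, "+-")$raw  # 0.4056
#' @export
pair_bias_exact <- function(a1, curve, delta, order = c("+-", "-+")) {
  order <- match.arg(order)
  signs <- if (order == "+-") c(1, -1) else c(-1, 1)
  bias_prediction(pair_trajectory(a1, curve, curve, signs, delta), delta)
}

#' First-order drift after a balanced pair of feedbacks
#'
#' The second-order expansion of [pair_bias_exact] in the intensity:
#' \eqn{-h'(a_1)\, h(a_1)\, \delta^2}, with the derivative per raw
#' self-evaluation unit. For linear curves the expansion is exact; for
#' curved families the discrepancy shrinks as \eqn{O(\delta^3)}.
#'
#' @inheritParams pair_bias_exact
#' @return A [bias_prediction].
#' @export
pair_bias_first_order <- function(a1, curve, delta) {
  raw <- -sensitivity_deriv(curve, a1) * eval_sensitivity(curve, a1) * delta^2
  bias_prediction(raw, delta)
}

#' Self-enhancement at a given self-evaluation
#'
#' The asymmetry between the reaction to a positive and to a negative
#' feedback of intensity `delta` at self-evaluation `a`:
#' \eqn{E(a) = (h_p(a) - h_n(a))\,\delta}. Negative values indicate
#' self-derogation.
#'
#' @param a Self-evaluation.
#' @param curve_p,curve_n Sensitivity curves for positive and negative
#'   feedback.
#' @param delta Feedback intensity.
#' @return A [bias_prediction] (the `fraction` field is
#'   `h_p(a) - h_n(a)`).
#' @export
enhancement_at <- function(a, curve_p, curve_n, delta) {
  frac <- eval_sensitivity(curve_p, a) - eval_sensitivity(curve_n, a)
  bias_prediction(frac * delta, delta)
}

#' Average decreasing-sensitivity drift over balanced four-feedback series
#'
#' For series of two positive and two negative feedbacks in random order
#' with asymmetric curves, the order-averaged second-order drift is
#' \eqn{-h_m'(a)\, h_m(a)\, \delta^2} where \eqn{h_m = (h_p + h_n)/2};
#' this equals the mean of the four order-specific cross terms
#' \eqn{-h_n' h_p, -h_p' h_n, -h_p' h_p, -h_n' h_n} times
#' \eqn{\delta^2 / 4}.
#'
#' @inheritParams enhancement_at
#' @return A [bias_prediction].
#' @export
avg_pair_bias <- function(a, curve_p, curve_n, delta) {
  hm <- mean_curve(curve_p, curve_n)
  raw <- -sensitivity_deriv(hm, a) * eval_sensitivity(hm, a) * delta^2
  bias_prediction(raw, delta)
}

#' Expected drift under random mean-zero feedback noise
#'
#' When feedbacks fluctuate around the current self-evaluation's anchor
#' (`f = a1 + theta`, `theta` mean-zero with variance `var_theta`), the
#' expected self-evaluation after two feedbacks exceeds `a1` by
#' \eqn{-h'(a_1)\, h^2(a_1)\, \overline{\theta^2}}; strictly positive for
#' decreasing curves. The `delta` used for normalization of the returned
#' [bias_prediction] is `sqrt(var_theta)`.
#'
#' @param a1 Initial self-evaluation (also the mean feedback).
#' @param curve A [sensitivity_curve][linear_curve].
#' @param var_theta Variance of the feedback perturbation (>= 0).
#' @return A [bias_prediction].
#' @export
random_bias_theory <- function(a1, curve, var_theta) {
  stopifnot(var_theta >= 0)
  raw <- -sensitivity_deriv(curve, a1) * eval_sensitivity(curve, a1)^2 *
    var_theta
  bias_prediction(raw, sqrt(var_theta))
}

#' Monte-Carlo drift under random feedback series
#'
#' Simulates `n_reps` independent agents receiving `n_steps` feedbacks
#' \eqn{f_t = a_1 + \theta_t} with \eqn{\theta_t \sim N(0, sd^2)}, and
#' returns the mean terminal drift `a_T - a1`. This is the brute-force
#' oracle for [random_bias_theory] (at `n_steps = 2`) and illustrates the
#' growth of the drift towards its asymptote for longer series.
#'
#' Trajectories can momentarily leave \[0, 100\]; by default they are
#' clamped (and flagged in the result), or discarded with
#' `bounds = "discard"`.
#'
#' @inheritParams random_bias_theory
#' @param sd_theta Standard deviation of the feedback perturbation.
#' @param n_steps Number of feedbacks per agent.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Integer seed (mandatory: results are reproducible).
#' @param bounds `"clamp"` or `"discard"` for trajectories leaving
#'   \[0, 100\].
#' @return A list with `mean_bias`, its standard error `se`, `n_reps`
#'   effectively used, and `n_out_of_bounds`.
#' @export
simulate_random_feedback_series <- function(a1, curve, sd_theta, n_steps,
                                            n_reps, seed,
                                            bounds = c("clamp", "discard")) {
  stopifnot(n_reps >= 1, n_steps >= 1)
  bounds <- match.arg(bounds)
  set.seed(as.integer(seed))
  a <- rep(a1, n_reps)
  out_flag <- logical(n_reps)
  for (t in seq_len(n_steps)) {
    theta <- stats::rnorm(n_reps, 0, sd_theta)
    f <- a1 + theta
    h <- eval_sensitivity_unchecked(curve, a)
    a <- a + h * (f - a)
    out <- a < 0 | a > 100
    out_flag <- out_flag | out
    a <- pmin(pmax(a, 0), 100)
  }
  keep <- if (bounds == "discard") !out_flag else rep(TRUE, n_reps)
  drift <- a[keep] - a1
  list(mean_bias = mean(drift),
       se = stats::sd(drift) / sqrt(length(drift)),
       n_reps = length(drift),
       n_out_of_bounds = sum(out_flag))
}

# eval_sensitivity without the [0,100] domain check, for inner Monte-Carlo
# loops where intermediate values are clamped right after the update.
eval_sensitivity_unchecked <- function(curve, a) {
  h <- switch(curve$family,
    linear = ,
    constant = curve$b + curve$c * (a / 100),
    logistic = curve$lo + (curve$hi - curve$lo) /
      (1 + exp(curve$steepness * (a / 100 - curve$midpoint))),
    mixture = (eval_sensitivity_unchecked(curve$p, a) +
                 eval_sensitivity_unchecked(curve$n, a)) / 2
  )
  if (curve$clip) h <- pmin(pmax(h, 0), 1) else h
}
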