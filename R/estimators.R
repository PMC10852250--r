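#' Fit the sensitivity-to-feedback regression
#'
#' The per-triple realized sensitivity \eqn{|a_{t+1} - a_t| / \delta_t}
#' is regressed on the normalized self-evaluation \eqn{a_t / 100} by
#' ordinary least squares:
#' \deqn{|a_{t+1} - a_t| / \delta_t \approx c\, a_t / 100 + b,}
#' giving a linear approximation of the average sensitivity function of
#' the triples in the frame. A negative slope `c` means the sensitivity
#' declines as self-evaluation rises. The `scope` restricts the fit to
#' positive feedbacks (approximating `h_p`), negative feedbacks (`h_n`) or
#' all of them (`h`).
#'
#' @param frame A [sample_frame].
#' @param scope `"all"`, `"positive"` or `"negative"`.
#' @return An object of class `sensitivity_fit`: list with `slope`,
#'   `intercept`, `p_slope` (two-sided), `n`, `scope`, `method`.
#' @export
fit_sensitivity <- function(frame, scope = c("all", "positive", "negative")) {
  scope <- match.arg(scope)
  df <- scope_frame(frame, scope)
  if (nrow(df) < 3) stop("need at least 3 triples to fit (scope=", scope, ")")
  if (any(df$delta_t <= 0)) stop("non-positive intensities in frame")
  x <- df$a_t / 100
  if (stats::var(x) == 0) stop("zero variance in self-evaluation predictor")
  y <- abs(df$a_next - df$a_t) / df$delta_t
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["x", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 p_slope = unname(cf["x", "Pr(>|t|)"]),
                 n = nrow(df), scope = scope, method = "ols"),
            class = "sensitivity_fit")
}

scope_frame <- function(frame, scope) {
  switch(scope,
    all = frame,
    positive = frame[frame$sign > 0, , drop = FALSE],
    negative = frame[frame$sign < 0, , drop = FALSE])
}

#' Mixed-effect variant of the sensitivity regression
#'
#' Because the three or four triples of one participant are not
#' independent, the pooled regression can also be fit as a linear mixed
#' model with a participant-level random intercept (maximum likelihood,
#' via \pkg{lme4}). Only the fixed-effect slope is returned; the method
#' provides no slope p-value. Applicable only when the frame spans at
#' least three time steps per participant.
#'
#' @param frame A [sample_frame].
#' @return A `sensitivity_fit` with `method = "lmer"` and `p_slope = NA`.
#' @export
fit_sensitivity_mixed <- function(frame) {
  steps <- length(unique(frame$t))
  if (steps < 3) {
    stop("mixed model not applicable: frame spans fewer than 3 time steps")
  }
  df <- data.frame(
    y = abs(frame$a_next - frame$a_t) / frame$delta_t,
    x = frame$a_t / 100,
    pid = factor(frame$participant_id)
  )
  fit <- lme4::lmer(y ~ x + (1 | pid), data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  fe <- lme4::fixef(fit)
  structure(list(slope = unname(fe["x"]),
                 intercept = unname(fe["(Intercept)"]),
                 p_slope = NA_real_,
                 n = nrow(df), scope = "all", method = "lmer"),
            class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_fit %s/%s> h(a) ~ %.4f %+.4f * a/100  (n = %d%s)\n",
    x$method, x$scope, x$intercept, x$slope, x$n,
    if (is.na(x$p_slope)) "" else sprintf(", p[slope] = %.3g", x$p_slope)))
  invisible(x)
}

#' Fitted curve from a sensitivity fit
#'
#' @param fit A `sensitivity_fit`.
#' @param clip Clamp evaluations to \[0,1\]?
#' @export
fit_curve <- function(fit, clip = FALSE) {
  linear_curve(fit$intercept, fit$slope, clip)
}

#' Total self-evaluation bias over complete series
#'
#' Mean over participants of the net change across the balanced
#' four-feedback series, normalized by the average feedback intensity:
#' \deqn{B = \frac{1}{p}\sum_i \frac{a_5^i - a_1^i}
#'   {\tfrac12 \sum_t \delta_t^i} \times 100,}
#' expressed as a percent of the feedback intensity. Requires every
#' participant in the frame to contribute all four time steps.
#'
#' @param frame A [sample_frame] with complete series.
#' @return Percent of feedback intensity.
#' @export
total_bias <- function(frame) {
  check_complete_series(frame)
  first <- frame[frame$t == 1, ]
  last <- frame[frame$t == 4, ]
  first <- first[order(first$participant_id), ]
  last <- last[order(last$participant_id), ]
  sum_delta <- tapply(frame$delta_t, frame$participant_id, sum)
  sum_delta <- sum_delta[as.character(first$participant_id)]
  per_part <- (last$a_next - first$a_t) / (0.5 * as.numeric(sum_delta))
  100 * mean(per_part)
}
attr(total_bias, "requires_complete_series") <- TRUE

check_complete_series <- function(frame) {
  tab <- table(frame$participant_id, frame$t)
  if (ncol(tab) != 4 || any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab == 1) != 4 | rowSums(tab) != 4]
    if (!length(bad)) bad <- "(structure)"
    stop("frame lacks complete 4-step series for participant(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  invisible(TRUE)
}

#' Self-enhancement bias of a sample
#'
#' Average asymmetry between the fitted reactions to positive and
#' negative feedbacks over the triples of the frame:
#' \deqn{E = \frac{1}{n}\sum_{i,t}\left[(c_p - c_n)\frac{a_t^i}{100}
#'   + b_p - b_n\right] \times 100,}
#' as a percent of the feedback intensity. Negative values indicate
#' self-derogation (stronger reaction to negative feedback).
#'
#' @param frame A [sample_frame].
#' @param fit_p,fit_n `sensitivity_fit`s for the positive and negative
#'   scopes of the *same* frame (computed when omitted).
#' @return Percent of feedback intensity.
#' @export
enhancement_bias <- function(frame, fit_p = NULL, fit_n = NULL) {
  if (is.null(fit_p)) fit_p <- fit_sensitivity(frame, "positive")
  if (is.null(fit_n)) fit_n <- fit_sensitivity(frame, "negative")
  stopifnot(fit_p$scope == "positive", fit_n$scope == "negative")
  100 * mean((fit_p$slope - fit_n$slope) * frame$a_t / 100 +
               fit_p$intercept - fit_n$intercept)
}

#' Theoretical decreasing-sensitivity bias of a sample
#'
#' Closed-form estimate of the drift induced by the declining sensitivity,
#' averaged over the triples, using the mean fitted curve
#' (`c_m = (c_p + c_n)/2`, `b_m = (b_p + b_n)/2`):
#' \deqn{S' = \frac{1}{n}\sum_{i,t} -c_m\left(c_m\frac{a_t^i}{100}
#'   + b_m\right)\delta_t^i.}
#' The per-triple term is the second-order drift divided by
#' \eqn{\delta_t} and multiplied by 100, so `S'` is already a percent of
#' the feedback intensity, directly comparable to `B` and `E`.
#'
#' @inheritParams enhancement_bias
#' @return Percent of feedback intensity.
#' @export
sensitivity_bias_theoretical <- function(frame, fit_p = NULL, fit_n = NULL) {
  if (is.null(fit_p)) fit_p <- fit_sensitivity(frame, "positive")
  if (is.null(fit_n)) fit_n <- fit_sensitivity(frame, "negative")
  stopifnot(fit_p$scope == "positive", fit_n$scope == "negative")
  c_m <- (fit_p$slope + fit_n$slope) / 2
  b_m <- (fit_p$intercept + fit_n$intercept) / 2
  mean(-c_m * (c_m * frame$a_t / 100 + b_m) * frame$delta_t)
}

#' Decompose the total self-evaluation bias
#'
#' Computes the four bias measures on a common percent-of-intensity unit:
#' total bias `B` ([total_bias]), self-enhancement `E`
#' ([enhancement_bias]), the measured decreasing-sensitivity bias
#' `S = B - E` (exact by construction) and its closed-form counterpart
#' `S'` ([sensitivity_bias_theoretical]).
#'
#' @inheritParams enhancement_bias
#' @return An object of class `bias_estimates`: list with `B`, `E`,
#'   `S_measured`, `S_theoretical`, `n`, `p` (triple and participant
#'   counts) and `units` (`"percent of delta"`).
#' @export
decompose_bias <- function(frame, fit_p = NULL, fit_n = NULL) {
  if (is.null(fit_p)) fit_p <- fit_sensitivity(frame, "positive")
  if (is.null(fit_n)) fit_n <- fit_sensitivity(frame, "negative")
  B <- total_bias(frame)
  E <- enhancement_bias(frame, fit_p, fit_n)
  Sp <- sensitivity_bias_theoretical(frame, fit_p, fit_n)
  structure(list(B = B, E = E, S_measured = B - E, S_theoretical = Sp,
                 n = n_triples(frame), p = n_participants(frame),
                 units = "percent of delta"),
            class = "bias_estimates")
}

#' @export
print.bias_estimates <- function(x, ...) {
  cat(sprintf(paste0(
    "<bias_estimates> (%s; n = %d triples, %d participants)\n",
    "  B  total bias            : %7.3f\n",
    "  E  self-enhancement      : %7.3f\n",
    "  S  = B - E (measured)    : %7.3f\n",
    "  S' (theoretical)         : %7.3f\n"),
    x$units, x$n, x$p, x$B, x$E, x$S_measured, x$S_theoretical))
  invisible(x)
}
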