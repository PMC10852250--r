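#' Sensitivity-to-feedback curves
#'
#' A sensitivity curve maps a self-evaluation `a` on the 1--100 scale to the
#' fraction of the feedback--self-evaluation gap that the agent adopts.
#' Three families are supported:
#'
#' * `linear`: \eqn{h(a) = b + c \, a/100}. The slope `c` is expressed per
#'   unit of *normalized* self-evaluation `a/100`, so the derivative per raw
#'   self-evaluation unit is `c/100`.
#' * `constant`: \eqn{h(a) = b} (a linear curve with `c = 0`).
#' * `logistic`: a smoothly decreasing (or increasing) S-shaped curve
#'   \eqn{h(a) = lo + (hi - lo) / (1 + e^{k (a/100 - m)})}, useful to probe
#'   how predictions degrade when the sensitivity is not linear.
#'
#' When `clip = TRUE`, evaluated sensitivities are clamped to \[0, 1\]
#' (responses in the experimental protocol are constrained between the
#' previous self-evaluation and the feedback, which amounts to this clamp).
#' Analytic bias formulas assume the unclipped curve; simulation uses the
#' clipped one.
#'
#' @param b Intercept: value of `h` at `a = 0` (sensitivity fraction).
#' @param c Slope per unit of normalized self-evaluation `a/100`.
#' @param clip Logical; clamp evaluated values to \[0, 1\]?
#' @param lo,hi Lower/upper asymptotes of the logistic family.
#' @param midpoint Normalized self-evaluation (`a/100`) at which the
#'   logistic curve is halfway between `hi` and `lo`.
#' @param steepness Positive logistic rate `k`; larger is steeper. The
#'   curve decreases in `a` when `hi > lo`.
#' @return An object of class `sensitivity_curve`.
#' @examples
#' h <- linear_curve(b = 0.65, c = -0.15)
#' eval_sensitivity(h, 50)  # 0.575
#' @export
linear_curve <- function(b, c = 0, clip = FALSE) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(c), length(c) == 1L)
  structure(list(family = "linear", b = b, c = c, clip = isTRUE(clip)),
            class = "sensitivity_curve")
}

#' @rdname linear_curve
#' @export
constant_curve <- function(b, clip = FALSE) {
  out <- linear_curve(b, 0, clip)
  out$family <- "constant"
  out
}

#' @rdname linear_curve
#' @export
logistic_curve <- function(lo = 0.2, hi = 0.8, midpoint = 0.5,
                           steepness = 6, clip = FALSE) {
  stopifnot(steepness > 0, hi >= lo)
  structure(list(family = "logistic", lo = lo, hi = hi, midpoint = midpoint,
                 steepness = steepness, clip = isTRUE(clip)),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  if (x$family %in% c("linear", "constant")) {
    cat(sprintf("<sensitivity_curve %s> h(a) = %.4g %+.4g * a/100%s\n",
                x$family, x$b, x$c, if (x$clip) " [clipped to 0..1]" else ""))
  } else {
    cat(sprintf(
      "<sensitivity_curve logistic> lo=%.3g hi=%.3g mid=%.3g k=%.3g%s\n",
      x$lo, x$hi, x$midpoint, x$steepness,
      if (x$clip) " [clipped to 0..1]" else ""))
  }
  invisible(x)
}

#' Evaluate a sensitivity curve
#'
#' @param curve A [sensitivity_curve][linear_curve].
#' @param a Self-evaluation(s) in \[0, 100\].
#' @return Sensitivity fraction(s); clamped to \[0, 1\] when the curve has
#'   `clip = TRUE`.
#' @export
eval_sensitivity <- function(curve, a) {
  stopifnot(inherits(curve, "sensitivity_curve"), is.numeric(a))
  if (any(a < 0 | a > 100)) {
    stop("self-evaluation must lie in [0, 100]")
  }
  h <- switch(curve$family,
    linear = ,
    constant = curve$b + curve$c * (a / 100),
    logistic = curve$lo + (curve$hi - curve$lo) /
      (1 + exp(curve$steepness * (a / 100 - curve$midpoint))),
    mixture = (eval_sensitivity(curve$p, a) + eval_sensitivity(curve$n, a)) / 2,
    stop("unknown curve family: ", curve$family)
  )
  if (curve$clip) h <- pmin(pmax(h, 0), 1)
  h
}

#' Derivative of a sensitivity curve per raw self-evaluation unit
#'
#' Returns \eqn{dh/da} with `a` on the raw 1--100 scale. For the linear
#' family this is `c / 100`. The derivative of the unclipped curve is
#' returned even when `clip = TRUE`.
#'
#' @inheritParams eval_sensitivity
#' @export
sensitivity_deriv <- function(curve, a) {
  stopifnot(inherits(curve, "sensitivity_curve"), is.numeric(a))
  switch(curve$family,
    linear = ,
    constant = rep(curve$c / 100, length(a)),
    logistic = {
      z <- exp(curve$steepness * (a / 100 - curve$midpoint))
      -(curve$hi - curve$lo) * (curve$steepness / 100) * z / (1 + z)^2
    },
    mixture = (sensitivity_deriv(curve$p, a) + sensitivity_deriv(curve$n, a)) / 2,
    stop("unknown curve family: ", curve$family)
  )
}

#' Pointwise average of two sensitivity curves
#'
#' Builds the mean curve \eqn{h_m(a) = (h_p(a) + h_n(a)) / 2} used by the
#' decreasing-sensitivity bias formulas. Averaging two linear (or constant)
#' curves yields a linear curve with `b_m = (b_p + b_n)/2` and
#' `c_m = (c_p + c_n)/2`; other combinations are kept as a lazy pointwise
#' mixture.
#'
#' @param curve_p,curve_n Sensitivity curves (reaction to positive and
#'   negative feedback).
#' @export
mean_curve <- function(curve_p, curve_n) {
  stopifnot(inherits(curve_p, "sensitivity_curve"),
            inherits(curve_n, "sensitivity_curve"))
  lin <- c("linear", "constant")
  if (curve_p$family %in% lin && curve_n$family %in% lin) {
    return(linear_curve((curve_p$b + curve_n$b) / 2,
                        (curve_p$c + curve_n$c) / 2,
                        clip = curve_p$clip && curve_n$clip))
  }
  structure(list(family = "mixture", p = curve_p, n = curve_n,
                 clip = curve_p$clip && curve_n$clip),
            class = "sensitivity_curve")
}

#' Serialize / deserialize a sensitivity curve
#'
#' Curves round-trip through a plain key-value list (and hence JSON/YAML
#' configuration blocks): `family`, `b`, `c`, `clip` for the linear and
#' constant families; `lo`, `hi`, `midpoint`, `steepness`, `clip` for the
#' logistic family.
#'
#' @param x A `sensitivity_curve` (for `as.list`) or a named list
#'   (for `curve_from_list`).
#' @param ... Unused.
#' @export
as.list.sensitivity_curve <- function(x, ...) {
  unclass(x)
}

#' @rdname as.list.sensitivity_curve
#' @export
curve_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$family))
  clip <- isTRUE(x$clip)
  switch(as.character(x$family),
    linear = linear_curve(x$b, if (is.null(x$c)) 0 else x$c, clip),
    constant = constant_curve(x$b, clip),
    logistic = logistic_curve(x$lo, x$hi, x$midpoint, x$steepness, clip),
    stop("unknown curve family: ", x$family)
  )
}
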