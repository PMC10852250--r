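#' The six balanced feedback-sign sequences
#'
#' Every participant receives four feedbacks, two positive and two
#' negative. The six distinct orderings are enumerated in the protocol's
#' canonical order, `(+,+,-,-)` first.
#'
#' @return A 6 x 4 integer matrix of +1 / -1.
#' @export
feedback_sequences <- function() {
  m <- rbind(
    c( 1,  1, -1, -1),
    c( 1, -1,  1, -1),
    c( 1, -1, -1,  1),
    c(-1,  1,  1, -1),
    c(-1,  1, -1,  1),
    c(-1, -1,  1,  1)
  )
  dimnames(m) <- list(NULL, paste0("f", 1:4))
  m
}

#' Draw experiment anchors
#'
#' The anchor is the experimenter-chosen initial evaluation: an integer
#' uniform on \[60, 85\] ("high") with probability `p_high`, uniform on
#' \[15, 40\] ("low") otherwise. The protocol over-samples the high-anchor
#' condition (2/3 vs 1/3) because the decline of sensitivity is expected
#' mainly there. Anchors are expressed on the increasing (score) scale.
#'
#' @param n Number of anchors to draw.
#' @param p_high Probability of the high-anchor condition.
#' @return Integer vector of anchors in \[15,40\] or \[60,85\].
#' @export
draw_anchor <- function(n = 1, p_high = 2 / 3) {
  stopifnot(p_high >= 0, p_high <= 1)
  high <- stats::runif(n) < p_high
  lo <- sample.int(26L, n, replace = TRUE) + 14L   # 15..40
  hi <- sample.int(26L, n, replace = TRUE) + 59L   # 60..85
  ifelse(high, hi, lo)
}

#' Plan one protocol feedback
#'
#' The feedback shown at step `t` is defined from the current
#' self-evaluation as \eqn{f_t = a_t \pm \delta \pm \epsilon} with the sign
#' taken from the participant's sequence and the small jitter
#' \eqn{\pm\epsilon} drawn equiprobably (it avoids too-regular series).
#' When the raw value leaves \[1, 100\] it is truncated to the bound and
#' the observation is flagged: its intensity then differs from
#' \eqn{\delta \pm \epsilon} and the participant's series is no longer
#' balanced.
#'
#' @param a Current self-evaluation in \[1, 100\].
#' @param sign +1 for a positive, -1 for a negative feedback.
#' @param delta Base feedback intensity (default 13).
#' @param epsilon Jitter magnitude (default 1); requires
#'   `delta > epsilon >= 0`.
#' @return A list with `f` (feedback value) and `truncated` (logical).
#' @export
plan_feedback <- function(a, sign, delta = 13, epsilon = 1) {
  stopifnot(all(a >= 1 & a <= 100), all(sign %in% c(-1, 1)),
            delta > epsilon, epsilon >= 0)
  n <- max(length(a), length(sign))
  a <- rep_len(a, n)
  sign <- rep_len(sign, n)
  jitter <- sample(c(-1, 1), n, replace = TRUE) * epsilon
  raw <- a + sign * (delta + jitter)
  f <- pmin(pmax(raw, 1), 100)
  list(f = f, truncated = f != raw)
}

# Round half away from zero; responses live on an integer 1..100 scale.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate a participant response to one feedback
#'
#' The participant is constrained to answer between their previous
#' self-evaluation and the feedback, so the realized sensitivity is a
#' number in \[0, 1\]. It is modeled as the participant's latent curve
#' evaluated at `a`, plus Gaussian response noise, clamped to \[0, 1\]; the
#' answer is the implied evaluation rounded to the on-screen integer
#' scale. By construction the response never leaves the closed interval
#' between `a` and `f`.
#'
#' @param a Current self-evaluation.
#' @param f Feedback value; must differ from `a`.
#' @param curve Latent [sensitivity_curve][linear_curve] (use the
#'   positive-feedback curve when `f > a`, the negative one otherwise).
#' @param noise_sd Standard deviation of the response noise, on the
#'   sensitivity-fraction scale.
#' @return Integer next self-evaluation.
#' @export
respond <- function(a, f, curve, noise_sd = 0) {
  if (any(f == a)) stop("degenerate feedback: f equals current self-evaluation")
  n <- max(length(a), length(f))
  a <- rep_len(a, n)
  f <- rep_len(f, n)
  s <- eval_sensitivity(curve, a)
  if (noise_sd > 0) s <- s + stats::rnorm(n, 0, noise_sd)
  s <- pmin(pmax(s, 0), 1)
  round_half_up(a + s * (f - a))
}

#' Cohort generator configuration
#'
#' Collects every knob of the synthetic cohort generator. Latent behavior
#' is always simulated on the increasing (score) scale; participants in
#' the rank condition have their recorded values mirrored (`100 - value`)
#' as the instrument would show them.
#'
#' Group-level defaults are package choices, not measured quantities: the
#' mean sensitivity decreases with self-evaluation, the score condition
#' induces mild self-derogation and the rank condition mild
#' self-enhancement, men and high self-esteem participants self-enhance
#' slightly more. With `trust_coupling = TRUE` the common slope steepens
#' linearly with trust between `trust_slope_range[1]` (trust 0) and
#' `trust_slope_range[2]` (trust 10), mimicking the observed trust
#' gradient; by default trust is drawn independently of behavior.
#'
#' @param n_participants Number of participants (default 1500).
#' @param delta,epsilon Feedback intensity and jitter (defaults 13 and 1).
#' @param p_high_anchor Probability of the high anchor condition (2/3).
#' @param anchor_sd SD of the Gaussian gap between the anchor and the
#'   first self-evaluation (self-evaluation units).
#' @param curve_p,curve_n Population-level latent curves for positive and
#'   negative feedback (linear or constant).
#' @param response_noise_sd Response noise SD on the sensitivity scale.
#' @param participant_sd SD of the participant-level random shift of both
#'   curve intercepts (shared by `curve_p` and `curve_n`).
#' @param scale_enhancement Named numeric, additive `h_p - h_n` offset by
#'   scale condition (half added to `b_p`, half removed from `b_n`).
#' @param gender_enhancement,esteem_enhancement Additive enhancement
#'   offsets: `gender_enhancement` applied +/- half to men/women;
#'   `esteem_enhancement` scales with `(self_esteem - 3)`.
#' @param p_score Probability of the score (increasing) scale condition.
#' @param p_female Probability of gender "female".
#' @param trust_coupling Couple trust to slope steepness?
#' @param trust_slope_range Length-2 numeric, slope at trust 0 and at
#'   trust 10 when `trust_coupling` is on.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1500,
                          delta = 13,
                          epsilon = 1,
                          p_high_anchor = 2 / 3,
                          anchor_sd = 5,
                          curve_p = linear_curve(0.65, -0.12),
                          curve_n = linear_curve(0.65, -0.12),
                          response_noise_sd = 0.15,
                          participant_sd = 0.1,
                          scale_enhancement = c(rank = 0.05, score = -0.10),
                          gender_enhancement = 0.04,
                          esteem_enhancement = 0.03,
                          p_score = 0.5,
                          p_female = 0.53,
                          trust_coupling = FALSE,
                          trust_slope_range = c(-0.04, -0.20)) {
  stopifnot(n_participants >= 1, delta > epsilon, epsilon >= 0,
            p_high_anchor >= 0, p_high_anchor <= 1,
            p_score >= 0, p_score <= 1,
            inherits(curve_p, "sensitivity_curve"),
            inherits(curve_n, "sensitivity_curve"),
            all(c("rank", "score") %in% names(scale_enhancement)),
            length(trust_slope_range) == 2)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a synthetic cohort through the feedback protocol
#'
#' Generates `n_participants` synthetic participants and walks each
#' through the experimental protocol: draw an anchor, form the first
#' self-evaluation as the anchor plus Gaussian noise (clamped to
#' \[1, 100\]), pick one of the six balanced sign sequences uniformly,
#' then four times plan a feedback ([plan_feedback]) and record the
#' response ([respond]). Each participant yields four triples; a
#' participant with any truncated feedback is flagged for exclusion
#' (the planned balanced series could not be applied).
#'
#' @param config A [cohort_config].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `cohort` with two data frames:
#'   `triples` (participant_id, t, a_t, f_t, a_next, delta_t, sign,
#'   truncated) on the instrument scale, and `participants` (id, trust,
#'   gender, self_esteem, scale, anchor, interview_time, sequence,
#'   excluded). The anchor is stored on the score scale.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_participants
  seqs <- feedback_sequences()

  trust <- sample(0:10, n, replace = TRUE)
  gender <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  self_esteem <- pmin(pmax(round(stats::rnorm(n, 3, 0.5), 1), 1), 4)
  scale <- ifelse(stats::runif(n) < config$p_score, "score", "rank")
  anchor <- draw_anchor(n, config$p_high_anchor)
  interview_time <- round_half_up(stats::rlnorm(n, log(420), 0.55))
  seq_id <- sample.int(6L, n, replace = TRUE)
  u_i <- stats::rnorm(n, 0, config$participant_sd)

  # participant-level curves: enhancement offsets move b_p and b_n apart
  enh <- config$scale_enhancement[scale] +
    ifelse(gender == "male", 0.5, -0.5) * config$gender_enhancement +
    (self_esteem - 3) * config$esteem_enhancement
  b_p <- config$curve_p$b + u_i + enh / 2
  b_n <- config$curve_n$b + u_i - enh / 2
  if (config$trust_coupling) {
    r <- config$trust_slope_range
    c_p <- c_n <- r[1] + (r[2] - r[1]) * trust / 10
  } else {
    c_p <- rep(config$curve_p$c, n)
    c_n <- rep(config$curve_n$c, n)
  }

  a1 <- pmin(pmax(round_half_up(anchor + stats::rnorm(n, 0, config$anchor_sd)),
                  1), 100)

  tr <- matrix(NA_real_, nrow = 4 * n, ncol = 5,
               dimnames = list(NULL, c("t", "a_t", "f_t", "a_next", "sign")))
  truncated <- logical(4 * n)
  for (i in seq_len(n)) {
    cp <- linear_curve(b_p[i], c_p[i], clip = TRUE)
    cn <- linear_curve(b_n[i], c_n[i], clip = TRUE)
    a <- a1[i]
    for (t in 1:4) {
      s <- seqs[seq_id[i], t]
      fb <- plan_feedback(a, s, config$delta, config$epsilon)
      if (fb$f == a) {
        # feedback truncated onto the current value: protocol failure,
        # nothing to react to; keep the evaluation and flag the series
        a_next <- a
        fb$truncated <- TRUE
      } else {
        a_next <- respond(a, fb$f, if (fb$f > a) cp else cn,
                          config$response_noise_sd)
      }
      row <- (i - 1) * 4 + t
      tr[row, ] <- c(t, a, fb$f, a_next,
                     if (fb$f > a) 1 else if (fb$f < a) -1 else s)
      truncated[row] <- fb$truncated
      a <- a_next
    }
  }

  triples <- data.frame(
    participant_id = rep(seq_len(n), each = 4),
    t = as.integer(tr[, "t"]),
    a_t = tr[, "a_t"],
    f_t = tr[, "f_t"],
    a_next = tr[, "a_next"],
    sign = as.integer(tr[, "sign"]),
    truncated = truncated
  )
  # mirror to the instrument (rank) scale for rank-condition participants
  is_rank <- scale[triples$participant_id] == "rank"
  for (col in c("a_t", "f_t", "a_next")) {
    triples[[col]][is_rank] <- 100 - triples[[col]][is_rank]
  }
  triples$sign[is_rank] <- -triples$sign[is_rank]
  triples$delta_t <- abs(triples$f_t - triples$a_t)
  triples <- triples[, c("participant_id", "t", "a_t", "f_t", "a_next",
                         "delta_t", "sign", "truncated")]

  participants <- data.frame(
    id = seq_len(n),
    trust = trust,
    gender = gender,
    self_esteem = self_esteem,
    scale = scale,
    anchor = anchor,
    interview_time = interview_time,
    sequence = seq_id,
    excluded = as.logical(tapply(truncated, rep(seq_len(n), each = 4), any))
  )
  structure(list(triples = triples, participants = participants,
                 config = config, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants, %d triples (%d flagged for exclusion)\n",
    nrow(x$participants), nrow(x$triples), sum(x$participants$excluded)))
  invisible(x)
}
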