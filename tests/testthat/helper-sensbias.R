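# Shared fixtures, all generated in code.

# A cohort configuration with group-level heterogeneity switched off:
# every participant shares the same symmetric latent curves. This is the
# configuration used for parameter-recovery checks (estimating the model
# that generated the data).
recovery_config <- function(n = 1500, b = 0.65, c = -0.12,
                            noise_sd = 0.15, participant_sd = 0.1,
                            enhancement = 0, ...) {
  cohort_config(
    n_participants = n,
    curve_p = linear_curve(b, c),
    curve_n = linear_curve(b, c),
    response_noise_sd = noise_sd,
    participant_sd = participant_sd,
    scale_enhancement = c(rank = enhancement, score = enhancement),
    gender_enhancement = 0,
    esteem_enhancement = 0,
    ...
  )
}

# Analysis-ready frame from a cohort: join covariates, map ranks to the
# score scale, drop truncated series.
cohort_frame <- function(cohort) {
  fr <- sample_frame(cohort$triples, cohort$participants)
  filter_excluded(rank_to_score(fr), quiet = TRUE)
}

# A deterministic frame built without response noise or rounding: each
# participant follows a chained balanced four-feedback trajectory with
# responses exactly on h_p, h_n (defaulting to one symmetric line), so
# regressions recover the generating lines exactly and the total bias is
# the exact chained drift.
noiseless_frame <- function(n_participants = 50, b = 0.65, c = -0.15,
                            b_n = b, c_n = c, delta = 13, jitter = 1,
                            seed = 1) {
  set.seed(seed)
  seqs <- feedback_sequences()
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    a <- sample(25:75, 1)
    signs <- seqs[sample.int(6, 1), ]
    rec <- matrix(NA_real_, 4, 5)
    for (t in 1:4) {
      d <- delta + sample(c(-1, 1), 1) * jitter
      f <- a + signs[t] * d
      h <- if (signs[t] > 0) b + c * a / 100 else b_n + c_n * a / 100
      a_next <- a + h * (f - a)
      rec[t, ] <- c(t, a, f, a_next, signs[t])
      a <- a_next
    }
    rows[[i]] <- data.frame(participant_id = i, t = rec[, 1], a_t = rec[, 2],
                            f_t = rec[, 3], a_next = rec[, 4],
                            sign = as.integer(rec[, 5]))
  }
  df <- do.call(rbind, rows)
  df$delta_t <- abs(df$f_t - df$a_t)
  sample_frame(df[, c("participant_id", "t", "a_t", "f_t", "a_next",
                      "delta_t", "sign")])
}

# Minimal hand-built frame (one or more participants with full series).
tiny_frame <- function(a1 = 50, a_next_shift = 0.52) {
  df <- data.frame(
    participant_id = 1L,
    t = 1:4,
    a_t = c(50, 57, 64.26, 57.26),
    sign = c(1, 1, -1, -1),
    delta_t = c(14, 12, 14, 12)
  )
  df$f_t <- df$a_t + df$sign * df$delta_t
  df$a_next <- c(57, 64.26, 57.26, 50 + a_next_shift)
  sample_frame(df)
}

# Attach constant covariates so subset/analyze paths work on built frames.
with_covariates <- function(frame, trust = 8, gender = "female",
                            self_esteem = 3, scale = "score",
                            interview_time = 400) {
  ids <- unique(frame$participant_id)
  participants <- data.frame(
    id = ids, trust = trust, gender = gender, self_esteem = self_esteem,
    scale = scale, anchor = 70, interview_time = interview_time
  )
  sample_frame(as.data.frame(frame), participants,
               selection = frame_selection(frame) %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
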