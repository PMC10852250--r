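#' Bootstrap a measure by resampling triples
#'
#' Draws `n_samples` bootstrap samples of the frame's rows (with
#' replacement), recomputes `measure` on each, and summarizes with the
#' bootstrap mean and standard deviation. Measures that need complete
#' four-step series per participant (such as [total_bias], which carries
#' the `requires_complete_series` attribute) are refused: row resampling
#' breaks series, use [bootstrap_participants] instead.
#'
#' @param frame A [sample_frame].
#' @param measure Function of a frame returning one number.
#' @param n_samples Number of bootstrap samples (default 200, which keeps
#'   means and standard deviations within roughly 20% of their
#'   1000-sample values).
#' @param seed Mandatory integer seed.
#' @param name Measure name recorded in the summary.
#' @return An object of class `bootstrap_summary`: list with `measure`,
#'   `scheme`, `mean`, `sd`, `n_samples`, `seed`, `values`.
#' @export
bootstrap_triples <- function(frame, measure, n_samples = 200, seed,
                              name = deparse(substitute(measure))) {
  stopifnot(inherits(frame, "sample_frame"), is.function(measure),
            n_samples >= 1)
  if (isTRUE(attr(measure, "requires_complete_series"))) {
    stop("measure requires complete series; use bootstrap_participants()")
  }
  set.seed(as.integer(seed))
  n <- nrow(frame)
  vals <- vapply(seq_len(n_samples), function(k) {
    measure(frame[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  bootstrap_summary(name, "triple", vals, n_samples, seed)
}

#' Bootstrap measures by resampling whole participants
#'
#' Participant-level (cluster-preserving) bootstrap: each sample draws
#' participants with replacement and keeps all four triples of every
#' drawn participant, so series-level measures (total bias, hence the
#' measured decreasing-sensitivity bias) remain computable on every
#' sample. All measures are evaluated on the same samples, which makes
#' differences such as `S - S'` directly comparable.
#'
#' @param frame A [sample_frame] with complete four-step series.
#' @param measures Named list of functions of a frame.
#' @param n_samples Number of bootstrap samples (default 200).
#' @param seed Mandatory integer seed.
#' @return A named list of `bootstrap_summary` objects.
#' @export
bootstrap_participants <- function(frame, measures, n_samples = 200, seed) {
  stopifnot(inherits(frame, "sample_frame"), is.list(measures),
            length(names(measures)) == length(measures), n_samples >= 1)
  check_complete_series(frame)
  set.seed(as.integer(seed))
  ids <- unique(frame$participant_id)
  rows_of <- split(seq_len(nrow(frame)), frame$participant_id)
  rows_of <- rows_of[as.character(ids)]
  out <- matrix(NA_real_, nrow = n_samples, ncol = length(measures),
                dimnames = list(NULL, names(measures)))
  for (k in seq_len(n_samples)) {
    drawn <- sample.int(length(ids), length(ids), replace = TRUE)
    idx <- unlist(rows_of[drawn], use.names = FALSE)
    samp <- frame[idx, , drop = FALSE]
    # relabel so a participant drawn twice counts as two clusters
    samp$participant_id <- rep(seq_along(drawn), lengths(rows_of)[drawn])
    for (m in names(measures)) out[k, m] <- measures[[m]](samp)
  }
  stats::setNames(lapply(names(measures), function(m) {
    bootstrap_summary(m, "participant", out[, m], n_samples, seed)
  }), names(measures))
}

bootstrap_summary <- function(measure, scheme, values, n_samples, seed) {
  structure(list(measure = measure, scheme = scheme,
                 mean = mean(values), sd = stats::sd(values),
                 n_samples = n_samples, seed = as.integer(seed),
                 values = values),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_summary %s> mean = %.4g, sd = %.4g (%d %s-level samples)\n",
    x$measure, x$mean, x$sd, x$n_samples, x$scheme))
  invisible(x)
}

#' Bootstrap effect size between two sets
#'
#' The effect size comparing a measure across two sets is
#' \deqn{s = |m_1 - m_2| / \sigma_1,}
#' where \eqn{m_1, m_2} are the bootstrap means and \eqn{\sigma_1} the
#' bootstrap standard deviation of the *first* set. The definition is
#' deliberately asymmetric: swapping the arguments changes the
#' denominator. Labels follow the conventional thresholds 0.2 (small),
#' 0.5 (medium), 0.8 (large) and 1.3 (very large).
#'
#' @param summary1,summary2 `bootstrap_summary` objects for the same
#'   measure; `summary1` supplies \eqn{\sigma_1}.
#' @return An object of class `effect_size`: list with `s`, `label`,
#'   `m1`, `m2`, `sigma1`.
#' @export
effect_size <- function(summary1, summary2) {
  stopifnot(inherits(summary1, "bootstrap_summary"),
            inherits(summary2, "bootstrap_summary"))
  if (summary1$measure != summary2$measure) {
    stop("effect size compares the same measure on two sets")
  }
  if (summary1$sd == 0) {
    stop("undefined effect size: first set has zero bootstrap sd")
  }
  s <- abs(summary1$mean - summary2$mean) / summary1$sd
  label <- if (s < 0.2) "negligible" else if (s < 0.5) "small" else
    if (s < 0.8) "medium" else if (s < 1.3) "large" else "very large"
  structure(list(s = s, label = label, m1 = summary1$mean,
                 m2 = summary2$mean, sigma1 = summary1$sd),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> s = %.3g (%s)\n", x$s, x$label))
  invisible(x)
}

#' Export bootstrap summaries as JSON-ready records
#'
#' @param summaries A `bootstrap_summary` or list of them.
#' @return A list of plain records (measure, scheme, mean, sd, n_samples,
#'   seed), suitable for `jsonlite::write_json`.
#' @export
summary_records <- function(summaries) {
  if (inherits(summaries, "bootstrap_summary")) summaries <- list(summaries)
  lapply(summaries, function(s) {
    s[c("measure", "scheme", "mean", "sd", "n_samples", "seed")]
  })
}
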