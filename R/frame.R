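#' Analysis frames of feedback triples
#'
#' A `sample_frame` bundles the long-format triples — one row per
#' (participant, time step) with self-evaluation before feedback, feedback
#' value and self-evaluation after — joined to participant covariates,
#' together with the selection metadata that produced it. All estimator
#' and bootstrap functions operate on sample frames.
#'
#' @param triples Data frame with columns `participant_id`, `t`, `a_t`,
#'   `f_t`, `a_next`, `delta_t`, `sign` (and optionally `truncated`).
#' @param participants Data frame with columns `id`, `trust`, `gender`,
#'   `self_esteem`, `scale`, `anchor`, `interview_time` (and optionally
#'   `excluded`). May be `NULL` when covariates are already joined.
#' @param selection Named list recording how the frame was selected.
#' @return An object of class `sample_frame`: a data frame of triples with
#'   covariate columns, carrying a `selection` attribute.
#' @export
sample_frame <- function(triples, participants = NULL, selection = list()) {
  need <- c("participant_id", "t", "a_t", "f_t", "a_next", "delta_t", "sign")
  miss <- setdiff(need, names(triples))
  if (length(miss)) {
    stop("triples are missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(triples)
  if (!is.null(participants)) {
    cov_need <- c("id", "trust", "gender", "self_esteem", "scale", "anchor",
                  "interview_time")
    miss <- setdiff(cov_need, names(participants))
    if (length(miss)) {
      stop("participants are missing column(s): ", paste(miss, collapse = ", "))
    }
    covs <- participants[setdiff(names(participants), "sequence")]
    df <- merge(df, covs, by.x = "participant_id", by.y = "id",
                sort = FALSE)
    df <- df[order(df$participant_id, df$t), ]
    rownames(df) <- NULL
  }
  structure(df, class = c("sample_frame", "data.frame"),
            selection = selection)
}

#' @rdname sample_frame
#' @param x A `sample_frame`.
#' @export
frame_selection <- function(x) attr(x, "selection")

#' @rdname sample_frame
#' @export
n_triples <- function(x) nrow(x)

#' @rdname sample_frame
#' @export
n_participants <- function(x) length(unique(x$participant_id))

#' @export
print.sample_frame <- function(x, ...) {
  sel <- frame_selection(x)
  cat(sprintf("<sample_frame> %d triples, %d participants\n",
              n_triples(x), n_participants(x)))
  if (length(sel)) {
    cat("  selection:", paste(names(sel), vapply(sel, function(v)
      paste(format(v), collapse = ":"), ""), sep = "=", collapse = "; "),
      "\n")
  }
  invisible(x)
}

# keep the class/attributes through `[` subsetting on rows
#' @export
`[.sample_frame` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "selection") <- attr(x, "selection")
    class(out) <- c("sample_frame", "data.frame")
  }
  out
}

#' Map rank-scale rows onto the increasing score scale
#'
#' Analyses use a single increasing scale. Rank values (1 best) are
#' transformed to `100 - r` for both self-evaluations and feedbacks of
#' rank-condition rows; score-condition rows pass through unchanged. The
#' sign of each feedback is flipped accordingly; intensities are
#' unaffected. A rank of 101 (worst possible) would map to -1 and is
#' clamped to 0; the number of clamped values is reported via a message.
#'
#' @param frame A [sample_frame] with a `scale` covariate column.
#' @return The transformed frame, with `scale` left as a record of the
#'   original condition.
#' @export
rank_to_score <- function(frame) {
  stopifnot(inherits(frame, "sample_frame"))
  if (is.null(frame$scale)) stop("frame has no 'scale' covariate column")
  is_rank <- frame$scale == "rank"
  clamped <- 0L
  for (col in c("a_t", "f_t", "a_next")) {
    v <- 100 - frame[[col]][is_rank]
    clamped <- clamped + sum(v < 0)
    frame[[col]][is_rank] <- pmax(v, 0)
  }
  frame$sign[is_rank] <- -frame$sign[is_rank]
  if (clamped > 0) {
    message(clamped, " rank value(s) of 101 mapped below 0; clamped to 0")
  }
  sel <- attr(frame, "selection")
  sel$rescaled <- TRUE
  attr(frame, "selection") <- sel
  frame
}

#' Drop participants whose planned feedback series was unbalanced
#'
#' A feedback is truncated when the planned value `a_t +/- (delta +/-
#' epsilon)` would leave \[1, 100\]: the participant's series of two
#' positive and two negative feedbacks of equal intensity could not be
#' applied, so all four of their triples are removed. Truncation is
#' detected from the intensity (`delta_t` outside
#' `{delta - epsilon, delta + epsilon}`); a pre-computed `truncated` or
#' participant-level `excluded` column, when present, is honored as well.
#'
#' @param frame A [sample_frame].
#' @param delta,epsilon Protocol intensity parameters.
#' @param quiet Suppress the message reporting removals?
#' @return The filtered frame; the number of removed participants is
#'   recorded in the selection metadata.
#' @export
filter_excluded <- function(frame, delta = 13, epsilon = 1, quiet = FALSE) {
  stopifnot(inherits(frame, "sample_frame"))
  bad_row <- !(frame$delta_t %in% c(delta - epsilon, delta + epsilon))
  if (!is.null(frame$truncated)) bad_row <- bad_row | frame$truncated
  if (!is.null(frame$excluded)) bad_row <- bad_row | frame$excluded
  bad_participants <- unique(frame$participant_id[bad_row])
  keep <- !(frame$participant_id %in% bad_participants)
  out <- frame[keep, , drop = FALSE]
  rownames(out) <- NULL
  sel <- attr(out, "selection")
  sel$excluded_participants <- length(bad_participants)
  attr(out, "selection") <- sel
  if (!quiet && length(bad_participants)) {
    message("removed ", length(bad_participants),
            " participant(s) with truncated feedback series")
  }
  out
}

#' Select an analysis subset
#'
#' Applies the selection criteria used throughout the result treatment:
#' closed trust intervals, time-step ranges, scale/gender filters, the
#' self-esteem split at 3 (`"low"` is `<= 3`, `"high"` is `> 3`), a
#' minimum interview duration, and optionally the requirement that every
#' retained participant contributes all four time steps (needed by the
#' total-bias measure).
#'
#' @param frame A [sample_frame].
#' @param trust Closed integer interval, e.g. `c(7, 10)`; `NULL` keeps all.
#' @param timesteps Time steps to keep, e.g. `1:3` or `4`.
#' @param scale `"rank"`, `"score"` or `NULL`.
#' @param gender Value(s) to keep, or `NULL`.
#' @param self_esteem `"low"` (`<= 3`), `"high"` (`> 3`) or `NULL`.
#' @param min_interview_time Minimum duration in seconds, or `NULL`.
#' @param require_complete_series Drop participants missing any of the
#'   four steps *after* filtering?
#' @return A [sample_frame] whose selection metadata records the criteria.
#' @export
subset_frame <- function(frame, trust = NULL, timesteps = NULL, scale = NULL,
                         gender = NULL, self_esteem = NULL,
                         min_interview_time = NULL,
                         require_complete_series = FALSE) {
  stopifnot(inherits(frame, "sample_frame"))
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(trust)) {
    stopifnot(length(trust) == 2, trust[1] >= 0, trust[2] <= 10)
    keep <- keep & frame$trust >= trust[1] & frame$trust <= trust[2]
  }
  if (!is.null(timesteps)) {
    stopifnot(all(timesteps %in% 1:4))
    keep <- keep & frame$t %in% timesteps
  }
  if (!is.null(scale)) keep <- keep & frame$scale %in% scale
  if (!is.null(gender)) keep <- keep & frame$gender %in% gender
  if (!is.null(self_esteem)) {
    self_esteem <- match.arg(self_esteem, c("low", "high"))
    keep <- keep & if (self_esteem == "low") frame$self_esteem <= 3 else
      frame$self_esteem > 3
  }
  if (!is.null(min_interview_time)) {
    keep <- keep & frame$interview_time >= min_interview_time
  }
  out <- frame[keep, , drop = FALSE]
  if (require_complete_series) {
    steps <- if (is.null(timesteps)) 1:4 else sort(unique(timesteps))
    counts <- table(out$participant_id)
    complete <- names(counts)[counts == length(steps)]
    out <- out[out$participant_id %in% complete, , drop = FALSE]
  }
  rownames(out) <- NULL
  sel <- attr(frame, "selection")
  crit <- list(trust = trust, timesteps = timesteps, scale = scale,
               gender = gender, self_esteem = self_esteem,
               min_interview_time = min_interview_time,
               require_complete_series = require_complete_series)
  attr(out, "selection") <- utils::modifyList(sel %||% list(),
                                              Filter(Negate(is.null), crit))
  attr(out, "empty") <- nrow(out) == 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate triples against the protocol invariants
#'
#' Checks, row by row, that the response lies in the closed interval
#' between the previous self-evaluation and the feedback, that recorded
#' intensities match `|f_t - a_t|`, that intensities of unflagged rows
#' are positive, and that time steps are in 1..4.
#'
#' @param frame A [sample_frame] (or plain triples data frame).
#' @return A data frame of violations (zero rows when clean) with columns
#'   `row`, `participant_id`, `t`, `problem`.
#' @export
validate_triples <- function(frame) {
  probs <- list()
  flag <- if (!is.null(frame$truncated)) frame$truncated else
    rep(FALSE, nrow(frame))
  note <- function(idx, what) {
    if (any(idx)) {
      probs[[length(probs) + 1L]] <<- data.frame(
        row = which(idx), participant_id = frame$participant_id[idx],
        t = frame$t[idx], problem = what)
    }
  }
  lo <- pmin(frame$a_t, frame$f_t)
  hi <- pmax(frame$a_t, frame$f_t)
  note(frame$a_next < lo | frame$a_next > hi,
       "a_next outside [a_t, f_t] interval")
  note(abs(frame$delta_t - abs(frame$f_t - frame$a_t)) > 1e-9,
       "delta_t does not equal |f_t - a_t|")
  note(!flag & frame$delta_t <= 0, "non-positive intensity in unflagged row")
  note(!frame$t %in% 1:4, "time step outside 1..4")
  note(frame$sign * (frame$f_t - frame$a_t) < 0,
       "sign inconsistent with f_t - a_t")
  if (length(probs)) do.call(rbind, probs) else
    data.frame(row = integer(), participant_id = integer(), t = integer(),
               problem = character())
}

#' Read and write triples / participants CSV files
#'
#' Plain-CSV round trips of the canonical long format. The reader
#' validates the schema and the protocol invariants and fails with an
#' itemized report when rows violate them (use `validate = FALSE` to load
#' data for inspection). `col_map` renames external column names onto the
#' canonical schema, e.g. `c(participant_id = "subj")` when the file calls
#' the participant column `subj`.
#'
#' @param path CSV file path.
#' @param validate Check invariants on read?
#' @param col_map Named character vector mapping canonical names to the
#'   file's column names.
#' @return `read_triples`/`read_participants` return data frames;
#'   `write_*` return the path invisibly.
#' @export
read_triples <- function(path, validate = TRUE, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  need <- c("participant_id", "t", "a_t", "f_t", "a_next", "delta_t", "sign")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("triples file is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (validate) {
    v <- validate_triples(df)
    if (nrow(v)) {
      stop("invalid triples (", nrow(v), " violation(s)); first: row ",
           v$row[1], " - ", v$problem[1])
    }
  }
  df
}

#' @rdname read_triples
#' @param triples,participants Data frames to write.
#' @export
write_triples <- function(triples, path) {
  utils::write.csv(as.data.frame(triples)[, c(
    "participant_id", "t", "a_t", "f_t", "a_next", "delta_t", "sign",
    intersect("truncated", names(triples)))],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_triples
#' @export
read_participants <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  need <- c("id", "trust", "gender", "self_esteem", "scale", "anchor",
            "interview_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("participants file is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_triples
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(as.data.frame(participants), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
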