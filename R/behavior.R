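#' Recall accuracy for one sequence repetition
#'
#' Cumulative sequence knowledge: the ratio of correct responses to the
#' total number of stimuli in the repetition.
#'
#' @param responses Logical (or 0/1) vector of graded responses.
#' @param n_expected Expected number of responses (default 8).
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(responses, n_expected = 8) {
  if (length(responses) != n_expected)
    stop(sprintf("expected %d graded responses, got %d", n_expected,
                 length(responses)), call. = FALSE)
  sum(as.logical(responses)) / n_expected
}

#' Sequence completion under the stopping rule
#'
#' A sequence ends after the participant recalls it fully correctly
#' `need_correct` times in total (not necessarily consecutively), or after
#' `max_repetitions`, whichever comes first.
#'
#' @param fully_correct Ordered logical vector of fully-correct flags, one
#'   per performed repetition (at most `max_repetitions`).
#' @param need_correct Required total of fully-correct recalls (default 3).
#' @param max_repetitions Maximum repetitions (default 8).
#' @return List with `repetitions_used` and `terminated_early`.
#' @export
completion <- function(fully_correct, need_correct = 3, max_repetitions = 8) {
  fully_correct <- as.logical(fully_correct)
  hit <- which(cumsum(fully_correct) >= need_correct)
  if (length(hit)) {
    list(repetitions_used = hit[1], terminated_early = hit[1] < max_repetitions)
  } else {
    list(repetitions_used = max_repetitions, terminated_early = FALSE)
  }
}

#' Learning-state labels from per-item recall history
#'
#' Default cumulative rule, driven by the number of correct recalls of the
#' item up to and including the current repetition: 0 = `unknown`,
#' 1 = `newly_learned`, 2 = `known`, >= 3 = `very_well_known`. The rule is
#' monotone (no demotion). Thresholds are configurable; the rule is a
#' documented package default, applied per item.
#'
#' @param correct Logical vector: the item's correctness across repetitions.
#' @param thresholds Integer cumulative-correct counts at which the item
#'   becomes newly learned / known / very well known.
#' @return Factor vector of states, one per repetition.
#' @export
label_learning_states <- function(correct, thresholds = c(1, 2, 3)) {
  cum <- cumsum(as.logical(correct))
  lv <- c("unknown", "newly_learned", "known", "very_well_known")
  state <- lv[1 + findInterval(cum, thresholds)]
  factor(state, levels = lv, ordered = TRUE)
}

#' Distance to the first fully-correct recall
#'
#' Aligns a sequence's repetitions to the first fully-correct recall:
#' that repetition gets distance 0, earlier repetitions negative and later
#' ones positive distances. All-missing when the sequence is never fully
#' recalled.
#'
#' @param fully_correct Ordered logical vector of fully-correct flags.
#' @return Integer vector of distances (NA when no full recall exists).
#' @export
align_to_first_recall <- function(fully_correct) {
  fully_correct <- as.logical(fully_correct)
  first <- which(fully_correct)[1]
  if (is.na(first)) return(rep(NA_integer_, length(fully_correct)))
  seq_along(fully_correct) - first
}

#' Fixation classification from a gaze trace
#'
#' A trial keeps fixation when the gaze stays inside a centered square of
#' side `square_side_deg` (Chebyshev norm, inclusive boundary) for at least
#' `min_fraction` of the stimulus presentation (boundary inclusive: exactly
#' 90% inside counts as kept).
#'
#' @param x,y Gaze coordinates in degrees of visual angle, centered on the
#'   fixation dot.
#' @param square_side_deg Side of the square (default 1.26 degrees).
#' @param min_fraction Minimum inside fraction (default 0.9).
#' @return `TRUE` (kept) or `FALSE` (lost).
#' @export
classify_fixation <- function(x, y, square_side_deg = 1.26,
                              min_fraction = 0.9) {
  if (!length(x) || length(x) != length(y))
    stop("gaze trace must be non-empty with matching x/y", call. = FALSE)
  inside <- pmax(abs(x), abs(y)) <= square_side_deg / 2
  mean(inside) >= min_fraction
}

#' Score a behavior table
#'
#' Adds the derived behavioral measures to a per-repetition behavior table
#' (as produced by [generate_behavior()]): per-sequence completion,
#' distance-to-first-recall alignment and, when per-item responses are
#' available, per-item learning states (stored as a list-column of state
#' factors).
#'
#' @param behavior Tibble with columns `subject`, `sequence`, `repetition`,
#'   `fully_correct`, optionally `responses` (list of per-item logicals).
#' @param need_correct,max_repetitions Stopping-rule parameters.
#' @return The table with columns `distance`, `repetitions_used`,
#'   `terminated_early` and (if responses exist) `item_states`.
#' @export
score_behavior <- function(behavior, need_correct = 3, max_repetitions = 8) {
  scored <- behavior |>
    dplyr::group_by(.data$subject, .data$sequence) |>
    dplyr::arrange(.data$repetition, .by_group = TRUE) |>
    dplyr::mutate(
      distance = align_to_first_recall(.data$fully_correct),
      repetitions_used = completion(.data$fully_correct, need_correct,
                                    max_repetitions)$repetitions_used,
      terminated_early = completion(.data$fully_correct, need_correct,
                                    max_repetitions)$terminated_early
    ) |>
    dplyr::ungroup()
  if ("responses" %in% names(behavior)) {
    scored <- scored |>
      dplyr::group_by(.data$subject, .data$sequence) |>
      dplyr::mutate(item_states = {
        m <- do.call(rbind, .data$responses)   # repetition x item
        st <- matrix(apply(m, 2, function(cc)
          as.character(label_learning_states(cc))), nrow = nrow(m))
        lapply(seq_len(nrow(m)), function(r) st[r, ])
      }) |>
      dplyr::ungroup()
  }
  scored
}

#' Exact distribution of repetitions-to-completion
#'
#' Markov-chain computation of the stopping time of the "`need_correct`
#' fully-correct recalls in total, else `max_repetitions`" rule, given the
#' per-repetition probability that all items are recalled correctly.
#' Serves as the closed-form oracle for the Monte-Carlo generator.
#'
#' @param p_full Probability that a repetition is fully correct; scalar or
#'   vector over repetitions 1..`max_repetitions`.
#' @param need_correct,max_repetitions Stopping-rule parameters.
#' @return List with `expected` (mean stopping time) and `pmf` (stopping
#'   probability by repetition).
#' @export
completion_time_distribution <- function(p_full, need_correct = 3,
                                         max_repetitions = 8) {
  q <- rep_len(p_full, max_repetitions)
  # state: successes accumulated before the repetition, given not stopped
  prob <- matrix(0, max_repetitions + 1, need_correct)
  prob[1, 1] <- 1
  pmf <- numeric(max_repetitions)
  for (r in seq_len(max_repetitions)) {
    for (s in 0:(need_correct - 1)) {
      p <- prob[r, s + 1]
      if (p == 0) next
      if (r == max_repetitions) {
        pmf[r] <- pmf[r] + p
        next
      }
      if (s + 1 == need_correct) {
        pmf[r] <- pmf[r] + p * q[r]
      } else {
        prob[r + 1, s + 2] <- prob[r + 1, s + 2] + p * q[r]
      }
      prob[r + 1, s + 1] <- prob[r + 1, s + 1] + p * (1 - q[r])
    }
  }
  list(expected = sum(pmf * seq_len(max_repetitions)), pmf = pmf)
}
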