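#' Generate a power-level mediation dataset with known path coefficients
#'
#' Draws per-subject, per-repetition pre-stimulus power and event-related
#' (ERS/ERD) values from the two-equation linear mixed system
#' \deqn{prestim = a \cdot rep + u_1 + \epsilon_1}
#' \deqn{outcome = b \cdot prestim + c' \cdot rep + u_2 + \epsilon_2}
#' with independent random subject intercepts per equation
#' (`subject_intercept_sd`) and residual noise (`residual_sd`). The path
#' coefficients `a`, `b`, `c'` come from the config, so the true ACME
#' (`a*b`), ADE (`c'`) and total effect are known by construction.
#'
#' @param config A [sim_config()]; path coefficients and variance components
#'   are taken from it.
#' @param n_subjects Total number of subjects; defaults to
#'   `2 * n_subjects_per_group` split over the config groups.
#' @param standardize If `TRUE`, z-score `prestim` and `outcome` columns
#'   before returning (the repetition column is left on its 1..8 scale).
#' @return Tibble with columns `subject`, `group`, `repetition`, `prestim`,
#'   `outcome`. True path values are attached as attribute `paths`.
#' @export
generate_power_table <- function(config, n_subjects = NULL,
                                 standardize = FALSE) {
  validate_sim_config(config)
  if (config$subject_intercept_sd < 0 || config$residual_sd < 0)
    stop("variance components must be >= 0", call. = FALSE)
  withr::local_seed(config$seed + 2L)
  if (is.null(n_subjects))
    n_subjects <- config$n_subjects_per_group * length(config$groups)
  grp <- rep_len(config$groups, n_subjects)
  reps <- seq_len(config$max_repetitions)
  u1 <- rnorm(n_subjects, 0, config$subject_intercept_sd)
  u2 <- rnorm(n_subjects, 0, config$subject_intercept_sd)
  tab <- tidyr::expand_grid(id = seq_len(n_subjects), repetition = reps) |>
    dplyr::mutate(
      subject = sprintf("s%03d", .data$id),
      group = grp[.data$id],
      prestim = config$path_a * .data$repetition + u1[.data$id] +
        rnorm(dplyr::n(), 0, config$residual_sd),
      outcome = config$path_b * .data$prestim +
        config$path_c_prime * .data$repetition + u2[.data$id] +
        rnorm(dplyr::n(), 0, config$residual_sd)
    ) |>
    dplyr::select("subject", "group", "repetition", "prestim", "outcome")
  if (standardize)
    tab <- standardize(tab, c("prestim", "outcome"))
  attr(tab, "paths") <- c(a = config$path_a, b = config$path_b,
                          c_prime = config$path_c_prime,
                          acme = config$path_a * config$path_b,
                          ade = config$path_c_prime)
  tab
}

#' Generate synthetic recall behavior
#'
#' Simulates the sequence-learning task: per sequence and repetition, eight
#' per-item correctness draws from a logistic learning curve
#' (`plogis(slope * (repetition - offset))`, per group). A sequence ends
#' after `completion_correct_total` fully-correct repetitions (not
#' necessarily consecutive) or after `max_repetitions`, whichever comes
#' first.
#'
#' @param config A [sim_config()].
#' @param item_prob Optional fixed per-item success probability overriding
#'   the learning curve (scalar or vector over repetitions); useful for
#'   exercising the stopping rule.
#' @return A behavior table: one row per performed repetition with columns
#'   `subject`, `group`, `sequence`, `repetition`, `n_correct`, `n_total`,
#'   `accuracy`, `fully_correct`, and a list-column `responses` holding the
#'   per-item logical correctness vector.
#' @export
generate_behavior <- function(config, item_prob = NULL) {
  validate_sim_config(config)
  subjects <- draw_subjects(config)
  withr::local_seed(config$seed + 3L)
  n_item <- config$n_stimuli
  need <- config$completion_correct_total
  maxr <- config$max_repetitions
  if (!is.null(item_prob)) item_prob <- rep_len(item_prob, maxr)

  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    g <- subjects$group[i]
    p_curve <- if (is.null(item_prob)) {
      plogis(config$learning_slope[[g]] *
               (seq_len(maxr) - config$learning_offset[[g]]))
    } else item_prob
    for (sq in seq_len(config$n_sequences)) {
      n_full <- 0L
      for (r in seq_len(maxr)) {
        correct <- runif(n_item) < p_curve[r]
        full <- all(correct)
        if (full) n_full <- n_full + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subjects$subject[i], group = g,
          sequence = sq, repetition = r,
          n_correct = sum(correct), n_total = n_item,
          accuracy = sum(correct) / n_item,
          fully_correct = full,
          responses = list(correct)
        )
        if (n_full >= need) break
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate synthetic gaze traces
#'
#' Produces gaze sample tables (x, y in degrees of visual angle at the
#' config sampling rate over one stimulus presentation period) with a
#' configurable fraction of samples inside the central fixation square, for
#' exercising the fixation classifier. Inside samples jitter tightly around
#' the fixation dot; outside samples sit at an eccentric location.
#'
#' @param config A [sim_config()].
#' @param n_traces Number of traces to generate.
#' @param inside_fraction Fraction of each trace's samples inside the
#'   central square (scalar or vector over traces). Defaults to draws that
#'   are fully inside with probability `fixation_kept_prob` and 50% inside
#'   otherwise.
#' @param square_side_deg Side of the central square in degrees.
#' @return Tibble with columns `trace`, `t` (ms), `x`, `y` (degrees), and
#'   the generating `inside` flag per sample.
#' @export
generate_gaze <- function(config, n_traces = 10, inside_fraction = NULL,
                          square_side_deg = 1.26) {
  validate_sim_config(config)
  withr::local_seed(config$seed + 4L)
  n <- round(config$stimulus_duration / 1000 * config$sampling_rate)
  if (is.null(inside_fraction)) {
    inside_fraction <- ifelse(runif(n_traces) < config$fixation_kept_prob,
                              1, 0.5)
  }
  inside_fraction <- rep_len(inside_fraction, n_traces)
  half <- square_side_deg / 2
  purrr::map_dfr(seq_len(n_traces), function(i) {
    n_in <- round(inside_fraction[i] * n)
    inside <- seq_len(n) <= n_in     # leading block inside, remainder outside
    x <- ifelse(inside, runif(n, -half * 0.8, half * 0.8), 5 + runif(n, 0, 0.5))
    y <- ifelse(inside, runif(n, -half * 0.8, half * 0.8), 5 + runif(n, 0, 0.5))
    tibble::tibble(trace = i,
                   t = (seq_len(n) - 1) * 1000 / config$sampling_rate,
                   x = x, y = y, inside = inside)
  })
}
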