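#' Baseline-correction scenario curves
#'
#' Builds the simulation illustrating how per-repetition baseline correction
#' conflates pre- and post-stimulus power changes. A reference repetition-1
#' curve (flat pre-stimulus level, raised-cosine post-stimulus dip with
#' recovery) is paired with four repetition-2 variants:
#' \describe{
#'   \item{A}{pre-stimulus increase, post level unchanged}
#'   \item{B}{post-stimulus decrease, pre level unchanged}
#'   \item{C}{pre-stimulus increase and post-stimulus decrease}
#'   \item{D}{decrease in both pre- and post-stimulus phases}
#' }
#' The defining calibration is that all four variants share the same
#' post-minus-pre level shift `d = -(pre_delta_magnitude +
#' post_delta_magnitude)`, which makes their per-repetition-corrected curves
#' *exactly* identical (the conflation). With magnitudes `(mp, mq)` the
#' level deltas are A `(mp+mq, 0)`, B `(0, -(mp+mq))`, C `(mp, -mq)`,
#' D `(-mp, -(2mp+mq))`.
#'
#' @param pre_delta_magnitude,post_delta_magnitude Positive level-shift
#'   magnitudes (arbitrary power units).
#' @param time_grid Time axis in ms; stimulus onset at 0.
#' @param ref_level Reference pre-stimulus power level.
#' @param dip_depth Depth of the post-stimulus desynchronization dip.
#' @param dip_duration Duration of the dip (ms).
#' @param ramp_duration Raised-cosine ramp (ms) over which a scenario's
#'   post-stimulus level shift fades in after onset.
#' @return Tibble of class `scenario_set`: columns `scenario`
#'   (`"reference"`, `"A"`..`"D"`), `repetition` (1 for reference, 2
#'   otherwise), `time`, `power`, `pre_delta`, `post_delta`.
#' @export
build_scenarios <- function(pre_delta_magnitude = 0.1,
                            post_delta_magnitude = 0.1,
                            time_grid = seq(-500, 900, by = 10),
                            ref_level = 1,
                            dip_depth = 0.4,
                            dip_duration = 600,
                            ramp_duration = 200) {
  stopifnot(pre_delta_magnitude > 0, post_delta_magnitude > 0)
  mp <- pre_delta_magnitude; mq <- post_delta_magnitude
  d <- -(mp + mq)
  deltas <- tibble::tibble(
    scenario = c("reference", "A", "B", "C", "D"),
    repetition = c(1L, 2L, 2L, 2L, 2L),
    pre_delta = c(0, mp + mq, 0, mp, -mp),
    post_delta = c(0, 0, -(mp + mq), -mq, -(2 * mp + mq))
  )
  t <- time_grid
  dip <- ifelse(t >= 0 & t <= dip_duration,
                -dip_depth * (1 - cos(2 * pi * t / dip_duration)) / 2, 0)
  ramp <- ifelse(t < 0, 0,
                 ifelse(t >= ramp_duration, 1,
                        (1 - cos(pi * t / ramp_duration)) / 2))
  out <- purrr::pmap_dfr(deltas, function(scenario, repetition,
                                          pre_delta, post_delta) {
    shift <- if (scenario == "reference") 0 else d
    tibble::tibble(scenario = scenario, repetition = repetition, time = t,
                   power = ref_level + pre_delta + dip + shift * ramp,
                   pre_delta = pre_delta, post_delta = post_delta)
  })
  class(out) <- c("scenario_set", class(out))
  out
}

#' Apply a baseline-correction scheme to scenario curves
#'
#' `per_repetition` subtracts each repetition's own pre-stimulus baseline
#' mean (the state-of-the-art ERD correction, which sets pre-stimulus
#' activity to 0 and hides where a power change happened). `per_subject`
#' subtracts the across-repetition mean baseline of the scenario's subject
#' (reference + variant), preserving pre-stimulus differences and thereby
#' disambiguating pre- from post-stimulus changes. With a single repetition
#' the two schemes coincide.
#'
#' @param trajectories A tibble from [build_scenarios()] (columns
#'   `scenario`, `repetition`, `time`, `power`); curves share the time grid
#'   with onset at 0.
#' @param scheme `"per_repetition"` or `"per_subject"`.
#' @param baseline_window Baseline interval in ms (default -500..-250).
#' @return The input with a `corrected` column.
#' @export
apply_scheme <- function(trajectories,
                         scheme = c("per_repetition", "per_subject"),
                         baseline_window = c(-500, -250)) {
  scheme <- match.arg(scheme)
  in_base <- function(time) {
    time >= baseline_window[1] & time <= baseline_window[2]
  }
  if (scheme == "per_repetition") {
    out <- trajectories |>
      dplyr::group_by(.data$scenario, .data$repetition) |>
      dplyr::mutate(corrected = .data$power -
                      mean(.data$power[in_base(.data$time)])) |>
      dplyr::ungroup()
  } else {
    # the subject's average baseline pools the reference repetition with
    # the scenario's second repetition
    ref <- dplyr::filter(trajectories, .data$scenario == "reference")
    ref_base <- mean(ref$power[in_base(ref$time)])
    out <- trajectories |>
      dplyr::group_by(.data$scenario) |>
      dplyr::mutate(
        avg_base = if (.data$scenario[1] == "reference") ref_base else
          (ref_base + mean(.data$power[in_base(.data$time) &
                                         .data$repetition == 2])) / 2,
        corrected = .data$power - .data$avg_base
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-"avg_base")
  }
  out$scheme <- scheme
  out
}
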