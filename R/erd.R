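#' Average band power in a time-frequency window
#'
#' Averages log-power over selected channels, frequency bins and time bins
#' of a spectral tensor. A bin contributes when its center lies inside the
#' closed interval.
#'
#' @param tensor A `spectral_tensor` (typically aperiodic-adjusted).
#' @param band Frequency interval in Hz, length-2.
#' @param window Time interval in ms, length-2.
#' @param channels Channel labels, or a region name present in the tensor's
#'   montage (`"midfrontal"`, `"parietal"`).
#' @return Tibble: the tensor's repetition metadata plus a `power` column
#'   (mean log10 power per repetition row).
#' @export
extract_band_power <- function(tensor, band, window, channels = NULL) {
  stopifnot(inherits(tensor, "spectral_tensor"))
  ch_lab <- tensor$channels$channel
  if (is.null(channels)) {
    ch <- seq_along(ch_lab)
  } else if (length(channels) == 1 && channels %in% tensor$channels$region) {
    ch <- which(tensor$channels$region == channels)
  } else {
    ch <- match(channels, ch_lab)
    if (anyNA(ch)) stop("unknown channel labels", call. = FALSE)
  }
  fi <- which(tensor$frequencies >= band[1] - 1e-9 &
                tensor$frequencies <= band[2] + 1e-9)
  ti <- which(tensor$times >= window[1] - 1e-9 &
                tensor$times <= window[2] + 1e-9)
  if (!length(ch) || !length(fi) || !length(ti))
    stop("empty channel/frequency/time selection", call. = FALSE)
  sub <- tensor$log_power[, ch, fi, ti, drop = FALSE]
  dplyr::mutate(tensor$repetitions,
                power = apply(sub, 1, mean))
}

#' Event-related power under per-repetition baseline correction
#'
#' For log-scaled (aperiodic-adjusted) power, the event-related response of
#' a sequence repetition is the post-stimulus power minus that repetition's
#' own baseline power: negative values indicate desynchronization (ERD),
#' positive values synchronization (ERS).
#'
#' @param post_power_sr,baseline_sr Log10 power values (vectors align).
#' @return `post_power_sr - baseline_sr`.
#' @export
ers_erd_per_repetition <- function(post_power_sr, baseline_sr) {
  post_power_sr - baseline_sr
}

#' Conventional (non-adjusted) event-related power in dB
#'
#' For linear-scale power the conventional measure is
#' `10 * log10(post / baseline)` dB.
#'
#' @param post_linear,baseline_linear Strictly positive linear power.
#' @return Event-related power in dB.
#' @export
ers_erd_conventional <- function(post_linear, baseline_linear) {
  if (any(post_linear <= 0) || any(baseline_linear <= 0))
    stop("linear power must be strictly positive", call. = FALSE)
  10 * log10(post_linear / baseline_linear)
}

#' Per-subject baseline scheme and the pre-stimulus activity term
#'
#' Completes a band-power table with the per-subject baseline-correction
#' scheme: within each subject x sequence (x band x region) cell the
#' *average baseline* is the mean of `baseline_sr` over that sequence's
#' repetitions; `prestim_sr = baseline_sr - average_baseline` (zero mean
#' over repetitions by construction) and
#' `ers_erd_subj = post_power_sr - average_baseline`. The per-repetition
#' measure `ers_erd_rep = post_power_sr - baseline_sr` is (re)computed so
#' the identity `ers_erd_subj = ers_erd_rep + prestim_sr` holds exactly.
#'
#' @param table Tibble with columns `subject`, `sequence`, `post_power_sr`,
#'   `baseline_sr` and optionally `band`, `region`, `group`, `repetition`.
#' @return The table with added columns `average_baseline`, `prestim_sr`,
#'   `ers_erd_rep`, `ers_erd_subj`, `single_repetition` (flag for cells
#'   with fewer than 2 repetitions, which get a warning).
#' @export
prestim_and_subject_scheme <- function(table) {
  keys <- intersect(c("subject", "sequence", "band", "region"), names(table))
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      average_baseline = mean(.data$baseline_sr),
      prestim_sr = .data$baseline_sr - .data$average_baseline,
      ers_erd_rep = .data$post_power_sr - .data$baseline_sr,
      ers_erd_subj = .data$post_power_sr - .data$average_baseline,
      single_repetition = dplyr::n() < 2
    ) |>
    dplyr::ungroup()
  if (any(out$single_repetition))
    warning("some subject x sequence cells have a single repetition",
            call. = FALSE)
  out
}

#' Band-power table from an adjusted tensor and per-subject bands
#'
#' Builds the long per-repetition band-power table: for each band (theta on
#' the mid-frontal region, alpha on the parietal region by default) the
#' post-stimulus window power and the baseline-window power are extracted
#' with the subject's IAF-relative band, then both baseline-correction
#' schemes are applied via [prestim_and_subject_scheme()].
#'
#' @param tensor Aperiodic-adjusted `spectral_tensor`.
#' @param bands Tibble mapping subjects to band definitions: columns
#'   `subject`, `band`, `f_lo`, `f_hi`, `t_lo`, `t_hi`, `baseline_lo`,
#'   `baseline_hi` (see [bands_from_iaf()]).
#' @param regions Named character vector mapping band name to region.
#' @return A band-power table (see [prestim_and_subject_scheme()]).
#' @export
band_power_table <- function(tensor, bands,
                             regions = c(theta = "midfrontal",
                                         alpha = "parietal")) {
  rows <- purrr::pmap_dfr(
    dplyr::distinct(bands, .data$subject, .data$band, .keep_all = TRUE),
    function(subject, band, f_lo, f_hi, t_lo, t_hi,
             baseline_lo, baseline_hi, ...) {
      region <- regions[[band]]
      post <- extract_band_power(tensor, c(f_lo, f_hi), c(t_lo, t_hi), region)
      base <- extract_band_power(tensor, c(f_lo, f_hi),
                                 c(baseline_lo, baseline_hi), region)
      out <- post[post$subject == subject, ]
      names(out)[names(out) == "power"] <- "post_power_sr"
      out$baseline_sr <- base$power[base$subject == subject]
      out$band <- band
      out$region <- region
      out
    })
  prestim_and_subject_scheme(rows)
}
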