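#' Default channel montage
#'
#' Generic montage with a mid-frontal and a parietal cluster. Cluster sizes
#' default to 8 frontal and 23 parietal channels, mirroring the cluster sizes
#' commonly used for mid-frontal theta and parietal alpha analyses on
#' high-density nets. EGI-style E-numbers are accepted as channel labels.
#'
#' @param n_frontal Number of mid-frontal channels.
#' @param n_parietal Number of parietal channels.
#' @param frontal,parietal Optional explicit character vectors of channel
#'   labels; when supplied they override the counts.
#' @return A tibble with columns `channel` and `region`
#'   (`"midfrontal"` / `"parietal"`).
#' @export
default_montage <- function(n_frontal = 8, n_parietal = 23,
                            frontal = NULL, parietal = NULL) {
  if (is.null(frontal)) frontal <- paste0("F", seq_len(n_frontal))
  if (is.null(parietal)) parietal <- paste0("P", seq_len(n_parietal))
  tibble::tibble(
    channel = c(frontal, parietal),
    region = c(rep("midfrontal", length(frontal)),
               rep("parietal", length(parietal)))
  )
}

#' EGI-128 cluster preset
#'
#' Named preset with the 8 mid-frontal and 23 parietal electrodes of the
#' 128-channel hydrogel geodesic net commonly used for these analyses.
#' @return A tibble with columns `channel` and `region`.
#' @export
egi128_clusters <- function() {
  default_montage(
    frontal = c("E5", "E6", "E7", "E11", "E12", "E106", "E13", "E112"),
    parietal = c("E75", "E70", "E83", "E62", "E72", "E67", "E71", "E77",
                 "E76", "E52", "E65", "E60", "E61", "E59", "E66", "E78",
                 "E90", "E92", "E85", "E84", "E91", "E58", "E96")
  )
}

grp_param <- function(x, groups, what) {
  if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, length(groups)), groups)
  if (!all(groups %in% names(x)))
    stop(sprintf("`%s` must be named with all groups: %s", what,
                 paste(groups, collapse = ", ")), call. = FALSE)
  x[groups]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: task structure,
#' epoching, the aperiodic (1/f) background, subject alpha oscillations,
#' post-stimulus theta bursts, the mediation path system, the behavioral
#' learning curve, and gaze/fixation behavior. All downstream generators are
#' deterministic given a config (the `seed` is part of the config).
#'
#' Trajectory parameters (`alpha_amp_pre`, `alpha_amp_post`,
#' `theta_burst_amp`) may be single values or vectors over repetitions
#' (recycled to `max_repetitions`), allowing learning-dependent drift of
#' pre- and post-stimulus band power.
#'
#' Group defaults: the aperiodic exponent is 1.5 for young and 1.3 for older
#' subjects (older spectra are flatter); group IAF distributions default to
#' 10.5277 +/- 1.2478 Hz (young) and 10.2362 +/- 1.4032 Hz (older). IAF draws
#' are truncated to `iaf_range` so each simulated subject carries a peak
#' detectable inside the 7-14 Hz search range.
#'
#' @param n_subjects_per_group Subjects per age group.
#' @param groups Group labels (default `c("young", "older")`).
#' @param n_sequences Sequences learned per subject (default 6).
#' @param max_repetitions Maximum sequence repetitions (default 8).
#' @param completion_correct_total Fully-correct recalls that end a sequence
#'   (default 3; not necessarily consecutive).
#' @param n_stimuli Stimuli per repetition (default 8).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param epoch_window Epoch limits in ms relative to stimulus onset
#'   (default `c(-750, 1150)`).
#' @param stimulus_duration Stimulus duration in ms (default 600).
#' @param offset_to_onset_isi Offset-to-onset interval in ms (default 1300).
#' @param aperiodic_offset,aperiodic_exponent Aperiodic background per group:
#'   log10-power offset and (positive) exponent of the 1/f background.
#' @param iaf_mean,iaf_sd Group IAF distribution in Hz.
#' @param iaf_range Truncation range for IAF draws.
#' @param alpha_amp_pre,alpha_amp_post Alpha sinusoid amplitude (uV) before /
#'   after stimulus onset; vectors are trajectories over repetitions.
#' @param theta_burst_amp Amplitude (uV) of the post-stimulus theta burst;
#'   vector = trajectory over repetitions.
#' @param theta_burst_latency Burst center latency in ms after onset.
#' @param theta_burst_duration Burst duration (Hanning envelope) in ms.
#' @param path_a,path_b,path_c_prime Mediation path coefficients used by
#'   [generate_power_table()]: treatment->mediator (`a`), mediator->outcome
#'   (`b`) and direct treatment->outcome (`c'`), in standardized units.
#' @param subject_intercept_sd,residual_sd Variance components of the
#'   two-equation mediation system (standardized units).
#' @param learning_slope,learning_offset Logistic learning curve per group:
#'   per-item recall probability at repetition r is
#'   `plogis(slope * (r - offset))`.
#' @param fixation_kept_prob Probability that fixation is kept on a stimulus.
#' @param channels Channel montage tibble (`channel`, `region`); see
#'   [default_montage()] and [egi128_clusters()].
#' @param seed Integer seed; every generator derives its randomness from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects_per_group = 20,
                       groups = c("young", "older"),
                       n_sequences = 6,
                       max_repetitions = 8,
                       completion_correct_total = 3,
                       n_stimuli = 8,
                       sampling_rate = 500,
                       epoch_window = c(-750, 1150),
                       stimulus_duration = 600,
                       offset_to_onset_isi = 1300,
                       aperiodic_offset = c(young = 1, older = 1),
                       aperiodic_exponent = c(young = 1.5, older = 1.3),
                       iaf_mean = c(young = 10.5277, older = 10.2362),
                       iaf_sd = c(young = 1.2478, older = 1.4032),
                       iaf_range = c(7.5, 13.5),
                       alpha_amp_pre = 2,
                       alpha_amp_post = 2,
                       theta_burst_amp = 2,
                       theta_burst_latency = 250,
                       theta_burst_duration = 400,
                       path_a = 0.15,
                       path_b = -0.6,
                       path_c_prime = -0.1,
                       subject_intercept_sd = 0.2,
                       residual_sd = 0.3,
                       learning_slope = c(young = 1.8, older = 1.8),
                       learning_offset = c(young = 0.5, older = 2.5),
                       fixation_kept_prob = 0.95,
                       channels = default_montage(),
                       seed = 1L) {
  groups <- as.character(groups)
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    groups = groups,
    n_sequences = as.integer(n_sequences),
    max_repetitions = as.integer(max_repetitions),
    completion_correct_total = as.integer(completion_correct_total),
    n_stimuli = as.integer(n_stimuli),
    sampling_rate = sampling_rate,
    epoch_window = epoch_window,
    stimulus_duration = stimulus_duration,
    offset_to_onset_isi = offset_to_onset_isi,
    aperiodic_offset = grp_param(aperiodic_offset, groups, "aperiodic_offset"),
    aperiodic_exponent = grp_param(aperiodic_exponent, groups, "aperiodic_exponent"),
    iaf_mean = grp_param(iaf_mean, groups, "iaf_mean"),
    iaf_sd = grp_param(iaf_sd, groups, "iaf_sd"),
    iaf_range = iaf_range,
    alpha_amp_pre = rep_len(alpha_amp_pre, max_repetitions),
    alpha_amp_post = rep_len(alpha_amp_post, max_repetitions),
    theta_burst_amp = rep_len(theta_burst_amp, max_repetitions),
    theta_burst_latency = theta_burst_latency,
    theta_burst_duration = theta_burst_duration,
    path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
    subject_intercept_sd = subject_intercept_sd,
    residual_sd = residual_sd,
    learning_slope = grp_param(learning_slope, groups, "learning_slope"),
    learning_offset = grp_param(learning_offset, groups, "learning_offset"),
    fixation_kept_prob = fixation_kept_prob,
    channels = channels,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the documented invariants (non-negative SDs, group IAF means in
#' \[7, 14\] Hz, epoch window spanning the analysis range and containing
#' the theta burst, stopping-rule consistency, montage schema). Called by
#' every generator; exported so external configs can be checked directly.
#'
#' @param cfg A [sim_config()].
#' @return The config, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  amps <- c(cfg$alpha_amp_pre, cfg$alpha_amp_post, cfg$theta_burst_amp)
  if (!all(is.finite(amps)))
    stop("oscillation amplitudes must be finite", call. = FALSE)
  if (any(c(cfg$iaf_sd, cfg$subject_intercept_sd, cfg$residual_sd) < 0))
    stop("all standard deviations must be >= 0", call. = FALSE)
  if (any(cfg$iaf_mean < 7 | cfg$iaf_mean > 14))
    stop("group IAF means must lie within [7, 14] Hz", call. = FALSE)
  if (cfg$max_repetitions < cfg$completion_correct_total)
    stop("max_repetitions must be >= completion_correct_total", call. = FALSE)
  if (cfg$epoch_window[1] >= cfg$epoch_window[2])
    stop("epoch_window must be an increasing ms pair", call. = FALSE)
  burst <- cfg$theta_burst_latency + c(-1, 1) * cfg$theta_burst_duration / 2
  if (burst[1] < cfg$epoch_window[1] || burst[2] > cfg$epoch_window[2])
    stop("theta burst does not fit inside the epoch window", call. = FALSE)
  if (cfg$epoch_window[1] > -500 || cfg$epoch_window[2] < 900)
    stop("epoch_window must span the -500..900 ms analysis range", call. = FALSE)
  if (cfg$fixation_kept_prob < 0 || cfg$fixation_kept_prob > 1)
    stop("fixation_kept_prob must be a probability", call. = FALSE)
  if (!all(c("channel", "region") %in% names(cfg$channels)))
    stop("channels must have columns `channel` and `region`", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects/group (%s), %d sequences x up to %d repetitions\n",
              x$n_subjects_per_group, paste(x$groups, collapse = ", "),
              x$n_sequences, x$max_repetitions))
  cat(sprintf("  fs = %g Hz, epochs %g..%g ms, %d channels, seed %d\n",
              x$sampling_rate, x$epoch_window[1], x$epoch_window[2],
              nrow(x$channels), x$seed))
  invisible(x)
}

#' Draw subject-level parameters for a configuration
#'
#' Draws each simulated subject's IAF (truncated normal per group) and
#' assigns group labels. Deterministic given the config seed; every
#' generator that needs subject identities calls this, so subjects are
#' consistent across generators.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `subject`, `group`, `iaf_true`,
#'   `aperiodic_exponent`, `aperiodic_offset`.
#' @export
draw_subjects <- function(config) {
  validate_sim_config(config)
  withr::local_seed(config$seed)
  n <- config$n_subjects_per_group
  purrr::map_dfr(config$groups, function(g) {
    iaf <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        x <- rnorm(1, config$iaf_mean[[g]], config$iaf_sd[[g]])
        if (x > config$iaf_range[1] && x < config$iaf_range[2]) break
      }
      iaf[i] <- x
    }
    tibble::tibble(
      subject = sprintf("%s_%02d", substr(g, 1, 1), seq_len(n)),
      group = g,
      iaf_true = iaf,
      aperiodic_exponent = config$aperiodic_exponent[[g]],
      aperiodic_offset = config$aperiodic_offset[[g]]
    )
  })
}
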