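#' Power-law (1/f) noise
#'
#' Synthesizes aperiodic background signal by shaping white Gaussian noise in
#' the frequency domain with amplitude proportional to
#' `10^(offset/2) * f^(-exponent/2)`, which gives exact control of the target
#' aperiodic exponent of the power spectrum (PSD proportional to
#' `10^offset * f^-exponent`).
#'
#' @param n Number of samples per trace.
#' @param fs Sampling rate in Hz.
#' @param exponent Target aperiodic exponent (positive = downward slope).
#' @param offset Log10-power offset of the background.
#' @param n_traces Number of independent traces.
#' @return A numeric matrix `n x n_traces`.
#' @export
powerlaw_noise <- function(n, fs, exponent, offset = 0, n_traces = 1) {
  w <- matrix(rnorm(n * n_traces), n, n_traces)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) * fs / n            # two-sided frequency axis
  shape <- c(0, 10^(offset / 2) * f[-1]^(-exponent / 2))
  x <- mvfft(mvfft(w) * shape, inverse = TRUE)
  Re(x) / n
}

#' Hanning (raised-cosine) taper
#'
#' The symmetric Hann window used by the sliding-window TFR, the Welch
#' spectrum estimator and the synthetic theta burst.
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Construct an epoch set
#'
#' Low-level constructor for the time-domain epoch container used throughout
#' the package. Checks the time axis (strictly increasing, uniform step of
#' `1000 / sampling_rate` ms) and that the metadata has one row per epoch.
#'
#' @param samples Numeric array `epoch x channel x time` in microvolts.
#' @param time_axis Time axis in ms relative to stimulus onset.
#' @param metadata Tibble with one row per epoch; expected columns are
#'   `subject`, `group`, `sequence`, `repetition`, `stimulus`, `fixation`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Montage tibble (`channel`, `region`); must match the
#'   second array dimension.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(samples, time_axis, metadata, sampling_rate,
                      channels = default_montage(dim(samples)[2], 0)) {
  stopifnot(length(dim(samples)) == 3)
  if (dim(samples)[3] != length(time_axis))
    stop("time_axis length must match the third array dimension", call. = FALSE)
  if (dim(samples)[1] != nrow(metadata))
    stop("metadata must have one row per epoch", call. = FALSE)
  if (dim(samples)[2] != nrow(channels))
    stop("channels must have one row per channel", call. = FALSE)
  dt <- diff(time_axis)
  if (any(dt <= 0) || max(abs(dt - 1000 / sampling_rate)) > 1e-9)
    stop("time_axis must increase uniformly with step 1000/sampling_rate ms",
         call. = FALSE)
  structure(
    list(samples = samples, time = time_axis,
         metadata = tibble::as_tibble(metadata),
         sampling_rate = sampling_rate,
         channels = tibble::as_tibble(channels)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              dim(x$samples)[1], dim(x$samples)[2], dim(x$samples)[3],
              x$sampling_rate, min(x$time), max(x$time)))
  invisible(x)
}

#' Generate synthetic epoched EEG
#'
#' Builds multi-subject, multi-sequence, multi-repetition epochs around
#' stimulus onset. Each epoch is the sum of
#' \itemize{
#'   \item power-law-shaped Gaussian noise at the group's target aperiodic
#'     exponent and offset (independent per channel);
#'   \item a continuous sinusoid at the subject's drawn IAF on the parietal
#'     channels, whose amplitude is `alpha_amp_pre[repetition]` before onset
#'     and `alpha_amp_post[repetition]` after onset (100 ms raised-cosine
#'     crossfade at onset);
#'   \item a Hanning-windowed theta burst at `IAF - 5` Hz on the mid-frontal
#'     channels, centered at `theta_burst_latency` ms post-onset with
#'     amplitude `theta_burst_amp[repetition]`.
#' }
#' Amplitude trajectories over repetitions implement learning-dependent
#' drift of pre- and post-stimulus band power. Fully reproducible from the
#' config seed. If the montage defines no parietal (or mid-frontal) region,
#' the alpha (theta) component is applied to all channels.
#'
#' @param config A [sim_config()].
#' @param sequences Which sequences to generate (default all); useful to
#'   bound memory for large configs.
#' @return An [epoch_set()].
#' @export
generate_epochs <- function(config, sequences = seq_len(config$n_sequences)) {
  validate_sim_config(config)
  subjects <- draw_subjects(config)
  withr::local_seed(config$seed + 1L)

  fs <- config$sampling_rate
  t_ms <- seq(config$epoch_window[1], config$epoch_window[2], by = 1000 / fs)
  nt <- length(t_ms)
  nch <- nrow(config$channels)
  alpha_ch <- config$channels$region == "parietal"
  if (!any(alpha_ch)) alpha_ch <- rep(TRUE, nch)
  theta_ch <- config$channels$region == "midfrontal"
  if (!any(theta_ch)) theta_ch <- rep(TRUE, nch)

  # alpha amplitude envelope: pre value before onset, post value after,
  # blended with a 100 ms raised-cosine crossfade centered on onset
  fade <- 100
  blend <- ifelse(t_ms <= -fade / 2, 0,
                  ifelse(t_ms >= fade / 2, 1,
                         (1 - cos(pi * (t_ms + fade / 2) / fade)) / 2))
  # theta burst envelope (unit peak)
  burst_env <- numeric(nt)
  in_burst <- abs(t_ms - config$theta_burst_latency) <= config$theta_burst_duration / 2
  burst_env[in_burst] <- hann_window(sum(in_burst))

  grid <- tidyr::expand_grid(
    subject = subjects$subject,
    sequence = as.integer(sequences),
    repetition = seq_len(config$max_repetitions)
  ) |> dplyr::left_join(subjects, by = "subject")

  n_stim <- config$n_stimuli
  n_epochs <- nrow(grid) * n_stim
  samples <- array(0, dim = c(n_epochs, nch, nt))
  meta <- vector("list", nrow(grid))
  t_s <- t_ms / 1000

  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rep_no <- g$repetition
    noise <- powerlaw_noise(nt, fs, g$aperiodic_exponent, g$aperiodic_offset,
                            n_traces = n_stim * nch)
    a_env <- config$alpha_amp_pre[rep_no] * (1 - blend) +
      config$alpha_amp_post[rep_no] * blend
    th_amp <- config$theta_burst_amp[rep_no]
    th_f <- g$iaf_true - 5
    block <- array(noise, dim = c(nt, nch, n_stim))
    for (s in seq_len(n_stim)) {
      ph_a <- runif(1, 0, 2 * pi)
      ph_t <- runif(1, 0, 2 * pi)
      alpha_sig <- a_env * sin(2 * pi * g$iaf_true * t_s + ph_a)
      theta_sig <- th_amp * burst_env * sin(2 * pi * th_f * t_s + ph_t)
      block[, alpha_ch, s] <- block[, alpha_ch, s] + alpha_sig
      block[, theta_ch, s] <- block[, theta_ch, s] + theta_sig
    }
    idx <- (i - 1) * n_stim + seq_len(n_stim)
    samples[idx, , ] <- aperm(block, c(3, 2, 1))
    meta[[i]] <- tibble::tibble(
      subject = g$subject, group = g$group,
      sequence = g$sequence, repetition = rep_no,
      stimulus = seq_len(n_stim),
      fixation = rbinom(n_stim, 1, config$fixation_kept_prob) == 1
    )
  }

  epoch_set(samples, t_ms, dplyr::bind_rows(meta), fs, config$channels)
}
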