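# Shared helpers for the test suite.

# Small, fast config for tests that need time-domain epochs.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_group = 1,
         n_sequences = 1,
         channels = default_montage(n_frontal = 2, n_parietal = 2),
         seed = 123L),
    list(...))
  do.call(sim_config, args)
}

# Synthetic log10 spectrum: power law + one Gaussian + optional noise.
synth_spectrum <- function(freqs, offset = 1, exponent = 1.5,
                           cf = 10, height = 0.8, gsd = 1.2,
                           noise_sd = 0) {
  offset - exponent * log10(freqs) +
    height * exp(-(freqs - cf)^2 / (2 * gsd^2)) +
    rnorm(length(freqs), 0, noise_sd)
}

# One subject's time-domain signal: power-law noise + alpha sinusoid.
alpha_signal <- function(duration_s, fs, iaf, amp, exponent = 1.5,
                         offset = 0) {
  n <- duration_s * fs
  noise <- powerlaw_noise(n, fs, exponent, offset)
  tt <- (seq_len(n) - 1) / fs
  as.vector(noise) + amp * sin(2 * pi * iaf * tt)
}

# Minimal epoch_set wrapping a given per-epoch signal matrix list.
make_epochs <- function(sig_list, fs = 500, t0 = -750) {
  n_t <- nrow(sig_list[[1]])
  n_ch <- ncol(sig_list[[1]])
  samples <- array(0, c(length(sig_list), n_ch, n_t))
  for (i in seq_along(sig_list)) samples[i, , ] <- t(sig_list[[i]])
  time_axis <- t0 + (seq_len(n_t) - 1) * 1000 / fs
  meta <- tibble::tibble(
    subject = "s01", group = "young", sequence = 1L,
    repetition = seq_along(sig_list), stimulus = 1L, fixation = TRUE)
  channels <- tibble::tibble(
    channel = paste0("ch", seq_len(n_ch)),
    region = rep(c("midfrontal", "parietal"), length.out = n_ch))
  epoch_set(samples, time_axis, meta, fs, channels)
}
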