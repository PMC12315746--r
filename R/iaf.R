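#' High-resolution spectrum from concatenated epochs
#'
#' Estimates a single high-resolution power spectrum per subject by treating
#' the concatenated epochs as one long recording and averaging
#' Hanning-tapered, 50%-overlapping segment spectra (Welch's method). The
#' segment length is chosen as `sampling_rate / resolution` samples so the
#' native frequency resolution equals `resolution` (0.2 Hz by default: 5 s
#' segments) without zero-padding.
#'
#' @param x Concatenated signal: a numeric vector, or a `time x channel`
#'   matrix (power is averaged across channels), or an [epoch_set()] whose
#'   epochs are concatenated per channel.
#' @param sampling_rate Sampling rate in Hz (taken from the epoch set when
#'   `x` is one).
#' @param resolution Frequency resolution in Hz (default 0.2).
#' @param fmin,fmax Frequency range to keep.
#' @param min_duration_s Minimum required signal duration in seconds
#'   (default 30); shorter inputs are an error.
#' @return Tibble with columns `frequency` (Hz) and `log_power` (log10).
#' @export
long_segment_spectrum <- function(x, sampling_rate = NULL, resolution = 0.2,
                                  fmin = 1, fmax = 40, min_duration_s = 30) {
  if (inherits(x, "epoch_set")) {
    sampling_rate <- x$sampling_rate
    d <- dim(x$samples)
    x <- matrix(aperm(x$samples, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  }
  if (is.null(sampling_rate)) stop("sampling_rate is required", call. = FALSE)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_duration_s * sampling_rate)
    stop(sprintf("need at least %g s of signal (%g s given)", min_duration_s,
                 n / sampling_rate), call. = FALSE)
  seg_n <- round(sampling_rate / resolution)
  hop <- seg_n %/% 2
  starts <- seq(1, n - seg_n + 1, by = hop)
  w <- hann_window(seg_n)
  wnorm <- sum(w)^2
  freqs_all <- (seq_len(seg_n) - 1) * sampling_rate / seg_n
  fsel <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_n - 1), , drop = FALSE] * w
    acc <- acc + rowMeans(Mod(mvfft(seg)[fsel, , drop = FALSE])^2) / wnorm
  }
  tibble::tibble(frequency = freqs_all[fsel],
                 log_power = log10(acc / length(starts) + .Machine$double.eps))
}

#' Detect the individual alpha frequency
#'
#' Finds the frequency of maximum aperiodic-adjusted power strictly inside
#' the search range (default 7-14 Hz). No IAF is returned when the argmax
#' sits at either border bin of the search grid or when the adjusted power
#' at the argmax is not positive (no oscillatory peak above the aperiodic
#' background). Ties between equal maxima resolve to the lower frequency
#' with a warning.
#'
#' @param adjusted_spectrum Tibble with columns `frequency` and an
#'   adjusted-power column (`adjusted` or `log_power`), typically the output
#'   of [long_segment_spectrum()] + [fit_spectrum()] + [adjust_power()].
#' @param fmin,fmax Search limits in Hz (defaults 7 and 14).
#' @return Tibble of class `iaf_result` with columns `iaf` (Hz or `NA`),
#'   `detected`, `fmin`, `fmax`.
#' @export
detect_iaf <- function(adjusted_spectrum, fmin = 7, fmax = 14) {
  col <- intersect(c("adjusted", "log_power"), names(adjusted_spectrum))[1]
  if (is.na(col))
    stop("adjusted_spectrum needs an `adjusted` or `log_power` column",
         call. = FALSE)
  f <- adjusted_spectrum$frequency
  if (min(f) > fmin || max(f) < fmax)
    stop("spectrum does not cover the search range", call. = FALSE)
  sel <- which(f >= fmin - 1e-9 & f <= fmax + 1e-9)
  p <- adjusted_spectrum[[col]][sel]
  mx <- max(p)
  hits <- which(p == mx)
  if (length(hits) > 1)
    warning("tied spectral maxima; keeping the lower frequency", call. = FALSE)
  ind <- hits[1]
  at_border <- ind == 1 || ind == length(sel)
  detected <- !at_border && mx > 0
  out <- tibble::tibble(iaf = if (detected) f[sel[ind]] else NA_real_,
                        detected = detected, fmin = fmin, fmax = fmax)
  class(out) <- c("iaf_result", class(out))
  out
}

#' IAF-relative analysis bands
#'
#' Derives the subject-specific theta and alpha bands from a detected IAF:
#' theta spans `IAF - 6` to `IAF - 4` Hz, alpha spans `IAF - 4` to
#' `IAF + 2` Hz (contiguous at `IAF - 4`). Fixed analysis windows: theta
#' 100-500 ms, alpha 250-900 ms, baseline -500..-250 ms. Alternative
#' post-stimulus windows (100-900, 250-500 ms) are available as presets via
#' `theta_window` / `alpha_window`.
#'
#' @param iaf IAF in Hz, or an `iaf_result` row.
#' @param fit_range Frequency range of the underlying spectral fit; bands
#'   reaching below it are flagged.
#' @param theta_window,alpha_window,baseline_window Time windows in ms.
#' @return Tibble with one row per band: `band`, `f_lo`, `f_hi`, `t_lo`,
#'   `t_hi`, plus the baseline window and a `below_fit_range` flag.
#' @export
bands_from_iaf <- function(iaf, fit_range = c(1, 40),
                           theta_window = c(100, 500),
                           alpha_window = c(250, 900),
                           baseline_window = c(-500, -250)) {
  if (inherits(iaf, "iaf_result") || is.data.frame(iaf)) {
    if (!isTRUE(iaf$detected[1]))
      stop("no detectable IAF: subject must be excluded", call. = FALSE)
    iaf <- iaf$iaf[1]
  }
  if (is.na(iaf)) stop("no detectable IAF: subject must be excluded",
                       call. = FALSE)
  out <- tibble::tibble(
    band = c("theta", "alpha"),
    f_lo = c(iaf - 6, iaf - 4),
    f_hi = c(iaf - 4, iaf + 2),
    t_lo = c(theta_window[1], alpha_window[1]),
    t_hi = c(theta_window[2], alpha_window[2]),
    baseline_lo = baseline_window[1],
    baseline_hi = baseline_window[2],
    below_fit_range = c(iaf - 6, iaf - 4) < fit_range[1]
  )
  if (any(out$below_fit_range))
    warning("band extends below the fitted frequency range", call. = FALSE)
  out
}
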