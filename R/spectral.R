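#' Amplitude-based epoch rejection
#'
#' Removes epochs whose maximum absolute amplitude over any channel or time
#' point exceeds the threshold (default 90 microvolts).
#'
#' @param epochs An [epoch_set()].
#' @param threshold_uv Rejection threshold in microvolts (> 0).
#' @return A list with `epochs` (the surviving [epoch_set()]) and
#'   `rejection_rate` (rejected fraction). Signals an error if every epoch
#'   is rejected.
#' @export
reject_epochs <- function(epochs, threshold_uv = 90) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  peak <- apply(abs(epochs$samples), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep))
    stop("all epochs exceed the amplitude threshold", call. = FALSE)
  out <- epoch_set(epochs$samples[keep, , , drop = FALSE], epochs$time,
                   epochs$metadata[keep, ], epochs$sampling_rate,
                   epochs$channels)
  list(epochs = out, rejection_rate = mean(!keep))
}

#' Sliding-window time-frequency decomposition
#'
#' Hanning-tapered short-time FFT: for each window position the tapered
#' segment is zero-padded to the requested frequency resolution and its
#' power spectrum computed. Window positions are the window *centers*; only
#' windows lying fully inside the epoch are produced, which truncates a
#' -750..1150 ms epoch to output times -500..900 ms for a 500 ms window.
#' Power is averaged over the stimulus epochs of each subject x sequence x
#' repetition cell before the log10 transform, yielding one
#' time-frequency plane per sequence repetition.
#'
#' Power normalization: the squared FFT magnitude is divided by the squared
#' taper sum, so a unit-amplitude sinusoid at a bin center yields 0.25
#' linear power. A floor of `.Machine$double.eps` is added before the log10
#' transform so silent inputs stay finite; the floor is recorded in the
#' result.
#'
#' @param epochs An [epoch_set()].
#' @param window_ms Window length in ms (default 500).
#' @param step_ms Step between window centers in ms (default 50).
#' @param taper Taper name; only `"hanning"` is implemented.
#' @param pad_resolution Output frequency resolution in Hz obtained by
#'   zero-padding (default 0.2). `NULL` keeps the native window resolution
#'   (2 Hz for a 500 ms window).
#' @param fmin,fmax Frequency range to keep in Hz (defaults 1 and 40).
#' @return An object of class `spectral_tensor`: a list with `log_power`
#'   (array `repetition x channel x frequency x time`), `frequencies`,
#'   `times` (window centers, ms), `repetitions` (metadata tibble with one
#'   row per tensor row), `channels`, and spectral settings.
#' @export
sliding_tfr <- function(epochs, window_ms = 500, step_ms = 50,
                        taper = "hanning", pad_resolution = 0.2,
                        fmin = 1, fmax = 40) {
  stopifnot(inherits(epochs, "epoch_set"))
  taper <- match.arg(taper, "hanning")
  fs <- epochs$sampling_rate
  dt <- 1000 / fs
  if (abs(step_ms / dt - round(step_ms / dt)) > 1e-9)
    stop("step_ms must be a multiple of the sample interval", call. = FALSE)
  win_n <- round(window_ms / 1000 * fs)
  if (win_n > length(epochs$time))
    stop("window does not fit inside the epoch", call. = FALSE)
  half <- window_ms / 2
  centers <- seq(min(epochs$time) + half, max(epochs$time) - half, by = step_ms)
  # align centers to the sample grid starting from epoch edge
  if (!length(centers))
    stop("window does not fit inside the epoch", call. = FALSE)

  pad_n <- if (is.null(pad_resolution)) win_n else round(fs / pad_resolution)
  if (pad_n < win_n)
    stop("pad_resolution coarser than the native window resolution", call. = FALSE)
  freqs_all <- (seq_len(pad_n) - 1) * fs / pad_n
  fsel <- which(freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9)
  freqs <- freqs_all[fsel]
  w <- hann_window(win_n)
  wnorm <- sum(w)^2
  floor_val <- .Machine$double.eps

  md <- epochs$metadata
  md$.row <- seq_len(nrow(md))
  cell <- dplyr::group_by(md, .data$subject, .data$group, .data$sequence,
                          .data$repetition)
  cells <- dplyr::group_split(cell)
  reps_meta <- dplyr::summarise(cell, n_epochs = dplyr::n(), .groups = "drop")
  # group_split follows the same ordering as summarise on grouped data
  nch <- dim(epochs$samples)[2]
  out <- array(NA_real_,
               dim = c(length(cells), nch, length(freqs), length(centers)))

  t0 <- min(epochs$time)
  for (ti in seq_along(centers)) {
    i1 <- round((centers[ti] - half - t0) / dt) + 1
    idx <- i1:(i1 + win_n - 1)
    for (ci in seq_along(cells)) {
      rows <- cells[[ci]]$.row
      # segment matrix: time x (epoch*channel)
      seg <- matrix(aperm(epochs$samples[rows, , idx, drop = FALSE],
                          c(3, 1, 2)), nrow = win_n)
      seg <- seg * w
      if (pad_n > win_n)
        seg <- rbind(seg, matrix(0, pad_n - win_n, ncol(seg)))
      pw <- Mod(mvfft(seg)[fsel, , drop = FALSE])^2 / wnorm
      pw <- array(pw, dim = c(length(fsel), length(rows), nch))
      out[ci, , , ti] <- t(apply(pw, c(1, 3), mean))  # channel x freq
    }
  }

  structure(
    list(log_power = log10(out + floor_val),
         frequencies = freqs, times = centers,
         repetitions = reps_meta, channels = epochs$channels,
         window_ms = window_ms, step_ms = step_ms, taper = taper,
         pad_resolution = if (is.null(pad_resolution)) fs / win_n else pad_resolution,
         log_floor = floor_val),
    class = "spectral_tensor"
  )
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$log_power)
  cat(sprintf("<spectral_tensor> %d repetitions x %d channels x %d freqs (%g..%g Hz) x %d times (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$frequencies), max(x$frequencies),
              d[4], min(x$times), max(x$times)))
  invisible(x)
}

#' Tidy a spectral tensor into long format
#'
#' @param x A `spectral_tensor`.
#' @param ... Unused.
#' @return Long tibble with repetition metadata, `channel`, `frequency`,
#'   `time`, `log_power`.
#' @export
tidy.spectral_tensor <- function(x, ...) {
  d <- dim(x$log_power)
  grid <- tidyr::expand_grid(
    row = seq_len(d[1]), channel = x$channels$channel,
    frequency = x$frequencies, time = x$times
  )
  grid$log_power <- as.vector(aperm(x$log_power, c(4, 3, 2, 1)))
  dplyr::bind_cols(x$repetitions[grid$row, ],
                   grid[c("channel", "frequency", "time", "log_power")])
}
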