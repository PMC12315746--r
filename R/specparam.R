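#' Settings for spectral parameterization
#'
#' Defaults: fixed aperiodic mode (no knee), at most 6 peaks, peak width
#' (FWHM) limits 1-8 Hz, minimum peak height 0.05 log10 units, relative
#' peak threshold 2 SD of the flattened-spectrum residuals.
#'
#' @param aperiodic_mode `"fixed"` (offset + exponent) or `"knee"`.
#' @param max_n_peaks Maximum number of Gaussian peaks.
#' @param peak_width_limits FWHM limits in Hz, length-2.
#' @param min_peak_height Absolute height threshold (log10 units above the
#'   aperiodic fit).
#' @param peak_threshold Relative height threshold in SD units of the
#'   flattened spectrum.
#' @return A list of class `specparam_settings`.
#' @export
specparam_settings <- function(aperiodic_mode = c("fixed", "knee"),
                               max_n_peaks = 6,
                               peak_width_limits = c(1, 8),
                               min_peak_height = 0.05,
                               peak_threshold = 2) {
  structure(list(aperiodic_mode = match.arg(aperiodic_mode),
                 max_n_peaks = max_n_peaks,
                 peak_width_limits = peak_width_limits,
                 min_peak_height = min_peak_height,
                 peak_threshold = peak_threshold),
            class = "specparam_settings")
}

ap_curve <- function(freqs, p, mode) {
  if (mode == "knee")
    p[["offset"]] - log10(p[["knee"]] + freqs^p[["exponent"]])
  else
    p[["offset"]] - p[["exponent"]] * log10(freqs)
}

ap_fit_simple <- function(freqs, y, mode) {
  lf <- log10(freqs)
  if (mode == "fixed") {
    fit <- lm.fit(cbind(1, lf), y)
    c(offset = fit$coefficients[[1]], exponent = -fit$coefficients[[2]])
  } else {
    guess <- ap_fit_simple(freqs, y, "fixed")
    obj <- function(p) sum((y - ap_curve(freqs, c(offset = p[1], knee = p[2],
                                                  exponent = p[3]), "knee"))^2)
    res <- optim(c(guess[["offset"]], 0, guess[["exponent"]]), obj,
                 method = "L-BFGS-B",
                 lower = c(-Inf, 0, 0), upper = c(Inf, Inf, Inf))
    c(offset = res$par[1], knee = res$par[2], exponent = res$par[3])
  }
}

# robust aperiodic fit: fit, flatten, ignore points rising above the fit
# (the peaks), refit on the remainder
ap_fit_robust <- function(freqs, y, mode) {
  init <- ap_fit_simple(freqs, y, mode)
  flat <- y - ap_curve(freqs, init, mode)
  flat[flat < 0] <- 0
  thresh <- quantile(flat, 0.025 / 100, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) < 3) return(init)
  ap_fit_simple(freqs[keep], y[keep], mode)
}

gauss_sum <- function(freqs, par) {
  # par: c(cf1, h1, sd1, cf2, h2, sd2, ...)
  out <- numeric(length(freqs))
  for (i in seq_len(length(par) / 3)) {
    p <- par[(3 * i - 3) + 1:3]
    out <- out + p[2] * exp(-(freqs - p[1])^2 / (2 * p[3]^2))
  }
  out
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Iterative decomposition of a log10 power spectrum into a 1/f-like
#' aperiodic component plus Gaussian oscillatory peaks:
#' (1) robust aperiodic fit in log-log space (residuals above the initial
#' fit -- the peaks -- are ignored before refitting); (2) the aperiodic fit
#' is subtracted; (3) the largest residual maximum exceeding both the
#' absolute (`min_peak_height`) and relative (`peak_threshold` SD)
#' thresholds is located, a Gaussian is guessed from its half-height width
#' and subtracted, repeatedly, up to `max_n_peaks`; (4) all Gaussian guesses
#' are refined by a joint bounded least-squares fit; (5) the aperiodic
#' component is refit on the peak-subtracted spectrum and the full model
#' (aperiodic + Gaussians) is assembled.
#'
#' R-squared is the squared Pearson correlation between the model and the
#' input spectrum; `fit_error` is the RMSE in log10 units.
#'
#' @param frequencies Strictly increasing frequency grid (Hz), >= 10 points.
#' @param log_power Log10 power at `frequencies`; finite.
#' @param settings A [specparam_settings()].
#' @return An object of class `specparam_fit` with elements `aperiodic`
#'   (offset, exponent, optional knee, mode), `peaks` (tibble:
#'   `center_frequency`, `power`, `bandwidth` -- the Gaussian SD-scaled
#'   width in Hz), `r_squared`, `fit_error`, plus the input, model and
#'   aperiodic curves.
#' @export
fit_spectrum <- function(frequencies, log_power,
                         settings = specparam_settings()) {
  if (length(frequencies) < 10)
    stop("need at least 10 frequency points", call. = FALSE)
  if (any(diff(frequencies) <= 0))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(log_power)))
    stop("log_power must be finite", call. = FALSE)
  mode <- settings$aperiodic_mode

  if (sd(log_power) == 0) {
    ap <- c(offset = log_power[1], exponent = 0)
    return(new_specparam_fit(frequencies, log_power, ap, numeric(0), mode,
                             settings, r_squared = NA_real_))
  }

  ap <- ap_fit_robust(frequencies, log_power, mode)
  flat <- log_power - ap_curve(frequencies, ap, mode)

  sd_lim <- settings$peak_width_limits / 2   # FWHM limits -> Gaussian SD limits
  fwhm_to_sd <- 1 / (2 * sqrt(2 * log(2)))
  guesses <- NULL
  resid <- flat
  for (k in seq_len(settings$max_n_peaks)) {
    ind <- which.max(resid)
    h <- resid[ind]
    if (h <= settings$peak_threshold * sd(resid)) break
    if (h <= settings$min_peak_height) break
    cf <- frequencies[ind]
    # half-height crossing width estimate (full span across both flanks)
    half <- h / 2
    le <- ind; while (le > 1 && resid[le - 1] > half) le <- le - 1
    ri <- ind; while (ri < length(resid) && resid[ri + 1] > half) ri <- ri + 1
    fwhm <- if (ri > le) (frequencies[ri] - frequencies[le]) else
      mean(settings$peak_width_limits)
    gsd <- min(max(fwhm * fwhm_to_sd, sd_lim[1]), sd_lim[2])
    guesses <- rbind(guesses, c(cf, h, gsd))
    resid <- resid - gauss_sum(frequencies, c(cf, h, gsd))
  }
  # drop guesses overlapping a taller neighbour (within 0.75 SD bounds)
  if (!is.null(guesses) && nrow(guesses) > 1) {
    ord <- order(guesses[, 1])
    drop <- rep(FALSE, nrow(guesses))
    for (j in seq_len(length(ord) - 1)) {
      a <- ord[j]; b <- ord[j + 1]
      if (guesses[a, 1] + 0.75 * guesses[a, 3] >
          guesses[b, 1] - 0.75 * guesses[b, 3]) {
        drop[if (guesses[a, 2] < guesses[b, 2]) a else b] <- TRUE
      }
    }
    guesses <- guesses[!drop, , drop = FALSE]
  }

  joint_fit <- function(g) {
    par0 <- as.vector(t(g))
    res <- tryCatch(
      minpack.lm::nls.lm(par0,
                         fn = function(p) flat - gauss_sum(frequencies, p),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    # the unconstrained fit is sign-invariant in the SD; normalize, then
    # drop degenerate components (vanished or negative height, center
    # outside the fit range, width outside twice the configured limits)
    # BEFORE scoring, so that e.g. a mutually-cancelling Gaussian pair is
    # judged by what remains of it, not by its intact residual
    par <- res$par
    keep <- logical(length(par) / 3)
    for (i in seq_along(keep)) {
      j <- (3 * i - 3)
      par[j + 3] <- abs(par[j + 3])
      p <- par[j + 1:3]
      keep[i] <- p[2] > 1e-6 && p[1] > frequencies[1] &&
        p[1] < frequencies[length(frequencies)] &&
        p[3] >= sd_lim[1] / 2 && p[3] <= sd_lim[2] * 2
    }
    par <- par[rep(keep, each = 3)]
    list(par = par, sse = sum((flat - gauss_sum(frequencies, par))^2))
  }

  peaks <- numeric(0)
  if (!is.null(guesses)) {
    # multi-start: the sum-of-Gaussians objective is multimodal and greedy
    # guesses can split one broad peak into several narrow ones; also start
    # from the tallest guess alone and keep whichever converged fit has the
    # lower residual sum of squares
    starts <- list(guesses)
    if (nrow(guesses) > 1)
      starts <- c(starts,
                  list(guesses[which.max(guesses[, 2]), , drop = FALSE]))
    fits <- Filter(Negate(is.null), lapply(starts, joint_fit))
    if (!length(fits)) {
      warning("Gaussian peak fit did not converge; dropping peaks",
              call. = FALSE)
    } else {
      peaks <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]$par
    }
  }

  # refit aperiodic on the peak-removed spectrum (simple fit: the peaks,
  # which the robust variant exists to sidestep, are already subtracted)
  ap <- ap_fit_simple(frequencies,
                      log_power - gauss_sum(frequencies, peaks), mode)
  new_specparam_fit(frequencies, log_power, ap, peaks, mode, settings)
}

new_specparam_fit <- function(frequencies, log_power, ap, peaks, mode,
                              settings, r_squared = NULL) {
  apc <- ap_curve(frequencies, ap, mode)
  model <- apc + gauss_sum(frequencies, peaks)
  if (is.null(r_squared))
    r_squared <- suppressWarnings(stats::cor(model, log_power)^2)
  pk <- if (length(peaks)) {
    m <- matrix(peaks, ncol = 3, byrow = TRUE)
    m <- m[order(-m[, 2]), , drop = FALSE]
    tibble::tibble(center_frequency = m[, 1], power = m[, 2],
                   bandwidth = 2 * m[, 3])
  } else {
    tibble::tibble(center_frequency = numeric(0), power = numeric(0),
                   bandwidth = numeric(0))
  }
  structure(
    list(aperiodic = as.list(ap), mode = mode, peaks = pk,
         r_squared = r_squared,
         fit_error = sqrt(mean((log_power - model)^2)),
         frequencies = frequencies, spectrum = log_power,
         model = model, aperiodic_curve = apc, settings = settings),
    class = "specparam_fit"
  )
}

#' @export
print.specparam_fit <- function(x, ...) {
  cat(sprintf("<specparam_fit> offset %.3f, exponent %.3f (%s), %d peak(s), R^2 = %.4f\n",
              x$aperiodic$offset, x$aperiodic$exponent, x$mode,
              nrow(x$peaks), x$r_squared))
  invisible(x)
}

#' @export
tidy.specparam_fit <- function(x, ...) x$peaks

#' @export
glance.specparam_fit <- function(x, ...) {
  tibble::tibble(offset = x$aperiodic$offset,
                 exponent = x$aperiodic$exponent,
                 knee = if (x$mode == "knee") x$aperiodic$knee else NA_real_,
                 n_peaks = nrow(x$peaks),
                 r_squared = x$r_squared,
                 fit_error = x$fit_error)
}

#' Aperiodic-adjusted power
#'
#' Subtracts the reconstructed aperiodic curve of a fitted model from a
#' log10 power spectrum on the same frequency grid, yielding power relative
#' to the aperiodic background.
#'
#' @param log_power Log10 power values.
#' @param model A [fit_spectrum()] result fitted on the same grid.
#' @param frequencies Optional frequency grid of `log_power` for the grid
#'   check; defaults to the model's grid.
#' @return Numeric vector of aperiodic-adjusted log10 power.
#' @export
adjust_power <- function(log_power, model, frequencies = model$frequencies) {
  stopifnot(inherits(model, "specparam_fit"))
  if (length(frequencies) != length(model$frequencies) ||
      max(abs(frequencies - model$frequencies)) > 1e-9)
    stop("frequency grid does not match the fitted model", call. = FALSE)
  if (length(log_power) != length(frequencies))
    stop("log_power length does not match the frequency grid", call. = FALSE)
  log_power - model$aperiodic_curve
}

#' Model-fit quality filter
#'
#' Averages the specparam R-squared over time points and channels within
#' each sequence repetition and masks out repetitions whose mean falls
#' below the threshold (default 0.9).
#'
#' @param fits Tibble with at least columns `subject`, `sequence`,
#'   `repetition`, `r_squared` (one row per fitted spectrum; any finer
#'   granularity such as channels/time bins is averaged over), optionally
#'   `group`.
#' @param threshold Minimum acceptable mean R-squared.
#' @return Tibble with one row per subject x sequence x repetition:
#'   `mean_r_squared` and `excluded`. Per-group exclusion counts are
#'   attached as attribute `exclusions`.
#' @export
qc_filter <- function(fits, threshold = 0.9) {
  keys <- intersect(c("subject", "group", "sequence", "repetition"),
                    names(fits))
  out <- fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_r_squared = mean(.data$r_squared),
                     .groups = "drop") |>
    dplyr::mutate(excluded = .data$mean_r_squared < threshold)
  excl <- if ("group" %in% keys) {
    dplyr::count(dplyr::filter(out, .data$excluded), .data$group,
                 name = "n_excluded")
  } else {
    tibble::tibble(group = "all", n_excluded = sum(out$excluded))
  }
  attr(out, "exclusions") <- excl
  out
}
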