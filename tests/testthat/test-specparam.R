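test_that("a pure power law is recovered almost exactly", {
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs, offset = 1, exponent = 1.5, height = 0)
  fit <- fit_spectrum(freqs, y)
  expect_lt(abs(fit$aperiodic$offset - 1), 0.01)
  expect_lt(abs(fit$aperiodic$exponent - 1.5), 0.01)
  expect_equal(nrow(fit$peaks), 0)
  expect_gte(fit$r_squared, 0.999)
})

test_that("power law + Gaussian + mild noise recovers the peak", {
  withr::local_seed(2)
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs, cf = 10, height = 0.6, gsd = 1, noise_sd = 0.02)
  fit <- fit_spectrum(freqs, y)
  expect_gte(nrow(fit$peaks), 1)
  tall <- which.max(fit$peaks$power)
  expect_lt(abs(fit$peaks$center_frequency[tall] - 10), 0.1)
  expect_lt(abs(fit$peaks$power[tall] - 0.6), 0.05)
})

test_that("reconstruction identity and fit error hold", {
  withr::local_seed(3)
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs, noise_sd = 0.03)
  fit <- fit_spectrum(freqs, y)
  gaussians <- rep(0, length(freqs))
  for (i in seq_len(nrow(fit$peaks))) {
    p <- fit$peaks[i, ]
    gaussians <- gaussians +
      p$power * exp(-(freqs - p$center_frequency)^2 /
                      (2 * (p$bandwidth / 2)^2))
  }
  expect_equal(fit$aperiodic_curve + gaussians, fit$model,
               tolerance = 1e-12)
  expect_equal(fit$fit_error,
               sqrt(mean((y - fit$model)^2)), tolerance = 1e-12)
  expect_lte(fit$r_squared, 1)
})

test_that("adding a constant shifts the offset only", {
  withr::local_seed(4)
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs, noise_sd = 0.02)
  f1 <- fit_spectrum(freqs, y)
  f2 <- fit_spectrum(freqs, y + 2)
  expect_equal(f2$aperiodic$offset - f1$aperiodic$offset, 2,
               tolerance = 1e-6)
  expect_equal(f2$aperiodic$exponent, f1$aperiodic$exponent,
               tolerance = 1e-6)
  expect_equal(f2$peaks$center_frequency, f1$peaks$center_frequency,
               tolerance = 1e-4)
})

test_that("exponent recovery bias is below 0.05 at all target exponents", {
  withr::local_seed(6)
  freqs <- seq(1, 40, by = 0.2)
  for (chi in c(0.5, 1, 1.5, 2)) {
    err <- replicate(25, {
      y <- synth_spectrum(freqs, exponent = chi, cf = runif(1, 8, 13),
                          noise_sd = 0.05)
      fit_spectrum(freqs, y)$aperiodic$exponent - chi
    })
    expect_lt(abs(mean(err)), 0.05)
  }
})

test_that("input validation errors fire", {
  expect_error(fit_spectrum(1:5, rnorm(5)), "10")
  expect_error(fit_spectrum(c(1:10, 10), rnorm(11)), "increasing")
  expect_error(fit_spectrum(seq(1, 40, 0.2),
                            c(NA, rnorm(195))), "finite")
})

test_that("adjust_power subtracts the aperiodic curve exactly", {
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs, height = 0)
  fit <- fit_spectrum(freqs, y)
  adj <- adjust_power(fit$aperiodic_curve, fit, freqs)
  expect_equal(max(abs(adj)), 0, tolerance = 1e-12)
  # aperiodic + Gaussian input -> adjusted equals the Gaussian (within fit)
  g <- 0.8 * exp(-(freqs - 10)^2 / (2 * 1.2^2))
  y2 <- 1 - 1.5 * log10(freqs) + g
  fit2 <- fit_spectrum(freqs, y2)
  adj2 <- adjust_power(y2, fit2, freqs)
  expect_lt(max(abs(adj2 - g)), 0.05)
  # far from the peak the adjusted spectrum is centered on 0
  far <- freqs > 20
  expect_lt(abs(mean(adj2[far])), 0.02)
  expect_error(adjust_power(y2, fit2, freqs + 0.1), "grid")
})

test_that("qc_filter masks repetitions below the R-squared threshold", {
  fits <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 2),
    group = rep(c("young", "older"), each = 2),
    sequence = 1L,
    repetition = rep(1:2, 2),
    r_squared = c(0.95, 0.89, 0.97, 0.91)
  )
  qc <- qc_filter(fits, 0.9)
  expect_equal(qc$excluded, c(FALSE, TRUE, FALSE, FALSE))
  qc_all <- qc_filter(dplyr::mutate(fits, r_squared = 0.95), 0.9)
  expect_false(any(qc_all$excluded))
  # exclusion fraction equals a direct count on a random draw
  withr::local_seed(9)
  big <- tibble::tibble(subject = sprintf("s%03d", 1:100), group = "young",
                        sequence = 1L, repetition = 1L,
                        r_squared = runif(100, 0.8, 1))
  qcb <- qc_filter(big, 0.9)
  expect_equal(sum(qcb$excluded), sum(big$r_squared < 0.9))
})

test_that("multiple fit rows per repetition are averaged before QC", {
  fits <- tibble::tibble(
    subject = "s1", group = "young", sequence = 1L,
    repetition = c(1L, 1L, 2L, 2L),
    r_squared = c(0.85, 0.97, 0.85, 0.89)
  )
  qc <- qc_filter(fits, 0.9)
  expect_equal(nrow(qc), 2)
  expect_equal(qc$mean_r_squared, c(0.91, 0.87))
  expect_equal(qc$excluded, c(FALSE, TRUE))
})

test_that("specparam fit broom-style accessors work", {
  freqs <- seq(1, 40, by = 0.2)
  y <- synth_spectrum(freqs)
  fit <- fit_spectrum(freqs, y)
  expect_identical(generics::tidy(fit), fit$peaks)
  gl <- generics::glance(fit)
  expect_true(all(c("offset", "exponent", "r_squared", "n_peaks") %in%
                    names(gl)))
  expect_equal(gl$n_peaks, nrow(fit$peaks))
})
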