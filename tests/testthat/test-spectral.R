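test_that("reject_epochs applies the amplitude threshold", {
  clean <- replicate(9, matrix(0, 951, 2), simplify = FALSE)
  bad <- matrix(0, 951, 2)
  bad[100, 1] <- 100
  ep <- make_epochs(c(clean, list(bad)))
  res <- reject_epochs(ep, 90)
  expect_equal(res$rejection_rate, 0.1)
  expect_equal(dim(res$epochs$samples)[1], 9)
  res0 <- reject_epochs(ep, 200)
  expect_equal(res0$rejection_rate, 0)
  expect_error(reject_epochs(make_epochs(list(bad, bad)), 1), "all")
})

test_that("rejection rate matches the max-of-Gaussians exceedance", {
  withr::local_seed(42)
  n_ep <- 400
  n_t <- 300
  sd <- 28
  eps <- lapply(seq_len(n_ep), function(i) matrix(rnorm(n_t, 0, sd), n_t, 1))
  ep <- make_epochs(eps)
  res <- reject_epochs(ep, 90)
  p_exceed <- 1 - (pnorm(90 / sd) - pnorm(-90 / sd))^n_t
  se <- sqrt(p_exceed * (1 - p_exceed) / n_ep)
  expect_lt(abs(res$rejection_rate - p_exceed), 3 * se + 1e-12)
})

test_that("sliding_tfr output grid matches the documented contract", {
  ep <- make_epochs(replicate(2, matrix(0, 951, 2), simplify = FALSE))
  tens <- sliding_tfr(ep)
  expect_equal(tens$times, seq(-500, 900, by = 50))
  expect_equal(length(tens$times), 29)
  expect_equal(tens$frequencies, seq(1, 40, by = 0.2), tolerance = 1e-9)
  expect_true(all(is.finite(tens$log_power)))
  # constant-zero input -> log power at the floor
  expect_equal(max(tens$log_power), log10(.Machine$double.eps))
  expect_equal(min(tens$log_power), log10(.Machine$double.eps))
})

test_that("a pure 10 Hz tone peaks at the 10 Hz bin in every slice", {
  fs <- 500
  tt <- (-750 / 1000) + (seq_len(951) - 1) / fs
  sig <- matrix(sin(2 * pi * 10 * tt), 951, 1)
  ep <- make_epochs(list(sig, sig))
  tens <- sliding_tfr(ep)
  for (j in seq_along(tens$times)) {
    peak <- tens$frequencies[which.max(tens$log_power[1, 1, , j])]
    expect_equal(peak, 10, tolerance = 1e-9)
  }
  # unit-amplitude sinusoid at a bin center -> 0.25 linear power
  expect_equal(10^max(tens$log_power[1, 1, , 15]), 0.25, tolerance = 0.01)
})

test_that("doubling the amplitude adds log10(4) at the tone frequency", {
  fs <- 500
  tt <- (-750 / 1000) + (seq_len(951) - 1) / fs
  s1 <- matrix(sin(2 * pi * 10 * tt), 951, 1)
  ep <- make_epochs(list(s1, 2 * s1))
  tens <- sliding_tfr(ep)
  fi <- which.min(abs(tens$frequencies - 10))
  diff_lp <- tens$log_power[2, 1, fi, ] - tens$log_power[1, 1, fi, ]
  expect_equal(max(abs(diff_lp - log10(4))), 0, tolerance = 1e-6)
})

test_that("delaying a transient by k steps shifts the TFR by k bins", {
  fs <- 500
  n_t <- 951
  burst <- function(center_ind) {
    x <- numeric(n_t)
    win <- (center_ind - 50):(center_ind + 49)
    tt <- (seq_along(win) - 1) / fs
    x[win] <- sin(2 * pi * 20 * tt) * hann_window(100)
    matrix(x, n_t, 1)
  }
  k <- 3
  step_samples <- 25 # 50 ms at 500 Hz
  ep <- make_epochs(list(burst(400), burst(400 + k * step_samples)))
  tens <- sliding_tfr(ep)
  fi <- which.min(abs(tens$frequencies - 20))
  p1 <- tens$log_power[1, 1, fi, ]
  p2 <- tens$log_power[2, 1, fi, ]
  expect_equal(which.max(p2) - which.max(p1), k)
})

test_that("white-noise mean linear power matches Parseval within 5%", {
  withr::local_seed(5)
  fs <- 500
  sigma <- 1
  eps <- lapply(1:30, function(i) matrix(rnorm(951, 0, sigma), 951, 1))
  ep <- make_epochs(eps)
  tens <- sliding_tfr(ep, fmin = 0.2, fmax = 250)
  # sum of linear power over all FFT bins (one-sided grid here covers
  # 0.2..250 of a 0.2 Hz padded grid; total power ~ sigma^2 * ENBW factor)
  lin <- 10^tens$log_power
  total <- 2 * mean(apply(lin, c(1, 4), sum)[, 15])
  # Hanning window: sum(w^2)/sum(w)^2 = 1.5/n; FFT bins = pad_n
  w <- hann_window(250)
  expected <- sigma^2 * sum(w^2) / sum(w)^2 * (fs / 0.2)
  expect_lt(abs(total - expected) / expected, 0.05)
})

test_that("windows extending past the epoch are rejected", {
  ep <- make_epochs(list(matrix(0, 951, 1)))
  expect_error(sliding_tfr(ep, window_ms = 3000), "window")
})

test_that("tidy.spectral_tensor matches the array layout", {
  withr::local_seed(8)
  eps <- lapply(1:2, function(i) matrix(rnorm(951), 951, 2))
  ep <- make_epochs(eps)
  tens <- sliding_tfr(ep)
  td <- generics::tidy(tens)
  i <- 777
  row <- td[i, ]
  ri <- which(tens$repetitions$repetition == row$repetition)
  ci <- which(tens$channels$channel == row$channel)
  fi <- which(abs(tens$frequencies - row$frequency) < 1e-9)
  ti <- which(tens$times == row$time)
  expect_equal(row$log_power, tens$log_power[ri, ci, fi, ti])
})
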