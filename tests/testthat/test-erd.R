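test_that("extract_band_power averages the selected window", {
  ep <- make_epochs(replicate(2, matrix(0, 951, 2), simplify = FALSE))
  tens <- sliding_tfr(ep)
  # constant tensor -> the constant
  tens$log_power[] <- 0.7
  bp <- extract_band_power(tens, c(8, 12), c(250, 900))
  expect_equal(bp$power, rep(0.7, 2))
  # value 1 inside the window, 0 outside -> 1
  tens$log_power[] <- 0
  fi <- tens$frequencies >= 8 & tens$frequencies <= 12
  ti <- tens$times >= 250 & tens$times <= 900
  tens$log_power[, , fi, ti] <- 1
  bp2 <- extract_band_power(tens, c(8, 12), c(250, 900))
  expect_equal(bp2$power, rep(1, 2))
  # random tensor -> equals the brute-force triple-loop average
  withr::local_seed(12)
  tens$log_power[] <- rnorm(length(tens$log_power))
  ch <- which(tens$channels$region == "parietal")
  bp3 <- extract_band_power(tens, c(8, 12), c(250, 900), "parietal")
  acc <- 0; n <- 0
  for (ci in ch) for (f in which(fi)) for (t in which(ti)) {
    acc <- acc + tens$log_power[1, ci, f, t]; n <- n + 1
  }
  expect_equal(bp3$power[1], acc / n, tolerance = 1e-12)
})

test_that("extract_band_power rejects empty selections and bad labels", {
  ep <- make_epochs(list(matrix(0, 951, 2)))
  tens <- sliding_tfr(ep)
  expect_error(extract_band_power(tens, c(50, 60), c(0, 100)), "empty")
  expect_error(extract_band_power(tens, c(8, 12), c(2000, 3000)), "empty")
  expect_error(extract_band_power(tens, c(8, 12), c(0, 100), "nope"),
               "channel")
})

test_that("ERS/ERD formulas behave as documented", {
  expect_equal(ers_erd_per_repetition(0.5, 0.5), 0)
  expect_equal(ers_erd_per_repetition(0.3, 0.5), -0.2)
  expect_equal(ers_erd_conventional(1, 1), 0)
  expect_equal(ers_erd_conventional(2, 1), 10 * log10(2))
  expect_equal(ers_erd_conventional(0.1, 1), -10)
  expect_error(ers_erd_conventional(-1, 1), "positive")
  expect_error(ers_erd_conventional(1, 0), "positive")
  # log-domain difference x 10 equals the conventional dB on linear inputs
  post <- c(1.5, 0.4); base <- c(1.0, 0.8)
  expect_equal(10 * ers_erd_per_repetition(log10(post), log10(base)),
               ers_erd_conventional(post, base))
})

test_that("prestim_and_subject_scheme satisfies the exact identities", {
  withr::local_seed(13)
  tab <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:6), sequence = 1:3, repetition = 1:8,
    band = "alpha")
  tab$post_power_sr <- rnorm(nrow(tab))
  tab$baseline_sr <- rnorm(nrow(tab))
  out <- prestim_and_subject_scheme(tab)
  expect_equal(out$ers_erd_rep, out$post_power_sr - out$baseline_sr)
  expect_lt(max(abs(out$ers_erd_subj - out$ers_erd_rep - out$prestim_sr)),
            1e-12)
  sums <- out |>
    dplyr::group_by(subject, sequence, band) |>
    dplyr::summarise(s = sum(prestim_sr), .groups = "drop")
  expect_lt(max(abs(sums$s)), 1e-12)
})

test_that("worked baseline example and degenerate case", {
  tab <- tibble::tibble(subject = "s1", sequence = 1L, repetition = 1:2,
                        band = "alpha",
                        post_power_sr = c(1, 1),
                        baseline_sr = c(0.4, 0.6))
  out <- prestim_and_subject_scheme(tab)
  expect_equal(out$average_baseline, c(0.5, 0.5))
  expect_equal(out$prestim_sr, c(-0.1, 0.1))
  # equal baselines -> prestim 0 and the two schemes coincide
  tab2 <- dplyr::mutate(tab, baseline_sr = 0.5)
  out2 <- prestim_and_subject_scheme(tab2)
  expect_equal(out2$prestim_sr, c(0, 0))
  expect_equal(out2$ers_erd_subj, out2$ers_erd_rep)
})

test_that("single-repetition sequences are flagged", {
  tab <- tibble::tibble(subject = "s1", sequence = 1L, repetition = 1L,
                        band = "alpha", post_power_sr = 1,
                        baseline_sr = 0.4)
  expect_warning(out <- prestim_and_subject_scheme(tab), "single")
  expect_true(out$single_repetition)
})

test_that("increasing post power strictly increases both measures", {
  tab <- tibble::tibble(subject = "s1", sequence = 1L, repetition = 1:2,
                        band = "alpha", post_power_sr = c(0.2, 0.2),
                        baseline_sr = c(0.1, 0.3))
  out1 <- prestim_and_subject_scheme(tab)
  tab$post_power_sr <- tab$post_power_sr + 0.5
  out2 <- prestim_and_subject_scheme(tab)
  expect_true(all(out2$ers_erd_rep > out1$ers_erd_rep))
  expect_true(all(out2$ers_erd_subj > out1$ers_erd_subj))
})
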