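test_that("powerlaw noise reproduces the target aperiodic exponent", {
  withr::local_seed(1)
  fs <- 500
  for (chi in c(0.5, 1.5)) {
    x <- powerlaw_noise(60 * fs, fs, chi)
    spec <- long_segment_spectrum(as.vector(x), fs)
    fit <- lm(log_power ~ log10(frequency), data = spec)
    expect_lt(abs(-coef(fit)[[2]] - chi), 0.1)
  }
})

test_that("generate_epochs is deterministic and has the declared shape", {
  cfg <- tiny_config()
  e1 <- generate_epochs(cfg)
  e2 <- generate_epochs(cfg)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$metadata, e2$metadata)
  expect_equal(dim(e1$samples)[1], nrow(e1$metadata))
  step <- diff(e1$time)
  expect_equal(max(abs(step - 1000 / cfg$sampling_rate)), 0, tolerance = 1e-9)
  expect_equal(e1$time[1], cfg$epoch_window[1])
})

test_that("oscillation-free configs yield no alpha peak and slope recovery", {
  cfg <- tiny_config(alpha_amp_pre = 0, alpha_amp_post = 0,
                     theta_burst_amp = 0,
                     aperiodic_exponent = c(young = 1.5, older = 1.5))
  ep <- generate_epochs(cfg)
  spec <- long_segment_spectrum(ep)
  fit <- fit_spectrum(spec$frequency, spec$log_power)
  expect_lt(abs(fit$aperiodic$exponent - 1.5), 0.1)
  # no oscillation injected: the model should place no substantial peak in
  # the alpha search range
  in_alpha <- fit$peaks$center_frequency >= 7 &
    fit$peaks$center_frequency <= 14
  expect_false(any(in_alpha & fit$peaks$power > 0.2))
})

test_that("a strong injected alpha oscillation peaks at the subject's IAF", {
  cfg <- tiny_config(n_subjects_per_group = 1,
                     alpha_amp_pre = 6, alpha_amp_post = 6,
                     theta_burst_amp = 0)
  truth <- draw_subjects(cfg)
  ep <- generate_epochs(cfg)
  young_rows <- which(ep$metadata$subject == truth$subject[1])
  d <- dim(ep$samples)
  sig <- matrix(aperm(ep$samples[young_rows, , , drop = FALSE], c(3, 1, 2)),
                nrow = length(young_rows) * d[3])
  spec <- long_segment_spectrum(sig, cfg$sampling_rate)
  peak_f <- spec$frequency[which.max(spec$log_power -
                                       predict(lm(log_power ~ log10(frequency),
                                                  data = spec)))]
  expect_lt(abs(peak_f - truth$iaf_true[1]), 0.21)
})

test_that("generate_power_table realizes the configured path system", {
  # zero paths, zero noise -> all zero
  cfg0 <- sim_config(path_a = 0, path_b = 0, path_c_prime = 0,
                     subject_intercept_sd = 0, residual_sd = 0)
  t0 <- generate_power_table(cfg0)
  expect_true(all(t0$prestim == 0))
  expect_true(all(t0$outcome == 0))
  # a = 1, no noise -> prestim equals repetition
  cfg1 <- sim_config(path_a = 1, path_b = 0, path_c_prime = 0,
                     subject_intercept_sd = 0, residual_sd = 0)
  t1 <- generate_power_table(cfg1)
  expect_equal(t1$prestim, as.numeric(t1$repetition))
  # OLS on a large draw recovers b and c' within 3 SEs
  cfg <- sim_config(seed = 7L)
  tab <- generate_power_table(cfg, n_subjects = 200)
  fit <- lm(outcome ~ prestim + repetition, data = tab)
  sm <- summary(fit)$coefficients
  expect_lt(abs(sm["prestim", 1] - cfg$path_b), 3 * sm["prestim", 2])
  expect_lt(abs(sm["repetition", 1] - cfg$path_c_prime),
            3 * sm["repetition", 2])
  expect_identical(attr(tab, "paths")[["acme"]],
                   cfg$path_a * cfg$path_b)
})

test_that("generate_power_table rejects negative variance components", {
  cfg <- sim_config()
  cfg$residual_sd <- -0.1
  expect_error(generate_power_table(cfg), ">= 0")
})

test_that("generate_behavior honors the stopping rule at the extremes", {
  cfg <- sim_config(n_subjects_per_group = 3, n_sequences = 2)
  b1 <- generate_behavior(cfg, item_prob = 1)
  per_seq <- dplyr::count(b1, subject, sequence)
  expect_true(all(per_seq$n == 3))
  expect_true(all(b1$accuracy == 1))
  b0 <- generate_behavior(cfg, item_prob = 0)
  per_seq0 <- dplyr::count(b0, subject, sequence)
  expect_true(all(per_seq0$n == 8))
  expect_true(all(b0$accuracy == 0))
})

test_that("behavior generator is seeded and accuracy is consistent", {
  cfg <- sim_config(n_subjects_per_group = 2, n_sequences = 2)
  b1 <- generate_behavior(cfg)
  b2 <- generate_behavior(cfg)
  expect_identical(b1, b2)
  expect_equal(b1$accuracy, b1$n_correct / b1$n_total)
  expect_equal(b1$fully_correct, b1$n_correct == b1$n_total)
})

test_that("generate_gaze controls the inside fraction", {
  cfg <- tiny_config()
  g <- generate_gaze(cfg, n_traces = 3, inside_fraction = c(1, 0, 0.9))
  fr <- g |>
    dplyr::group_by(trace) |>
    dplyr::summarise(inside = mean(pmax(abs(x), abs(y)) <= 1.26 / 2))
  expect_equal(fr$inside[1], 1)
  expect_equal(fr$inside[2], 0)
  expect_equal(fr$inside[3], 0.9, tolerance = 0.01)
})
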