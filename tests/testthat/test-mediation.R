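test_that("standardize z-scores with the sample SD and is idempotent", {
  tab <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 9))
  out <- standardize(tab, "x")
  expect_equal(out$x, c(-1, 0, 1))
  out2 <- standardize(out, c("x", "y"))
  expect_equal(standardize(out2, c("x", "y"))$x, out2$x, tolerance = 1e-12)
  expect_equal(mean(out2$y), 0, tolerance = 1e-12)
  expect_equal(sd(out2$y), 1, tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(x = rep(1, 3)), "x"), "variance")
})

test_that("model_spec enforces the M0/M/Y structure", {
  expect_error(model_spec("Y", "out", "rep"), "mediator")
  expect_silent(model_spec("M0", "out", "rep"))
  sp <- model_spec("Y", "out", "rep", "med")
  expect_match(deparse(lmm_formula(sp)), "med")
  expect_match(deparse(lmm_formula(sp)), "1 \\| subject")
  sp0 <- model_spec("M0", "out", "rep")
  expect_false(grepl("med", deparse(lmm_formula(sp0))))
})

test_that("fit_lmm recovers a known slope and falls back to OLS", {
  withr::local_seed(41)
  n_subj <- 30
  tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n_subj),
                            repetition = 1:8)
  tab$y <- 0.5 * tab$repetition + rnorm(nrow(tab), 0, 0.3)
  sp <- model_spec("M0", "y", "repetition")
  expect_warning(fit <- fit_lmm(tab, sp), "OLS")
  co <- tidy(fit)[tidy(fit)$term == "repetition", ]
  expect_lt(abs(co$estimate - 0.5), 3 * co$std_error)
  expect_true(co$ci_lower < co$estimate && co$estimate < co$ci_upper)
  # with real subject intercepts the mixed model is used
  u <- rnorm(n_subj, 0, 1)
  tab$y <- tab$y + u[match(tab$subject, unique(tab$subject))]
  fit2 <- fit_lmm(tab, sp)
  expect_gt(glance(fit2)$random_sd, 0.5)
})

test_that("fit_lmm requires five grouping levels", {
  tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:4),
                            repetition = 1:8)
  tab$y <- rnorm(nrow(tab))
  expect_error(fit_lmm(tab, model_spec("M0", "y", "repetition")), "5")
})

test_that("duplicating rows leaves LMM point estimates unchanged", {
  withr::local_seed(43)
  tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                            repetition = 1:8)
  u <- rnorm(10, 0, 0.5)
  tab$y <- 0.3 * tab$repetition + u[match(tab$subject,
                                          unique(tab$subject))] +
    rnorm(nrow(tab), 0, 0.3)
  sp <- model_spec("M0", "y", "repetition")
  f1 <- fit_lmm(tab, sp)
  f2 <- fit_lmm(dplyr::bind_rows(tab, tab), sp)
  expect_equal(coef_of(f2, "repetition")$est,
               coef_of(f1, "repetition")$est, tolerance = 1e-6)
})

test_that("nominal coverage of the LMM slope CI under the null", {
  withr::local_seed(44)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                              repetition = 1:6)
    u <- rnorm(12, 0, 0.3)
    tab$y <- u[match(tab$subject, unique(tab$subject))] +
      rnorm(nrow(tab), 0, 0.5)
    fit <- suppressWarnings(
      fit_lmm(tab, model_spec("M0", "y", "repetition")))
    co <- tidy(fit)[tidy(fit)$term == "repetition", ]
    if (co$ci_lower <= 0 && 0 <= co$ci_upper) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("mediate recovers generator paths (Monte-Carlo route)", {
  cfg <- sim_config(seed = 17L)
  tab <- generate_power_table(cfg, n_subjects = 100)
  res <- mediate(tab, outcome = "outcome", treatment = "repetition",
                 mediator = "prestim", n_draws = 500,
                 ci_method = "montecarlo", seed = 3L)
  expect_equal(res$total, res$acme + res$ade, tolerance = 1e-10)
  truth <- attr(tab, "paths")
  expect_gt(res$acme_ci[2], truth[["acme"]])
  expect_lt(res$acme_ci[1], truth[["acme"]])
  expect_gt(res$ade_ci[2], truth[["ade"]])
  expect_lt(res$ade_ci[1], truth[["ade"]])
  expect_true(res$premise_ok)
  expect_false(res$inconsistent_mediation)
})

test_that("bootstrap and Monte-Carlo routes agree on the same table", {
  cfg <- sim_config(seed = 23L)
  tab <- generate_power_table(cfg, n_subjects = 60)
  boot <- mediate(tab, outcome = "outcome", mediator = "prestim",
                  n_draws = 200, ci_method = "bootstrap", seed = 4L)
  mc <- mediate(tab, outcome = "outcome", mediator = "prestim",
                n_draws = 200, ci_method = "montecarlo", seed = 4L)
  # identical point estimates (same fits), comparable uncertainty
  expect_equal(boot$acme, mc$acme)
  expect_equal(boot$ade, mc$ade)
  expect_lt(abs(diff(boot$acme_ci) - diff(mc$acme_ci)),
            0.6 * diff(mc$acme_ci))
})

test_that("seeded mediation draws are bit-reproducible", {
  cfg <- sim_config(seed = 29L)
  tab <- generate_power_table(cfg, n_subjects = 40)
  r1 <- mediate(tab, outcome = "outcome", mediator = "prestim",
                n_draws = 50, ci_method = "bootstrap", seed = 11L)
  r2 <- mediate(tab, outcome = "outcome", mediator = "prestim",
                n_draws = 50, ci_method = "bootstrap", seed = 11L)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$acme_ci, r2$acme_ci)
})

test_that("premise failure warns and prop_mediated degenerates safely", {
  withr::local_seed(47)
  tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:40),
                            repetition = 1:8)
  tab$prestim <- rnorm(nrow(tab))
  tab$outcome <- rnorm(nrow(tab))
  expect_warning(
    res <- mediate(tab, outcome = "outcome", mediator = "prestim",
                   n_draws = 50, ci_method = "montecarlo", seed = 1L),
    "premise")
  expect_false(res$premise_ok)
  if (abs(res$total) < 0.01) {
    expect_true(res$prop_mediated_undefined)
    expect_true(is.na(res$prop_mediated))
  }
})

test_that("mediation_result accessors expose the effect table", {
  cfg <- sim_config(seed = 31L)
  tab <- generate_power_table(cfg, n_subjects = 40)
  res <- mediate(tab, outcome = "outcome", mediator = "prestim",
                 n_draws = 50, ci_method = "montecarlo", seed = 2L)
  td <- tidy(res)
  expect_setequal(td$term[1:3], c("acme", "ade", "total"))
  expect_true(all(td$ci_lower[1:3] <= td$estimate[1:3]))
  gl <- glance(res)
  expect_equal(gl$n_draws, 50)
  expect_s3_class(autoplot(res), "ggplot")
})
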