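#' Demo configuration for the end-to-end pipeline
#'
#' A compact study: 20 subjects per group, one sequence, an 8-channel
#' montage (4 mid-frontal + 4 parietal), pre-stimulus alpha amplitude
#' drifting upward across repetitions (the mediator path) and a mild
#' upward drift of post-stimulus alpha (the direct path), so the alpha
#' outcome carries an inconsistent-mediation structure (negative ACME,
#' positive ADE) by construction.
#'
#' @param n_subjects_per_group Subjects per group (default 20).
#' @param seed Seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
demo_config <- function(n_subjects_per_group = 20, seed = 1L, ...) {
  sim_config(
    n_subjects_per_group = n_subjects_per_group,
    n_sequences = 1,
    channels = default_montage(n_frontal = 4, n_parietal = 4),
    alpha_amp_pre = seq(1.2, 3.0, length.out = 8),
    alpha_amp_post = seq(1.6, 2.0, length.out = 8),
    theta_burst_amp = 2,
    seed = seed,
    ...
  )
}

#' Region- and window-averaged spectra from a tensor
#'
#' Averages linear power over a region's channels and a time window's bins,
#' returning one log10 spectrum per tensor repetition row.
#'
#' @param tensor A `spectral_tensor`.
#' @param region Region name or channel labels.
#' @param window Time window in ms.
#' @return Matrix `rows x frequencies` of log10 power.
#' @export
window_spectra <- function(tensor, region, window) {
  ch <- if (length(region) == 1 && region %in% tensor$channels$region)
    which(tensor$channels$region == region)
  else match(region, tensor$channels$channel)
  ti <- which(tensor$times >= window[1] - 1e-9 &
                tensor$times <= window[2] + 1e-9)
  if (!length(ch) || !length(ti)) stop("empty selection", call. = FALSE)
  lin <- 10^tensor$log_power[, ch, , ti, drop = FALSE]
  log10(apply(lin, c(1, 3), mean))
}

#' Run the full synthetic analysis pipeline
#'
#' End-to-end orchestration on synthetic data: epoch generation ->
#' amplitude rejection -> sliding-window TFR -> spectral parameterization
#' and QC -> IAF detection and IAF-relative bands -> band-power extraction
#' under both baseline schemes -> behavioral scoring -> causal mediation
#' per band and age group (outcome = per-repetition ERS/ERD, mediator =
#' pre-stimulus power, treatment = repetition number; all variables
#' z-scored first, as in the underlying analyses).
#'
#' Spectral parameterization is applied to region- and window-averaged
#' spectra (baseline, theta and alpha windows per repetition), which keeps
#' the fit count tractable at desk scale; the per-repetition QC averages
#' the resulting fits. Deterministic given the config seed; re-running
#' with an unchanged config reproduces every table byte-identically.
#'
#' @param config A [sim_config()]; see [demo_config()].
#' @param reject_threshold_uv Epoch rejection threshold (default 90).
#' @param qc_threshold Minimum mean model R-squared per repetition
#'   (default 0.9).
#' @param n_draws Mediation draws (default 1000).
#' @param ci_method `"bootstrap"` or `"montecarlo"` (see [mediate()]).
#' @param out_dir Optional directory; when given, every tabular artifact is
#'   written as TSV together with a `manifest.tsv` (file, rows, md5).
#' @param verbose Print per-stage progress and exclusion counts.
#' @return List of class `pipeline_result`: `config`, `rejection_rate`,
#'   `iaf` (per-subject table), `qc`, `band_power`, `behavior`,
#'   `mediation` (tibble with one row per band x group and a `result`
#'   list-column of [mediate()] objects), `manifest` (or `NULL`).
#' @export
run_pipeline <- function(config = demo_config(),
                         reject_threshold_uv = 90,
                         qc_threshold = 0.9,
                         n_draws = 1000,
                         ci_method = "bootstrap",
                         out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  validate_sim_config(config)

  say("generating epochs ...")
  epochs <- generate_epochs(config)
  rej <- reject_epochs(epochs, reject_threshold_uv)
  say("epoch rejection: %.1f%% rejected", 100 * rej$rejection_rate)

  say("sliding-window TFR ...")
  tensor <- sliding_tfr(rej$epochs)

  say("IAF detection ...")
  md <- rej$epochs$metadata
  par_ch <- which(rej$epochs$channels$region == "parietal")
  if (!length(par_ch)) par_ch <- seq_len(nrow(rej$epochs$channels))
  subjects <- unique(md$subject)
  iaf_tab <- purrr::map_dfr(subjects, function(sb) {
    rows <- which(md$subject == sb)
    d <- dim(rej$epochs$samples)
    sig <- matrix(aperm(rej$epochs$samples[rows, par_ch, , drop = FALSE],
                        c(3, 1, 2)), nrow = length(rows) * d[3])
    spec <- long_segment_spectrum(sig, rej$epochs$sampling_rate)
    fit <- fit_spectrum(spec$frequency, spec$log_power)
    spec$adjusted <- adjust_power(spec$log_power, fit, spec$frequency)
    res <- detect_iaf(spec[, c("frequency", "adjusted")])
    tibble::tibble(subject = sb, group = md$group[rows[1]],
                   iaf = res$iaf, detected = res$detected,
                   iaf_fit_r_squared = fit$r_squared)
  })
  say("IAF detected for %d / %d subjects", sum(iaf_tab$detected),
      nrow(iaf_tab))

  bands <- iaf_tab |>
    dplyr::filter(.data$detected) |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(bands_from_iaf(.data$iaf))

  say("spectral parameterization ...")
  theta_win <- c(100, 500); alpha_win <- c(250, 900); base_win <- c(-500, -250)
  combos <- list(
    theta_post = list(region = "midfrontal", window = theta_win),
    theta_base = list(region = "midfrontal", window = base_win),
    alpha_post = list(region = "parietal", window = alpha_win),
    alpha_base = list(region = "parietal", window = base_win)
  )
  spectra <- lapply(combos, function(cb)
    window_spectra(tensor, cb$region, cb$window))
  freqs <- tensor$frequencies
  nrows <- nrow(tensor$repetitions)
  adjusted <- list(); rsq <- list()
  for (nm in names(combos)) {
    adj <- matrix(NA_real_, nrows, length(freqs))
    r2 <- numeric(nrows)
    for (i in seq_len(nrows)) {
      ft <- fit_spectrum(freqs, spectra[[nm]][i, ])
      adj[i, ] <- adjust_power(spectra[[nm]][i, ], ft, freqs)
      r2[i] <- ft$r_squared
    }
    adjusted[[nm]] <- adj; rsq[[nm]] <- r2
  }

  qc_in <- purrr::map_dfr(names(combos), function(nm)
    dplyr::mutate(tensor$repetitions[c("subject", "group", "sequence",
                                       "repetition")],
                  fit = nm, r_squared = rsq[[nm]]))
  qc <- qc_filter(qc_in, qc_threshold)
  say("QC: %d repetition(s) excluded", sum(qc$excluded))

  say("band power ...")
  band_mean <- function(adj_row, f_lo, f_hi)
    mean(adj_row[freqs >= f_lo - 1e-9 & freqs <= f_hi + 1e-9])
  reps <- tensor$repetitions
  bp <- purrr::map_dfr(c("theta", "alpha"), function(bd) {
    src_post <- paste0(bd, "_post"); src_base <- paste0(bd, "_base")
    bdef <- dplyr::filter(bands, .data$band == bd)
    rows <- which(reps$subject %in% bdef$subject)
    purrr::map_dfr(rows, function(i) {
      bi <- bdef[bdef$subject == reps$subject[i], ]
      tibble::tibble(
        subject = reps$subject[i], group = reps$group[i],
        sequence = reps$sequence[i], repetition = reps$repetition[i],
        band = bd,
        region = if (bd == "theta") "midfrontal" else "parietal",
        post_power_sr = band_mean(adjusted[[src_post]][i, ], bi$f_lo, bi$f_hi),
        baseline_sr = band_mean(adjusted[[src_base]][i, ], bi$f_lo, bi$f_hi)
      )
    })
  })
  keep <- dplyr::filter(qc, !.data$excluded)[c("subject", "sequence",
                                               "repetition")]
  bp <- dplyr::semi_join(bp, keep, by = c("subject", "sequence",
                                          "repetition"))
  if (nrow(bp) == 0)
    stop("band-power stage: no repetitions left after QC exclusion ",
         "(qc_threshold = ", qc_threshold, ")", call. = FALSE)
  band_power <- prestim_and_subject_scheme(bp)

  say("behavior ...")
  behavior <- score_behavior(generate_behavior(config),
                             config$completion_correct_total,
                             config$max_repetitions)

  say("mediation (%s, %d draws) ...", ci_method, n_draws)
  med_grid <- tidyr::expand_grid(band = c("theta", "alpha"),
                                 group = config$groups)
  mediation <- purrr::pmap_dfr(med_grid, function(band, group) {
    dat <- dplyr::filter(band_power, .data$band == !!band,
                         .data$group == !!group)
    dat <- standardize(dat, c("ers_erd_rep", "prestim_sr", "repetition"))
    res <- suppressWarnings(
      mediate(dat, outcome = "ers_erd_rep", mediator = "prestim_sr",
              treatment = "repetition", group = "subject",
              n_draws = n_draws, ci_method = ci_method,
              seed = config$seed + 100L))
    tibble::tibble(band = band, group = group,
                   acme = res$acme, acme_lo = res$acme_ci[1],
                   acme_hi = res$acme_ci[2],
                   ade = res$ade, ade_lo = res$ade_ci[1],
                   ade_hi = res$ade_ci[2],
                   total = res$total,
                   prop_mediated = res$prop_mediated,
                   inconsistent = res$inconsistent_mediation,
                   premise_ok = res$premise_ok,
                   result = list(res))
  })

  out <- structure(list(
    config = config, rejection_rate = rej$rejection_rate,
    iaf = iaf_tab, qc = qc, band_power = band_power,
    behavior = behavior, mediation = mediation, manifest = NULL),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(iaf = iaf_tab, qc = qc, band_power = band_power,
                  behavior = behavior,
                  mediation = mediation[setdiff(names(mediation), "result")])
    for (nm in names(files))
      write_table_tsv(files[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    paths <- file.path(out_dir, paste0(names(files), ".tsv"))
    out$manifest <- tibble::tibble(
      file = basename(paths),
      n_rows = vapply(files, nrow, integer(1)),
      md5 = unname(tools::md5sum(paths)))
    write_table_tsv(out$manifest, file.path(out_dir, "manifest.tsv"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d subjects with IAF / %d; rejection %.1f%%; %d QC-excluded repetitions\n",
              sum(x$iaf$detected), nrow(x$iaf), 100 * x$rejection_rate,
              sum(x$qc$excluded)))
  print(x$mediation[setdiff(names(x$mediation), "result")])
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Builds a [sim_config()] from a YAML mapping whose keys are
#' `sim_config()` argument names. Nested mappings (for the per-group
#' parameters such as `aperiodic_exponent`) become named vectors. A
#' `montage` mapping is translated through [default_montage()] (keys
#' `n_frontal` / `n_parietal` or explicit `frontal` / `parietal` label
#' lists). Unknown keys are an error, so typos do not silently fall back
#' to defaults. Requires the `yaml` package.
#'
#' @param path Path to the YAML file.
#' @return A validated [sim_config()].
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$montage)) {
    raw$channels <- do.call(default_montage, raw$montage)
    raw$montage <- NULL
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw <- lapply(raw, function(x)
    if (is.list(x) && !is.data.frame(x)) unlist(x) else x)
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  do.call(sim_config, raw)
}
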