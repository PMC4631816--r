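#' Default pipeline configuration
#'
#' A nested list holding every stage's parameters. The `"full"` preset is
#' the study-scale design (160 channels, 4004 vertices, 560 trials,
#' 9 subjects); `"smoke"` is a minutes-scale end-to-end check (8 channels,
#' 16 vertices, 2 repetitions, 1 subject).
#'
#' @param preset `"full"` or `"smoke"`.
#' @return a named configuration list.
#' @export
default_config <- function(preset = c("full", "smoke")) {
  preset <- match.arg(preset)
  cfg <- list(
    geometry = list(n_channels = 160, n_vertices = 4004, head_radius = 0.09),
    stimuli = list(repetitions = 40),
    template = list(n_active = 12, overlap = 0.5, amplitude = 10,
                    category_effect = 1, image_gain_sd = 0.1, peak_ms = 190,
                    support = c(100, 300), target_peak_T = 100e-15),
    noise = list(sensor_sd = 300e-15, n_background = 20, background_sd = 2,
                 gain_jitter_sd = 0.05),
    preprocess = list(notch_hz = 60, bandpass = c(1, 30),
                      baseline = c(-500, -100), drop_region = "frontal",
                      artifact_threshold = 3e-12, zero_phase = TRUE),
    inverse = list(lambda = 0.1, window = c(140, 240), shrinkage = 0.1),
    fmap = list(window_center = 190),
    decode = list(win = 20, step = 10, range = c(-100, 500), k = 10, C = 1,
                  n_random = 20),
    n_subjects = 9)
  if (preset == "smoke") {
    cfg$geometry <- list(n_channels = 8, n_vertices = 16, head_radius = 0.09)
    cfg$stimuli <- list(repetitions = 2)
    cfg$template$n_active <- 2
    cfg$preprocess[c("notch_hz", "bandpass")] <- list(NULL, NULL)
    cfg$decode$k <- 3
    cfg$decode$n_random <- 2
    cfg$n_subjects <- 1
  }
  cfg
}

check_config <- function(config, blocks) {
  missing <- setdiff(blocks, names(config))
  if (length(missing))
    stop_invalid("configuration is missing block(s): ",
                 paste(missing, collapse = ", "))
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> evoked peaks -> source F-maps -> decoding,
#' for every subject, followed by the cohort-level statistics: the
#' category ANOVA on peak latency/amplitude, the subject-averaged F-map,
#' and the per-window decoding significance table. Identical seed and
#' configuration give an identical report.
#'
#' @param config configuration list, see [default_config()].
#' @param seed master seed.
#' @param out optional directory; when given, `report.json` and the
#'   decoding table CSV are written there.
#' @return a `meg_report` list: `peaks`, `peak_anova`, `fmap_mean`,
#'   `significance`, `config_hash`, `seed`, `n_rejected`.
#' @export
run_pipeline <- function(config = default_config("smoke"), seed = 7,
                         out = NULL) {
  check_config(config, c("geometry", "stimuli", "template", "noise",
                         "preprocess", "inverse", "fmap", "decode",
                         "n_subjects"))
  seeds <- derive_seeds(seed, 2L + config$n_subjects)
  setup <- cohort_setup(config, seeds[1], config$n_subjects)
  cohort_raw <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(setup$stimuli, setup$template, setup$noise,
                     setup$leadfield, seed = setup$subject_seeds[i],
                     subject_id = sprintf("S%02d", i)))
  stim <- setup$stimuli

  clean <- list(); dec_cat <- list(); dec_rand <- list(); fmaps <- list()
  n_rejected <- integer(0)
  for (i in seq_along(cohort_raw)) {
    pp <- do.call(preprocess, c(list(epochs = cohort_raw[[i]]),
                                config$preprocess))
    ep <- pp$epochs
    n_rejected[i] <- length(pp$rejected)
    clean[[i]] <- ep

    # lead field restricted to the retained channels for the inverse stage
    lf <- compute_lead_field(ep$sensors, setup$geometry$sources,
                             head_radius = config$geometry$head_radius)
    ncov <- estimate_noise_covariance(ep, shrinkage = config$inverse$shrinkage)
    inv <- compute_inverse_filter(lf, ncov, lambda = config$inverse$lambda,
                                  epochs = ep, window = config$inverse$window)
    cur <- apply_inverse(inv, ep)
    fmaps[[i]] <- f_map(cur, window_center = config$fmap$window_center)

    feats <- do.call(extract_features,
                     c(list(epochs = ep), config$decode[c("win", "step",
                                                          "range")]))
    dec <- decode_subject(feats, stim, k = config$decode$k,
                          seed = seeds[2L + i], C = config$decode$C,
                          n_random = config$decode$n_random)
    dec_cat[[i]] <- dec$categorical
    dec_rand[[i]] <- dec$random
  }

  peaks <- cohort_peaks(clean)
  report <- list(
    peaks = peaks,
    peak_anova = if (length(unique(peaks$subject)) >= 2)
      compare_peaks(peaks) else NULL,
    fmap_mean = average_f_maps(fmaps),
    significance = if (config$n_subjects >= 2)
      test_significance(dec_cat, dec_rand) else NULL,
    decoding_categorical = dec_cat, decoding_random = dec_rand,
    n_rejected = n_rejected,
    config_hash = config_hash(config), seed = seed)
  class(report) <- "meg_report"

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    json <- list(seed = seed, config_hash = report$config_hash,
                 n_rejected = n_rejected,
                 peak_anova = report$peak_anova,
                 fmap_max = max(report$fmap_mean$F),
                 peak_accuracy_categorical =
                   max(colMeans(do.call(rbind, lapply(dec_cat, `[[`,
                                                      "accuracy")))),
                 peak_accuracy_random =
                   max(colMeans(do.call(rbind, lapply(dec_rand, `[[`,
                                                      "accuracy")))))
    jsonlite::write_json(json, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$significance))
      utils::write.csv(report$significance$table,
                       file.path(out, "decoding.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.meg_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, ", config ", substr(x$config_hash,
      1, 8), ")\n", sep = "")
  if (!is.null(x$peak_anova))
    cat(sprintf("  peak ANOVA: latency p = %.2f, amplitude p = %.2f\n",
                x$peak_anova$latency_p, x$peak_anova$amplitude_p))
  print(x$fmap_mean)
  if (!is.null(x$significance)) print(x$significance)
  invisible(x)
}

#' Chance-level recovery under the null
#'
#' Monte-Carlo calibration of the decoding chain: simulates small subjects
#' with the category effect and the per-image gains set to zero (so trial
#' labels carry no information), runs the full sliding-window categorical
#' decoding, and averages accuracy over all windows and seeds. With a
#' correct cross-validation chain the result is the 3-class chance rate,
#' 1/3.
#'
#' @param n_seeds number of independent simulated subjects (default 50).
#' @param seed master seed.
#' @param n_channels,n_vertices geometry of the null subjects (default 8
#'   and 16; channel selection is not applied).
#' @param repetitions stimulus repetitions (default 10, i.e. 120 body-part
#'   trials).
#' @return list: `mean_accuracy` (over windows and seeds), `se`
#'   (Monte-Carlo standard error across seeds), `accuracies` (per seed),
#'   `n_predictions` (trials x windows x seeds).
#' @export
null_chance_accuracy <- function(n_seeds = 50, seed = 1, n_channels = 8,
                                 n_vertices = 16, repetitions = 10) {
  cfg <- default_config("smoke")
  cfg$geometry <- list(n_channels = n_channels, n_vertices = n_vertices,
                       head_radius = 0.09)
  cfg$stimuli <- list(repetitions = repetitions)
  cfg$template$n_active <- 2
  cfg$template$category_effect <- 0
  cfg$template$image_gain_sd <- 0
  seeds <- derive_seeds(seed, n_seeds)
  accs <- vapply(seeds, function(s) {
    setup <- cohort_setup(cfg, s, 1)
    ep <- simulate_subject(setup$stimuli, setup$template, setup$noise,
                           setup$leadfield, seed = setup$subject_seeds[1])
    ep <- baseline_correct(ep)
    feats <- extract_features(ep)
    dec <- crossval_decode(feats, make_labels(setup$stimuli, "categorical"),
                           k = 10, seed = s)
    mean(dec$accuracy)
  }, numeric(1))
  list(mean_accuracy = mean(accs),
       se = stats::sd(accs) / sqrt(n_seeds),
       accuracies = accs,
       n_predictions = 12L * repetitions * 59L * n_seeds)
}
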