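#' Simulate one subject's epoch set
#'
#' Presents the stimulus schedule in a seeded pseudo-random order and
#' builds each trial as leadfield x (category source time course, scaled by
#' the image-specific gain) + background brain noise (random 1/f dipoles)
#' + white sensor noise. Per-channel gain jitter (the subject's geometry
#' mismatch) is drawn once per call from the same seed.
#'
#' Source amplitudes are calibrated so the noiseless evoked field peaks at
#' `template$target_peak_T` at the best channel (unless that is `NULL`).
#'
#' @param stimuli a `meg_stimuli` object.
#' @param template a `meg_template` object (vertex sets must exist in the
#'   lead field's source space).
#' @param noise a `meg_noise` object.
#' @param leadfield a `meg_leadfield` object.
#' @param seed integer; the full draw is deterministic given the seed.
#' @param subject_id label stored in the result.
#' @param times time axis in ms (default -500..499, 1000 samples at 1 kHz).
#' @return a `meg_epochs` object with `sim_info` holding the ground truth
#'   (jittered gain, per-image sensor patterns, kernel, active vertex sets).
#' @export
simulate_subject <- function(stimuli, template, noise, leadfield, seed,
                             subject_id = "S01", times = seq(-500, 499)) {
  nv <- ncol(leadfield$gain)
  all_v <- unlist(template$vertex_sets, use.names = FALSE)
  if (length(all_v) && max(all_v) > nv)
    stop_invalid("template references vertex ", max(all_v),
                 " outside the source space (", nv, " vertices)")
  nchan <- nrow(leadfield$gain)
  nsamp <- length(times)
  sfreq <- 1000 / stats::median(diff(times))

  with_seed(seed, {
    gain_jit <- 1 + stats::rnorm(nchan, 0, noise$gain_jitter_sd)
    G <- leadfield$gain * gain_jit
    order_idx <- sample.int(stimuli$schedule_length)

    # per-category noiseless sensor patterns (tesla at kernel peak)
    cats <- unique(stimuli$category)
    pat_cat <- sapply(cats, function(cat) {
      v <- template$vertex_sets[[cat]]
      a <- template$amplitudes[[cat]] * 1e-9      # nA.m -> A.m
      if (length(v) == 0) return(numeric(nchan))
      as.vector(G[, v, drop = FALSE] %*% a)
    })
    peak_field <- max(abs(pat_cat))
    scale <- if (is.null(template$target_peak_T) || peak_field == 0) 1
             else template$target_peak_T / peak_field
    pat_cat <- pat_cat * scale

    kernel <- evoked_kernel(times, template$peak_ms, template$support)
    sched_img <- rep(stimuli$image_id, each = stimuli$repetitions)[order_idx]
    sched_cat <- rep(stimuli$category, each = stimuli$repetitions)[order_idx]

    data <- array(0, c(length(sched_img), nchan, nsamp))
    bg_scale <- noise$background_sd * 1e-9
    for (t in seq_along(sched_img)) {
      pat <- pat_cat[, sched_cat[t]] * template$image_gain[sched_img[t]]
      x <- outer(pat, kernel)
      if (noise$n_background > 0 && bg_scale > 0) {
        vidx <- sample.int(nv, noise$n_background, replace = TRUE)
        series <- one_over_f_series(nsamp, noise$n_background, sfreq)
        x <- x + G[, vidx, drop = FALSE] %*% (bg_scale * t(series))
      }
      if (noise$sensor_sd > 0)
        x <- x + matrix(stats::rnorm(nchan * nsamp, 0, noise$sensor_sd),
                        nchan, nsamp)
      data[t, , ] <- x
    }
  })

  meg_epochs(data, times, sched_img, sched_cat, leadfield$sensors,
             subject_id, sfreq,
             sim_info = list(gain = G, gain_jitter = gain_jit,
                             pattern_by_category = pat_cat,
                             amplitude_scale = scale, kernel = kernel,
                             template = template, noise = noise))
}

# n x len matrix of unit-SD time series with 1/f power spectra
one_over_f_series <- function(len, n, sfreq) {
  white <- matrix(stats::rnorm(len * n), len, n)
  spec <- stats::mvfft(white)
  f <- c(0, seq_len(len - 1)) * sfreq / len
  f <- pmin(f, sfreq - f)                    # two-sided frequency axis
  w <- 1 / sqrt(pmax(f, 1))                  # flat below 1 Hz
  x <- Re(stats::mvfft(spec * w, inverse = TRUE)) / len
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Simulate a multi-subject cohort
#'
#' Builds the geometry, lead field, stimulus set and evoked template once
#' from `config`, then simulates `n_subjects` independent subjects with
#' per-subject seeds (gain jitter, trial order and noise are redrawn per
#' subject; the cortical template and image gains are cohort-level).
#'
#' @param n_subjects number of subjects (default 9).
#' @param config a configuration list, see [default_config()].
#' @param seed master seed; subject seeds are derived from it.
#' @return list of `meg_epochs`, one per subject.
#' @export
generate_cohort <- function(n_subjects = 9, config = default_config(),
                            seed = 7) {
  setup <- cohort_setup(config, seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(setup$stimuli, setup$template, setup$noise,
                     setup$leadfield, seed = setup$subject_seeds[i],
                     subject_id = sprintf("S%02d", i))
  })
}

# shared cohort-level objects: geometry, lead field, stimuli, template,
# noise model, and per-subject seeds, all derived from one master seed
cohort_setup <- function(config, seed, n_subjects = 1) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  check_config(config, c("geometry", "stimuli", "template", "noise"))
  seeds <- derive_seeds(seed, n_subjects + 2L)
  geom <- do.call(build_geometry, c(config$geometry, list(seed = seeds[1])))
  lf <- compute_lead_field(geom$sensors, geom$sources,
                           head_radius = geom$head_radius)
  stim <- do.call(stimulus_set, config$stimuli)
  tmpl <- do.call(evoked_template,
                  c(list(sources = geom$sources), config$template,
                    list(seed = seeds[2])))
  noi <- do.call(noise_model, config$noise)
  list(geometry = geom, leadfield = lf, stimuli = stim, template = tmpl,
       noise = noi, subject_seeds = seeds[-(1:2)])
}
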