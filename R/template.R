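#' Category-specific evoked-response template
#'
#' Defines where and when the simulated body-sensitive response is active.
#' Each body-part category activates a set of cortical vertices in the
#' EBA-like occipitotemporal patch: a fraction `overlap` of the set is
#' shared by all three body categories (the common body-sensitive
#' response) and the remainder is category-unique (the category-specific
#' variance the decoder must exploit). Object images activate a distinct
#' early-visual vertex set. The temporal profile is a smooth unimodal
#' pulse, identically zero outside `support`, built from two half-cosines
#' meeting at `peak_ms` (full width at half maximum 100 ms for the default
#' support and peak).
#'
#' @param sources a `meg_sources` object.
#' @param n_active vertices active per body category (default 12).
#' @param overlap fraction of `n_active` shared across body categories
#'   (default 0.5).
#' @param amplitude source amplitude in nA.m before calibration (default 10).
#' @param category_effect scale of the category-unique amplitude, 1 =
#'   default discriminability, 0 = no category information (all body
#'   categories share one identical source set).
#' @param image_gain_sd SD of the fixed per-image multiplicative gain
#'   (default 0.1), carrying image identity without category structure.
#' @param peak_ms kernel peak latency in ms (default 190).
#' @param support kernel support in ms, zero outside (default c(100, 300)).
#' @param target_peak_T calibrate source amplitudes so the noiseless evoked
#'   field peaks at this many tesla at the best channel (default 100 fT);
#'   `NULL` keeps raw `amplitude`.
#' @param seed seed for the vertex draws and per-image gains.
#' @return a `meg_template` object.
#' @export
evoked_template <- function(sources, n_active = 12, overlap = 0.5,
                            amplitude = 10, category_effect = 1,
                            image_gain_sd = 0.1, peak_ms = 190,
                            support = c(100, 300), target_peak_T = 100e-15,
                            seed = 1) {
  if (peak_ms <= support[1] || peak_ms >= support[2])
    stop_invalid("peak_ms must lie inside the kernel support")
  if (n_active < 1) stop_invalid("n_active must be >= 1")
  n_shared <- round(overlap * n_active)
  n_unique <- n_active - n_shared
  # candidate pool: the EBA-like patch, extended by the most patch-like
  # background vertices when the source space is small
  score <- -sources$positions[, "y"] + 0.6 * abs(sources$positions[, "x"]) -
    0.4 * sources$positions[, "z"]
  pool <- c(which(sources$region == "EBA-like"),
            setdiff(order(score, decreasing = TRUE),
                    which(sources$region != "background")))
  pool <- pool[!duplicated(pool)]
  need <- n_shared + 3 * n_unique
  if (need > length(pool))
    stop_invalid("source space too small for ", need, " template vertices")
  with_seed(seed, {
    picked <- sample(pool, need)
    shared <- if (n_shared > 0) picked[seq_len(n_shared)] else integer(0)
    rest <- if (n_shared > 0) picked[-seq_len(n_shared)] else picked
    uniq <- if (n_unique > 0) split(rest, rep(1:3, each = n_unique))
            else list(integer(0), integer(0), integer(0))
    ev_pool <- which(sources$region == "early-visual")
    obj <- sample(ev_pool, min(n_active, length(ev_pool)))
    image_gain <- 1 + stats::rnorm(14, 0, image_gain_sd)
  })
  vsets <- list(
    foot = c(shared, uniq[[1]]), hand = c(shared, uniq[[2]]),
    mouth = c(shared, uniq[[3]]), object = obj)
  amps <- lapply(body_categories, function(cat) {
    c(rep(amplitude, length(shared)),
      rep(amplitude * category_effect, length(vsets[[cat]]) - length(shared)))
  })
  names(amps) <- body_categories
  amps$object <- rep(amplitude, length(obj))
  structure(list(vertex_sets = vsets, amplitudes = amps,
                 shared_vertices = shared,
                 unique_vertices = unlist(uniq, use.names = FALSE),
                 category_effect = category_effect,
                 image_gain = image_gain, image_gain_sd = image_gain_sd,
                 peak_ms = peak_ms, support = support,
                 target_peak_T = target_peak_T),
            class = "meg_template")
}

#' Evoked temporal kernel
#'
#' Unit-peak pulse made of two half-cosine lobes joined at `peak_ms`,
#' identically zero outside `support`.
#'
#' @param times time axis in ms.
#' @param peak_ms peak latency.
#' @param support zero outside this interval (ms).
#' @return numeric vector, same length as `times`, peak value 1.
#' @export
evoked_kernel <- function(times, peak_ms = 190, support = c(100, 300)) {
  k <- numeric(length(times))
  up <- times >= support[1] & times <= peak_ms
  dn <- times > peak_ms & times <= support[2]
  k[up] <- 0.5 * (1 - cos(pi * (times[up] - support[1]) / (peak_ms - support[1])))
  k[dn] <- 0.5 * (1 + cos(pi * (times[dn] - peak_ms) / (support[2] - peak_ms)))
  k
}

#' Measurement and background noise model
#'
#' @param sensor_sd white sensor noise SD per sample, tesla (default
#'   300 fT, calibrated so single-trial decoding is above chance but below
#'   ceiling against the default 100 fT evoked peak).
#' @param n_background number of random background dipoles per trial
#'   (default 20) with 1/f-shaped spectra.
#' @param background_sd background dipole amplitude SD, nA.m (default 2).
#' @param gain_jitter_sd SD of the per-channel multiplicative gain jitter
#'   redrawn per subject (default 0.05).
#' @return a `meg_noise` object.
#' @export
noise_model <- function(sensor_sd = 300e-15, n_background = 20,
                        background_sd = 2, gain_jitter_sd = 0.05) {
  if (sensor_sd < 0 || background_sd < 0 || gain_jitter_sd < 0)
    stop_invalid("noise SDs must be >= 0")
  structure(list(sensor_sd = sensor_sd, n_background = as.integer(n_background),
                 background_sd = background_sd, gain_jitter_sd = gain_jitter_sd),
            class = "meg_noise")
}
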