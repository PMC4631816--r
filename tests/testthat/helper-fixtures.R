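# shared fixtures, all generated in code

# small cohort configuration used by most simulation-level tests
tiny_config <- function(n_channels = 16, n_vertices = 32, repetitions = 2,
                        n_active = 4) {
  cfg <- default_config("smoke")
  cfg$geometry <- list(n_channels = n_channels, n_vertices = n_vertices,
                       head_radius = 0.09)
  cfg$stimuli <- list(repetitions = repetitions)
  cfg$template$n_active <- n_active
  cfg
}

tiny_setup <- function(seed = 1, ...) {
  megdecode:::cohort_setup(tiny_config(...), seed, 1)
}

# epochs built directly from an array, with a synthetic sensor array
make_test_epochs <- function(data, times = NULL,
                             region = rep("other", dim(data)[2])) {
  nc <- dim(data)[2]
  if (is.null(times)) times <- seq_len(dim(data)[3]) - 1
  ang <- seq(0, pi, length.out = nc)
  pos <- 0.11 * cbind(x = sin(ang), y = cos(ang) * 0.5, z = abs(cos(ang)))
  sens <- structure(list(channel_id = sprintf("CH%02d", seq_len(nc)),
                         positions = pos,
                         orientations = pos / sqrt(rowSums(pos^2)),
                         region = region),
                    class = "meg_sensors")
  meg_epochs(data, times, image_id = seq_len(dim(data)[1]),
             category = rep("foot", dim(data)[1]), sensors = sens)
}

# single-trial sine epochs for filter measurements (1 kHz, 1 s)
sine_epochs <- function(freq, amp = 1, n_channels = 2) {
  times <- seq(-500, 499)
  x <- amp * sin(2 * pi * freq * times / 1000)
  data <- array(rep(x, each = n_channels), c(1, n_channels, length(times)))
  make_test_epochs(data, times)
}

trace_rms <- function(epochs, channel = 1) {
  sqrt(mean(epochs$data[1, channel, ]^2))
}

# noiseless single-category simulation used by evoked/source tests
noiseless_subject <- function(seed = 1, n_channels = 16, n_vertices = 32,
                              repetitions = 2, n_active = 4,
                              category_effect = 1) {
  cfg <- tiny_config(n_channels, n_vertices, repetitions, n_active)
  cfg$noise <- list(sensor_sd = 0, n_background = 0, background_sd = 0,
                    gain_jitter_sd = 0)
  cfg$template$image_gain_sd <- 0
  cfg$template$category_effect <- category_effect
  setup <- megdecode:::cohort_setup(cfg, seed, 1)
  list(setup = setup,
       epochs = simulate_subject(setup$stimuli, setup$template, setup$noise,
                                 setup$leadfield,
                                 seed = setup$subject_seeds[1]))
}
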