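#' Construct an epoch container
#'
#' Trials x channels x samples array of magnetic field values (tesla) with
#' per-trial stimulus labels, the time axis, and the sensor array.
#'
#' @param data numeric array, trials x channels x samples.
#' @param times time axis in ms (length = samples).
#' @param image_id integer per trial.
#' @param category character per trial.
#' @param sensors a `meg_sensors` object (channel count must match).
#' @param subject_id identifier stored with the data.
#' @param sfreq sampling rate, Hz.
#' @param sim_info optional list of generator ground truth (kept for
#'   forward-consistency checks).
#' @return a `meg_epochs` object.
#' @export
meg_epochs <- function(data, times, image_id, category, sensors,
                       subject_id = "S01", sfreq = 1000, sim_info = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times))
    stop_invalid("sample count does not match the time axis")
  if (dim(data)[2] != nrow(sensors$positions))
    stop_invalid("channel count does not match the sensor array")
  if (dim(data)[1] != length(image_id) || length(image_id) != length(category))
    stop_invalid("trial labels do not match the number of trials")
  if (anyNA(data)) stop_invalid("epoch data contain NA")
  structure(list(data = data, times = times, image_id = as.integer(image_id),
                 category = as.character(category), sensors = sensors,
                 subject_id = subject_id, sfreq = sfreq, sim_info = sim_info),
            class = "meg_epochs")
}

n_trials <- function(epochs) dim(epochs$data)[1]
n_channels <- function(epochs) dim(epochs$data)[2]

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("MEG epochs [", x$subject_id, "]: ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples (", min(x$times), "..", max(x$times),
      " ms @ ", x$sfreq, " Hz)\n", sep = "")
  tab <- table(x$category)
  cat("  trials per category:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# keep trials (rows) by logical or integer index, labels travelling with data
subset_trials <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$image_id <- epochs$image_id[keep]
  epochs$category <- epochs$category[keep]
  epochs
}

#' Write / read an epoch container as plain text
#'
#' Serializes a `meg_epochs` object to a directory holding `meta.json`
#' (labels, time axis, sensor geometry) and `data.csv` (one row per
#' trial-channel trace). A plain-text stand-in for a binary epoch
#' container; intended for small data sets.
#'
#' @param epochs a `meg_epochs` object.
#' @param dir directory to create/read.
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` returns
#'   the reconstructed `meg_epochs`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(times = epochs$times, image_id = epochs$image_id,
               category = epochs$category, subject_id = epochs$subject_id,
               sfreq = epochs$sfreq,
               sensors = list(channel_id = epochs$sensors$channel_id,
                              positions = epochs$sensors$positions,
                              orientations = epochs$sensors$orientations,
                              region = epochs$sensors$region))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  utils::write.csv(data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                              channel = rep(seq_len(d[2]), d[1]), flat),
                   file.path(dir, "data.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "data.csv"))
  nt <- max(tab$trial); nc <- max(tab$channel)
  ns <- ncol(tab) - 2L
  data <- aperm(array(t(as.matrix(tab[order(tab$trial, tab$channel), -(1:2)])),
                      dim = c(ns, nc, nt)), c(3, 2, 1))
  sens <- structure(list(channel_id = meta$sensors$channel_id,
                         positions = as.matrix(meta$sensors$positions),
                         orientations = as.matrix(meta$sensors$orientations),
                         region = meta$sensors$region),
                    class = "meg_sensors")
  colnames(sens$positions) <- colnames(sens$orientations) <- c("x", "y", "z")
  meg_epochs(data, meta$times, meta$image_id, meta$category, sens,
             meta$subject_id, meta$sfreq)
}
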