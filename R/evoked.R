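#' Per-category trial-averaged evoked fields
#'
#' @param epochs a `meg_epochs` object.
#' @param by label to average over: `"category"` (default) or `"image_id"`.
#' @return a named list of `meg_evoked` objects (`data`: channels x samples
#'   mean waveform in tesla, `times`, `n_trials`, `label`, `sensors`).
#' @export
average_evoked <- function(epochs, by = c("category", "image_id")) {
  assert_epochs(epochs)
  by <- match.arg(by)
  labels <- epochs[[by]]
  out <- lapply(sort(unique(labels)), function(lv) {
    sel <- which(labels == lv)
    structure(list(data = apply(epochs$data[sel, , , drop = FALSE],
                                c(2, 3), mean),
                   times = epochs$times, n_trials = length(sel),
                   label = as.character(lv), sensors = epochs$sensors),
              class = "meg_evoked")
  })
  names(out) <- as.character(sort(unique(labels)))
  out
}

#' @export
print.meg_evoked <- function(x, ...) {
  cat("Evoked [", x$label, "]: ", nrow(x$data), " channels x ",
      ncol(x$data), " samples, mean of ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

#' Locate the body-sensitive peak
#'
#' Finds the channel and latency of the maximum negative component (the
#' most negative signed field value) in the search window. Ties are broken
#' by the earliest time, then the lowest channel index.
#'
#' @param evoked a `meg_evoked` object.
#' @param window search window in ms (default c(140, 240)).
#' @param channel optional fixed channel index; when given, only the
#'   latency/amplitude on that channel are searched (used to hold one peak
#'   channel per subject across categories).
#' @return a list: `channel` (index), `channel_id`, `latency_ms`,
#'   `amplitude` (tesla, <= 0 for a genuine negative peak).
#' @export
find_peak <- function(evoked, window = c(140, 240), channel = NULL) {
  if (window[1] >= window[2]) stop_invalid("empty peak search window")
  idx <- window_index(evoked$times, window[1], window[2] + 1e-9)
  seg <- evoked$data[, idx, drop = FALSE]
  if (!is.null(channel)) seg <- seg[channel, , drop = FALSE]
  if (all(seg == 0))
    warning("evoked is flat in the search window", call. = FALSE)
  # seg is channels x time: column-major argmin visits channels within the
  # earliest time first, giving the required tie-break order
  m <- arrayInd(which.min(seg), dim(seg))
  ch <- if (is.null(channel)) m[1] else channel
  list(channel = ch, channel_id = evoked$sensors$channel_id[ch],
       latency_ms = evoked$times[idx[m[2]]], amplitude = min(seg))
}

#' Compare peak latency and amplitude across categories
#'
#' One-way ANOVA across categories of per-subject peak latencies and
#' amplitudes (each subject contributes one value per category).
#'
#' @param peaks data frame with columns `subject`, `category`,
#'   `latency_ms`, `amplitude`.
#' @return list with `latency_F`, `latency_p`, `amplitude_F`, `amplitude_p`.
#' @export
compare_peaks <- function(peaks) {
  stopifnot(all(c("subject", "category", "latency_ms", "amplitude")
                %in% names(peaks)))
  if (length(unique(peaks$category)) < 2)
    stop_invalid("need at least two categories")
  lat <- f_oneway(peaks$latency_ms, peaks$category)
  amp <- f_oneway(peaks$amplitude, peaks$category)
  list(latency_F = lat$F, latency_p = lat$p,
       amplitude_F = amp$F, amplitude_p = amp$p)
}

# classical fixed-effects one-way ANOVA from sums of squares; degenerate
# cases (no between-group variance) return F = 0, p = 1
f_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  if (ssb <= 0) return(list(F = 0, p = 1))
  if (ssw <= 0) return(list(F = Inf, p = 0))
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

#' Spatial field map and dipolarity index
#'
#' Extracts the per-channel field vector at time `t` and summarizes how
#' balanced its ingoing/outgoing pattern is: the dipolarity index is
#' `2 * min(max, -min) / (max - min)`, clamped to [0, 1] - it is 1 for a
#' perfectly balanced two-pole map and 0 for a single-signed map.
#'
#' @param evoked a `meg_evoked` object.
#' @param t time in ms (nearest sample is used).
#' @return list: `values` (per-channel tesla), `t_ms`, `dipolarity`.
#' @export
field_map <- function(evoked, t) {
  if (t < min(evoked$times) || t > max(evoked$times))
    stop_invalid("t outside the epoch time axis")
  i <- which.min(abs(evoked$times - t))
  v <- evoked$data[, i]
  M <- max(v); m <- min(v)
  dip <- if (M == m) 0 else max(0, 2 * min(M, -m) / (M - m))
  list(values = v, t_ms = evoked$times[i], dipolarity = dip)
}

#' Per-subject evoked peaks for a cohort
#'
#' Convenience wrapper: averages evoked responses per category, fixes one
#' peak channel per subject (the channel of the most negative component
#' over all body categories pooled), then records each category's latency
#' and amplitude on that channel.
#'
#' @param cohort list of `meg_epochs`.
#' @param window peak search window in ms.
#' @param per_category if TRUE, pick the peak channel independently per
#'   category instead of once per subject.
#' @return data frame: subject, category, channel_id, latency_ms, amplitude.
#' @export
cohort_peaks <- function(cohort, window = c(140, 240), per_category = FALSE) {
  do.call(rbind, lapply(cohort, function(ep) {
    ev <- average_evoked(ep)
    ev <- ev[intersect(body_categories, names(ev))]
    fixed_ch <- NULL
    if (!per_category) {
      pooled <- ev[[1]]
      pooled$data <- Reduce(`+`, lapply(ev, `[[`, "data")) / length(ev)
      fixed_ch <- find_peak(pooled, window)$channel
    }
    do.call(rbind, lapply(ev, function(e) {
      pk <- find_peak(e, window, channel = fixed_ch)
      data.frame(subject = ep$subject_id, category = e$label,
                 channel_id = pk$channel_id, latency_ms = pk$latency_ms,
                 amplitude = pk$amplitude)
    }))
  }))
}
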