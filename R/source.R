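#' Baseline noise covariance
#'
#' Channel covariance of the pre-stimulus samples pooled over trials
#' (maximum-likelihood normalization, so duplicating trials leaves it
#' unchanged), shrunk toward its diagonal.
#'
#' @param epochs a `meg_epochs` object.
#' @param window pre-stimulus window in ms (default c(-500, -100)).
#' @param shrinkage weight of the diagonal target in [0, 1] (default 0.1).
#' @return channels x channels symmetric positive semi-definite matrix.
#' @export
estimate_noise_covariance <- function(epochs, window = c(-500, -100),
                                      shrinkage = 0.1) {
  assert_epochs(epochs)
  if (window[2] > 0) stop_invalid("noise window must be pre-stimulus")
  idx <- window_index(epochs$times, window[1], window[2])
  d <- epochs$data[, , idx, drop = FALSE]
  # samples x channels, trials concatenated
  X <- matrix(aperm(d, c(3, 1, 2)), ncol = dim(d)[2])
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / nrow(X)
  if (all(C == 0))
    warning("zero baseline data: noise covariance is the zero matrix",
            call. = FALSE)
  (1 - shrinkage) * C + shrinkage * diag(diag(C), nrow(C))
}

#' Minimum-norm inverse filter
#'
#' L2-regularized linear inverse `W = G' (G G' + lambda_eff C)^-1` mapping
#' sensor data to per-vertex current estimates. `C` is the noise
#' covariance normalized to unit mean diagonal; `lambda_eff` scales
#' `lambda` by the mean diagonal of `G G'` and, when `epochs` are given,
#' divides by the mean signal power in `window` relative to the baseline
#' noise power (so stronger responses are regularized less).
#'
#' @param leadfield a `meg_leadfield` object.
#' @param noise_cov channels x channels covariance (tesla^2); NULL uses
#'   the identity.
#' @param lambda dimensionless regularization parameter > 0 (default 0.1).
#' @param epochs optional `meg_epochs` used only for the signal-power
#'   scaling of lambda.
#' @param window response window in ms for that scaling (default
#'   c(140, 240), when the body-sensitive response is present).
#' @return a `meg_inverse`: `W` (vertices x channels), `lambda`,
#'   `lambda_eff`, `channel_id`.
#' @export
compute_inverse_filter <- function(leadfield, noise_cov = NULL, lambda = 0.1,
                                   epochs = NULL, window = c(140, 240)) {
  if (!is.numeric(lambda) || lambda <= 0) stop_invalid("lambda must be > 0")
  G <- leadfield$gain
  nc <- nrow(G)
  if (is.null(noise_cov)) noise_cov <- diag(nc)
  if (!isSymmetric(unname(noise_cov), tol = 1e-8))
    stop_invalid("noise covariance must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop_invalid("noise covariance must be positive semi-definite")
  md <- mean(diag(noise_cov))
  Cn <- if (md > 0) noise_cov / md else diag(nc)
  GGt <- tcrossprod(G)
  snr <- 1
  if (!is.null(epochs) && md > 0) {
    idx <- window_index(epochs$times, window[1], window[2])
    snr <- max(mean(epochs$data[, , idx]^2) / md, 1e-12)
  }
  lambda_eff <- lambda * mean(diag(GGt)) / snr
  W <- t(G) %*% solve(GGt + lambda_eff * Cn)
  structure(list(W = W, lambda = lambda, lambda_eff = lambda_eff,
                 channel_id = leadfield$sensors$channel_id,
                 vertex_id = leadfield$sources$vertex_id),
            class = "meg_inverse")
}

#' Apply the inverse filter and window-average currents
#'
#' Estimates per-trial vertex currents and averages them in consecutive
#' non-overlapping windows (half-open, `[start, start + win)`).
#'
#' @param filter a `meg_inverse`.
#' @param epochs a `meg_epochs` with the same channels the filter was
#'   built for.
#' @param win window length in ms (default 20).
#' @return a `meg_currents`: `values` (trials x vertices x windows, A.m),
#'   `window_centers` (ms), `win`, with trial labels copied over.
#' @export
apply_inverse <- function(filter, epochs, win = 20) {
  assert_epochs(epochs)
  if (!identical(filter$channel_id, epochs$sensors$channel_id))
    stop_invalid("channel sets of filter and epochs do not match")
  starts <- seq(min(epochs$times), max(epochs$times) - win + 1, by = win)
  nt <- n_trials(epochs)
  nv <- nrow(filter$W)
  idx_list <- lapply(starts, function(s)
    which(epochs$times >= s & epochs$times < s + win))
  vals <- array(0, c(nt, nv, length(starts)))
  for (t in seq_len(nt)) {
    J <- filter$W %*% epochs$data[t, , ]          # vertices x samples
    for (w in seq_along(starts))
      vals[t, , w] <- rowMeans(J[, idx_list[[w]], drop = FALSE])
  }
  structure(list(values = vals, window_centers = starts + win / 2, win = win,
                 image_id = epochs$image_id, category = epochs$category,
                 subject_id = epochs$subject_id),
            class = "meg_currents")
}

#' @export
print.meg_currents <- function(x, ...) {
  d <- dim(x$values)
  cat("Current estimates [", x$subject_id, "]: ", d[1], " trials x ", d[2],
      " vertices x ", d[3], " windows (", x$win, " ms)\n", sep = "")
  invisible(x)
}

#' Per-vertex one-way ANOVA F-map
#'
#' For each vertex, the F statistic of a one-way ANOVA comparing the
#' window-averaged current values across the trial groups named in
#' `contrast` (all three body categories, or any pair).
#'
#' @param currents a `meg_currents`.
#' @param contrast categories to compare (default foot/hand/mouth).
#' @param window_center which 20-ms window to test, by its centre in ms
#'   (default 190, the 180-200 ms window); the nearest centre is used.
#' @param use_abs compare current magnitudes instead of signed values
#'   (default FALSE).
#' @return a `meg_fmap`: `F` per vertex, `contrast`, `group_n`,
#'   `window_center`.
#' @export
f_map <- function(currents, contrast = c("foot", "hand", "mouth"),
                  window_center = 190, use_abs = FALSE) {
  w <- which.min(abs(currents$window_centers - window_center))
  sel <- currents$category %in% contrast
  g <- factor(currents$category[sel], levels = contrast)
  if (nlevels(g) < 2 || any(tabulate(g, nlevels(g)) < 2))
    stop_invalid("each contrast group needs at least 2 trials")
  X <- currents$values[, , w, drop = FALSE][sel, , 1, drop = FALSE]
  X <- matrix(X, nrow = sum(sel))                 # trials x vertices
  if (use_abs) X <- abs(X)
  Fv <- f_oneway_columns(X, g)
  structure(list(F = Fv, contrast = contrast, group_n = tabulate(g, nlevels(g)),
                 window_center = currents$window_centers[w]),
            class = "meg_fmap")
}

# vectorized one-way ANOVA over the columns of X
f_oneway_columns <- function(X, g) {
  k <- nlevels(g)
  n <- nrow(X)
  gn <- tabulate(g, nlevels(g))
  gmean <- rowsum(X, g) / gn
  grand <- colMeans(X)
  ssb <- colSums(gn * sweep(gmean, 2, grand)^2)
  ssw <- colSums(X^2) - colSums(gn * gmean^2)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  F[ssb <= 0] <- 0
  F[ssw <= 0 & ssb > 0] <- Inf
  pmax(F, 0)
}

#' Average F-maps across subjects
#'
#' @param fmaps list of `meg_fmap` over the same source space and contrast.
#' @return a `meg_fmap` with the vertex-wise mean F.
#' @export
average_f_maps <- function(fmaps) {
  stopifnot(length(fmaps) >= 1)
  nv <- length(fmaps[[1]]$F)
  if (!all(vapply(fmaps, function(f) length(f$F) == nv, logical(1))))
    stop_invalid("F-maps cover different source spaces")
  out <- fmaps[[1]]
  out$F <- Reduce(`+`, lapply(fmaps, `[[`, "F")) / length(fmaps)
  out$n_subjects <- length(fmaps)
  out
}

#' @export
print.meg_fmap <- function(x, ...) {
  cat("F-map [", paste(x$contrast, collapse = "/"), "] at ",
      x$window_center, " ms: ", length(x$F), " vertices, max F = ",
      format(max(x$F), digits = 4), "\n", sep = "")
  invisible(x)
}
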