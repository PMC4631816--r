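#' Sliding-window feature extraction
#'
#' Per-channel mean amplitude in 20-ms windows slid by 10 ms over
#' -100..500 ms (59 windows with the defaults). Windows are half-open
#' `[t, t + win)` and a window is formed for every start from `range[1]`
#' up to `range[2] - win`.
#'
#' @param epochs a `meg_epochs` object.
#' @param win window length in ms (default 20).
#' @param step window step in ms (default 10).
#' @param range start/end of the sliding range in ms (default c(-100, 500)).
#' @return a `meg_features`: `windows` (list of trials x channels
#'   matrices), `centers` (ms), `image_id`, `category`.
#' @export
extract_features <- function(epochs, win = 20, step = 10,
                             range = c(-100, 500)) {
  assert_epochs(epochs)
  if (win <= 0 || step <= 0) stop_invalid("win and step must be > 0")
  if (range[1] < min(epochs$times) || range[2] > max(epochs$times) + 1)
    stop_invalid("feature range outside the epoch time axis")
  starts <- seq(range[1], range[2] - win, by = step)
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1] * d[2])   # (trial,channel) x samples
  windows <- lapply(starts, function(s) {
    idx <- which(epochs$times >= s & epochs$times < s + win)
    matrix(rowMeans(flat[, idx, drop = FALSE]), d[1], d[2])
  })
  structure(list(windows = windows, centers = starts + win / 2,
                 image_id = epochs$image_id, category = epochs$category,
                 subject_id = epochs$subject_id),
            class = "meg_features")
}

#' @export
print.meg_features <- function(x, ...) {
  cat("Decoding features [", x$subject_id, "]: ", length(x$windows),
      " windows x ", nrow(x$windows[[1]]), " trials x ",
      ncol(x$windows[[1]]), " channels\n", sep = "")
  invisible(x)
}

#' Categorical or random 3-class label scheme
#'
#' Maps the 12 body-part images (objects excluded) to three classes of
#' four images each. The categorical scheme uses the true body-part
#' categories; the random scheme draws a seeded balanced partition,
#' resampled until no class consists of four images of a single category
#' (so it carries image identity but not category structure).
#'
#' @param stimuli a `meg_stimuli` object.
#' @param scheme `"categorical"` or `"random"`.
#' @param seed seed for the random partition.
#' @return a `meg_labels`: `map` (named integer vector image_id -> class
#'   1..3), `scheme`.
#' @export
make_labels <- function(stimuli, scheme = c("categorical", "random"),
                        seed = 1) {
  scheme <- match.arg(scheme)
  body <- stimuli$image_id[stimuli$category %in% body_categories]
  if (length(body) != 12)
    stop_invalid("label schemes require the 12 body-part images")
  cat_of <- stimuli$category[match(body, stimuli$image_id)]
  if (scheme == "categorical") {
    map <- match(cat_of, body_categories)
  } else {
    map <- with_seed(seed, {
      repeat {
        perm <- sample(body)
        cls <- integer(12)
        cls[match(perm, body)] <- rep(1:3, each = 4)
        pure <- vapply(1:3, function(k)
          length(unique(cat_of[cls == k])) == 1, logical(1))
        if (!any(pure)) break
      }
      cls
    })
  }
  names(map) <- body
  structure(list(map = map, scheme = scheme), class = "meg_labels")
}

#' Train a 3-class linear max-margin classifier
#'
#' One-vs-rest scheme: three binary linear soft-margin SVMs (hinge loss,
#' penalty `C`), each reduced to an explicit weight vector and bias; the
#' predicted class is the argmax of the three linear scores
#' `w_k . x + b_k`.
#'
#' @param x trials x features matrix.
#' @param y class labels (3 levels after factoring).
#' @param C soft-margin penalty (default 1).
#' @return a `meg_classifier`: `W` (classes x features), `b` (length 3),
#'   `classes`.
#' @export
train_classifier <- function(x, y, C = 1) {
  y <- factor(y)
  if (nlevels(y) < 2) stop_invalid("training data contain a single class")
  if (any(table(y) < 2)) stop_invalid("need at least 2 examples per class")
  classes <- levels(y)
  W <- matrix(0, length(classes), ncol(x))
  b <- numeric(length(classes))
  for (k in seq_along(classes)) {
    yk <- factor(ifelse(y == classes[k], "pos", "rest"),
                 levels = c("pos", "rest"))
    m <- e1071::svm(x, yk, kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
    w <- as.vector(crossprod(m$coefs, m$SV))
    bias <- -m$rho
    s <- x %*% w + bias
    if (mean(s[y == classes[k]]) < mean(s[y != classes[k]])) {
      w <- -w; bias <- -bias
    }
    W[k, ] <- w
    b[k] <- bias
  }
  structure(list(W = W, b = b, classes = classes), class = "meg_classifier")
}

#' @export
predict.meg_classifier <- function(object, newdata, ...) {
  scores <- newdata %*% t(object$W) + rep(object$b, each = nrow(newdata))
  object$classes[max.col(scores, ties.method = "first")]
}

#' Stratified k-fold cross-validated decoding
#'
#' For every sliding window: z-scores features with training-fold
#' statistics, trains the one-vs-rest linear classifier on k-1 folds,
#' tests on the held-out fold, and averages fold accuracies. Trials whose
#' image is not in the label scheme (objects) are excluded.
#'
#' @param features a `meg_features`.
#' @param labels a `meg_labels`.
#' @param k number of folds (default 10).
#' @param seed seed for the stratified fold assignment.
#' @param C soft-margin penalty (default 1).
#' @return a `meg_decoding`: `accuracy` (per window), `correct` (per
#'   window total correct test predictions), `n` (trials decoded),
#'   `centers`, `scheme`, `k`.
#' @export
crossval_decode <- function(features, labels, k = 10, seed = 1, C = 1) {
  keep <- which(as.character(features$image_id) %in% names(labels$map))
  y <- factor(labels$map[as.character(features$image_id[keep])])
  if (length(keep) < k) stop_invalid("fewer trials than folds")
  folds <- with_seed(seed, {
    f <- integer(length(keep))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  acc <- correct <- numeric(length(features$windows))
  for (w in seq_along(features$windows)) {
    X <- features$windows[[w]][keep, , drop = FALSE]
    fold_acc <- numeric(k)
    for (fo in seq_len(k)) {
      tr <- folds != fo
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd[sd == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/")
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
      clf <- train_classifier(Xtr, y[tr], C = C)
      pred <- predict(clf, Xte)
      hits <- sum(pred == as.character(y[!tr]))
      fold_acc[fo] <- hits / sum(!tr)
      correct[w] <- correct[w] + hits
    }
    acc[w] <- mean(fold_acc)
  }
  structure(list(accuracy = acc, correct = correct, n = length(keep),
                 centers = features$centers, scheme = labels$scheme, k = k),
            class = "meg_decoding")
}

#' @export
print.meg_decoding <- function(x, ...) {
  cat("Decoding [", x$scheme, "]: ", length(x$accuracy), " windows, ",
      x$n, " trials, ", x$k, "-fold CV; peak accuracy ",
      sprintf("%.1f%%", 100 * max(x$accuracy)), " at ",
      x$centers[which.max(x$accuracy)], " ms\n", sep = "")
  invisible(x)
}

#' Significance of decoding accuracies across subjects
#'
#' Per window: a two-sided binomial test of the pooled correct counts
#' against chance 1/3 for each scheme, a paired two-sided t-test of
#' categorical vs random accuracy across subjects, and 95% t-based
#' confidence intervals of the mean accuracy.
#'
#' @param categorical list of `meg_decoding` (one per subject).
#' @param random list of `meg_decoding` (same subjects; each may be the
#'   average over several random partitions, see [decode_subject()]).
#' @return a `meg_significance`: data frame `table` with one row per
#'   window (centre, mean/CI per scheme, binomial p per scheme, paired p).
#' @export
test_significance <- function(categorical, random = NULL) {
  ns <- length(categorical)
  if (ns < 2) stop_invalid("need at least two subjects")
  centers <- categorical[[1]]$centers
  acc_c <- do.call(rbind, lapply(categorical, `[[`, "accuracy"))
  cor_c <- do.call(rbind, lapply(categorical, `[[`, "correct"))
  n_c <- sum(vapply(categorical, `[[`, numeric(1), "n"))
  res <- data.frame(center_ms = centers,
                    categorical_mean = colMeans(acc_c),
                    categorical_ci_low = ci_bound(acc_c, -1),
                    categorical_ci_high = ci_bound(acc_c, 1),
                    categorical_binom_p = binom_p(colSums(cor_c), n_c))
  if (!is.null(random)) {
    acc_r <- do.call(rbind, lapply(random, `[[`, "accuracy"))
    cor_r <- do.call(rbind, lapply(random, `[[`, "correct"))
    n_r <- sum(vapply(random, `[[`, numeric(1), "n"))
    res$random_mean <- colMeans(acc_r)
    res$random_ci_low <- ci_bound(acc_r, -1)
    res$random_ci_high <- ci_bound(acc_r, 1)
    res$random_binom_p <- binom_p(colSums(cor_r), n_r)
    res$paired_p <- vapply(seq_along(centers), function(w)
      paired_t_p(acc_c[, w], acc_r[, w]), numeric(1))
  }
  structure(list(table = res, n_subjects = ns), class = "meg_significance")
}

ci_bound <- function(acc, side) {
  ns <- nrow(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(ns)
  colMeans(acc) + side * stats::qt(0.975, ns - 1) * se
}

binom_p <- function(correct, n) {
  vapply(correct, function(x)
    stats::binom.test(round(x), n, p = 1 / 3)$p.value, numeric(1))
}

# paired two-sided t-test robust to zero-variance differences
paired_t_p <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' @export
print.meg_significance <- function(x, ...) {
  tab <- x$table
  w <- which.max(tab$categorical_mean)
  cat("Decoding significance over ", x$n_subjects, " subjects, ",
      nrow(tab), " windows\n", sep = "")
  cat(sprintf("  peak categorical accuracy %.1f%% at %g ms (binomial p = %.2g)\n",
              100 * tab$categorical_mean[w], tab$center_ms[w],
              tab$categorical_binom_p[w]))
  if ("random_mean" %in% names(tab))
    cat(sprintf("  random-scheme accuracy there %.1f%% (paired p = %.2g)\n",
                100 * tab$random_mean[w], tab$paired_p[w]))
  invisible(x)
}

#' Decode one subject with both schemes
#'
#' Runs categorical decoding and `n_random` random-partition decodings
#' (accuracies averaged across partitions) on one subject's features.
#'
#' @param features a `meg_features`.
#' @param stimuli the `meg_stimuli` the labels derive from.
#' @param k folds (default 10).
#' @param seed seed for folds and random partitions.
#' @param C soft-margin penalty.
#' @param n_random number of random partitions averaged (default 20).
#' @return list with elements `categorical` and `random` (`meg_decoding`;
#'   the random element has partition-averaged accuracies/counts).
#' @export
decode_subject <- function(features, stimuli, k = 10, seed = 1, C = 1,
                           n_random = 20) {
  seeds <- derive_seeds(seed, n_random + 1L)
  cat_res <- crossval_decode(features, make_labels(stimuli, "categorical"),
                             k = k, seed = seeds[1], C = C)
  rand_runs <- lapply(seq_len(n_random), function(i)
    crossval_decode(features,
                    make_labels(stimuli, "random", seed = seeds[i + 1L]),
                    k = k, seed = seeds[1], C = C))
  rand <- rand_runs[[1]]
  rand$accuracy <- Reduce(`+`, lapply(rand_runs, `[[`, "accuracy")) / n_random
  rand$correct <- Reduce(`+`, lapply(rand_runs, `[[`, "correct")) / n_random
  list(categorical = cat_res, random = rand)
}
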