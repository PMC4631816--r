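# features with class-specific means for separability tests: 12 body
# images x reps trials, 4 channels, nw windows
separable_features <- function(reps = 4, nw = 2, sd = 0, seed = 1) {
  set.seed(seed)
  stim <- stimulus_set(reps)
  image_id <- rep(stim$image_id[stim$category != "object"], each = reps)
  category <- rep(stim$category[stim$category != "object"], each = reps)
  centers <- seq(0, by = 10, length.out = nw)
  mu <- rbind(foot = c(4, 0, 0, 0), hand = c(0, 4, 0, 0),
              mouth = c(0, 0, 4, 0))
  windows <- lapply(seq_len(nw), function(w)
    mu[category, ] + matrix(rnorm(length(category) * 4, 0, sd),
                            ncol = 4))
  structure(list(windows = windows, centers = centers, image_id = image_id,
                 category = category, subject_id = "S01"),
            class = "meg_features")
}

test_that("sliding windows enumerate 59 starts over -100..500 ms", {
  ns <- noiseless_subject(seed = 1, repetitions = 1)
  feats <- extract_features(ns$epochs)
  expect_length(feats$windows, 59)
  expect_equal(feats$centers[1], -90)
  expect_equal(feats$centers[59], 490)
  expect_equal(diff(feats$centers), rep(10, 58))
  expect_equal(ncol(feats$windows[[1]]), n_channels(ns$epochs))
  expect_error(extract_features(ns$epochs, win = 0), "> 0")
  expect_error(extract_features(ns$epochs, range = c(-900, 500)),
               "time axis")
})

test_that("features are window means of the raw signal", {
  data <- array(0, c(2, 3, 1000))
  data[1, , ] <- 2.5                        # constant trial
  times <- seq(-500, 499)
  ramp <- as.numeric(times)                 # linear trial
  data[2, , ] <- rep(ramp, each = 3)
  ep <- make_test_epochs(data, times)
  feats <- extract_features(ep)
  expect_true(all(abs(feats$windows[[1]][1, ] - 2.5) < 1e-12))
  # window [0, 20) of a unit ramp has mean 9.5
  w0 <- which(feats$centers == 10)
  expect_equal(feats$windows[[w0]][2, ], rep(9.5, 3), tolerance = 1e-12)
})

test_that("label schemes partition the 12 body images 4/4/4", {
  stim <- stimulus_set()
  cat_lab <- make_labels(stim, "categorical")
  expect_length(cat_lab$map, 12)
  expect_equal(as.integer(table(cat_lab$map)), c(4L, 4L, 4L))
  expect_true(all(cat_lab$map[as.character(1:4)] ==
                  cat_lab$map[as.character(1)]))   # feet together
  for (seed in 1:10) {
    r <- make_labels(stim, "random", seed = seed)
    expect_equal(as.integer(table(r$map)), c(4L, 4L, 4L))
    truecat <- stim$category[match(as.integer(names(r$map)), stim$image_id)]
    for (k in 1:3)
      expect_gt(length(unique(truecat[r$map == k])), 1)
  }
  expect_identical(make_labels(stim, "random", seed = 3),
                   make_labels(stim, "random", seed = 3))
  # object images must be excluded before building schemes
  only_obj <- stimulus_set()
  only_obj$category <- rep("object", 14)
  expect_error(make_labels(only_obj, "categorical"), "12 body-part")
})

test_that("the one-vs-rest linear classifier separates point clouds", {
  set.seed(7)
  x <- rbind(matrix(rnorm(20, 5, 0.3), 10, 2),
             matrix(rnorm(20, -5, 0.3), 10, 2),
             matrix(rnorm(20, 0, 0.3) + rep(c(0, 8), each = 10), 10, 2))
  y <- rep(c("a", "b", "c"), each = 10)
  clf <- train_classifier(x, y)
  expect_equal(dim(clf$W), c(3, 2))
  expect_equal(unname(predict(clf, x)), y)
  # duplicating the training set leaves the decision function unchanged
  clf2 <- train_classifier(rbind(x, x), c(y, y))
  grid <- as.matrix(expand.grid(seq(-6, 6, 2), seq(-6, 10, 2)))
  expect_equal(predict(clf, grid), predict(clf2, grid))
  expect_error(train_classifier(x, rep("a", 30)), "single class")
})

test_that("cross-validated decoding is perfect on separable features", {
  feats <- separable_features(reps = 4, nw = 3, sd = 0.1)
  stim <- stimulus_set(4)
  dec <- crossval_decode(feats, make_labels(stim, "categorical"), k = 10,
                         seed = 1)
  expect_equal(dec$accuracy, rep(1, 3))
  expect_equal(dec$n, 48)
  expect_equal(dec$correct, rep(48, 3))     # every trial tested exactly once
})

test_that("shuffled labels bring decoding back to chance", {
  set.seed(11)
  feats <- separable_features(reps = 4, nw = 6, sd = 0.1)
  # destroy the label-feature link
  perm <- sample(length(feats$image_id))
  feats$image_id <- feats$image_id[perm]
  feats$category <- feats$category[perm]
  dec <- crossval_decode(feats, make_labels(stimulus_set(4), "categorical"),
                         k = 6, seed = 2)
  n_pred <- dec$n * length(dec$accuracy)
  se <- sqrt(1 / 3 * 2 / 3 / n_pred)
  expect_lt(abs(mean(dec$accuracy) - 1 / 3), 3 * se + 0.05)
})

test_that("stratified folds have the expected size at full scale", {
  # 480 body-part trials, k = 10 -> test folds of 48 with 16 per class
  feats <- separable_features(reps = 40, nw = 1, sd = 0.5)
  stim <- stimulus_set(40)
  dec <- crossval_decode(feats, make_labels(stim, "categorical"), k = 10,
                         seed = 3)
  expect_equal(dec$n, 480)
  folds <- with(list(), {
    y <- factor(make_labels(stim, "categorical")$map[
      as.character(feats$image_id)])
    f <- megdecode:::with_seed(3, {
      fv <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fv[idx] <- rep_len(seq_len(10), length(idx))
      }
      fv
    })
    f
  })
  expect_equal(as.integer(table(folds)), rep(48L, 10))
})

test_that("decoding accuracy is invariant to channel order and scale", {
  feats <- separable_features(reps = 4, nw = 2, sd = 1, seed = 5)
  lab <- make_labels(stimulus_set(4), "categorical")
  base <- crossval_decode(feats, lab, k = 4, seed = 9)
  permuted <- feats
  permuted$windows <- lapply(feats$windows, function(w) w[, c(3, 1, 4, 2)])
  scaled <- feats
  scaled$windows <- lapply(feats$windows, function(w) w * 1e3)
  expect_equal(crossval_decode(permuted, lab, k = 4, seed = 9)$accuracy,
               base$accuracy)
  expect_equal(crossval_decode(scaled, lab, k = 4, seed = 9)$accuracy,
               base$accuracy, tolerance = 1e-9)
})

test_that("significance statistics behave on constructed accuracies", {
  mk <- function(acc, correct, n) structure(
    list(accuracy = acc, correct = correct, n = n, centers = c(100, 200),
         scheme = "categorical", k = 10), class = "meg_decoding")
  # all-correct 100-trial windows across 2 subjects
  allc <- list(mk(c(1, 1), c(50, 50), 50), mk(c(1, 1), c(50, 50), 50))
  sig <- test_significance(allc)
  expect_lt(max(sig$table$categorical_binom_p), 1e-10)
  # accuracy exactly at chance
  third <- list(mk(c(1, 1) / 3, c(20, 20), 60), mk(c(1, 1) / 3, c(20, 20), 60))
  expect_gt(min(test_significance(third)$table$categorical_binom_p), 0.9)
  # identical categorical and random accuracies -> paired p = 1
  sig2 <- test_significance(allc, allc)
  expect_equal(sig2$table$paired_p, c(1, 1))
  expect_error(test_significance(allc[1]), "two subjects")
})
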