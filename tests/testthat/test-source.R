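# orthogonal toy gain: 8 channels, 8 vertices
toy_leadfield <- function(scale = 1e-13) {
  G <- scale * diag(8)
  sens <- structure(list(channel_id = sprintf("T%02d", 1:8),
                         positions = NULL, orientations = NULL,
                         region = rep("other", 8)), class = "meg_sensors")
  structure(list(gain = G, center = c(0, 0, 0), head_radius = 0.09,
                 sensors = sens,
                 sources = list(vertex_id = 1:8)), class = "meg_leadfield")
}

test_that("noise covariance recovers white-noise variance with shrinkage", {
  set.seed(4)
  sd0 <- 2e-14
  data <- array(rnorm(50 * 4 * 1000, sd = sd0), c(50, 4, 1000))
  ep <- make_test_epochs(data, seq(-500, 499))
  C <- estimate_noise_covariance(ep)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(sd0^2, 4), tolerance = 0.1, ignore_attr = TRUE)
  # duplicating every trial leaves the ML covariance unchanged
  dup <- make_test_epochs(array(c(data, data), c(100, 4, 1000)),
                          seq(-500, 499))
  dup$image_id <- rep(1:100)
  expect_equal(estimate_noise_covariance(dup), C, tolerance = 1e-12)
  # zero data
  zero <- make_test_epochs(array(0, c(3, 4, 1000)), seq(-500, 499))
  expect_warning(Cz <- estimate_noise_covariance(zero), "zero")
  expect_true(all(Cz == 0))
  expect_error(estimate_noise_covariance(ep, window = c(100, 200)),
               "pre-stimulus")
})

test_that("inverse filter approaches the pseudo-inverse as lambda -> 0", {
  lf <- toy_leadfield()
  inv <- compute_inverse_filter(lf, noise_cov = diag(8), lambda = 1e-12)
  # one-hot current recovery through forward + inverse
  j <- rep(0, 8); j[3] <- 5e-9
  b <- lf$gain %*% j
  jhat <- inv$W %*% b
  expect_equal(as.vector(jhat), j, tolerance = 1e-6)
})

test_that("inverse estimates shrink to zero as lambda -> infinity", {
  lf <- toy_leadfield()
  b <- lf$gain %*% rep(1e-9, 8)
  norms <- sapply(c(1, 1e4, 1e8), function(l)
    sum(abs(compute_inverse_filter(lf, diag(8), lambda = l)$W %*% b)))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 1e-6 * norms[1])
})

test_that("invalid covariance and lambda are rejected", {
  lf <- toy_leadfield()
  expect_error(compute_inverse_filter(lf, diag(8), lambda = 0), "lambda")
  bad <- diag(8); bad[1, 1] <- -5
  expect_error(compute_inverse_filter(lf, bad), "positive semi-definite")
  asym <- diag(8); asym[1, 2] <- 1
  expect_error(compute_inverse_filter(lf, asym), "symmetric")
})

test_that("a single active vertex is localized by the minimum-norm inverse", {
  ns <- noiseless_subject(seed = 9, n_channels = 32, n_vertices = 48,
                          repetitions = 1, n_active = 1)
  setup <- ns$setup
  true_v <- setup$template$vertex_sets$foot[1]
  inv <- compute_inverse_filter(setup$leadfield, noise_cov = NULL,
                                lambda = 1e-6)
  trial <- which(ns$epochs$category == "foot")[1]
  jhat <- inv$W %*% ns$epochs$data[trial, , ns$epochs$times == 190]
  expect_equal(which.max(abs(jhat)), true_v)
})

test_that("apply_inverse windows currents on the 20-ms grid", {
  lf <- toy_leadfield()
  set.seed(5)
  data <- array(rnorm(3 * 8 * 1000, sd = 1e-13), c(3, 8, 1000))
  ep <- make_test_epochs(data, seq(-500, 499))
  ep$sensors$channel_id <- lf$sensors$channel_id
  inv <- compute_inverse_filter(lf, diag(8), lambda = 0.1)
  cur <- apply_inverse(inv, ep)
  expect_equal(dim(cur$values), c(3, 8, 50))      # 1000 ms / 20 ms
  expect_equal(cur$window_centers[1], -490)
  expect_equal(cur$win, 20)
  # linearity
  ep2 <- ep; ep2$data <- 3 * ep$data
  cur2 <- apply_inverse(inv, ep2)
  expect_equal(cur2$values, 3 * cur$values, tolerance = 1e-12)
  # zero data -> zero currents
  epz <- ep; epz$data[] <- 0
  expect_true(all(apply_inverse(inv, epz)$values == 0))
  # manual window average for one cell
  J <- inv$W %*% ep$data[2, , ]
  expect_equal(cur$values[2, 5, 3],
               mean(J[5, ep$times >= -460 & ep$times < -440]),
               tolerance = 1e-12)
  # mismatched channels are rejected
  ep$sensors$channel_id[1] <- "XX"
  expect_error(apply_inverse(inv, ep), "channel sets")
})

test_that("per-vertex F-map matches the sum-of-squares oracle", {
  # two groups (1,2) vs (3,4) at one vertex -> F = 8 (frozen from the
  # textbook oracle, cross-checked against oneway.test)
  vals <- array(0, c(4, 2, 1))
  vals[, 1, 1] <- c(1, 2, 3, 4)
  vals[, 2, 1] <- c(10, 10, 10, 10)
  cur <- structure(list(values = vals, window_centers = 0, win = 20,
                        image_id = 1:4,
                        category = c("foot", "foot", "hand", "hand"),
                        subject_id = "S01"), class = "meg_currents")
  fm <- f_map(cur, contrast = c("foot", "hand"), window_center = 0)
  expect_equal(fm$F[1], 8)
  ref <- stats::oneway.test(c(1, 2, 3, 4) ~ factor(c(1, 1, 2, 2)),
                            var.equal = TRUE)
  expect_equal(fm$F[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fm$F[2], 0)                 # identical groups
  expect_equal(fm$group_n, c(2L, 2L))
  expect_error(f_map(cur, contrast = c("foot", "mouth")), "at least 2")
})

test_that("F-map is invariant to global current rescaling", {
  set.seed(6)
  vals <- array(rnorm(20 * 5 * 2), c(20, 5, 2))
  cur <- structure(list(values = vals, window_centers = c(0, 20), win = 20,
                        image_id = 1:20,
                        category = rep(c("foot", "hand"), 10),
                        subject_id = "S01"), class = "meg_currents")
  f1 <- f_map(cur, c("foot", "hand"), window_center = 0)
  cur$values <- cur$values * 1e6
  f2 <- f_map(cur, c("foot", "hand"), window_center = 0)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
  expect_true(all(f1$F >= 0))
})

test_that("category-unique vertices carry higher F than background", {
  cfg <- tiny_config(n_channels = 32, n_vertices = 64, repetitions = 5,
                     n_active = 6)
  setup <- megdecode:::cohort_setup(cfg, 13, 1)
  ep <- simulate_subject(setup$stimuli, setup$template, setup$noise,
                         setup$leadfield, seed = 21)
  ep <- baseline_correct(ep)
  ncov <- estimate_noise_covariance(ep)
  inv <- compute_inverse_filter(setup$leadfield, ncov, lambda = 0.1,
                                epochs = ep)
  fm <- f_map(apply_inverse(inv, ep))
  uniq <- setup$template$unique_vertices
  bg <- setdiff(seq_along(fm$F),
                unlist(setup$template$vertex_sets, use.names = FALSE))
  expect_gt(mean(fm$F[uniq]), mean(fm$F[bg]))
})

test_that("F-map averaging is the vertex-wise mean", {
  f1 <- structure(list(F = c(0, 2), contrast = c("foot", "hand"),
                       group_n = c(2L, 2L), window_center = 190),
                  class = "meg_fmap")
  f2 <- f1; f2$F <- c(8, 2)
  avg <- average_f_maps(list(f1, f2))
  expect_equal(avg$F, c(4, 2))
  expect_equal(average_f_maps(list(f1))$F, f1$F)
  expect_equal(average_f_maps(list(f1, f1))$F, f1$F)
  f3 <- f1; f3$F <- 1:3
  expect_error(average_f_maps(list(f1, f3)), "different source spaces")
})
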