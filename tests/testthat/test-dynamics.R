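test_that("the mixture fit recovers noiseless two-Gaussian parameters", {
  sp <- simulate_profile(
    data.frame(beta0 = c(10, 18), velocity = 0, amplitude = c(50, 30),
               width = 2),
    n_x = 30, n_frames = 1, baseline = 10, noise_sigma = 0)
  f <- fit_two_gaussians(sp$x, sp$profile[, 1])
  expect_false(f$skipped)
  expect_equal(f$n_peaks_effective, 2L)
  expect_lt(abs(f$beta1 - 10), 0.1)
  expect_lt(abs(f$beta2 - 18), 0.1)
  expect_lt(abs(f$A1p - 50) / 50, 0.05)
})

test_that("a single-Gaussian profile yields one effective peak", {
  sp <- simulate_profile(
    data.frame(beta0 = 15, velocity = 0, amplitude = 60, width = 2.5),
    n_x = 30, n_frames = 1, baseline = 10, noise_sigma = 0)
  f <- fit_two_gaussians(sp$x, sp$profile[, 1])
  expect_equal(f$n_peaks_effective, 1L)
  expect_lt(abs(f$effective$beta - 15), 0.2)
})

test_that("a mirror-symmetric profile fits symmetric centres", {
  x <- 1:41
  y <- 10 + 40 * exp(-(x - 14)^2 / 8) + 40 * exp(-(x - 28)^2 / 8)
  f <- fit_two_gaussians(x, y)
  expect_equal(f$beta1 + f$beta2, 42, tolerance = 0.1)
})

test_that("too few bright samples gives a skip marker, not an error", {
  y <- c(rep(10, 25), 60, rep(10, 25))
  expect_true(fit_two_gaussians(seq_along(y), y)$skipped)
})

test_that("profile extraction reproduces an analytic ridge and stays fixed", {
  # Gaussian ridge across the adhesion axis
  n <- 96
  X <- matrix(rep(1:n, each = n), n, n)
  ridge <- 80 * exp(-(X - 48)^2 / (2 * 4^2))
  frames <- list(ridge, ridge, ridge)
  series <- image_series(frames, pixel_size = 0.105, frame_interval = 5)
  phi <- seq(0, 2 * pi, length.out = 721)
  contour <- cbind(x = 48 + 40 * cos(phi), y = 48 + 40 * sin(phi))
  adh <- data.frame(x = 48, y = 48, a = 8, xi = 0.5, theta = 0, id = 1)
  pr <- extract_profile(series, adh, list(contour, contour, contour), 2,
                        window = 1)
  pred <- 80 * exp(-pr$s^2 / (2 * 4^2))
  expect_lt(max(abs(pr$intensity[, 1] - pred)) / 80, 0.01)
  # positions identical at every frame by construction
  expect_identical(dim(pr$intensity), c(length(pr$s), 3L))
  expect_equal(pr$boundary_s, rep(40, 3), tolerance = 1e-6)
  # window clipping at the series start
  pr2 <- extract_profile(series, adh, list(contour, contour, contour), 1,
                         window = 20)
  expect_equal(pr2$frames, 1:3)
})

test_that("an axis that misses the contour raises a named error", {
  series <- image_series(list(matrix(1, 32, 32)))
  contour <- cbind(x = c(1, 2, 2, 1, 1), y = c(1, 1, 2, 2, 1))
  adh <- data.frame(x = 25, y = 25, a = 6, xi = 0.5, theta = 0, id = 7)
  expect_error(extract_profile(series, adh, list(contour), 1),
               "does not intersect")
})

test_that("well-separated constant-velocity clusters give clean tracks", {
  sc <- data.frame(beta0 = c(15, 40), velocity = c(0, -0.4),
                   amplitude = c(70, 80), width = 3)
  pf <- profile_from_script(sc, n_x = 61, n_frames = 41, noise_sigma = 0)
  bt <- build_trajectories(pf)
  expect_equal(length(bt$trajectories), 2L)
  expect_true(all(!vapply(bt$trajectories, function(g) any(g$stray),
                          logical(1))))
  # appearance at the first unflagged frame
  expect_equal(min(bt$trajectories[[1]]$frame), 1)
})

test_that("velocity estimation converts slopes and catches switches", {
  # 0.25 px/frame toward smaller s = away; 5 s/frame, 0.105 um/px
  g <- data.frame(frame = 1:20, s = 50 - 0.25 * (0:19), stray = FALSE)
  v <- estimate_velocity(g)
  expect_equal(v$v_um_min, 0.25 * 0.105 * 12, tolerance = 1e-6)
  # stationary cluster with noise: confidence interval brackets zero
  set.seed(41)
  hits <- 0
  for (k in 1:20) {
    gn <- data.frame(frame = 1:30, s = 30 + rnorm(30, 0, 0.2),
                     stray = FALSE)
    ci <- estimate_velocity(gn)$ci
    if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # direction switch at mid-window
  gs <- data.frame(frame = 1:40,
                   s = c(40 - 0.5 * (0:19), 30.5 + 0.5 * (1:20)),
                   stray = FALSE)
  vs <- estimate_velocity(gs)
  expect_true(vs$switch)
  expect_true(vs$segments[1] > 0 && vs$segments[2] < 0)
  # too few samples: undefined marker
  expect_true(is.na(estimate_velocity(
    data.frame(frame = 1:3, s = 1:3, stray = FALSE))$v_um_min))
})

test_that("velocity estimates are unbiased over repeated noise draws", {
  sc <- data.frame(beta0 = 45, velocity = -0.4, amplitude = 80, width = 3)
  vs <- vapply(1:25, function(seed) {
    pf <- profile_from_script(sc, noise_sigma = 8, seed = seed)
    bt <- build_trajectories(pf)
    g <- bt$trajectories[[which.max(vapply(bt$trajectories, nrow,
                                           integer(1)))]]
    estimate_velocity(g, pf)$v_um_min
  }, numeric(1))
  expect_lt(abs(mean(vs) - 0.4) / 0.4, 0.05)
})

test_that("velocity histograms conserve counts and separate directions", {
  v <- c(rep(0.32, 5), rep(-0.18, 3))
  r <- rep(c("protruding", "central"), c(5, 3))
  h <- regional_velocity_histograms(v, r)
  expect_equal(sum(vapply(h$histograms, function(d) sum(d$count),
                          integer(1))), 8L)
  expect_equal(h$histograms$protruding$mid, 0.35)
  set.seed(42)
  mix <- c(runif(140, 0.1, 0.6), runif(60, -0.6, -0.1))
  hm <- regional_velocity_histograms(mix, rep("central", 200))
  pos <- sum(hm$histograms$central$count[hm$histograms$central$mid > 0])
  expect_equal(pos / 200, 0.7, tolerance = 0.07)
})
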