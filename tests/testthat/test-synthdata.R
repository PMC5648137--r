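test_that("rendering is bit-reproducible under a fixed seed", {
  cfg <- scene_config(shape = c(48, 48), n_frames = 3,
                      adhesions = data.frame(x = 24, y = 24, a = 8,
                                             xi = 0.5, theta = 40,
                                             amplitude = 100),
                      noise = list(gaussian_sigma = 10,
                                   poisson_gain = 0.5),
                      seed = 7L)
  s1 <- simulate_movie(cfg)
  s2 <- simulate_movie(cfg)
  expect_identical(s1$series$frames, s2$series$frames)
})

test_that("a noiseless adhesion peaks at its scripted centre", {
  cfg <- scene_config(shape = c(48, 48),
                      adhesions = data.frame(x = 30, y = 18, a = 8,
                                             xi = 0.5, theta = 40,
                                             amplitude = 100))
  fr <- simulate_movie(cfg)$noiseless[[1]]
  idx <- which(fr == max(fr), arr.ind = TRUE)
  expect_lte(abs(idx[1, 2] - 30), 1)
  expect_lte(abs(idx[1, 1] - 18), 1)
})

test_that("scripted front displacement follows the exact arithmetic", {
  cfg <- scene_config(
    shape = c(160, 160), n_frames = 5,
    cell = list(center = c(80, 80), radius = 40, base_intensity = 50,
                fronts = data.frame(phi0 = 0, phi1 = 360, velocity = 1.8,
                                    taper = 1e-6)))
  sim <- simulate_movie(cfg)
  b <- sim$truth$boundary
  r1 <- sqrt((b$x[b$frame == 1] - 80)^2 + (b$y[b$frame == 1] - 80)^2)
  r5 <- sqrt((b$x[b$frame == 5] - 80)^2 + (b$y[b$frame == 5] - 80)^2)
  # 1.8 um/min * (5 s / 60) / 0.105 um/px per frame, times 4 frames
  # (the cosine roll-off at the seam angle leaves a sub-0.2% residual)
  expect_equal(mean(r5) - mean(r1), 4 * 1.8 * (5 / 60) / 0.105,
               tolerance = 2e-3)
})

test_that("an adhesion outside the cell mask is a configuration error", {
  cfg <- scene_config(
    shape = c(96, 96),
    cell = list(center = c(48, 48), radius = 20, base_intensity = 50),
    adhesions = data.frame(x = 90, y = 90, a = 6, xi = 0.5, theta = 0,
                           amplitude = 80))
  expect_error(simulate_movie(cfg), "outside")
})

test_that("profile scripts render exactly and noise follows the model", {
  sc <- data.frame(beta0 = c(20, 40), velocity = c(0.4, -0.4),
                   amplitude = 80, width = 3)
  pr <- simulate_profile(sc, n_x = 61, n_frames = 11, noise_sigma = 0)
  # zero velocity, zero noise: constant over time
  pr0 <- simulate_profile(data.frame(beta0 = 30, velocity = 0,
                                     amplitude = 80, width = 3),
                          n_frames = 5, noise_sigma = 0)
  expect_true(all(pr0$profile == pr0$profile[, 1]))
  # scripted slopes are exact in the truth table
  tr <- pr$truth[pr$truth$cluster == 1, ]
  slope_px <- (tr$beta[11] - tr$beta[1]) / 10
  expect_equal(slope_px, 0.4 * (5 / 60) / 0.105, tolerance = 1e-12)
  # Poisson noise: per-sample variance tracks the mean
  prp <- simulate_profile(data.frame(beta0 = 30, velocity = 0,
                                     amplitude = 0.0, width = 3),
                          n_x = 100, n_frames = 100, baseline = 100,
                          noise_sigma = 0, poisson_gain = 1, seed = 5)
  expect_equal(var(as.vector(prp$profile)), 100, tolerance = 10)
})

test_that("the scenario library scripts every regime", {
  lib <- scenario_library()
  cats <- grep("^category_", names(lib), value = TRUE)
  expect_equal(length(cats), 10L)
  expect_setequal(sub("category_", "", cats), LETTERS[1:10])
  expect_equal(lib$bundle_mutant$bundles$v_vinculin /
                 lib$bundle_mutant$bundles$v_myosin, 13 / 7)
  expect_lt(mean(c(lib$bundle_wildtype$bundles$v_myosin,
                   lib$bundle_wildtype$bundles$v_vinculin)), 0.03)
  expect_true(!is.null(lib$protrusion$cell))
  expect_equal(nrow(detection_scene(seed = 2L)$adhesions), 20L)
})
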