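gauss_prof <- function(A = 100, sigma = 3, center = 25, n = 50,
                       noise = 0, seed = 1) {
  x <- seq_len(n)
  y <- A * exp(-(x - center)^2 / (2 * sigma^2))
  if (noise > 0) y <- with_seed_test(seed, y + rnorm(n, 0, noise))
  y
}
with_seed_test <- function(seed, expr) {
  set.seed(seed); force(expr)
}

test_that("prominence method finds clean Gaussians and orders by height", {
  p1 <- peaks_by_prominence(gauss_prof())
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$center - 25), 0.2)
  # two well-separated Gaussians, prominence ordering by amplitude
  y <- gauss_prof(A = 100, center = 15, n = 80) +
    gauss_prof(A = 60, center = 60, n = 80)
  p2 <- peaks_by_prominence(y)
  expect_equal(nrow(p2), 2L)
  expect_lt(abs(p2$center[1] - 15), 0.5)
  expect_lt(abs(p2$center[2] - 60), 0.5)
  expect_true(p2$prominence[1] > p2$prominence[2])
  # constant profile: empty
  expect_equal(nrow(peaks_by_prominence(rep(5, 40))), 0L)
})

test_that("second-derivative method agrees with method 1 on clean data", {
  y <- gauss_prof(A = 100, sigma = 3, center = 25)
  p1 <- peaks_by_prominence(y)
  p2 <- peaks_by_second_derivative(y)
  expect_gte(nrow(p2), 1L)
  expect_lt(abs(p2$center[1] - p1$center[1]), 0.5)
  # recovered size within 10% of the analytic area
  expect_lt(abs(p2$size[1] - 100 * 3 * sqrt(2 * pi)) /
              (100 * 3 * sqrt(2 * pi)), 0.1)
  # the second difference of a Gaussian is most negative at the centre
  ys <- y
  d2 <- diff(ys, differences = 2)
  expect_equal(which.min(d2) + 1L, 25L)
})

test_that("lorentzian-wavelet fits recover their own template exactly", {
  x <- 1:80
  y <- 500 * psi_lorentzian_pair(x, 33, 4)
  p3 <- peaks_by_lorentzian_wavelet(y, x)
  expect_gte(nrow(p3), 1L)
  expect_lt(abs(p3$center[1] - 33) / 33, 0.01)
  expect_lt(abs(p3$width[1] - 4) / 4, 0.01)
  # and land within half a pixel on a clean Gaussian
  g <- gauss_prof(A = 80, sigma = 3, center = 25)
  pg <- peaks_by_lorentzian_wavelet(g)
  expect_lt(abs(pg$center[1] - 25), 0.5)
  expect_equal(nrow(peaks_by_lorentzian_wavelet(rep(2, 40))), 0L)
})

test_that("cross-method centres agree on noiseless Gaussians", {
  for (A in c(10, 100, 1000)) {
    for (sigma in c(1.5, 3, 6)) {
      y <- gauss_prof(A = A, sigma = sigma, center = 30, n = 64)
      c1 <- peaks_by_prominence(y)$center[1]
      c2 <- peaks_by_second_derivative(y)$center[1]
      c3 <- peaks_by_lorentzian_wavelet(y)$center[1]
      expect_lt(abs(c1 - c2), 0.5)
      expect_lt(abs(c1 - c3), 0.5)
    }
  }
})

test_that("consensus keeps three-way coincidences and is order invariant", {
  y <- gauss_prof(A = 100, center = 15, n = 80) +
    gauss_prof(A = 60, center = 60, n = 80)
  s1 <- peaks_by_prominence(y)
  s2 <- peaks_by_second_derivative(y)
  s3 <- peaks_by_lorentzian_wavelet(y)
  cons <- peaks_consensus(s1, s2, s3)
  expect_equal(nrow(cons), 2L)
  cons_perm <- peaks_consensus(s3, s1, s2)
  expect_equal(sort(cons$center), sort(cons_perm$center))
  # a peak reported by only two methods is dropped
  s3_missing <- s3[abs(s3$center - 60) > 5, , drop = FALSE]
  cons2 <- peaks_consensus(s1, s2, s3_missing)
  expect_equal(nrow(cons2), 1L)
  expect_lt(abs(cons2$center - 15), 1)
})

test_that("pole velocities are recovered in both scripted regimes", {
  lib <- scenario_library()
  for (nm in c("bundle_wildtype", "bundle_mutant")) {
    sim <- simulate_movie(lib[[nm]])
    bundle <- data.frame(x = 48, y = 48, theta = 25, half_length = 18)
    pa <- pole_analysis(sim$series, bundle)
    expect_gte(nrow(pa$poles), 3)
    truth <- lib[[nm]]$bundles
    for (ch in c("myosin", "vinculin")) {
      v_true <- if (ch == "myosin") truth$v_myosin else truth$v_vinculin
      v_est <- pa$poles$v_um_min[pa$poles$channel == ch]
      expect_lt(max(abs(v_est - v_true)) / v_true, 0.25)
    }
    if (nm == "bundle_mutant") {
      expect_true(all(pa$pairs$delta_v_um_min > 0))
    }
  }
})
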