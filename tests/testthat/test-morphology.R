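test_that("boundary extraction of an empty frame warns and returns nothing", {
  expect_warning(b <- extract_boundary(matrix(0, 64, 64), band = c(20, 40)),
                 "no foreground")
  expect_null(b$contour)
})

test_that("a bright disk's contour is recovered within the smallest scale", {
  n <- 220
  X <- matrix(rep(1:n, each = n), n, n)
  Y <- matrix(rep(1:n, n), n, n)
  frame <- ifelse((X - 110)^2 + (Y - 110)^2 <= 80^2, 100, 0)
  b <- extract_boundary(frame, band = c(20, 100), delta_a = 8)
  expect_false(is.null(b$contour))
  r <- sqrt((b$contour[, 1] - 110)^2 + (b$contour[, 2] - 110)^2)
  expect_lt(abs(mean(r) - 80), 20)   # within a_min of the true radius
})

test_that("raising the threshold never grows the enclosed area", {
  n <- 128
  X <- matrix(rep(1:n, each = n), n, n)
  Y <- matrix(rep(1:n, n), n, n)
  frame <- 100 * exp(-((X - 64)^2 + (Y - 64)^2) / (2 * 30^2))
  fld <- cwt_forward(frame, scales = seq(20, 48, by = 4))
  areas <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(f)
    extract_boundary(frame, threshold = f, field = fld)$enclosed_area,
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("region decomposition obeys the exact set identities", {
  set.seed(21)
  for (rep in 1:5) {
    m0 <- matrix(runif(400) > 0.5, 20, 20)
    m1 <- matrix(runif(400) > 0.5, 20, 20)
    d <- decompose_regions(m0, m1)
    expect_identical(d$stable | d$protruded, m1)
    expect_identical(d$stable | d$retracted, m0)
    expect_false(any(d$protruded & d$retracted))
    expect_false(any(d$protruded & d$stable))
  }
  # a translated disk sweeps congruent crescents
  n <- 64
  X <- matrix(rep(1:n, each = n), n, n)
  Y <- matrix(rep(1:n, n), n, n)
  d0 <- (X - 28)^2 + (Y - 32)^2 <= 15^2
  d1 <- (X - 34)^2 + (Y - 32)^2 <= 15^2
  d <- decompose_regions(d0, d1)
  expect_equal(sum(d$protruded), sum(d$retracted))
  same <- decompose_regions(d0, d0)
  expect_equal(sum(same$protruded), 0)
  expect_equal(sum(same$retracted), 0)
})

test_that("front metrics recover a uniformly growing disk analytically", {
  n <- 200
  radii <- 60 + (0:5)   # 1 px per frame
  bounds <- lapply(radii, function(r) circle_boundary(n, 100, 100, r))
  fm <- front_metrics(bounds, pixel_size = 0.105, frame_interval = 5)
  expect_equal(fm$front_velocity$um_min, 0.105 * 12, tolerance = 0.1)
  # full-circle front arc length
  expect_equal(fm$per_frame$arc_length_um[1], 2 * pi * 61 * 0.105,
               tolerance = 0.02)
  # swept annulus area
  expect_equal(fm$per_frame$swept_area_um2[5],
               pi * (65^2 - 60^2) * 0.105^2, tolerance = 0.03)
})

test_that("adhesion-boundary geometry matches analytic cases", {
  straight <- cbind(x = seq(0, 100, by = 0.5), y = 50)
  perp <- list(x = 50, y = 30, a = 8, xi = 0.5, theta = 90)
  par <- list(x = 50, y = 30, a = 8, xi = 0.5, theta = 0)
  g_perp <- adhesion_boundary_geometry(perp, straight)
  g_par <- adhesion_boundary_geometry(par, straight)
  expect_equal(g_perp$tangent_angle, 90, tolerance = 0.5)
  expect_equal(g_par$tangent_angle, 0, tolerance = 0.5)
  expect_equal(g_perp$distance_um, 20 * 0.105, tolerance = 0.01)
  # radially oriented adhesion inside a circular boundary
  phi <- seq(0, 2 * pi, length.out = 1441)
  circ <- cbind(x = 150 + 100 * cos(phi), y = 150 + 100 * sin(phi))
  radial <- list(x = 150 + 80, y = 150, a = 8, xi = 0.5, theta = 0)
  g <- adhesion_boundary_geometry(radial, circ)
  expect_equal(g$distance_um, 20 * 0.105, tolerance = 0.01)
  expect_lt(abs(g$tangent_angle - 90), 2)
})

test_that("region assignment follows the distance and nearest-front rules", {
  front1 <- data.frame(x = seq(0, 100, by = 1), y = 50,
                       label = rep(c("protruding", "stable"), c(51, 50)))
  front0 <- data.frame(x = seq(0, 100, by = 1), y = 55,
                       label = rep(c("stable", "retracting"), c(51, 50)))
  dec <- list(front_t0 = front0, front_t1 = front1)
  # ~6 um away: central (centrality threshold 4 um)
  far <- list(x = 25, y = 50 - 6 / 0.105)
  expect_equal(assign_region(far, dec), "central")
  # ~1 um from a purely protruding stretch
  near <- list(x = 10, y = 50 - 1 / 0.105)
  expect_equal(assign_region(near, dec), "protruding")
  near_r <- list(x = 95, y = 55 - 1 / 0.105)
  expect_equal(assign_region(near_r, dec), "retracting")
  # equidistant within tolerance
  mid <- list(x = 52, y = 52.5)
  expect_equal(assign_region(mid, dec), "intersecting")
})
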