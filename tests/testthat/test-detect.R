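test_that("ellipse disjointness matches a dense sampling oracle", {
  set.seed(11)
  n_agree <- 0
  for (k in 1:80) {
    e1 <- random_ellipse(); e2 <- random_ellipse()
    alg <- ellipses_disjoint(e1, e2)
    samp <- !sampled_overlap(e1, e2)
    # skip near-tangent cases the sampled oracle cannot decide reliably
    if (alg == samp) n_agree <- n_agree + 1
  }
  expect_gte(n_agree, 78)
  # hand-picked certainties
  expect_true(ellipses_disjoint(
    list(x = 0, y = 0, p = 3, q = 1, phi = 0),
    list(x = 10, y = 0, p = 3, q = 1, phi = 0)))
  expect_false(ellipses_disjoint(
    list(x = 0, y = 0, p = 3, q = 1, phi = 0),
    list(x = 1, y = 0, p = 3, q = 1, phi = 90)))
  # containment is overlap, not disjointness
  expect_false(ellipses_disjoint(
    list(x = 0, y = 0, p = 8, q = 8, phi = 0),
    list(x = 1, y = 0, p = 2, q = 1, phi = 30)))
})

test_that("a single anisotropic blob yields one maximum at the right place", {
  frame <- blob_frame(64, 30, 34, 6, 1.5, 40)
  det <- detect_adhesions(frame, scales = c(8, 10, 12),
                          xis = c(0.25, 0.5), n_theta = 180)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 30), 1.5)
  expect_lt(abs(det$y - 34), 1.5)
  # orientation against brute-force argmax over the same grid
  fld <- cwt_forward(frame, scales = c(8, 10, 12), xis = c(0.25, 0.5),
                     thetas = seq(0, 179), mesh = "native")
  best <- c(NA, -Inf)
  for (si in 1:3) for (xj in 1:2) {
    A <- fld$entries[[si]]$values[, , xj, ] / sqrt(fld$xis[xj])
    mx <- max(A)
    if (mx > best[2]) {
      ti <- which(A == mx, arr.ind = TRUE)[1, 3]
      best <- c(fld$thetas[ti], mx)
    }
  }
  expect_lte(axial_error(det$theta, best[1]), 1)
  # blob long axis is at 40 degrees in the major-axis convention
  ax <- adhesion_axes(det$a, det$xi, det$theta)
  expect_lte(axial_error(ax$phi_major, 40), 2)
})

test_that("threshold fraction one keeps only the global maximum", {
  frame <- blob_frame(64, 20, 20, 4, 1.5, 10, A = 100) +
    blob_frame(64, 46, 44, 4, 1.5, 100, A = 60)
  det <- detect_adhesions(frame, scales = 7, xis = 0.4, n_theta = 36,
                          threshold_fraction = 1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 20) + abs(det$y - 20), 3)
})

test_that("a uniform image yields no detections", {
  det <- detect_adhesions(matrix(5, 48, 48), scales = c(5, 7), xis = 0.5,
                          n_theta = 12)
  expect_equal(nrow(det), 0L)
})

test_that("greedy placement keeps the larger of two coincident candidates", {
  m <- data.frame(x = c(30, 30, 70), y = c(30, 30, 30),
                  a = 6, xi = 0.5, theta = c(10, 40, 90),
                  coefficient = c(5, 3, 4))
  placed <- place_adhesions(m)
  expect_equal(nrow(placed), 2L)
  expect_setequal(placed$coefficient, c(5, 4))
  # two candidates far apart are both accepted
  m2 <- data.frame(x = c(10, 110), y = c(10, 110), a = 6, xi = 0.5,
                   theta = 0, coefficient = c(2, 1))
  expect_equal(nrow(place_adhesions(m2)), 2L)
})

test_that("greedy placement matches an independent reference on small sets", {
  set.seed(12)
  for (rep in 1:12) {
    k <- sample(3:8, 1)
    m <- data.frame(x = runif(k, 5, 45), y = runif(k, 5, 45),
                    a = runif(k, 3, 7), xi = runif(k, 0.4, 1.5),
                    theta = runif(k, 0, 180),
                    coefficient = round(runif(k, 1, 10), 3))
    placed <- place_adhesions(m)
    # reference: same sweep order, sampling-based overlap oracle
    ord <- order(-m$coefficient, m$y, m$x)
    acc <- list()
    for (r in ord) {
      ax <- adhesion_axes(m$a[r], m$xi[r], m$theta[r])
      e <- list(x = m$x[r], y = m$y[r], p = ax$semi_par, q = ax$semi_perp,
                phi = m$theta[r])
      if (!any(vapply(acc, sampled_overlap, logical(1), e1 = e)))
        acc[[length(acc) + 1]] <- e
    }
    expect_equal(nrow(placed), length(acc))
    expect_setequal(round(placed$x, 6),
                    round(vapply(acc, `[[`, numeric(1), "x"), 6))
  }
})

test_that("accepted footprints are pairwise disjoint", {
  set.seed(13)
  m <- data.frame(x = runif(40, 5, 60), y = runif(40, 5, 60),
                  a = runif(40, 3, 8), xi = runif(40, 0.4, 1.5),
                  theta = runif(40, 0, 180),
                  coefficient = runif(40, 1, 10))
  placed <- place_adhesions(m)
  if (nrow(placed) >= 2) {
    for (i in 1:(nrow(placed) - 1)) for (j in (i + 1):nrow(placed)) {
      axi <- adhesion_axes(placed$a[i], placed$xi[i], placed$theta[i])
      axj <- adhesion_axes(placed$a[j], placed$xi[j], placed$theta[j])
      expect_true(ellipses_disjoint(
        list(x = placed$x[i], y = placed$y[i], p = axi$semi_par,
             q = axi$semi_perp, phi = placed$theta[i]),
        list(x = placed$x[j], y = placed$y[j], p = axj$semi_par,
             q = axj$semi_perp, phi = placed$theta[j])))
    }
  }
})

test_that("detection output is deterministic", {
  set.seed(14)
  frame <- blob_frame(48, 24, 24, 5, 1.5, 70) +
    matrix(rnorm(48 * 48, 0, 3), 48, 48)
  frame <- pmax(frame, 0)
  d1 <- detect_adhesions(frame, scales = c(6, 8), xis = 0.5, n_theta = 24)
  d2 <- detect_adhesions(frame, scales = c(6, 8), xis = 0.5, n_theta = 24)
  expect_identical(d1, d2)
})

test_that("reconstruction from maxima is one wavelet per term and linear", {
  one <- data.frame(x = 24, y = 20, a = 6, xi = 0.5, theta = 30,
                    coefficient = 2)
  img <- reconstruct_from_maxima(one, c(48, 48))
  kern <- stretched_kernel_cpp(6, 0.5, 30, 1, 3, FALSE)
  h <- (nrow(kern) - 1) / 2
  expect_equal(img[20, 24], (2 / 6^4) * kern[h + 1, h + 1])
  two <- rbind(one, data.frame(x = 36, y = 36, a = 4, xi = 1.5, theta = 100,
                               coefficient = 1))
  expect_equal(reconstruct_from_maxima(two, c(48, 48)),
               img + reconstruct_from_maxima(two[2, ], c(48, 48)))
})

test_that("size histogram conserves counts and uses physical bins", {
  adh <- data.frame(a = rep(4, 7))
  h <- size_histogram(adh, pixel_size = 0.105)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 7L)
  expect_lt(abs(h$mid - 0.42), 0.0530)  # within half a bin
  set.seed(15)
  adh2 <- data.frame(a = runif(60, 4, 20))
  h2 <- size_histogram(adh2, pixel_size = 0.105)
  expect_equal(sum(h2$count), 60L)
})

test_that("constant-mode reconstruction correlates with the clean frame", {
  # fixed (a, xi): every term of the maxima reconstruction carries the
  # same 1/a^4 weight, the regime the single-frame reconstruction is
  # designed for
  set.seed(16)
  n <- 128
  frame <- matrix(0, n, n); truth <- frame
  centers <- cbind(x = c(30, 70, 100, 40, 90, 60, 105, 25),
                   y = c(30, 25, 45, 70, 80, 105, 100, 95))
  for (i in seq_len(nrow(centers))) {
    th <- runif(1, 0, 180)
    truth <- truth + blob_frame(n, centers[i, 1], centers[i, 2],
                                10 / sqrt(3), 5 / sqrt(3), th, A = 100)
  }
  noisy <- pmax(truth + matrix(rnorm(n * n, 0, 10), n, n), 0)
  det <- detect_adhesions(noisy, scales = 10, xis = 0.5, n_theta = 90)
  rec <- reconstruct_from_maxima(det, c(n, n))
  expect_gte(cor(as.vector(rec), as.vector(truth)), 0.8)
})
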