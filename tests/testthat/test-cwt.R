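test_that("mesh refinement replicates pixels and preserves the mean", {
  f <- matrix(c(1, 3, 2, 4), 2, 2)
  r <- refine_mesh(f, 4)
  expect_equal(dim(r), c(8L, 8L))
  expect_true(all(r[1:4, 1:4] == 1))
  expect_true(all(r[5:8, 5:8] == 4))
  expect_identical(refine_mesh(f, 1), f)
  set.seed(3)
  g <- matrix(runif(256), 16, 16)
  expect_equal(mean(refine_mesh(g, 4)), mean(g))
  expect_error(refine_mesh(g, 0), "integer")
})

test_that("coarsening takes 2x2 block means and pads with exact zeros", {
  f <- matrix(8, 4, 4)
  cp <- coarsen_and_pad(f, a = 2)
  inner <- cp$frame[cp$pad + 1:2, cp$pad + 1:2]
  expect_true(all(inner == 8))
  border <- cp$frame
  border[cp$pad + 1:2, cp$pad + 1:2] <- NA
  expect_true(all(border == 0, na.rm = TRUE))
  expect_equal(cp$step, 2)
})

test_that("coarse-mesh coordinates map back to original pixels", {
  # a bright pixel at (x, y) = (21, 13) must put the coefficient maximum
  # at the mesh point nearest those original coordinates
  f <- matrix(0, 32, 40); f[13, 21] <- 5
  fld <- cwt_forward(f, scales = 18, mesh = "coarse")
  e <- fld$entries[[1]]
  idx <- which(e$values[, , 1, 1] == max(e$values), arr.ind = TRUE)
  x_orig <- e$origin["x"] + (idx[2] - 1) * e$step
  y_orig <- e$origin["y"] + (idx[1] - 1) * e$step
  expect_lt(abs(x_orig - 21), 1.1)
  expect_lt(abs(y_orig - 13), 1.1)
})

test_that("a uniform image transforms to zero away from the frame edge", {
  u <- matrix(7, 64, 64)
  for (a in c(3, 5, 8)) {
    T <- cwt_forward(u, scales = a, mesh = "native")$entries[[1]]$values
    marg <- ceiling(3 * a) + 1
    expect_lt(max(abs(T[marg:(64 - marg), marg:(64 - marg), 1, 1])),
              1e-6 * 7 * a)
  }
})

test_that("single-pixel transform equals the demeaned-kernel closed form", {
  v <- 3; a <- 4
  img <- matrix(0, 41, 41); img[21, 21] <- v
  T <- cwt_forward(img, scales = a, mesh = "native")$entries[[1]]$values[, , 1, 1]
  kern <- stretched_kernel_cpp(a, 1, 0, 1)
  h <- (nrow(kern) - 1) / 2
  pred <- matrix(0, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    if (abs(i - 21) <= h && abs(j - 21) <= h)
      pred[i, j] <- (v / a) * kern[h + 1 + i - 21, h + 1 + j - 21]
  }
  expect_equal(T, pred, tolerance = 1e-12)
  expect_equal(which.max(T), 21L + 20L * 41L)  # maximum at the pixel
})

test_that("the transform is linear and the FFT path matches the direct sum", {
  set.seed(4)
  i1 <- matrix(runif(40 * 48), 40, 48)
  i2 <- matrix(runif(40 * 48), 40, 48)
  f <- function(img, method = "fft")
    cwt_forward(img, scales = 6, mesh = "native",
                method = method)$entries[[1]]$values
  t12 <- f(i1 + i2)
  expect_equal(t12, f(i1) + f(i2), tolerance = 1e-10)
  expect_equal(f(i1, "fft"), f(i1, "direct"), tolerance = 1e-12)
})

test_that("the transform is shift equivariant away from the frame edge", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  sh <- matrix(0, 64, 64)
  sh[4:64, 6:64] <- img[1:61, 1:59]    # shift by (dy, dx) = (3, 5)
  a <- 4
  t0 <- cwt_forward(img, scales = a, mesh = "native")$entries[[1]]$values[, , 1, 1]
  t1 <- cwt_forward(sh, scales = a, mesh = "native")$entries[[1]]$values[, , 1, 1]
  marg <- ceiling(3 * a) + 6
  idx_y <- marg:(64 - marg); idx_x <- marg:(64 - marg)
  expect_lt(max(abs(t1[idx_y + 3, idx_x + 5] - t0[idx_y, idx_x])) /
              max(abs(t0)), 1e-8)
})

test_that("stretched transform at xi = 1 equals the mexican-hat transform", {
  set.seed(6)
  img <- matrix(runif(48 * 48), 48, 48)
  tm <- cwt_forward(img, scales = 6, mesh = "native")$entries[[1]]$values
  ts <- cwt_forward(img, scales = 6, xis = 1, thetas = 57,
                    mesh = "native")$entries[[1]]$values
  expect_lt(max(abs(tm - ts)) / max(abs(tm)), 1e-10)
})

test_that("rotating the image by 90 degrees permutes the theta axis", {
  blob <- blob_frame(64, 32, 32, 6, 1.5, 30)
  rot <- t(blob)[, 64:1]   # 90-degree rotation
  th <- seq(0, 170, by = 10)
  f0 <- cwt_forward(blob, 8, xis = 0.5, thetas = th, mesh = "native")
  f90 <- cwt_forward(rot, 8, xis = 0.5, thetas = th, mesh = "native")
  m0 <- apply(f0$entries[[1]]$values[, , 1, ], 3, max)
  m90 <- apply(f90$entries[[1]]$values[, , 1, ], 3, max)
  shift <- (which.max(m90) - which.max(m0)) %% length(th)
  expect_equal(shift, 9L)  # 90 degrees = 9 grid steps of 10
})

test_that("inverse transform of zero coefficients is zero and bands filter", {
  img <- matrix(0, 48, 48)
  fld <- cwt_forward(img, scales = c(4, 6, 8), mesh = "native")
  expect_true(all(cwt_inverse(fld) == 0))
  # smooth blob plus fine sinusoid: a large-scale band suppresses the
  # sinusoid at least tenfold relative to the full band
  n <- 96
  X <- matrix(rep(1:n, each = n), n, n)
  Y <- matrix(rep(1:n, n), n, n)
  blob <- 50 * exp(-((X - 48)^2 + (Y - 48)^2) / (2 * 14^2))
  wave <- 5 * sin(2 * pi * X / 6)
  fld <- cwt_forward(blob + wave, scales = 2:40)
  full <- cwt_inverse(fld)
  low <- cwt_inverse(fld, band = c(12, 40))
  amp <- function(m) {
    # amplitude of the sinusoid by projection
    basis <- sin(2 * pi * X / 6)
    sum(m * basis) / sum(basis^2)
  }
  expect_lt(abs(amp(low)), abs(amp(full)) / 10)
  expect_error(cwt_inverse(fld, band = c(100, 200)), "outside")
})

test_that("scale list and band validation raise errors", {
  img <- matrix(1, 16, 16)
  expect_error(cwt_forward(img, scales = numeric(0)), "empty")
  expect_error(cwt_forward(img, scales = c(4, 3)), "increasing")
  expect_error(cwt_forward(img, scales = 500, mesh = "native"), "extent")
})
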