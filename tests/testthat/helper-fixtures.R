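# shared fixtures built in code

# compiled internals used by fixtures and oracle checks
render_blobs_cpp <- focalwave:::render_blobs_cpp
stretched_kernel_cpp <- focalwave:::stretched_kernel_cpp
corr_direct_cpp <- focalwave:::corr_direct_cpp
cwt_point_cpp <- focalwave:::cwt_point_cpp

# render one anisotropic Gaussian blob on a frame
blob_frame <- function(n, x0, y0, sig_par, sig_perp, theta, A = 100) {
  render_blobs_cpp(n, n, matrix(c(x0, y0, sig_par, sig_perp, theta, A, 0),
                                nrow = 1))
}

# analytic circle boundary object compatible with front_metrics()
circle_boundary <- function(n, cx, cy, r, n_vertices = 720) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)
  contour <- cbind(x = cx + r * cos(phi), y = cy + r * sin(phi))
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), n), n, n)
  mask <- (X - cx)^2 + (Y - cy)^2 <= r^2
  list(contour = contour, mask = mask, threshold = NA,
       enclosed_area = sum(mask))
}

# profile_series wrapper around simulate_profile() output
profile_from_script <- function(clusters, n_x = 61, n_frames = 41,
                                baseline = 10, noise_sigma = 0, seed = 1,
                                boundary_x = n_x) {
  pr <- simulate_profile(clusters, n_x, n_frames, baseline, noise_sigma,
                         seed = seed)
  structure(list(s = pr$x, intensity = pr$profile,
                 frames = seq_len(n_frames),
                 boundary_s = rep(boundary_x, n_frames)),
            class = "profile_series")
}

scenario_profile <- function(sc, seed = 1) {
  profile_from_script(sc$clusters, sc$n_x, sc$n_frames, sc$baseline,
                      sc$noise_sigma, seed = seed,
                      boundary_x = sc$boundary_x)
}

# greedy reference placement using a sampling-based overlap oracle
sampled_overlap <- function(e1, e2, k = 720) {
  phis <- seq(0, 2 * pi, length.out = k)
  pts_in <- function(e, px, py) {
    t <- e$phi * pi / 180
    dx <- px - e$x; dy <- py - e$y
    rp <- dx * cos(t) - dy * sin(t)
    rq <- dx * sin(t) + dy * cos(t)
    (rp / e$p)^2 + (rq / e$q)^2 < 1 - 1e-9
  }
  bnd <- function(e) {
    t <- e$phi * pi / 180
    px <- e$p * cos(phis); py <- e$q * sin(phis)
    cbind(e$x + px * cos(t) + py * sin(t),
          e$y - px * sin(t) + py * cos(t))
  }
  b1 <- bnd(e1); b2 <- bnd(e2)
  any(pts_in(e2, b1[, 1], b1[, 2])) || any(pts_in(e1, b2[, 1], b2[, 2])) ||
    pts_in(e1, e2$x, e2$y) || pts_in(e2, e1$x, e1$y)
}

random_ellipse <- function(span = 40) {
  list(x = runif(1, 0, span), y = runif(1, 0, span),
       p = runif(1, 1, 8), q = runif(1, 1, 8), phi = runif(1, 0, 180))
}

axial_error <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  pmin(d, 180 - d)
}
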