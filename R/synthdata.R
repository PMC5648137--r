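# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  force(code)
}

# micrometres/minute -> pixels/frame
um_min_to_px_frame <- function(v, pixel_size, frame_interval) {
  v * (frame_interval / 60) / pixel_size
}

#' Scene configuration for the synthetic movie generator
#'
#' Collects everything needed to render a ground-truthed fluorescence
#' movie: a smooth cell whose boundary protrudes/retracts at prescribed
#' normal velocities, elongated adhesions modelled as oriented anisotropic
#' Gaussian blobs (a deliberate model mismatch with the detection wavelet,
#' as with real data), optional intra-adhesion 1-D clusters moving along
#' each adhesion axis, optional two-channel actomyosin bundles with pole
#' populations, and a camera noise model (Poisson shot noise on
#' `gain * I` followed by Gaussian read noise).
#'
#' @param shape frame dimensions `c(ny, nx)` in pixels.
#' @param n_frames number of frames.
#' @param pixel_size micrometres per pixel (default 0.105).
#' @param frame_interval seconds per frame (default 5).
#' @param cell `NULL`, or a list with `center` (x, y), `radius` (px),
#'   `base_intensity`, optional `harmonics` (data.frame `n`, `amp`,
#'   `phase` in radians, fractional radial perturbation) and optional
#'   `fronts` (data.frame `phi0`, `phi1` in degrees, `velocity` in
#'   um/min, positive outward; smooth cosine roll-off of `taper` degrees
#'   at each edge).
#' @param adhesions `NULL`, or a data.frame with columns `x`, `y`, `a`
#'   (length scale, px), `xi`, `theta` (wavelet-convention orientation,
#'   degrees), `amplitude`, and optional `birth`, `death` frame indices.
#'   The rendered blob has sigma `a / sqrt(3)` along the wavelet parallel
#'   axis and `xi a / sqrt(3)` perpendicular, so a matched-filter search
#'   recovers `(a, xi, theta)`.
#' @param clusters `NULL`, or a list (one element per adhesion row) of
#'   data.frames with `beta0` (px along the adhesion major axis),
#'   `velocity` (um/min along the +axis direction), `amplitude`,
#'   `amp_trend` (intensity units/s), `width` (Gaussian sigma, px) and
#'   optional `birth`, `death`.  When given, the adhesion is rendered as
#'   the sum of its clusters.
#' @param bundles `NULL`, or a data.frame with `x`, `y`, `theta`,
#'   `half_length` (px), `v_myosin`, `v_vinculin` (um/min, positive
#'   toward the bundle centre), `amplitude`, `pole_sigma`.
#' @param noise list with `gaussian_sigma` (read noise sd) and
#'   `poisson_gain` (`NULL` disables shot noise).
#' @param seed RNG seed; a fixed seed makes the rendered stack
#'   bit-reproducible.
#' @return A `scene_config` list.
#' @export
scene_config <- function(shape = c(128, 128), n_frames = 1,
                         pixel_size = 0.105, frame_interval = 5,
                         cell = NULL, adhesions = NULL, clusters = NULL,
                         bundles = NULL,
                         noise = list(gaussian_sigma = 0, poisson_gain = NULL),
                         seed = 1L) {
  cfg <- list(shape = shape, n_frames = n_frames, pixel_size = pixel_size,
              frame_interval = frame_interval, cell = cell,
              adhesions = adhesions, clusters = clusters, bundles = bundles,
              noise = noise, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

# radius of the cell boundary at polar angle phi (radians) and frame t
cell_radius <- function(cell, phi, t, pixel_size, frame_interval) {
  r <- rep(cell$radius, length(phi))
  if (!is.null(cell$harmonics)) {
    for (h in seq_len(nrow(cell$harmonics))) {
      r <- r + cell$radius * cell$harmonics$amp[h] *
        cos(cell$harmonics$n[h] * phi + cell$harmonics$phase[h])
    }
  }
  if (!is.null(cell$fronts)) {
    taper <- (cell$fronts$taper %||% rep(15, nrow(cell$fronts))) * pi / 180
    deg <- phi * 180 / pi
    for (f in seq_len(nrow(cell$fronts))) {
      lo <- cell$fronts$phi0[f]; hi <- cell$fronts$phi1[f]
      span <- (hi - lo) %% 360
      if (span == 0 && hi != lo) span <- 360  # full-circle front
      d <- (deg - lo) %% 360
      w <- numeric(length(phi))
      inside <- d <= span
      tp <- taper[f] * 180 / pi
      edge <- pmin(d, span - d)
      w[inside] <- ifelse(edge[inside] >= tp, 1,
                          0.5 * (1 - cos(pi * edge[inside] / tp)))
      vpx <- um_min_to_px_frame(cell$fronts$velocity[f], pixel_size,
                                frame_interval)
      r <- r + w * vpx * (t - 1)
    }
  }
  r
}

# per-cluster blob rows for one adhesion at frame t
cluster_rows <- function(ad, cl, t, pixel_size, frame_interval) {
  rows <- list()
  for (k in seq_len(nrow(cl))) {
    birth <- cl$birth[k] %||% 1; death <- cl$death[k] %||% Inf
    if (t < birth || t > death) next
    vpx <- um_min_to_px_frame(cl$velocity[k], pixel_size, frame_interval)
    beta <- cl$beta0[k] + vpx * (t - birth)
    amp <- cl$amplitude[k] +
      (cl$amp_trend[k] %||% 0) * (t - birth) * frame_interval
    if (amp <= 0) next
    ax <- adhesion_axes(ad$a, ad$xi, ad$theta)
    rows[[length(rows) + 1]] <-
      c(ad$x, ad$y, cl$width[k], min(ax$semi_minor, ax$semi_major) / sqrt(3),
        ax$phi_major, amp, beta)
  }
  rows
}

#' Render a synthetic fluorescence movie with ground truth
#'
#' @param config a [scene_config()].
#' @return list with `series` (an [image_series()]; two channels
#'   `myosin`/`vinculin` when bundles are present), `truth` (tables of
#'   scripted boundary polylines, per-frame adhesion parameters, cluster
#'   kinematics and bundle pole positions) and `noiseless` (list of clean
#'   frames, first channel).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  ny <- config$shape[1]; nx <- config$shape[2]
  ps <- config$pixel_size; fi <- config$frame_interval
  two_channel <- !is.null(config$bundles)
  # static geometry for the cell mask
  if (!is.null(config$cell)) {
    cc <- config$cell$center
    X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    Y <- matrix(rep(seq_len(ny), nx), ny, nx)
    RHO <- sqrt((X - cc[1])^2 + (Y - cc[2])^2)
    PHI <- atan2(Y - cc[2], X - cc[1])
    if (!is.null(config$adhesions)) {
      ax <- config$adhesions$x; ay <- config$adhesions$y
      arho <- sqrt((ax - cc[1])^2 + (ay - cc[2])^2)
      aphi <- atan2(ay - cc[2], ax - cc[1])
      r0 <- cell_radius(config$cell, aphi, 1, ps, fi)
      if (any(arho > r0))
        stop("adhesion(s) ", paste(which(arho > r0), collapse = ", "),
             " lie outside the initial cell mask")
    }
  }
  frames <- vector("list", config$n_frames)
  noiseless <- vector("list", config$n_frames)
  truth_boundary <- list(); truth_adh <- list(); truth_cl <- list()
  truth_poles <- list()
  phigrid <- seq(0, 2 * pi, length.out = 721)[-721]
  with_seed(config$seed, {
    for (t in seq_len(config$n_frames)) {
      img <- matrix(0, ny, nx)
      if (!is.null(config$cell)) {
        r <- cell_radius(config$cell, PHI, t, ps, fi)
        # smooth ~1.5 px logistic edge
        img <- img + config$cell$base_intensity / (1 + exp((RHO - r) / 0.75))
        rb <- cell_radius(config$cell, phigrid, t, ps, fi)
        truth_boundary[[t]] <- data.frame(
          frame = t, phi = phigrid,
          x = cc[1] + rb * cos(phigrid), y = cc[2] + rb * sin(phigrid))
      }
      blobs <- list()
      if (!is.null(config$adhesions)) {
        for (i in seq_len(nrow(config$adhesions))) {
          ad <- config$adhesions[i, ]
          birth <- ad$birth %||% 1; death <- ad$death %||% Inf
          if (is.na(birth)) birth <- 1
          if (is.na(death)) death <- Inf
          if (t < birth || t > death) next
          if (!is.null(config$clusters) &&
              !is.null(config$clusters[[i]])) {
            cl <- config$clusters[[i]]
            rows <- cluster_rows(ad, cl, t, ps, fi)
            blobs <- c(blobs, rows)
            for (k in seq_len(nrow(cl))) {
              bk <- cl$birth[k] %||% 1; dk <- cl$death[k] %||% Inf
              if (t < bk || t > dk) next
              vpx <- um_min_to_px_frame(cl$velocity[k], ps, fi)
              truth_cl[[length(truth_cl) + 1]] <- data.frame(
                frame = t, adhesion = i, cluster = k,
                beta = cl$beta0[k] + vpx * (t - bk),
                velocity_um_min = cl$velocity[k])
            }
          } else {
            sl <- ad$a / sqrt(3)
            blobs[[length(blobs) + 1]] <-
              c(ad$x, ad$y, sl, ad$xi * sl,
                ad$theta, ad$amplitude, 0)
          }
          truth_adh[[length(truth_adh) + 1]] <-
            data.frame(frame = t, id = i, x = ad$x, y = ad$y, a = ad$a,
                       xi = ad$xi, theta = ad$theta,
                       amplitude = ad$amplitude)
        }
      }
      ch2_blobs <- list()
      if (two_channel) {
        for (i in seq_len(nrow(config$bundles))) {
          bd <- config$bundles[i, ]
          vm <- um_min_to_px_frame(bd$v_myosin, ps, fi)
          vv <- um_min_to_px_frame(bd$v_vinculin, ps, fi)
          pm <- bd$half_length - vm * (t - 1)
          pv <- bd$half_length - vv * (t - 1)
          sg <- bd$pole_sigma
          th <- bd$theta
          # myosin channel: two poles plus a dim connecting rod
          blobs <- c(blobs, list(
            c(bd$x, bd$y, sg, sg, th, bd$amplitude, +pm),
            c(bd$x, bd$y, sg, sg, th, bd$amplitude, -pm),
            c(bd$x, bd$y, bd$half_length * 0.7, sg, th,
              0.25 * bd$amplitude, 0)))
          ch2_blobs <- c(ch2_blobs, list(
            c(bd$x, bd$y, sg, sg, th, bd$amplitude, +pv),
            c(bd$x, bd$y, sg, sg, th, bd$amplitude, -pv)))
          truth_poles[[length(truth_poles) + 1]] <- data.frame(
            frame = t, bundle = i,
            pole = c("plus", "minus", "plus", "minus"),
            channel = c("myosin", "myosin", "vinculin", "vinculin"),
            position = c(pm, -pm, pv, -pv),
            v_um_min = c(bd$v_myosin, bd$v_myosin,
                         bd$v_vinculin, bd$v_vinculin))
        }
      }
      if (length(blobs))
        img <- img + render_blobs_cpp(ny, nx, do.call(rbind, blobs))
      noiseless[[t]] <- img
      img2 <- NULL
      if (two_channel) {
        img2 <- matrix(0, ny, nx)
        if (length(ch2_blobs))
          img2 <- img2 + render_blobs_cpp(ny, nx, do.call(rbind, ch2_blobs))
      }
      add_noise <- function(im) {
        if (!is.null(config$noise$poisson_gain)) {
          g <- config$noise$poisson_gain
          im <- matrix(stats::rpois(length(im), pmax(g * im, 0)) / g,
                       nrow(im), ncol(im))
        }
        s <- config$noise$gaussian_sigma %||% 0
        if (s > 0) im <- im + matrix(stats::rnorm(length(im), 0, s),
                                     nrow(im), ncol(im))
        pmax(im, 0)
      }
      if (two_channel) {
        frames[[t]] <- list(myosin = add_noise(img), vinculin = add_noise(img2))
      } else {
        frames[[t]] <- add_noise(img)
      }
    }
  })
  series <- image_series(frames, pixel_size = ps, frame_interval = fi,
                         channels = if (two_channel) c("myosin", "vinculin"))
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(series = series,
       truth = list(boundary = bind(truth_boundary),
                    adhesions = bind(truth_adh),
                    clusters = bind(truth_cl),
                    poles = bind(truth_poles)),
       noiseless = noiseless)
}

#' Simulate a 1-D space-time intensity profile from a cluster script
#'
#' Renders \eqn{\phi(x, t) = A_0 + \sum_c A_c(t)
#' e^{-(x - \beta_c(t))^2 / 2\alpha_c^2}} on an integer sample grid, plus
#' the camera noise model, and returns the scripted parameter
#' trajectories as ground truth.
#'
#' @param clusters data.frame with `beta0` (px), `velocity` (um/min along
#'   +x), `amplitude`, `width` (sigma, px), optional `amp_trend` (units/s),
#'   `birth`, `death` (frames).
#' @param n_x number of samples (positions `1..n_x`).
#' @param n_frames number of frames.
#' @param baseline constant offset `A_0`.
#' @param noise_sigma Gaussian read-noise sd.
#' @param poisson_gain `NULL` (off) or shot-noise gain.
#' @param pixel_size,frame_interval calibration used to convert scripted
#'   um/min to px/frame.
#' @param seed RNG seed.
#' @return list with `profile` (matrix `[n_x, n_frames]`), `x`, `truth`.
#' @export
simulate_profile <- function(clusters, n_x = 61, n_frames = 41,
                             baseline = 10, noise_sigma = 0,
                             poisson_gain = NULL,
                             pixel_size = 0.105, frame_interval = 5,
                             seed = 1L) {
  x <- seq_len(n_x)
  prof <- matrix(baseline, n_x, n_frames)
  truth <- list()
  for (t in seq_len(n_frames)) {
    for (k in seq_len(nrow(clusters))) {
      birth <- clusters$birth[k] %||% 1; death <- clusters$death[k] %||% Inf
      if (t < birth || t > death) next
      vpx <- um_min_to_px_frame(clusters$velocity[k], pixel_size,
                                frame_interval)
      beta <- clusters$beta0[k] + vpx * (t - birth)
      amp <- clusters$amplitude[k] +
        (clusters$amp_trend[k] %||% 0) * (t - birth) * frame_interval
      if (amp <= 0) next
      prof[, t] <- prof[, t] +
        amp * exp(-(x - beta)^2 / (2 * clusters$width[k]^2))
      truth[[length(truth) + 1]] <- data.frame(
        frame = t, cluster = k, beta = beta, amplitude = amp,
        width = clusters$width[k],
        velocity_um_min = clusters$velocity[k])
    }
  }
  if (noise_sigma > 0 || !is.null(poisson_gain)) {
    prof <- with_seed(seed, {
      p <- prof
      if (!is.null(poisson_gain))
        p <- matrix(stats::rpois(length(p), pmax(poisson_gain * p, 0)) /
                      poisson_gain, nrow(p), ncol(p))
      if (noise_sigma > 0)
        p <- p + matrix(stats::rnorm(length(p), 0, noise_sigma),
                        nrow(p), ncol(p))
      p
    })
  }
  list(profile = prof, x = x, truth = do.call(rbind, truth))
}

#' Library of scripted ground-truth scenarios
#'
#' One scenario per internal-dynamics category (A-J), two two-channel
#' bundle scenarios (a near-stationary wild-type-like regime at about
#' 0.02 um/min and a mutant-like regime with poles converging at about
#' 0.07/0.13 um/min, vinculin twice as fast as myosin), a whole-cell
#' protrusion scenario (uniformly growing disk at 1.8 um/min), and a
#' 20-adhesion detection scene.
#'
#' The categories are, in terms of concurrent sub-population
#' trajectories: (A) two peaks colliding; (B-D) one, two or three peaks
#' translating away from the cell boundary; (E) a stationary peak plus
#' one translating away; (F) a stationary peak plus one translating
#' toward; (G-H) one or two stationary peaks; (I) two peaks colliding
#' after which the boundary-bound peak switches direction and both move
#' away; (J) a stationary peak with two peaks translating away.
#' Profiles place the cell boundary at the high-x end, so "away from the
#' boundary" means decreasing x.
#'
#' @param pixel_size,frame_interval calibration for unit conversions.
#' @param snr amplitude-to-read-noise ratio used for the noisy scenarios.
#' @return Named list; category entries carry `clusters`, profile
#'   geometry and `category`; movie entries carry a [scene_config()].
#' @export
scenario_library <- function(pixel_size = 0.105, frame_interval = 5,
                             snr = 10) {
  cl <- function(...) {
    df <- data.frame(...)
    if (is.null(df$amp_trend)) df$amp_trend <- 0
    if (is.null(df$birth)) df$birth <- 1
    if (is.null(df$death)) df$death <- Inf
    df
  }
  cats <- list(
    A = cl(beta0 = c(22, 39), velocity = c(0.44, -0.44),
           amplitude = c(80, 70), width = 3, death = c(24, 24)),
    B = cl(beta0 = 40, velocity = -0.38, amplitude = 80, width = 3),
    C = cl(beta0 = c(25, 40), velocity = c(-0.38, -0.38),
           amplitude = c(80, 65), width = 3),
    D = cl(beta0 = c(45, 45, 45), velocity = -0.9,
           amplitude = c(80, 75, 70), width = 3,
           birth = c(1, 15, 29), death = c(15, 29, 41)),
    E = cl(beta0 = c(20, 40), velocity = c(0, -0.38),
           amplitude = c(70, 80), width = 3),
    F = cl(beta0 = c(20, 34), velocity = c(0, 0.32),
           amplitude = c(70, 80), width = 3),
    G = cl(beta0 = 30, velocity = 0, amplitude = 80, width = 3),
    H = cl(beta0 = c(22, 40), velocity = 0, amplitude = c(80, 70),
           width = 3),
    I = cl(beta0 = c(40, 14), velocity = c(-0.38, 1.07),
           amplitude = c(80, 70), width = 3),
    J = cl(beta0 = c(22, 45, 45), velocity = c(0, -0.9, -0.9),
           amplitude = c(70, 80, 75), width = 3,
           birth = c(1, 1, 19), death = c(Inf, 15, 41))
  )
  # category A's merged pair persists after the collision
  vpx_a <- um_min_to_px_frame(0.44, pixel_size, frame_interval)
  cats$A <- rbind(cats$A,
                  cl(beta0 = 22 + vpx_a * 23 + 0.5, velocity = 0,
                     amplitude = 130, width = 3.2, birth = 25))
  # category I's switch is scripted by splitting the moving cluster into
  # its pre- and post-collision legs (collision near frame 20); the
  # switched cluster retreats quickly so the pair re-resolves
  tstar <- 20
  vpx_in <- um_min_to_px_frame(1.07, pixel_size, frame_interval)
  meet <- 33.6
  cats$I <- cl(beta0 = c(39.6, meet - vpx_in * (tstar - 1),
                         meet - 0.4),
               velocity = c(-0.38, 1.07, -1.3),
               amplitude = c(80, 70, 70), width = 3,
               birth = c(1, 1, tstar + 1), death = c(Inf, tstar, Inf))
  out <- lapply(names(cats), function(nm) {
    list(kind = "profile", category = nm, clusters = cats[[nm]],
         n_x = 61, n_frames = 41, boundary_x = 61, baseline = 10,
         noise_sigma = 80 / snr,
         pixel_size = pixel_size, frame_interval = frame_interval)
  })
  names(out) <- paste0("category_", names(cats))
  mk_bundle <- function(v_m, v_v, seed) {
    scene_config(
      shape = c(96, 96), n_frames = 60, pixel_size = pixel_size,
      frame_interval = frame_interval,
      bundles = data.frame(x = 48, y = 48, theta = 25, half_length = 18,
                           v_myosin = v_m, v_vinculin = v_v,
                           amplitude = 120, pole_sigma = 2),
      noise = list(gaussian_sigma = 120 / snr, poisson_gain = NULL),
      seed = seed)
  }
  out$bundle_wildtype <- mk_bundle(0.016, 0.028, 101L)
  out$bundle_mutant <- mk_bundle(0.07, 0.13, 102L)
  out$protrusion <- scene_config(
    shape = c(200, 200), n_frames = 8, pixel_size = pixel_size,
    frame_interval = frame_interval,
    cell = list(center = c(100, 100), radius = 55, base_intensity = 60,
                fronts = data.frame(phi0 = 0, phi1 = 360, velocity = 1.8,
                                    taper = 1e-6)),
    noise = list(gaussian_sigma = 60 / snr, poisson_gain = NULL),
    seed = 103L)
  out$detection <- detection_scene(seed = 104L, snr = snr,
                                   pixel_size = pixel_size,
                                   frame_interval = frame_interval)
  out
}

#' Scripted 20-adhesion detection scene
#'
#' Adhesion length scales are drawn uniformly on 4-20 px with anisotropy
#' factors from the same family as the detection grid (xi = 1/2 for most,
#' occasionally 1), amplitudes vary mildly (90-110), and centres and
#' orientations are random with non-overlapping footprints.  `snr` sets
#' the Gaussian read noise to (mean amplitude)/snr.
#'
#' @param n_adhesions number of adhesions (default 20).
#' @param shape frame dimensions.
#' @param snr amplitude-to-noise ratio (default 10).
#' @param seed RNG seed.
#' @param pixel_size,frame_interval calibration.
#' @return A [scene_config()] with one frame.
#' @export
detection_scene <- function(n_adhesions = 20, shape = c(144, 144), snr = 10,
                            seed = 104L, pixel_size = 0.105,
                            frame_interval = 5) {
  ad <- with_seed(seed, {
    rows <- list()
    guard <- 0
    while (length(rows) < n_adhesions && guard < 20000) {
      guard <- guard + 1
      a <- stats::runif(1, 4, 20)
      xi <- sample(c(0.5, 1), 1, prob = c(0.8, 0.2))
      theta <- stats::runif(1, 0, 180)
      ax <- adhesion_axes(a, xi, theta)
      m <- ax$semi_major + 2
      x <- stats::runif(1, 1 + m, shape[2] - m)
      y <- stats::runif(1, 1 + m, shape[1] - m)
      cand <- list(x = x, y = y, p = ax$semi_par + 1.5,
                   q = ax$semi_perp + 1.5, phi = theta)
      ok <- TRUE
      for (e in rows) {
        axe <- adhesion_axes(e$a, e$xi, e$theta)
        if (!ellipses_disjoint(cand,
                               list(x = e$x, y = e$y, p = axe$semi_par + 1.5,
                                    q = axe$semi_perp + 1.5, phi = e$theta))) {
          ok <- FALSE; break
        }
      }
      if (ok) rows[[length(rows) + 1]] <-
          data.frame(x = x, y = y, a = a, xi = xi, theta = theta,
                     amplitude = stats::runif(1, 90, 110))
    }
    do.call(rbind, rows)
  })
  scene_config(shape = shape, n_frames = 1, pixel_size = pixel_size,
               frame_interval = frame_interval, adhesions = ad,
               noise = list(gaussian_sigma = 100 / snr, poisson_gain = NULL),
               seed = seed + 1L)
}
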