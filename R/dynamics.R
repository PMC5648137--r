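# bilinear interpolation of matrix img (indexed [y, x]) at continuous
# pixel coordinates (xs, ys); zero outside
bilinear_at <- function(img, xs, ys) {
  ny <- nrow(img); nx <- ncol(img)
  out <- numeric(length(xs))
  ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  x <- pmin(pmax(xs[ok], 1), nx); y <- pmin(pmax(ys[ok], 1), ny)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
  out[ok] <- v
  out
}

# signed distance along a ray (origin, direction d) to a polyline contour;
# smallest positive intersection parameter, or NA
ray_contour_intersection <- function(origin, d, contour) {
  p1 <- contour[-nrow(contour), , drop = FALSE]
  p2 <- contour[-1, , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  den <- d[1] * ey - d[2] * ex
  wx <- p1[, 1] - origin[1]; wy <- p1[, 2] - origin[2]
  tt <- (wx * ey - wy * ex) / den
  ss <- (wx * d[2] - wy * d[1]) / (-den)
  ok <- is.finite(tt) & is.finite(ss) & ss >= 0 & ss <= 1 & tt > 0
  if (!any(ok)) return(NA_real_)
  min(tt[ok])
}

#' Extract a fixed cross-section profile series through an adhesion
#'
#' Samples intensity along the adhesion's major axis at 1-px steps with
#' bilinear interpolation, on a line that stays fixed in position and
#' orientation across the window: one side ends at the reference-frame
#' cell boundary, the other extends an equal length in the opposite
#' direction (clipped at the frame edge, with a flag).  The boundary
#' intersection along the same axis is recorded for every frame.
#' Positive axis coordinates run toward the boundary.
#'
#' @param series an [image_series()] (first channel used).
#' @param adhesion one-row data.frame with `x`, `y`, `a`, `xi`, `theta`.
#' @param contours list of per-frame contours (closed polylines); the
#'   reference frame's contour fixes the geometry.
#' @param ref_frame reference frame index.
#' @param window frames before/after the reference frame (default 20;
#'   clipped at the series ends).
#' @param channel channel for multi-channel series.
#' @return A `profile_series` list: `s` (axis coordinates, px, positive
#'   toward the boundary, 0 at the adhesion centre), `intensity` (matrix
#'   `[length(s), n_frames]`), `frames`, `boundary_s` (per-frame boundary
#'   position along the axis), `origin`, `direction`, `clipped`.
#' @export
extract_profile <- function(series, adhesion, contours, ref_frame,
                            window = 20, channel = NULL) {
  ax <- adhesion_axes(adhesion$a, adhesion$xi, adhesion$theta)
  phi <- ax$phi_major * pi / 180
  d <- c(cos(phi), -sin(phi))   # unit vector along the major axis
  origin <- c(adhesion$x, adhesion$y)
  ref_contour <- contours[[ref_frame]]
  if (is.null(ref_contour)) stop("reference frame has no contour")
  t_plus <- ray_contour_intersection(origin, d, ref_contour)
  t_minus <- ray_contour_intersection(origin, -d, ref_contour)
  if (is.na(t_plus) && is.na(t_minus))
    stop("adhesion axis does not intersect the reference contour (id ",
         adhesion$id %||% "?", ")")
  # orient the +axis toward the nearest boundary crossing
  if (is.na(t_plus) || (!is.na(t_minus) && t_minus < t_plus)) {
    d <- -d
    t_plus <- t_minus
  }
  L <- t_plus
  dims <- series$dim
  smax <- floor(L)
  # equal length on the far side, clipped at the frame edge
  far <- function(s) origin + (-s) * d
  smin <- -floor(L)
  clipped <- FALSE
  repeat {
    p <- far(-smin)
    if (p[1] >= 1 && p[1] <= dims[2] && p[2] >= 1 && p[2] <= dims[1]) break
    smin <- smin + 1
    clipped <- TRUE
    if (smin >= 0) break
  }
  s <- seq(smin, smax)
  frames <- max(1, ref_frame - window):min(length(series), ref_frame + window)
  xs <- origin[1] + s * d[1]
  ys <- origin[2] + s * d[2]
  inten <- vapply(frames, function(t)
    bilinear_at(get_frame(series, t, channel), xs, ys),
    numeric(length(s)))
  boundary_s <- vapply(frames, function(t) {
    ct <- contours[[t]]
    if (is.null(ct)) return(NA_real_)
    ray_contour_intersection(origin, d, ct)
  }, numeric(1))
  structure(list(s = s, intensity = inten, frames = frames,
                 boundary_s = boundary_s, origin = origin, direction = d,
                 clipped = clipped),
            class = "profile_series")
}

# model: A1p * g(b1, a1) + A2p * g(b2, a2) on top of a fixed baseline
two_gauss <- function(p, x) {
  p[1] * exp(-(x - p[3])^2 / (2 * p[5]^2)) +
    p[2] * exp(-(x - p[4])^2 / (2 * p[6]^2))
}

#' Fit a constrained two-Gaussian mixture to one profile
#'
#' The baseline `A0` is the profile minimum; samples brighter than the
#' mean of the profile's extremes, `(max + min) / 2`, are fit to the sum
#' of two Gaussians with amplitudes constrained non-negative
#' (box-constrained least squares).  A fit is reported as effectively
#' single-peaked when one amplitude falls below 5 percent of the other.
#'
#' Both amplitudes must additionally clear `min_snr` times the robust
#' noise scale of the profile for a peak to count as real, and two
#' fitted centres closer than `merge_distance` are reported as one
#' effective (merged) peak at their amplitude-weighted centre.
#'
#' @param x sample positions.
#' @param y intensities.
#' @param min_points minimum samples above the cutoff (default 5); fewer
#'   returns a `skipped` marker rather than an error.
#' @param min_snr amplitude significance floor, in units of the robust
#'   noise scale (default 3).
#' @param merge_distance centres closer than this (px) count as one
#'   peak (default 2).
#' @return list with `A0`, `A1p`, `A2p`, `beta1`, `beta2`, `alpha1`,
#'   `alpha2`, `residual`, `n_peaks_effective`, `effective` (data.frame
#'   of the effective peaks: `beta`, `amplitude`, `width`), `skipped`.
#' @export
fit_two_gaussians <- function(x, y, min_points = 5, min_snr = 3,
                              merge_distance = 2) {
  A0 <- min(y)
  cutoff <- (max(y) + min(y)) / 2
  sel <- y > cutoff
  if (sum(sel) < min_points) {
    return(list(skipped = TRUE, A0 = A0, n_peaks_effective = 0L))
  }
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  xs <- x[sel]; ys <- y[sel] - A0
  # initial centres: the two strongest well-separated samples
  o <- order(-ys)
  b1 <- xs[o[1]]
  b2 <- NA
  for (i in o[-1]) if (abs(xs[i] - b1) >= 3) { b2 <- xs[i]; break }
  if (is.na(b2)) b2 <- b1 + 2
  amp0 <- max(ys)
  p0 <- c(amp0, 0.6 * amp0, b1, b2, 2, 2)
  lower <- c(0, 0, min(x), min(x), 0.5, 0.5)
  upper <- c(4 * amp0, 4 * amp0, max(x), max(x), diff(range(x)),
             diff(range(x)))
  rss <- function(p) sum((ys - two_gauss(p, xs))^2)
  fit <- stats::optim(p0, rss, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 400))
  # second start with swapped/merged centres guards against local minima
  p0b <- c(0.8 * amp0, 0.1 * amp0, (b1 + b2) / 2, b2, 2, 2)
  fit2 <- stats::optim(p0b, rss, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = list(maxit = 400))
  if (fit2$value < fit$value) fit <- fit2
  # third start: the two strongest separated maxima of the smoothed
  # profile, which survive noise much better than raw samples
  ksm <- exp(-(-4:4)^2 / (2 * 1.5^2)); ksm <- ksm / sum(ksm)
  ysm <- as.numeric(stats::filter(c(rep(y[1], 4), y, rep(y[length(y)], 4)),
                                  ksm, sides = 2))[5:(4 + length(y))]
  d <- sign(diff(ysm)); d[d == 0] <- 1e-9
  mx_i <- which(diff(d) < 0) + 1L
  if (length(mx_i) >= 2) {
    mx_i <- mx_i[order(-ysm[mx_i])]
    c1 <- x[mx_i[1]]
    c2 <- NA
    for (ii in mx_i[-1]) if (abs(x[ii] - c1) >= 4) { c2 <- x[ii]; break }
    if (!is.na(c2)) {
      p0c <- c(ysm[mx_i[1]] - A0, ysm[match(c2, x)] - A0, c1, c2, 3, 3)
      p0c[1:2] <- pmax(p0c[1:2], 1e-3)
      fit3 <- stats::optim(p0c, rss, method = "L-BFGS-B", lower = lower,
                           upper = upper, control = list(maxit = 400))
      if (fit3$value < fit$value) fit <- fit3
    }
  }
  # single-Gaussian comparison: a second component must earn its keep,
  # otherwise fitting two Gaussians to one peak splits it arbitrarily
  rss1g <- function(p) sum((ys - p[1] * exp(-(xs - p[2])^2 /
                                              (2 * p[3]^2)))^2)
  fit1 <- stats::optim(c(amp0, b1, 2), rss1g, method = "L-BFGS-B",
                       lower = c(0, min(x), 0.5),
                       upper = c(4 * amp0, max(x), diff(range(x))),
                       control = list(maxit = 400))
  p <- fit$par
  # order peaks by centre for stable reporting
  if (p[4] < p[3]) p <- p[c(2, 1, 4, 3, 6, 5)]
  amps <- c(p[1], p[2])
  real <- amps >= 0.05 * max(amps) & amps >= min_snr * max(sigma_hat, 1e-12)
  # model selection by BIC over the *full* profile: the reported fit
  # uses only the above-cutoff samples (the printed selection rule), but
  # one peak and two peaks can only be told apart on all of them, with
  # each model refit to the full profile so neither is handicapped
  # both comparison models carry a free constant offset (min(y) biases
  # the baseline low by a couple of noise sigmas, and without the offset
  # a broad second component wins by absorbing that bias) and peak
  # widths bounded at 12 px so a "peak" cannot model the background
  wmax <- 12
  rss_f2 <- function(q) sum((y - A0 - q[7] - two_gauss(q, x))^2)
  f2full <- stats::optim(c(pmin(p, c(Inf, Inf, Inf, Inf, wmax, wmax)), 0),
                         rss_f2, method = "L-BFGS-B",
                         lower = c(lower[1:4], 0.5, 0.5, -6 * sigma_hat),
                         upper = c(upper[1:4], wmax, wmax, 6 * sigma_hat),
                         control = list(maxit = 200))
  rss_f1 <- function(q) sum((y - A0 - q[4] - q[1] *
                               exp(-(x - q[2])^2 / (2 * q[3]^2)))^2)
  f1full <- stats::optim(c(fit1$par[1:2], min(fit1$par[3], wmax), 0),
                         rss_f1, method = "L-BFGS-B",
                         lower = c(0, min(x), 0.5, -6 * sigma_hat),
                         upper = c(4 * amp0, max(x), wmax, 6 * sigma_hat),
                         control = list(maxit = 200))
  n_all <- length(x)
  if (f2full$value > f1full$value * n_all^(-3 / n_all))
    real[which.min(amps)] <- FALSE
  # components pinned to the profile ends are edge artefacts
  edge <- 2
  real <- real & c(p[3], p[4]) > min(x) + edge &
    c(p[3], p[4]) < max(x) - edge
  if (!any(real)) real[which.max(amps)] <- TRUE
  eff <- data.frame(beta = c(p[3], p[4])[real], amplitude = amps[real],
                    width = c(p[5], p[6])[real])
  if (nrow(eff) == 2 && abs(eff$beta[2] - eff$beta[1]) < merge_distance) {
    w <- eff$amplitude / sum(eff$amplitude)
    eff <- data.frame(beta = sum(eff$beta * w),
                      amplitude = sum(eff$amplitude),
                      width = max(eff$width))
  }
  if (nrow(eff) == 1 && sum(real) == 2) {
    # report the merged single peak from the one-Gaussian fit instead
    eff <- data.frame(beta = fit1$par[2], amplitude = fit1$par[1],
                      width = fit1$par[3])
  }
  edge <- 2
  eff <- eff[eff$beta > min(x) + edge & eff$beta < max(x) - edge &
               eff$amplitude >= min_snr * max(sigma_hat, 1e-12), ,
             drop = FALSE]
  list(skipped = FALSE, A0 = A0, A1p = p[1], A2p = p[2],
       beta1 = p[3], beta2 = p[4], alpha1 = p[5], alpha2 = p[6],
       residual = fit$value, n_peaks_effective = nrow(eff),
       effective = eff)
}

#' Associate per-frame mixture fits into cluster trajectories
#'
#' Fits are applied frame by frame to a [extract_profile()] result; peaks
#' are associated across frames by nearest centre with a maximum jump.
#' Frames where the effective peak count differs from both neighbours
#' inside a two-peak run are flagged stray and excluded from velocity
#' estimates.  Peak intensity (area) is `A' * alpha * sqrt(2 pi)` per
#' sample.
#'
#' @param profile a `profile_series`.
#' @param max_jump maximum per-frame centre jump for association, px
#'   (default 3; scaled by the gap length when bridging).
#' @param min_length drop trajectories shorter than this many retained
#'   frames (default 4).
#' @param max_gap unmatched frames tolerated before a trajectory closes
#'   (default 12, long enough to ride out the merged frames of a
#'   collision; the bridge distance is capped at `3 * max_jump`).
#' @return list with `trajectories` (list of data.frames: `frame`, `s`
#'   (centre, px), `amplitude`, `width`, `area`, `stray`) and `fits`.
#' @export
build_trajectories <- function(profile, max_jump = 3, min_length = 4,
                               max_gap = 12) {
  nt <- ncol(profile$intensity)
  fits <- vector("list", nt)
  for (t in seq_len(nt)) {
    fits[[t]] <- fit_two_gaussians(profile$s, profile$intensity[, t])
  }
  npk <- vapply(fits, function(f)
    if (isTRUE(f$skipped)) 0L else f$n_peaks_effective, integer(1))
  stray <- rep(FALSE, nt)
  for (t in seq_len(nt)) {
    tp <- if (t > 1) npk[t - 1] else NA
    tn <- if (t < nt) npk[t + 1] else NA
    if (!is.na(tp) && !is.na(tn) && npk[t] != tp && npk[t] != tn &&
        tp == tn) stray[t] <- TRUE
  }
  # effective peak list per frame
  peaks <- lapply(seq_len(nt), function(t) {
    f <- fits[[t]]
    if (isTRUE(f$skipped) || is.null(f$effective) ||
        nrow(f$effective) == 0) return(NULL)
    e <- f$effective
    data.frame(frame = profile$frames[t], ti = t, s = e$beta,
               amplitude = e$amplitude, width = e$width,
               area = e$amplitude * e$width * sqrt(2 * pi),
               stray = stray[t])
  })
  # Nearest-centre association.  A trajectory that loses its peak is
  # kept open with long patience only when another peak sits where it
  # vanished (occlusion by a merger); otherwise it closes quickly, so a
  # dead trajectory cannot poach later passers-by.
  open <- list(); occluded <- logical(0); done <- list()
  for (t in seq_len(nt)) {
    pk <- peaks[[t]]
    if (!is.null(pk)) {
      taken <- rep(FALSE, nrow(pk))
      if (length(open)) {
        # short linear extrapolation of each trajectory's recent motion
        predict_pos <- function(g, t) {
          n <- nrow(g)
          tail_n <- min(5L, n)
          if (tail_n < 3) return(g$s[n])
          idx <- (n - tail_n + 1):n
          sl <- theil_sen(g$ti[idx], g$s[idx])
          if (!is.finite(sl)) sl <- 0
          sl <- max(-1.5, min(1.5, sl))   # physical speeds stay below this
          step <- sl * (t - g$ti[n])
          g$s[n] + max(-2 * max_jump, min(2 * max_jump, step))
        }
        lastpos <- vapply(open, predict_pos, numeric(1), t = t)
        lastt <- vapply(open, function(g) g$ti[nrow(g)], numeric(1))
        for (oi in order(-vapply(open, nrow, integer(1)))) {
          gap <- t - lastt[oi]
          d <- abs(pk$s - lastpos[oi])
          d[taken] <- Inf
          j <- which.min(d)
          if (length(j) && is.finite(d[j]) &&
              d[j] <= max_jump * min(gap, 2)) {
            open[[oi]] <- rbind(open[[oi]], pk[j, ])
            taken[j] <- TRUE
          }
        }
      }
      for (j in which(!taken)) open[[length(open) + 1]] <- pk[j, ]
      occluded <- c(occluded, rep(FALSE, length(open) - length(occluded)))
    }
    if (length(open)) {
      age <- t - vapply(open, function(g) g$ti[nrow(g)], numeric(1))
      first_lost <- age == 1
      if (any(first_lost)) {
        here <- if (is.null(pk)) numeric(0) else pk$s[taken]
        for (oi in which(first_lost)) {
          last_s <- open[[oi]]$s[nrow(open[[oi]])]
          occluded[oi] <- length(here) > 0 &&
            min(abs(here - last_s)) <= 2 * max_jump
        }
      }
      occluded[age == 0] <- FALSE
      expired <- age > ifelse(occluded, max_gap, 3)
      done <- c(done, open[expired])
      open <- open[!expired]
      occluded <- occluded[!expired]
    }
  }
  done <- c(done, open)
  # stitch fragments of one physical peak: trajectories that abut in
  # time and sit at the same place (median of the three frames on each
  # side of the break) are the same cluster
  repeat {
    if (length(done) < 2) break
    merged_any <- FALSE
    for (i in seq_along(done)) {
      for (j in seq_along(done)) {
        if (i == j) next
        gi <- done[[i]]; gj <- done[[j]]
        gap <- min(gj$frame) - max(gi$frame)
        if (gap < -2 || gap > 4) next
        end_i <- stats::median(utils::tail(gi$s, 3))
        start_j <- stats::median(utils::head(gj$s, 3))
        if (abs(end_i - start_j) <= 2 * max_jump) {
          both <- rbind(gi, gj[gj$frame > max(gi$frame), , drop = FALSE])
          done[[i]] <- both[order(both$frame), , drop = FALSE]
          done[[j]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  # merge duplicate tracks of one physical peak: overlapping time spans
  # at small median separation mean the fitter double-tracked (or two
  # trajectories alternately captured the same peak, leaving few shared
  # frames, so positions are compared by interpolation over the span)
  repeat {
    if (length(done) < 2) break
    merged_any <- FALSE
    for (i in seq_along(done)) {
      for (j in seq_along(done)) {
        if (i >= j) next
        gi <- done[[i]]; gj <- done[[j]]
        span <- c(max(min(gi$frame), min(gj$frame)),
                  min(max(gi$frame), max(gj$frame)))
        if (span[2] - span[1] < 4) next
        xout <- span[1]:span[2]
        si <- interp_traj(gi, xout)
        sj <- interp_traj(gj, xout)
        gap <- abs(si - sj)
        gap <- gap[is.finite(gap)]
        # a short track near a long one is almost always a double-fit
        # artefact of the same peak, so it is absorbed from further out
        radius <- if (min(sum(!gi$stray), sum(!gj$stray)) < 8)
          3 * max_jump else 2 * max_jump
        if (length(gap) < 4 || stats::median(gap) > radius ||
            stats::quantile(gap, 0.8) > 1.25 * radius) next
        keep_i <- nrow(gi) >= nrow(gj)
        main <- if (keep_i) gi else gj
        other <- if (keep_i) gj else gi
        extra <- other[!(other$frame %in% main$frame), , drop = FALSE]
        both <- rbind(main, extra)
        done[[i]] <- both[order(both$frame), , drop = FALSE]
        done[[j]] <- NULL
        merged_any <- TRUE
        break
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  # keep tracks with enough retained frames and a reasonable duty cycle
  # (sparse wanderers that match only every few frames are artefacts)
  done <- Filter(function(g) {
    span <- max(g$frame) - min(g$frame) + 1
    sum(!g$stray) >= min_length && nrow(g) / span >= 0.5
  }, done)
  # stable ordering: by first frame then first position
  if (length(done)) {
    o <- order(vapply(done, function(g) g$frame[1], numeric(1)),
               vapply(done, function(g) g$s[1], numeric(1)))
    done <- done[o]
  }
  list(trajectories = done, fits = fits)
}

# Theil-Sen slope: median of pairwise slopes, robust to the occasional
# mis-associated frame at a trajectory's ends
theil_sen <- function(t, y) {
  n <- length(t)
  if (n < 2) return(NA_real_)
  num <- outer(y, y, `-`); den <- outer(t, t, `-`)
  stats::median(num[den != 0] / den[den != 0])
}

#' Estimate a cluster's velocity relative to the cell boundary
#'
#' Least-squares slope of the signed centre position against time over
#' the retained (non-stray) samples, converted to micrometres per
#' minute.  Reported positive when the cluster moves away from the cell
#' boundary (profiles put the boundary on the +axis side, so away means
#' decreasing axis coordinate).  A single-breakpoint piecewise fit is
#' also attempted; the breakpoint is kept when it lowers the residual
#' and the two slopes differ in sign (a direction switch).
#'
#' @param traj one trajectory data.frame from [build_trajectories()].
#' @param profile the originating `profile_series` (for boundary motion);
#'   optional.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param min_samples minimum retained samples (default 4).
#' @return list with `v_um_min`, `ci` (95 percent), `switch` (logical),
#'   `segments` (piecewise slopes, um/min), `switch_frame`,
#'   `boundary_v_um_min` (same estimator on the boundary position).
#' @export
estimate_velocity <- function(traj, profile = NULL, pixel_size = 0.105,
                              frame_interval = 5, min_samples = 4) {
  g <- traj[!traj$stray, , drop = FALSE]
  if (nrow(g) < min_samples) {
    return(list(v_um_min = NA_real_, ci = c(NA_real_, NA_real_),
                switch = FALSE, segments = NULL, switch_frame = NA,
                boundary_v_um_min = NA_real_))
  }
  tt <- g$frame * frame_interval / 60
  # away-from-boundary positive: boundary lies toward +s
  pos <- -g$s * pixel_size
  fit <- stats::lm(pos ~ tt)
  v <- theil_sen(tt, pos)
  ci <- tryCatch(stats::confint(fit)[2, ], error = function(e)
    c(NA_real_, NA_real_))
  # centre the lm interval on the robust estimate
  if (all(is.finite(ci))) ci <- ci - unname(coef(fit)[2]) + v
  segments <- NULL; sw <- FALSE; swf <- NA
  n <- nrow(g)
  # piecewise fits on short tracks flag switches spuriously; a genuine
  # switch needs enough samples on both legs to be credible
  if (n >= max(16, 2 * min_samples)) {
    rss1 <- sum(stats::residuals(fit)^2)
    best <- list(rss = Inf)
    for (b in min_samples:(n - min_samples)) {
      f1 <- stats::lm(pos[1:b] ~ tt[1:b])
      f2 <- stats::lm(pos[(b + 1):n] ~ tt[(b + 1):n])
      r <- sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2)
      if (r < best$rss) best <- list(rss = r, b = b,
                                     s1 = theil_sen(tt[1:b], pos[1:b]),
                                     s2 = theil_sen(tt[(b + 1):n],
                                                    pos[(b + 1):n]))
    }
    v_floor <- 0.25  # um/min; both legs must clearly move
    if (is.finite(best$rss) && best$rss < 0.5 * rss1 &&
        abs(best$s1) > v_floor && abs(best$s2) > v_floor &&
        sign(best$s1) * sign(best$s2) < 0) {
      sw <- TRUE
      segments <- c(best$s1, best$s2)
      swf <- g$frame[best$b]
    }
  }
  bv <- NA_real_
  if (!is.null(profile)) {
    bs <- profile$boundary_s
    ok <- is.finite(bs)
    if (sum(ok) >= min_samples) {
      btt <- profile$frames[ok] * frame_interval / 60
      bfit <- stats::lm(I(-bs[ok] * pixel_size) ~ btt)
      bv <- unname(coef(bfit)[2])
    }
  }
  list(v_um_min = v, ci = unname(ci), switch = sw, segments = segments,
       switch_frame = swf, boundary_v_um_min = bv)
}

# interpolate a trajectory at integer frames, refusing to bridge long
# unmatched stretches (no information there)
interp_traj <- function(g, xout, max_span = 4) {
  v <- stats::approx(g$frame, g$s, xout, rule = 1)$y
  f <- sort(unique(g$frame))
  if (length(f) > 1) {
    d <- diff(f)
    for (k in which(d > max_span)) {
      v[xout > f[k] & xout < f[k + 1]] <- NA
    }
  }
  v
}

# Do two trajectories approach each other and meet?  Overlapping peaks
# merge into a single fitted component well before their true centres
# touch, so besides a small minimum gap we accept the signature of a
# merger: a steadily closing gap that ends with one trajectory
# terminating (or going dark) near the other while that other continues.
detect_collision <- function(g1, g2, dist_px = 2) {
  span <- c(max(min(g1$frame), min(g2$frame)),
            min(max(g1$frame), max(g2$frame)))
  if (span[2] - span[1] < 2) return(FALSE)
  common <- span[1]:span[2]
  s1 <- interp_traj(g1, common)
  s2 <- interp_traj(g2, common)
  ok <- is.finite(s1) & is.finite(s2)
  if (sum(ok) < 2) return(FALSE)
  common <- common[ok]; s1 <- s1[ok]; s2 <- s2[ok]
  gap <- abs(s1 - s2)
  k <- length(gap)
  closing <- gap[k] < gap[1] - 0.5
  if (!closing) return(FALSE)
  if (min(gap) <= 3 * dist_px) return(TRUE)
  e1 <- max(g1$frame); e2 <- max(g2$frame)
  # merger signature: a sustained, substantial approach down to the
  # effective resolution limit, after which the trajectories do not
  # both continue (a brief graze between passing tracks does not count)
  k >= 6 && gap[1] - gap[k] >= 4 &&
    gap[k] <= 5 * dist_px && abs(e1 - e2) >= 3 &&
    min(e1, e2) <= common[k] + 10
}

#' Classify the internal dynamics of one adhesion
#'
#' Deterministic rules over the cluster trajectories of one adhesion
#' window map to the ten canonical categories: (A) two peaks colliding;
#' (B, C, D) one, two or three peaks translating away from the cell
#' boundary; (E) a stationary peak plus one translating away; (F) a
#' stationary peak plus one translating toward; (G, H) one or two
#' stationary peaks; (I) a collision after which the boundary-bound peak
#' switches direction and both move away; (J) a stationary peak with two
#' peaks translating away.  A peak is stationary when `|v|` is below
#' `v_stationary`; a collision requires approaching trajectories whose
#' separation falls below `collision_distance`.  Patterns outside the
#' taxonomy return `"other"` with the raw pattern attached.
#'
#' @param trajs trajectory list from [build_trajectories()].
#' @param profile the originating `profile_series` (optional, improves
#'   velocity context).
#' @param v_stationary stationary threshold, um/min (default 0.05).
#' @param collision_distance px (default 2).
#' @param pixel_size,frame_interval calibration.
#' @return list with `category` (`"A"`..`"J"` or `"other"`), `pattern`
#'   (human-readable summary) and `velocities` (per-trajectory um/min).
#' @export
classify_dynamics <- function(trajs, profile = NULL, v_stationary = 0.05,
                              collision_distance = 2, pixel_size = 0.105,
                              frame_interval = 5) {
  vel <- lapply(trajs, estimate_velocity, profile = profile,
                pixel_size = pixel_size, frame_interval = frame_interval)
  ok <- !vapply(vel, function(v) is.na(v$v_um_min), logical(1))
  trajs <- trajs[ok]; vel <- vel[ok]
  n <- length(trajs)
  vs <- vapply(vel, `[[`, numeric(1), "v_um_min")
  sw <- vapply(vel, `[[`, logical(1), "switch")
  # a switching trajectory's post-switch direction decides its class
  state <- ifelse(abs(vs) < v_stationary, "stat",
                  ifelse(vs > 0, "away", "toward"))
  for (i in seq_len(n)) {
    if (sw[i]) state[i] <- if (vel[[i]]$segments[2] > 0) "away" else "toward"
  }
  collide <- FALSE
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (detect_collision(trajs[[i]], trajs[[j]], collision_distance))
        collide <- TRUE
    }
  }
  # what remains after a collision separates colliding (A) from
  # collide-and-switch (I): a merged pair leaves one late peak, a
  # bounced pair leaves two separating ones
  late_active <- 0L
  if (n) {
    t_max <- max(vapply(trajs, function(g) max(g$frame), numeric(1)))
    late_active <- sum(vapply(trajs, function(g)
      sum(g$frame > t_max - 6) >= 3, logical(1)))
  }
  pat <- paste0(n, ":", paste(sort(state), collapse = "+"),
                if (collide) "+collision" else "",
                if (any(sw)) "+switch" else "")
  cat_out <- if (collide) {
    if (late_active >= 2 || any(sw)) "I" else "A"
  } else if (n == 1) {
    if (state == "stat") "G" else if (state == "away") "B" else "other"
  } else if (n == 2) {
    if (all(state == "away")) "C"
    else if (all(state == "stat")) "H"
    else if (setequal(state, c("stat", "away")) &&
             sum(state == "stat") == 1) "E"
    else if (setequal(state, c("stat", "toward")) &&
             sum(state == "stat") == 1) "F"
    else "other"
  } else if (n >= 3) {
    # fragmentation can split one peak into several tracks, so the
    # multi-peak rules read the composition, not the exact count
    if (all(state == "away")) "D"
    else if (sum(state == "stat") == 1 &&
             sum(state == "away") == n - 1) "J"
    else "other"
  } else "other"
  list(category = cat_out, pattern = pat, velocities = vs)
}

#' Signed velocity histograms by cell region
#'
#' Bins retained cluster velocities into fixed-width bins (default
#' 0.1 um/min) per region, positive velocities moving away from the cell
#' boundary, and tabulates per-category mean velocities with 95 percent
#' confidence limits.
#'
#' @param velocities numeric vector of cluster velocities, um/min
#'   (positive away from the boundary).
#' @param regions character vector of region labels, one per velocity.
#' @param categories optional per-cluster category labels.
#' @param bin_width um/min (default 0.1).
#' @return list with `histograms` (per region: data.frame `mid`,
#'   `count`) and `category_table` (mean, ci95, n per category), bin
#'   totals equalling the number of retained velocities.
#' @export
regional_velocity_histograms <- function(velocities, regions,
                                         categories = NULL,
                                         bin_width = 0.1) {
  stopifnot(length(velocities) == length(regions))
  keep <- is.finite(velocities)
  velocities <- velocities[keep]; regions <- regions[keep]
  if (!is.null(categories)) categories <- categories[keep]
  hist1 <- function(v) {
    if (!length(v)) return(data.frame(mid = numeric(0), count = integer(0)))
    bins <- floor(v / bin_width)
    tab <- table(bins)
    data.frame(mid = (as.integer(names(tab)) + 0.5) * bin_width,
               count = as.integer(tab))
  }
  hists <- lapply(split(velocities, regions), hist1)
  cat_table <- NULL
  if (!is.null(categories)) {
    cat_table <- do.call(rbind, lapply(split(velocities, categories),
      function(v) {
        m <- mean(v)
        ci <- if (length(v) > 1)
          stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
          else NA_real_
        data.frame(mean_um_min = m, ci95 = ci, n = length(v))
      }))
    cat_table$category <- rownames(cat_table)
    rownames(cat_table) <- NULL
  }
  list(histograms = hists, category_table = cat_table)
}
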