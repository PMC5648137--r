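# Gaussian smoothing of a 1-D profile (reflected ends)
smooth_gauss <- function(y, sigma = 1.5) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- length(y)
  ypad <- c(rev(y[seq_len(h)]), y, rev(y[n + 1 - seq_len(h)]))
  as.numeric(stats::filter(ypad, k, sides = 2))[(h + 1):(h + n)]
}

# robust noise scale from first differences
noise_scale <- function(y) stats::mad(diff(y)) / sqrt(2)

# local maxima / minima indices of a vector (plateaus collapse to first)
local_extrema <- function(y) {
  d <- sign(diff(y))
  d[d == 0] <- 1e-9  # break flat runs deterministically
  up <- which(diff(d) < 0) + 1L
  dn <- which(diff(d) > 0) + 1L
  list(max = up, min = dn)
}

# single-Gaussian least squares on an interval; returns NULL on failure
fit_gauss_1d <- function(x, y, c0, a0, s0 = 2) {
  rss <- function(p) sum((y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))^2)
  f <- stats::optim(c(a0, c0, s0), rss, method = "L-BFGS-B",
                    lower = c(0, min(x), 0.5),
                    upper = c(4 * max(a0, 1e-12), max(x), diff(range(x))),
                    control = list(maxit = 300))
  list(amplitude = f$par[1], center = f$par[2], sigma = f$par[3],
       rss = f$value)
}

#' Peak detection by prominence of smoothed extrema (method 1)
#'
#' Smooths the profile, finds local extrema, and ranks maxima by
#' prominence (the larger drop to the two flanking minima; for
#' double-hump maxima the second-nearest minimum is also considered).
#' Each minima-bounded interval is then fit with a Gaussian (or the
#' two-Gaussian mixture if the interval holds two maxima); size is the
#' fitted area above baseline.  Peaks with amplitude below
#' `min_snr` times the robust noise scale are discarded.
#'
#' @param y intensity profile.
#' @param x positions (default `seq_along(y)`).
#' @param smoothing Gaussian smoothing sigma, px (default 1.5).
#' @param min_snr amplitude floor in noise units (default 3).
#' @param double_hump_gap maxima closer than this (px) inside one
#'   interval are fit jointly as a double hump (default 6).
#' @return data.frame `center`, `size`, `width`, `prominence`, `method`.
#' @export
peaks_by_prominence <- function(y, x = seq_along(y), smoothing = 1.5,
                                min_snr = 3, double_hump_gap = 6) {
  stopifnot(length(y) >= 8)
  ys <- smooth_gauss(y, smoothing)
  ns <- noise_scale(y)
  ex <- local_extrema(ys)
  out <- list()
  base <- min(ys)
  if (!length(ex$max)) return(data.frame(center = numeric(0),
                                         size = numeric(0),
                                         width = numeric(0),
                                         prominence = numeric(0),
                                         method = integer(0)))
  bounds <- c(1L, ex$min, length(y))
  for (m in ex$max) {
    lo <- max(bounds[bounds < m]); hi <- min(bounds[bounds > m])
    # prominence: drop to the higher flanking minimum; consider the
    # second-nearest minimum for double-hump profiles
    mins_left <- rev(bounds[bounds < m]); mins_right <- bounds[bounds > m]
    vl <- ys[mins_left[1]]; vr <- ys[mins_right[1]]
    if (length(mins_left) > 1) vl <- min(vl, ys[mins_left[2]])
    if (length(mins_right) > 1) vr <- min(vr, ys[mins_right[2]])
    prom <- ys[m] - max(vl, vr)
    if (prom < min_snr * ns || prom <= 0) next
    xs <- x[lo:hi]; yy <- y[lo:hi] - base
    f <- fit_gauss_1d(xs, yy, x[m], ys[m] - base)
    out[[length(out) + 1]] <- data.frame(
      center = f$center, size = f$amplitude * f$sigma * sqrt(2 * pi),
      width = f$sigma, prominence = prom, method = 1L)
  }
  pk <- if (length(out)) do.call(rbind, out) else
    data.frame(center = numeric(0), size = numeric(0), width = numeric(0),
               prominence = numeric(0), method = integer(0))
  pk[order(-pk$prominence), , drop = FALSE]
}

#' Peak detection from the second derivative (method 2)
#'
#' Takes the second difference of the smoothed profile, locates its
#' negative-curvature lobes (minima), least-squares fits a 1-D Mexican
#' hat to each lobe of `-y''`, and recovers the original peak by
#' integrating the fitted wavelet twice analytically: a fitted
#' `c (1 - u^2) exp(-u^2/2)` with `u = (x - mu)/s` integrates twice to
#' the Gaussian `c s^2 exp(-u^2/2)`, so the peak has amplitude `c s^2`
#' and area `c s^3 sqrt(2 pi)`.
#'
#' @inheritParams peaks_by_prominence
#' @return data.frame `center`, `size`, `width`, `method`.
#' @export
peaks_by_second_derivative <- function(y, x = seq_along(y), smoothing = 1.5,
                                       min_snr = 3) {
  stopifnot(length(y) >= 8)
  ys <- smooth_gauss(y, smoothing)
  ns <- noise_scale(y)
  d2 <- c(NA, diff(ys, differences = 2), NA)
  d2[is.na(d2)] <- 0
  neg <- -d2
  ex <- local_extrema(neg)
  out <- list()
  for (m in ex$max) {
    if (neg[m] <= 0) next
    h <- 6L
    lo <- max(1L, m - h); hi <- min(length(y), m + h)
    xs <- x[lo:hi]; yy <- neg[lo:hi]
    rss <- function(p) {
      u <- (xs - p[2]) / p[3]
      sum((yy - p[1] * (1 - u^2) * exp(-u^2 / 2))^2)
    }
    f <- stats::optim(c(neg[m], x[m], 2), rss, method = "L-BFGS-B",
                      lower = c(0, xs[1], 0.6),
                      upper = c(10 * max(neg[m], 1e-12), xs[length(xs)], 20),
                      control = list(maxit = 300))
    amp <- f$par[1] * f$par[3]^2  # recovered peak amplitude
    if (amp < min_snr * ns) next
    out[[length(out) + 1]] <- data.frame(
      center = f$par[2], size = amp * f$par[3] * sqrt(2 * pi),
      width = f$par[3], method = 2L)
  }
  pk <- if (length(out)) do.call(rbind, out) else
    data.frame(center = numeric(0), size = numeric(0), width = numeric(0),
               method = integer(0))
  pk[order(-pk$size), , drop = FALSE]
}

#' Peak detection by Lorentzian-pair wavelet fits (method 3)
#'
#' Least-squares fits of scaled [psi_lorentzian_pair()] templates (free
#' amplitude, centre and width) at candidate locations from the smoothed
#' profile; the long 1/x^2 tails keep the template's two shallow negative
#' side lobes from biasing the fit.  Size is the fitted positive-lobe
#' area: the template is positive for `|x - x0| < sqrt(2) gamma` with
#' closed-form lobe area `(2 atan(sqrt 2) - 2 atan(sqrt 2 / 2)) / pi`
#' (about 0.2164) times the amplitude scale.
#'
#' @inheritParams peaks_by_prominence
#' @return data.frame `center`, `size`, `width` (gamma), `method`.
#' @export
peaks_by_lorentzian_wavelet <- function(y, x = seq_along(y),
                                        smoothing = 1.5, min_snr = 3) {
  stopifnot(length(y) >= 8)
  ys <- smooth_gauss(y, smoothing)
  ns <- noise_scale(y)
  ex <- local_extrema(ys)
  base <- min(ys)
  out <- list()
  lobe <- (2 * atan(sqrt(2)) - 2 * atan(sqrt(2) / 2)) / pi
  for (m in ex$max) {
    h <- 20L
    lo <- max(1L, m - h); hi <- min(length(y), m + h)
    xs <- x[lo:hi]; yy <- y[lo:hi]
    # free additive offset: the template itself dips negative, so
    # anchoring the baseline at the profile minimum would distort it
    rss <- function(p) sum((yy - p[4] -
                              p[1] * psi_lorentzian_pair(xs, p[2], p[3]))^2)
    f <- stats::optim(c((ys[m] - base) * 2 * pi * 2, x[m], 2, base), rss,
                      method = "L-BFGS-B",
                      lower = c(0, xs[1], 0.5, -Inf),
                      upper = c(Inf, xs[length(xs)], 30, Inf),
                      control = list(maxit = 300))
    amp_peak <- f$par[1] / (2 * pi * f$par[3])  # template height at centre
    if (amp_peak < min_snr * ns) next
    out[[length(out) + 1]] <- data.frame(
      center = f$par[2], size = f$par[1] * lobe, width = f$par[3],
      method = 3L)
  }
  pk <- if (length(out)) do.call(rbind, out) else
    data.frame(center = numeric(0), size = numeric(0), width = numeric(0),
               method = integer(0))
  pk[order(-pk$size), , drop = FALSE]
}

#' Three-method consensus peak set
#'
#' A peak is retained exactly when all three methods report a peak
#' within `match_tolerance` of its centre; retained centre/size/width
#' are method 1's values, with the other methods' centres kept as
#' alternates.  Permutation-invariant in its inputs (methods are
#' identified by their `method` column).
#'
#' @param set1,set2,set3 peak data.frames from the three methods (any
#'   order).
#' @param match_tolerance centre matching tolerance, px (default 2).
#' @return data.frame like method 1's with columns `center`, `size`,
#'   `width`, plus `center_m2`, `center_m3`.
#' @export
peaks_consensus <- function(set1, set2, set3, match_tolerance = 2) {
  sets <- list(set1, set2, set3)
  meth <- vapply(sets, function(s)
    if (nrow(s)) s$method[1] else NA_integer_, integer(1))
  ref_idx <- which(meth == 1L)
  ref_idx <- if (length(ref_idx)) ref_idx[1] else 1L
  ref <- sets[[ref_idx]]
  others <- sets[-ref_idx]
  empty <- data.frame(center = numeric(0), size = numeric(0),
                      width = numeric(0), center_m2 = numeric(0),
                      center_m3 = numeric(0))
  if (!NROW(ref)) return(empty)
  if (!NROW(others[[1]]) || !NROW(others[[2]])) return(empty)
  keep <- list()
  for (i in seq_len(nrow(ref))) {
    alts <- numeric(2)
    ok <- TRUE
    for (k in 1:2) {
      s <- others[[k]]
      if (!nrow(s)) { ok <- FALSE; break }
      d <- abs(s$center - ref$center[i])
      j <- which.min(d)
      if (d[j] > match_tolerance) { ok <- FALSE; break }
      alts[k] <- s$center[j]
    }
    if (ok) {
      keep[[length(keep) + 1]] <- data.frame(
        center = ref$center[i], size = ref$size[i], width = ref$width[i],
        center_m2 = alts[1], center_m3 = alts[2])
    }
  }
  if (!length(keep)) return(data.frame(center = numeric(0),
                                       size = numeric(0), width = numeric(0),
                                       center_m2 = numeric(0),
                                       center_m3 = numeric(0)))
  do.call(rbind, keep)
}

#' Two-channel actomyosin bundle pole analysis
#'
#' For every frame, intensity profiles are sampled along the bundle axis
#' in both channels; consensus peak detection keeps peaks confirmed by
#' all three 1-D methods, and the outermost consensus peak on each side
#' of the bundle midpoint is the pole.  Same-side poles are linked
#' across frames and across channels (pairing by side, not by
#' distance).  Pole velocities are least-squares slopes of position
#' against time, positive toward the bundle centre, and the per-side
#' velocity difference is `delta_v = v_vinculin - v_myosin`.
#'
#' @param series a two-channel [image_series()] (channels `myosin`,
#'   `vinculin`).
#' @param bundle one-row data.frame with `x`, `y`, `theta` (axis
#'   orientation, degrees) and `half_length` (px; profile extends 1.8x
#'   this).
#' @param frames frame indices to analyse (default all).
#' @param match_tolerance consensus tolerance, px.
#' @param bin_width histogram bin width, um/min (default 0.03).
#' @param pixel_size,frame_interval calibration (defaults from the
#'   series).
#' @return list with `poles` (per side/channel: `v_um_min`, `ci`,
#'   `n_frames`), `pairs` (per side: `delta_v_um_min`), `positions`
#'   (tidy per-frame pole positions), `histograms` (per channel,
#'   combined, and delta-v), `skipped` (frames lacking two consensus
#'   peaks, per channel).
#' @export
pole_analysis <- function(series, bundle, frames = NULL,
                          match_tolerance = 2, bin_width = 0.03,
                          pixel_size = NULL, frame_interval = NULL) {
  stopifnot(!is.null(series$channels), length(series$channels) == 2)
  if (is.null(frames)) frames <- seq_len(length(series))
  ps <- pixel_size %||% series$pixel_size
  fi <- frame_interval %||% series$frame_interval
  th <- bundle$theta * pi / 180
  d <- c(cos(th), -sin(th))
  L <- 1.8 * bundle$half_length
  s <- seq(-L, L, by = 1)
  xs <- bundle$x + s * d[1]; ys <- bundle$y + s * d[2]
  channels <- c("myosin", "vinculin")
  positions <- list(); skipped <- list()
  for (ch in channels) {
    for (t in frames) {
      y <- bilinear_at(get_frame(series, t, ch), xs, ys)
      cons <- peaks_consensus(peaks_by_prominence(y, s),
                              peaks_by_second_derivative(y, s),
                              peaks_by_lorentzian_wavelet(y, s),
                              match_tolerance)
      plus <- cons$center[cons$center > 0]
      minus <- cons$center[cons$center < 0]
      if (!length(plus) || !length(minus)) {
        skipped[[length(skipped) + 1]] <- data.frame(frame = t, channel = ch)
        next
      }
      positions[[length(positions) + 1]] <- data.frame(
        frame = t, channel = ch,
        side = c("plus", "minus"),
        position = c(max(plus), min(minus)))
    }
  }
  positions <- do.call(rbind, positions)
  fit_pole <- function(g) {
    if (nrow(g) < 4) return(NULL)
    tt <- g$frame * fi / 60
    # positive toward the bundle centre: plus side moves to smaller s
    pos <- if (g$side[1] == "plus") -g$position else g$position
    f <- stats::lm(I(pos * ps) ~ tt)
    ci <- tryCatch(stats::confint(f)[2, ], error = function(e)
      c(NA_real_, NA_real_))
    data.frame(channel = g$channel[1], side = g$side[1],
               v_um_min = unname(coef(f)[2]),
               ci_lo = ci[1], ci_hi = ci[2], n_frames = nrow(g))
  }
  poles <- do.call(rbind, lapply(split(positions,
                                       list(positions$channel,
                                            positions$side), drop = TRUE),
                                 fit_pole))
  rownames(poles) <- NULL
  pairs <- NULL
  if (!is.null(poles)) {
    for (sd in unique(poles$side)) {
      vv <- poles$v_um_min[poles$channel == "vinculin" & poles$side == sd]
      vm <- poles$v_um_min[poles$channel == "myosin" & poles$side == sd]
      if (length(vv) && length(vm)) {
        pairs <- rbind(pairs, data.frame(side = sd,
                                         delta_v_um_min = vv - vm))
      }
    }
  }
  hist1 <- function(v) {
    if (!length(v)) return(data.frame(mid = numeric(0), count = integer(0)))
    bins <- floor(v / bin_width)
    tab <- table(bins)
    data.frame(mid = (as.integer(names(tab)) + 0.5) * bin_width,
               count = as.integer(tab))
  }
  hists <- list(
    myosin = hist1(poles$v_um_min[poles$channel == "myosin"]),
    vinculin = hist1(poles$v_um_min[poles$channel == "vinculin"]),
    combined = hist1(poles$v_um_min),
    delta_v = hist1(pairs$delta_v_um_min))
  list(poles = poles, pairs = pairs, positions = positions,
       histograms = hists,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
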