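# Otsu's threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), 256)
  w <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# shoelace area of a closed polyline (columns x, y)
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# closed sub-pixel iso-contours of matrix z (indexed [y, x]) at level
closed_contours <- function(z, level) {
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = level)
  lapply(cl, function(cc) {
    xy <- cbind(x = cc$y, y = cc$x)   # contourLines' x runs over rows
    if (any(xy[1, ] != xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
    xy
  })
}

#' Extract the cell boundary from a coarse-scale reconstruction
#'
#' Computes the wavelet transform of the frame over a coarse scale band,
#' reconstructs the band-limited image by the inverse transform, applies
#' a threshold (Otsu's method on the reconstruction by default), keeps
#' the largest connected foreground component and traces its outer
#' boundary as a closed sub-pixel iso-contour at the threshold level.
#' Smoothing by the band limits the accuracy: the recovered contour
#' tracks the true edge to within about the smallest scale in the band.
#'
#' @param frame numeric image matrix.
#' @param band scale band `c(a_min, a_max)` in pixels (default
#'   `c(20, 200)`, capped at the frame size).
#' @param delta_a scale spacing within the band (default 4).
#' @param threshold `"otsu"`, or a number in (0, 1]: that fraction of the
#'   reconstruction maximum.
#' @param field optional precomputed `cwt_field` to reuse.
#' @return list with `contour` (closed polyline matrix, columns `x`,
#'   `y`), `mask` (logical matrix of the largest component),
#'   `threshold`, `reconstruction` and `enclosed_area` (px^2).  With no
#'   foreground above threshold, `contour` is `NULL` with a warning.
#' @export
extract_boundary <- function(frame, band = c(20, 200), delta_a = 4,
                             threshold = "otsu", field = NULL) {
  amax <- min(band[2], max(dim(frame)))
  scales <- seq(band[1], amax, by = delta_a)
  if (is.null(field)) field <- cwt_forward(frame, scales)
  rec <- cwt_inverse(field)
  if (diff(range(rec)) < 1e-12) {
    warning("no foreground component above the boundary threshold")
    return(list(contour = NULL, mask = rec > Inf, threshold = NA_real_,
                reconstruction = rec, enclosed_area = 0))
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(rec)
         else threshold * max(rec)
  fg <- rec >= thr
  if (!any(fg)) {
    warning("no foreground component above the boundary threshold")
    return(list(contour = NULL, mask = fg, threshold = thr,
                reconstruction = rec, enclosed_area = 0))
  }
  lab <- label_components_cpp(fg)
  big <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == big
  cc <- closed_contours(rec, thr)
  if (!length(cc)) {
    warning("foreground present but no closed iso-contour found")
    return(list(contour = NULL, mask = mask, threshold = thr,
                reconstruction = rec, enclosed_area = sum(mask)))
  }
  areas <- vapply(cc, polygon_area, numeric(1))
  contour <- cc[[which.max(areas)]]
  list(contour = contour, mask = mask, threshold = thr,
       reconstruction = rec, enclosed_area = sum(mask))
}

#' Decompose two cell masks into protruded, retracted and stable regions
#'
#' Exact set decomposition between frames: `protruded = t1 \ t0`,
#' `retracted = t0 \ t1`, `stable = t0 & t1`, so
#' `stable | protruded == mask_t1` and `stable | retracted == mask_t0`
#' identically.  Contour vertices of `contour_t1` adjacent to protruded
#' pixels are labelled `protruding`; vertices of `contour_t0` adjacent to
#' retracted pixels are labelled `retracting`; the rest are `stable`.
#'
#' @param mask_t0,mask_t1 logical matrices of equal dimension.
#' @param contour_t0,contour_t1 optional closed polylines (from
#'   [extract_boundary()]); needed for labelled front segments.
#' @param adjacency_radius distance (px) within which a contour vertex
#'   counts as adjacent to a moving region.
#' @return list with `protruded`, `retracted`, `stable` masks and
#'   `front_t0`, `front_t1` (data.frames `x`, `y`, `label`).
#' @export
decompose_regions <- function(mask_t0, mask_t1,
                              contour_t0 = NULL, contour_t1 = NULL,
                              adjacency_radius = 2) {
  stopifnot(all(dim(mask_t0) == dim(mask_t1)))
  protruded <- mask_t1 & !mask_t0
  retracted <- mask_t0 & !mask_t1
  stable <- mask_t0 & mask_t1
  label_front <- function(contour, moving) {
    if (is.null(contour)) return(NULL)
    pts <- which(moving, arr.ind = TRUE)
    lab <- rep("stable", nrow(contour))
    if (nrow(pts)) {
      for (i in seq_len(nrow(contour))) {
        d2 <- (pts[, 2] - contour[i, 1])^2 + (pts[, 1] - contour[i, 2])^2
        if (min(d2) <= adjacency_radius^2) lab[i] <- "moving"
      }
    }
    data.frame(x = contour[, 1], y = contour[, 2], label = lab)
  }
  f1 <- label_front(contour_t1, protruded)
  if (!is.null(f1)) f1$label[f1$label == "moving"] <- "protruding"
  f0 <- label_front(contour_t0, retracted)
  if (!is.null(f0)) f0$label[f0$label == "moving"] <- "retracting"
  list(protruded = protruded, retracted = retracted, stable = stable,
       front_t0 = f0, front_t1 = f1)
}

# min distance from each point (px, py) to the vertices of a polyline
min_dist_to_polyline <- function(px, py, contour) {
  vapply(seq_along(px), function(i)
    sqrt(min((contour[, 1] - px[i])^2 + (contour[, 2] - py[i])^2)),
    numeric(1))
}

#' Front kinematics over an extracted boundary series
#'
#' For each consecutive frame pair the masks are decomposed into moving
#' and stable regions; the arc length of the protruding front, the
#' cumulative area swept since the first frame, and the mean normal
#' advance of the front (nearest-point distance between consecutive
#' contours, averaged along the protruding front) are accumulated.  The
#' front velocity is the least-squares slope of cumulative mean advance
#' against time, reported in micrometres per minute with its standard
#' error.
#'
#' @param boundaries list of [extract_boundary()] results, one per frame.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return list with `per_frame` (data.frame: `frame`, `arc_length_um`,
#'   `swept_area_um2`, `mean_advance_px`) and `front_velocity` (list
#'   `um_min`, `se`).
#' @export
front_metrics <- function(boundaries, pixel_size = 0.105,
                          frame_interval = 5) {
  n <- length(boundaries)
  stopifnot(n >= 2)
  mask1 <- boundaries[[1]]$mask
  rows <- list()
  cum_adv <- 0
  for (t in 2:n) {
    b0 <- boundaries[[t - 1]]; b1 <- boundaries[[t]]
    dec <- decompose_regions(b0$mask, b1$mask, b0$contour, b1$contour)
    arc <- 0; adv <- 0
    if (!is.null(dec$front_t1) && !is.null(b0$contour)) {
      f1 <- dec$front_t1
      prot <- f1$label == "protruding"
      if (any(prot)) {
        seg <- which(prot[-nrow(f1)] & prot[-1])
        if (length(seg)) {
          dx <- f1$x[seg + 1] - f1$x[seg]; dy <- f1$y[seg + 1] - f1$y[seg]
          arc <- sum(sqrt(dx^2 + dy^2))
        }
        adv <- mean(min_dist_to_polyline(f1$x[prot], f1$y[prot],
                                         b0$contour))
      }
    }
    cum_adv <- cum_adv + adv
    swept <- sum(b1$mask & !mask1)
    rows[[t - 1]] <- data.frame(
      frame = t, arc_length_um = arc * pixel_size,
      swept_area_um2 = swept * pixel_size^2,
      mean_advance_px = cum_adv)
  }
  pf <- do.call(rbind, rows)
  tt <- (pf$frame - 1) * frame_interval / 60        # minutes
  adv_um <- pf$mean_advance_px * pixel_size
  fit <- stats::lm(adv_um ~ tt)
  list(per_frame = pf,
       front_velocity = list(um_min = unname(coef(fit)[2]),
                             se = summary(fit)$coefficients[2, 2]))
}

#' Distance and tangent angle between an adhesion and the cell boundary
#'
#' Distance is the minimum Euclidean distance from the adhesion centre to
#' the contour; the local boundary tangent is estimated by principal
#' component of a window of vertices around the nearest point, and the
#' angle between the adhesion's major axis and that tangent is folded to
#' `[0, 90]` degrees (adhesion orientation is axial).
#'
#' @param adhesion one-row data.frame (or list) with `x`, `y`, `a`, `xi`,
#'   `theta`.
#' @param contour closed polyline matrix (columns `x`, `y`).
#' @param pixel_size micrometres per pixel.
#' @param window half-width of the tangent window, vertices (default 5).
#' @return list with `distance_um`, `tangent_angle` (degrees in
#'   `[0, 90]`) and `nearest_vertex`.
#' @export
adhesion_boundary_geometry <- function(adhesion, contour,
                                       pixel_size = 0.105, window = 5) {
  if (is.null(contour) || !nrow(contour)) stop("contour is empty")
  d2 <- (contour[, 1] - adhesion$x)^2 + (contour[, 2] - adhesion$y)^2
  i <- which.min(d2)
  n <- nrow(contour) - 1L  # last vertex repeats the first
  idx <- ((i - 1 + seq(-window, window)) %% n) + 1
  w <- contour[idx, , drop = FALSE]
  w <- sweep(w, 2, colMeans(w))
  tangent <- svd(w)$v[, 1]
  phi_t <- (atan2(-tangent[2], tangent[1]) * 180 / pi) %% 180
  phi_a <- adhesion_axes(adhesion$a, adhesion$xi, adhesion$theta)$phi_major
  dphi <- abs(phi_a - phi_t) %% 180
  if (dphi > 90) dphi <- 180 - dphi
  list(distance_um = sqrt(d2[i]) * pixel_size, tangent_angle = dphi,
       nearest_vertex = i)
}

#' Assign an adhesion to a cell region
#'
#' `central` when the adhesion sits at least `centrality_distance` from
#' the boundary; otherwise the label of the nearest moving front segment
#' (`protruding` or `retracting`), or `intersecting` when the two are
#' equidistant within `tie_tolerance`.
#'
#' @param adhesion one-row data.frame (or list) with `x`, `y`.
#' @param decomposition a [decompose_regions()] result with labelled
#'   fronts.
#' @param pixel_size micrometres per pixel.
#' @param centrality_distance micrometres (default 4).
#' @param tie_tolerance micrometres (default 0.5).
#' @return one of `"protruding"`, `"retracting"`, `"central"`,
#'   `"intersecting"`.
#' @export
assign_region <- function(adhesion, decomposition, pixel_size = 0.105,
                          centrality_distance = 4, tie_tolerance = 0.5) {
  f1 <- decomposition$front_t1; f0 <- decomposition$front_t0
  if (is.null(f1)) stop("decomposition lacks labelled fronts")
  d_boundary <- min(sqrt((f1$x - adhesion$x)^2 + (f1$y - adhesion$y)^2)) *
    pixel_size
  if (d_boundary >= centrality_distance) return("central")
  dp <- dr <- Inf
  p <- f1[f1$label == "protruding", , drop = FALSE]
  if (nrow(p)) dp <- min(sqrt((p$x - adhesion$x)^2 +
                              (p$y - adhesion$y)^2)) * pixel_size
  r <- f0[f0$label == "retracting", , drop = FALSE]
  if (!is.null(f0) && nrow(r))
    dr <- min(sqrt((r$x - adhesion$x)^2 + (r$y - adhesion$y)^2)) *
      pixel_size
  if (!is.finite(dp) && !is.finite(dr)) return("central")
  if (abs(dp - dr) <= tie_tolerance) return("intersecting")
  if (dp < dr) "protruding" else "retracting"
}
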