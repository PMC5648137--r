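#' Ellipse geometry of a detected adhesion
#'
#' A detection `(a, xi, theta)` describes an oriented elliptical footprint
#' with semi-axes `a` along the wavelet's parallel axis and `a * xi` along
#' its perpendicular axis (the "scaled" footprint convention; the literal
#' reading with semi-axes `(a, xi)` is available via
#' `ellipse_convention = "literal"` in [place_adhesions()]).  For
#' `xi > 1` the wavelet is elongated along the perpendicular axis, so the
#' major axis of the footprint lies at `theta - 90` degrees; for `xi < 1`
#' it lies at `theta`.
#'
#' @param a scale, pixels.
#' @param xi anisotropy factor.
#' @param theta wavelet orientation, degrees.
#' @param convention `"scaled"` (semi-axes `a`, `a*xi`) or `"literal"`
#'   (semi-axes `a`, `xi`).
#' @return list with `semi_par`, `semi_perp`, `semi_major`, `semi_minor`
#'   and `phi_major` (major-axis angle, degrees in `[0, 180)`).
#' @export
adhesion_axes <- function(a, xi, theta, convention = c("scaled", "literal")) {
  convention <- match.arg(convention)
  sp <- a
  sq <- if (convention == "scaled") a * xi else xi
  if (sq >= sp) {
    list(semi_par = sp, semi_perp = sq, semi_major = sq, semi_minor = sp,
         phi_major = (theta - 90) %% 180)
  } else {
    list(semi_par = sp, semi_perp = sq, semi_major = sp, semi_minor = sq,
         phi_major = theta %% 180)
  }
}

# 3x3 homogeneous conic matrix of an ellipse with centre (cx, cy),
# semi-axes (p along phi, q perpendicular), phi in degrees. Interior < 0.
conic_matrix <- function(cx, cy, p, q, phi) {
  t <- phi * pi / 180
  # direction of the p axis is (cos t, -sin t) in image coordinates
  R <- matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2)
  M <- R %*% diag(c(1 / p^2, 1 / q^2)) %*% t(R)
  ctr <- c(cx, cy)
  rbind(cbind(M, -M %*% ctr),
        c(-crossprod(ctr, M), crossprod(ctr, M %*% ctr) - 1))
}

#' Exact ellipse-ellipse disjointness test
#'
#' Algebraic separation test via the characteristic cubic of the pencil of
#' the two conics: with both conics normalised so that interiors are
#' negative, the ellipses are separated exactly when
#' `f(lambda) = det(lambda A + B)` has two distinct positive real roots
#' (a positive double root is external tangency).  Resolution-independent,
#' unlike raster tests.
#'
#' @param e1,e2 lists with `x`, `y`, `semi_par` (or `p`), `semi_perp` (or
#'   `q`) and `phi` (angle of the `p` axis, degrees).
#' @param tangent_ok treat external tangency as disjoint (default TRUE).
#' @return TRUE when the ellipse interiors are disjoint (neither overlaps
#'   nor contains the other).
#' @export
ellipses_disjoint <- function(e1, e2, tangent_ok = TRUE) {
  # cheap bounding-circle prechecks
  d <- sqrt((e1$x - e2$x)^2 + (e1$y - e2$y)^2)
  r1 <- max(e1$p, e1$q); r2 <- max(e2$p, e2$q)
  if (d > r1 + r2) return(TRUE)
  if (d < min(e1$p, e1$q) + min(e2$p, e2$q)) return(FALSE)
  A <- conic_matrix(e1$x, e1$y, e1$p, e1$q, e1$phi)
  B <- conic_matrix(e2$x, e2$y, e2$p, e2$q, e2$phi)
  # cubic f(l) = det(l A + B): recover coefficients from 4 evaluations
  f <- function(l) det(l * A + B)
  y <- c(f(0), f(1), f(-1), f(2))
  # y = c0, c0+c1+c2+c3, c0-c1+c2-c3, c0+2c1+4c2+8c3
  c0 <- y[1]
  c2 <- (y[2] + y[3]) / 2 - c0
  c13 <- (y[2] - y[3]) / 2            # c1 + c3
  c3 <- (y[4] - c0 - 4 * c2 - 2 * c13) / 6
  c1 <- c13 - c3
  rts <- polyroot(c(c0, c1, c2, c3))
  scale <- max(Mod(rts), 1)
  real <- rts[abs(Im(rts)) < 1e-8 * scale]
  pos <- sort(Re(real[Re(real) > 1e-12]))
  if (length(pos) < 2) return(FALSE)
  gap <- (pos[2] - pos[1]) / max(pos[2], 1e-12)
  if (gap > 1e-9) TRUE else tangent_ok
}

# Candidate (b, theta) maxima of one (a, xi) coefficient stack.
# A: [ny, nx, ntheta]; returns data.frame(y, x, ti, value).
stack_maxima <- function(A, floor_value) {
  ny <- dim(A)[1]; nx <- dim(A)[2]; nt <- dim(A)[3]
  out <- vector("list", nt)
  ys <- 2:(ny - 1); xs <- 2:(nx - 1)
  for (t in seq_len(nt)) {
    M <- A[, , t]
    C <- M[ys, xs]
    ok <- C >= floor_value & C > 0 &
      C > M[ys - 1, xs] & C > M[ys + 1, xs] &
      C > M[ys, xs - 1] & C > M[ys, xs + 1] &
      C > M[ys - 1, xs - 1] & C > M[ys - 1, xs + 1] &
      C > M[ys + 1, xs - 1] & C > M[ys + 1, xs + 1]
    if (nt > 1) {
      tp <- if (t == 1) nt else t - 1
      tn <- if (t == nt) 1 else t + 1
      ok <- ok & C > A[ys, xs, tp] & C > A[ys, xs, tn]
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[t]] <- data.frame(y = idx[, 1] + 1, x = idx[, 2] + 1, ti = t,
                             value = C[idx])
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Locate local maxima of a computed coefficient field
#'
#' Returns positions that are strict maxima over the 8-neighbourhood in
#' `b`, over adjacent orientations (wrapped modulo 180 degrees), and, when
#' several scales/anisotropies are present, over grid-adjacent `(a, xi)`
#' pairs; candidates below `threshold_fraction` of the global maximum are
#' discarded and the rest returned sorted by decreasing coefficient.
#'
#' @param field a `cwt_field` from [cwt_forward()] (all scales must share
#'   one mesh for the cross-scale comparison; use `mesh = "native"`).
#' @param frame the image the field was computed from (needed for exact
#'   cross-`(a, xi)` comparisons; may be omitted for single-scale fields).
#' @param threshold_fraction keep maxima at least this fraction of the
#'   highest maximum (default 0.10).
#' @param normalize compare family members on the unit-energy (matched
#'   filter) score `T / sqrt(xi)` rather than the raw coefficient
#'   (default TRUE; irrelevant for a single-`xi` field).  The reported
#'   `coefficient` stays raw either way.
#' @return data.frame with `x`, `y`, `a`, `xi`, `theta`, `score`,
#'   `coefficient`, sorted by decreasing score.
#' @export
find_local_maxima <- function(field, frame = NULL, threshold_fraction = 0.1,
                              normalize = TRUE) {
  stopifnot(inherits(field, "cwt_field"))
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  na <- length(field$scales); nxi <- length(field$xis)
  if ((na > 1 || nxi > 1) && is.null(frame))
    stop("`frame` is required for cross-scale maxima comparisons")
  gmax <- -Inf
  cand <- list()
  for (si in seq_len(na)) {
    e <- field$entries[[si]]
    for (xj in seq_len(nxi)) {
      A <- e$values[, , xj, , drop = TRUE]
      if (length(dim(A)) == 2) dim(A) <- c(dim(A), 1)
      if (normalize) A <- A / sqrt(field$xis[xj])
      mx <- max(A)
      gmax <- max(gmax, mx)
      if (mx <= 0) next
      cm <- stack_maxima(A, threshold_fraction * mx)
      if (is.null(cm) || !nrow(cm)) next
      cm$si <- si; cm$xj <- xj; cm$step <- e$step
      cm$px <- e$origin["x"] + (cm$x - 1) * e$step
      cm$py <- e$origin["y"] + (cm$y - 1) * e$step
      a_i <- field$scales[si]
      cm <- cm[cm$px > a_i & cm$px <= field$frame_dim[2] + 1 - a_i &
               cm$py > a_i & cm$py <= field$frame_dim[1] + 1 - a_i, ,
               drop = FALSE]
      if (!nrow(cm)) next
      cand[[length(cand) + 1]] <- cm
    }
  }
  if (!length(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      xi = numeric(0), theta = numeric(0),
                      coefficient = numeric(0)))
  }
  cm <- do.call(rbind, cand)
  cm <- cm[cm$value >= threshold_fraction * gmax, , drop = FALSE]
  # strictness across grid-adjacent (a, xi) at the same (b, theta),
  # evaluated by the truncated direct sum on the native frame
  if ((na > 1 || nxi > 1) && nrow(cm)) {
    keep <- logical(nrow(cm))
    for (r in seq_len(nrow(cm))) {
      a <- field$scales[cm$si[r]]; xi <- field$xis[cm$xj[r]]
      th <- field$thetas[cm$ti[r]]
      row <- as.integer(round(cm$py[r])); col <- as.integer(round(cm$px[r]))
      nrm <- function(x) if (normalize) sqrt(x) else 1
      v0 <- cwt_point_cpp(frame, a, xi, th, row, col, 1, field$box,
                          isTRUE(field$demean)) / nrm(xi)
      ok <- TRUE
      for (dsi in c(-1L, 1L)) {
        s2 <- cm$si[r] + dsi
        if (s2 >= 1 && s2 <= na) {
          v <- cwt_point_cpp(frame, field$scales[s2], xi, th, row, col, 1,
                             field$box, isTRUE(field$demean)) / nrm(xi)
          if (v >= v0) { ok <- FALSE; break }
        }
      }
      if (ok) for (dxj in c(-1L, 1L)) {
        x2 <- cm$xj[r] + dxj
        if (x2 >= 1 && x2 <= nxi) {
          v <- cwt_point_cpp(frame, a, field$xis[x2], th, row, col, 1,
                             field$box, isTRUE(field$demean)) /
            nrm(field$xis[x2])
          if (v >= v0) { ok <- FALSE; break }
        }
      }
      keep[r] <- ok
    }
    cm <- cm[keep, , drop = FALSE]
  }
  out <- data.frame(x = cm$px, y = cm$py,
                    a = field$scales[cm$si], xi = field$xis[cm$xj],
                    theta = field$thetas[cm$ti], score = cm$value,
                    coefficient = cm$value *
                      (if (normalize) sqrt(field$xis[cm$xj]) else 1))
  out[order(-out$score, out$y, out$x), , drop = FALSE]
}

#' Greedy non-overlapping placement of candidate adhesions
#'
#' Candidates are swept in order of decreasing coefficient (ties broken by
#' lower y, then lower x, for determinism); a candidate is accepted exactly
#' when its elliptical footprint is disjoint from every previously
#' accepted footprint ([ellipses_disjoint()]).
#'
#' @param maxima data.frame from [find_local_maxima()].
#' @param ellipse_convention `"scaled"` footprint semi-axes `(a, a xi)`
#'   or `"literal"` `(a, xi)`; see [adhesion_axes()].
#' @param frame_index frame id recorded on the output rows.
#' @param pixel_size optional micrometres per pixel, adds `a_um`.
#' @param order_by column used for the descending sweep (default the raw
#'   `coefficient`; detection uses the unit-energy `score`).
#' @return data.frame of accepted adhesions with stable `id`s.
#' @export
place_adhesions <- function(maxima, ellipse_convention = c("scaled", "literal"),
                            frame_index = 1L, pixel_size = NULL,
                            order_by = "coefficient") {
  ellipse_convention <- match.arg(ellipse_convention)
  if (!nrow(maxima)) {
    return(cbind(maxima[0, ], data.frame(frame = integer(0), id = integer(0))))
  }
  if (is.null(maxima[[order_by]])) order_by <- "coefficient"
  ord <- order(-maxima[[order_by]], maxima$y, maxima$x)
  maxima <- maxima[ord, , drop = FALSE]
  placed <- list()
  ell <- list()
  for (r in seq_len(nrow(maxima))) {
    ax <- adhesion_axes(maxima$a[r], maxima$xi[r], maxima$theta[r],
                        ellipse_convention)
    cand <- list(x = maxima$x[r], y = maxima$y[r],
                 p = ax$semi_par, q = ax$semi_perp, phi = maxima$theta[r])
    ok <- TRUE
    for (e in ell) if (!ellipses_disjoint(cand, e)) { ok <- FALSE; break }
    if (ok) {
      ell[[length(ell) + 1]] <- cand
      placed[[length(placed) + 1]] <- maxima[r, , drop = FALSE]
    }
  }
  out <- do.call(rbind, placed)
  rownames(out) <- NULL
  out$frame <- as.integer(frame_index)
  out$id <- seq_len(nrow(out))
  if (!is.null(pixel_size)) out$a_um <- out$a * pixel_size
  out
}

#' Detect oriented adhesions in one frame
#'
#' Runs the stretched-wavelet transform over a grid of scales,
#' anisotropies and orientations, finds coefficient maxima over
#' `(a, xi, theta, b)` at least `threshold_fraction` of the highest one,
#' and greedily places non-overlapping oriented ellipses.  The whole grid
#' is evaluated on the native pixel mesh so coefficient magnitudes are
#' comparable across scales; the computation streams one `(a, xi)`
#' coefficient stack at a time to bound memory.
#'
#' Two grid presets mirror common usage: `grid = "constant"` uses a fixed
#' `a = 10`, `xi = 1.5` over 180 orientations; `grid = "variable"` uses
#' `a = 4..20`, `xi = {1/2, 1, 3/2}` over the same orientations.
#'
#' @param frame numeric image matrix.
#' @param scales,xis,thetas explicit grids (override `grid`).
#' @param grid `"variable"` (default) or `"constant"` preset.
#' @param n_theta number of orientations in `[0, 180)` for the presets.
#' @param threshold_fraction maxima threshold (default 0.10 of the
#'   highest maximum, applied per frame).
#' @param ellipse_convention see [place_adhesions()].
#' @param pixel_size optional micrometres per pixel, adds `a_um`.
#' @param frame_index frame id recorded on the output.
#' @param box truncation half-width in units of `a`.
#' @return data.frame of accepted adhesions (`x`, `y`, `a`, `xi`,
#'   `theta`, `coefficient`, `frame`, `id`, optionally `a_um`).
#' @export
detect_adhesions <- function(frame, scales = NULL, xis = NULL, thetas = NULL,
                             grid = c("variable", "constant"), n_theta = 180,
                             threshold_fraction = 0.1,
                             ellipse_convention = "scaled",
                             pixel_size = NULL, frame_index = 1L, box = 3) {
  grid <- match.arg(grid)
  if (is.null(scales)) scales <- if (grid == "constant") 10 else 4:20
  if (is.null(xis)) xis <- if (grid == "constant") 1.5 else c(0.5, 1, 1.5)
  if (is.null(thetas)) thetas <- seq(0, 180 - 180 / n_theta, by = 180 / n_theta)
  na <- length(scales); nxi <- length(xis)
  # pass 1: stream (a, xi) stacks, harvesting (b, theta) maxima above 10%
  # of each stack's own maximum (a superset of the global-threshold set)
  gmax <- -Inf
  cand <- list()
  for (si in seq_len(na)) {
    for (xj in seq_len(nxi)) {
      f1 <- cwt_forward(frame, scales[si], xis = xis[xj], thetas = thetas,
                        mesh = "native", box = box)
      A <- f1$entries[[1]]$values[, , 1, ] / sqrt(xis[xj])
      if (length(dim(A)) == 2) dim(A) <- c(dim(A), 1)
      mx <- max(A)
      gmax <- max(gmax, mx)
      if (mx <= 0) next
      cm <- stack_maxima(A, threshold_fraction * mx)
      if (is.null(cm) || !nrow(cm)) next
      # centres within one scale length of the frame edge are artefacts
      # of the zero-intensity boundary convention
      a_i <- scales[si]
      cm <- cm[cm$x > a_i & cm$x <= ncol(frame) + 1 - a_i &
               cm$y > a_i & cm$y <= nrow(frame) + 1 - a_i, , drop = FALSE]
      if (!nrow(cm)) next
      cm$si <- si; cm$xj <- xj
      cand[[length(cand) + 1]] <- cm
    }
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      xi = numeric(0), theta = numeric(0),
                      coefficient = numeric(0))
  if (!length(cand)) return(place_adhesions(empty, ellipse_convention,
                                            frame_index, pixel_size))
  cm <- do.call(rbind, cand)
  cm <- cm[cm$value >= threshold_fraction * gmax, , drop = FALSE]
  # pass 2: strictness across grid-adjacent (a, xi) by direct evaluation;
  # candidates near the frame edge must also beat (twice over) the
  # response that the zero-intensity boundary step alone produces there
  flat <- matrix(mean(frame), nrow(frame), ncol(frame))
  keep <- logical(nrow(cm))
  for (r in seq_len(nrow(cm))) {
    a <- scales[cm$si[r]]; xi <- xis[cm$xj[r]]; th <- thetas[cm$ti[r]]
    edge_d <- min(cm$x[r] - 1, ncol(frame) - cm$x[r],
                  cm$y[r] - 1, nrow(frame) - cm$y[r])
    if (edge_d < 3 * a) {
      ce <- cwt_point_cpp(flat, a, xi, th, cm$y[r], cm$x[r], 1, box, TRUE) /
        sqrt(xi)
      if (cm$value[r] <= 2 * abs(ce)) { keep[r] <- FALSE; next }
    }
    v0 <- cwt_point_cpp(frame, a, xi, th, cm$y[r], cm$x[r], 1, box, TRUE) /
      sqrt(xi)
    ok <- TRUE
    for (dsi in c(-1L, 1L)) {
      s2 <- cm$si[r] + dsi
      if (s2 >= 1 && s2 <= na &&
          cwt_point_cpp(frame, scales[s2], xi, th, cm$y[r], cm$x[r], 1, box,
                        TRUE) / sqrt(xi) >= v0) { ok <- FALSE; break }
    }
    if (ok) for (dxj in c(-1L, 1L)) {
      x2 <- cm$xj[r] + dxj
      if (x2 >= 1 && x2 <= nxi &&
          cwt_point_cpp(frame, a, xis[x2], th, cm$y[r], cm$x[r], 1, box,
                        TRUE) / sqrt(xis[x2]) >= v0) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  cm <- cm[keep, , drop = FALSE]
  if (!nrow(cm)) return(place_adhesions(empty, ellipse_convention,
                                        frame_index, pixel_size))
  maxima <- data.frame(x = cm$x, y = cm$y, a = scales[cm$si],
                       xi = xis[cm$xj], theta = thetas[cm$ti],
                       score = cm$value,
                       coefficient = cm$value * sqrt(xis[cm$xj]))
  maxima <- maxima[order(-maxima$score, maxima$y, maxima$x), , drop = FALSE]
  place_adhesions(maxima, ellipse_convention, frame_index, pixel_size,
                  order_by = "score")
}

#' Render the wavelet reconstruction of placed adhesions
#'
#' Sums one stretched wavelet per detection,
#' \eqn{I_R(r) = \sum_\ell \Delta a \Delta b\, a^{-4}\, T_\ell\,
#' \psi_{\xi,\theta_\ell}((r - b_\ell)/a)}, each term truncated at the
#' usual box.  Linear in the detection list.
#'
#' @param adhesions data.frame with `x`, `y`, `a`, `xi`, `theta`,
#'   `coefficient`.
#' @param dim output dimensions `c(ny, nx)`.
#' @param da,db scale/position grid spacings of the originating grid
#'   (defaults 1).
#' @param box truncation half-width in units of `a`.
#' @return numeric matrix.
#' @export
reconstruct_from_maxima <- function(adhesions, dim, da = 1, db = 1, box = 3) {
  out <- matrix(0, dim[1], dim[2])
  for (r in seq_len(nrow(adhesions))) {
    a <- adhesions$a[r]
    kern <- stretched_kernel_cpp(a, adhesions$xi[r], adhesions$theta[r],
                                 1, box, FALSE)
    h <- (nrow(kern) - 1) / 2
    cy <- round(adhesions$y[r]); cx <- round(adhesions$x[r])
    ys <- max(1, cy - h):min(dim[1], cy + h)
    xs <- max(1, cx - h):min(dim[2], cx + h)
    fac <- da * db * adhesions$coefficient[r] / a^4
    out[ys, xs] <- out[ys, xs] +
      fac * kern[ys - cy + h + 1, xs - cx + h + 1]
  }
  out
}

#' Histogram of detected length scales in physical units
#'
#' @param adhesions data.frame with column `a` (pixels).
#' @param pixel_size micrometres per pixel.
#' @param bin_width histogram bin width in micrometres (default one
#'   pixel's width).
#' @return data.frame with `mid` (bin centre, um) and `count`; counts sum
#'   to the number of detections.
#' @export
size_histogram <- function(adhesions, pixel_size = 0.105,
                           bin_width = pixel_size) {
  a_um <- adhesions$a * pixel_size
  if (!length(a_um)) return(data.frame(mid = numeric(0), count = integer(0)))
  bins <- floor(a_um / bin_width)
  tab <- table(bins)
  data.frame(mid = (as.integer(names(tab)) + 0.5) * bin_width,
             count = as.integer(tab))
}
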