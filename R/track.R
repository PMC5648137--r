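# axial angular difference in degrees (orientations mod 180)
axial_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  pmin(d, 180 - d)
}

#' Link detected adhesions between two consecutive frames
#'
#' Adhesions of frame `t` are swept in descending coefficient order; each
#' claims the highest-coefficient unclaimed detection of frame `t + 1`
#' that lies inside the elliptical search region (the frame-`t`
#' adhesion's own footprint, same convention as detection) centred on it,
#' with axial orientation difference of at most `max_dtheta` degrees.
#' Each candidate is claimed at most once, so higher-coefficient
#' adhesions win contested candidates.
#'
#' @param det_t,det_t1 data.frames of detections (columns `x`, `y`, `a`,
#'   `xi`, `theta`, `coefficient`, `id`).
#' @param max_dtheta maximum axial orientation difference, degrees
#'   (default 10).
#' @param ellipse_convention footprint convention, see [adhesion_axes()].
#' @return data.frame with `id_t`, `id_t1` for each link.
#' @export
link_frames <- function(det_t, det_t1, max_dtheta = 10,
                        ellipse_convention = "scaled") {
  links <- list()
  if (!nrow(det_t) || !nrow(det_t1)) {
    return(data.frame(id_t = integer(0), id_t1 = integer(0)))
  }
  claimed <- logical(nrow(det_t1))
  ord <- order(-det_t$coefficient, det_t$y, det_t$x)
  for (r in ord) {
    ax <- adhesion_axes(det_t$a[r], det_t$xi[r], det_t$theta[r],
                        ellipse_convention)
    th <- det_t$theta[r] * pi / 180
    # coordinates of candidates in the search ellipse's axis frame
    dx <- det_t1$x - det_t$x[r]; dy <- det_t1$y - det_t$y[r]
    rp <- dx * cos(th) - dy * sin(th)
    rq <- dx * sin(th) + dy * cos(th)
    inside <- (rp / ax$semi_par)^2 + (rq / ax$semi_perp)^2 <= 1
    ok <- inside & !claimed &
      axial_diff(det_t1$theta, det_t$theta[r]) <= max_dtheta
    if (!any(ok)) next
    cand <- which(ok)
    # highest coefficient; ties -> nearest centre, then index order
    d2 <- dx[cand]^2 + dy[cand]^2
    o <- order(-det_t1$coefficient[cand], d2, cand)
    j <- cand[o[1]]
    claimed[j] <- TRUE
    links[[length(links) + 1]] <- data.frame(id_t = det_t$id[r],
                                             id_t1 = det_t1$id[j])
  }
  if (!length(links)) return(data.frame(id_t = integer(0),
                                        id_t1 = integer(0)))
  do.call(rbind, links)
}

#' Build adhesion tracks across a detection series
#'
#' Applies the consecutive-frame linking rule ([link_frames()]) across
#' the series and takes its transitive closure: a track ends as soon as
#' its adhesion is unmatched in the next frame (no gap closing).  Each
#' track records lifetime and a least-squares translational velocity.
#'
#' @param detections list of per-frame detection data.frames (each with
#'   an `id` column unique within its frame).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param max_dtheta,ellipse_convention passed to [link_frames()].
#' @return list with `tracks` (data.frame: `track_id`, `frame`, `id`,
#'   `x`, `y`, `a`, `xi`, `theta`, `coefficient`), `summary` (per track:
#'   `first_frame`, `last_frame`, `lifetime_frames`, `speed_um_min`) and
#'   `counts` (detections per frame).
#' @export
build_tracks <- function(detections, pixel_size = 0.105, frame_interval = 5,
                         max_dtheta = 10, ellipse_convention = "scaled") {
  n <- length(detections)
  track_of <- vector("list", n)  # per frame: id -> track_id
  rows <- list()
  next_track <- 0L
  for (t in seq_len(n)) {
    det <- detections[[t]]
    track_of[[t]] <- integer(0)
    if (!nrow(det)) next
    assigned <- setNames(rep(NA_integer_, nrow(det)), det$id)
    if (t > 1 && nrow(detections[[t - 1]])) {
      links <- link_frames(detections[[t - 1]], det, max_dtheta,
                           ellipse_convention)
      if (nrow(links)) {
        prev <- track_of[[t - 1]]
        for (k in seq_len(nrow(links))) {
          assigned[as.character(links$id_t1[k])] <-
            prev[[as.character(links$id_t[k])]]
        }
      }
    }
    for (i in seq_len(nrow(det))) {
      if (is.na(assigned[i])) {
        next_track <- next_track + 1L
        assigned[i] <- next_track
      }
    }
    track_of[[t]] <- setNames(as.integer(assigned), det$id)
    rows[[t]] <- cbind(data.frame(track_id = as.integer(assigned),
                                  frame = t), det)
  }
  tracks <- do.call(rbind, rows)
  counts <- data.frame(frame = seq_len(n),
                       count = vapply(detections, nrow, integer(1)))
  summ <- NULL
  if (!is.null(tracks) && nrow(tracks)) {
    sp <- split(tracks, tracks$track_id)
    summ <- do.call(rbind, lapply(sp, function(g) {
      lifetime <- nrow(g)
      speed <- 0
      if (lifetime >= 2) {
        tt <- (g$frame - g$frame[1]) * frame_interval / 60
        vx <- unname(coef(stats::lm(g$x ~ tt))[2])
        vy <- unname(coef(stats::lm(g$y ~ tt))[2])
        speed <- sqrt(vx^2 + vy^2) * pixel_size
      }
      data.frame(track_id = g$track_id[1], first_frame = g$frame[1],
                 last_frame = g$frame[nrow(g)], lifetime_frames = lifetime,
                 speed_um_min = speed)
    }))
    rownames(summ) <- NULL
  }
  list(tracks = tracks, summary = summ, counts = counts)
}
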