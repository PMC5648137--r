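#' Read a calibrated image series from TIFF stacks
#'
#' Accepts a single multi-frame TIFF stack, or one stack per channel for
#' multi-channel data (all stacks must agree in dimensions and frame
#' count).  Calibration given here overrides any file metadata, with a
#' message.
#'
#' @param paths character vector of TIFF paths (one per channel).
#' @param channels channel names (defaults to file basenames for
#'   multi-channel input).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return An [image_series()].
#' @export
read_series <- function(paths, channels = NULL, pixel_size = 0.105,
                        frame_interval = 5) {
  stacks <- lapply(paths, function(p) {
    fr <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(fr)) fr <- list(fr)
    lapply(fr, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]  # first plane of RGB-ish data
      m
    })
  })
  dims <- lapply(stacks, function(s) dim(s[[1]]))
  if (length(unique(vapply(stacks, length, integer(1)))) != 1 ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("channel stacks disagree in shape: ",
         paste(vapply(seq_along(paths), function(i)
           sprintf("%s: %dx%dx%d", basename(paths[i]), dims[[i]][1],
                   dims[[i]][2], length(stacks[[i]])), character(1)),
           collapse = "; "))
  n <- length(stacks[[1]])
  if (length(paths) == 1) {
    frames <- stacks[[1]]
    channels <- NULL
  } else {
    if (is.null(channels)) channels <- basename(paths)
    frames <- lapply(seq_len(n), function(t)
      setNames(lapply(stacks, `[[`, t), channels))
  }
  message(sprintf(
    "calibration from configuration: %g um/px, %g s/frame (file metadata ignored)",
    pixel_size, frame_interval))
  image_series(frames, pixel_size = pixel_size,
               frame_interval = frame_interval, channels = channels)
}

#' Write an image series (or single frames) to a TIFF stack
#'
#' Intensities are scaled to the stack maximum and written as 32-bit
#' float TIFF.
#'
#' @param series an [image_series()], or a list of matrices.
#' @param path output file.
#' @param channel channel to write for multi-channel series.
#' @export
write_series <- function(series, path, channel = NULL) {
  frames <- if (inherits(series, "image_series")) {
    lapply(seq_len(length(series)), get_frame, series = series,
           channel = channel)
  } else series
  mx <- max(vapply(frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(frames, function(m) m / mx), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Default run configuration
#'
#' All thresholds of the analysis pipeline with their default values:
#' detection keeps coefficient maxima at least 10 percent of the highest
#' one; the boundary band spans scales 20-200 px in steps of 4; linked
#' adhesions must agree in orientation within 10 degrees; profile windows
#' extend 20 frames either side of the reference frame; sub-populations
#' slower than 0.05 um/min count as stationary; collisions require
#' approach below 2 px; consensus peaks must agree within 2 px.
#'
#' @param ... overrides for any configuration entry.
#' @return A named list with class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size = 0.105,
    frame_interval = 5,
    threshold_fraction = 0.10,
    detect_scales = 4:20,
    detect_xis = c(0.5, 1, 1.5),
    detect_n_theta = 180,
    boundary_band = c(20, 200),
    boundary_delta_a = 4,
    boundary_threshold = "otsu",
    link_max_dtheta = 10,
    profile_window = 20,
    v_stationary = 0.05,
    collision_distance = 2,
    consensus_tolerance = 2,
    refine_below = 8,
    coarsen_above = 16,
    ellipse_convention = "scaled",
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  num <- c("pixel_size", "frame_interval", "threshold_fraction",
           "link_max_dtheta", "profile_window", "v_stationary",
           "collision_distance", "consensus_tolerance")
  for (nm in num) if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0))
    stop("configuration entry `", nm, "` must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  s <- paste(vapply(cfg[order(names(cfg))], function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    collapse = ";")
  # small deterministic polynomial hash, hex encoded
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on an image series
#'
#' Detection, boundary extraction, region decomposition,
#' frame linking, and intra-adhesion dynamics on every frame of a
#' calibrated series; the pole analysis runs when two channels are
#' present (otherwise it is skipped with a notice).  All outputs are
#' plain CSV/JSON in `out_dir` and are byte-reproducible for a fixed
#' configuration and seed.
#'
#' @param series an [image_series()], or a [scene_config()] to simulate.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param frames frame indices to analyse (default all).
#' @return list with `detections`, `tracks`, `boundaries`, `metrics`,
#'   `regions`, `dynamics`, `poles` (or NULL), `config`.
#' @export
run_pipeline <- function(series, config = run_config(), out_dir = NULL,
                         frames = NULL) {
  if (inherits(series, "scene_config")) series <- simulate_movie(series)$series
  stopifnot(inherits(series, "image_series"))
  ps <- config$pixel_size; fi <- config$frame_interval
  if (is.null(frames)) frames <- seq_len(length(series))
  stage <- "detect"
  res <- tryCatch({
    detections <- lapply(frames, function(t)
      detect_adhesions(get_frame(series, t), scales = config$detect_scales,
                       xis = config$detect_xis,
                       n_theta = config$detect_n_theta,
                       threshold_fraction = config$threshold_fraction,
                       ellipse_convention = config$ellipse_convention,
                       pixel_size = ps, frame_index = t))
    stage <- "boundary"
    boundaries <- lapply(frames, function(t)
      extract_boundary(get_frame(series, t), band = config$boundary_band,
                       delta_a = config$boundary_delta_a,
                       threshold = config$boundary_threshold))
    stage <- "regions"
    metrics <- if (length(frames) >= 2)
      front_metrics(boundaries, ps, fi) else NULL
    nlast <- length(frames)
    dec <- if (nlast >= 2)
      decompose_regions(boundaries[[1]]$mask, boundaries[[nlast]]$mask,
                        boundaries[[1]]$contour,
                        boundaries[[nlast]]$contour) else NULL
    regions <- NULL
    if (!is.null(dec) && nrow(detections[[nlast]])) {
      det <- detections[[nlast]]
      regions <- vapply(seq_len(nrow(det)), function(i)
        assign_region(det[i, ], dec, ps), character(1))
      regions <- data.frame(id = det$id, region = regions)
    }
    stage <- "track"
    tracks <- build_tracks(detections, ps, fi, config$link_max_dtheta,
                           config$ellipse_convention)
    stage <- "dynamics"
    dynamics <- NULL
    ref <- frames[ceiling(length(frames) / 2)]
    if (length(frames) >= 2 * 4 + 1 &&
        !is.null(boundaries[[ref]]$contour) && nrow(detections[[ref]])) {
      det <- detections[[ref]]
      contours <- lapply(boundaries, `[[`, "contour")
      dynamics <- lapply(seq_len(nrow(det)), function(i) {
        pr <- tryCatch(extract_profile(series, det[i, ], contours, ref,
                                       config$profile_window),
                       error = function(e) NULL)
        if (is.null(pr)) return(NULL)
        bt <- build_trajectories(pr)
        cl <- classify_dynamics(bt$trajectories, pr,
                                v_stationary = config$v_stationary,
                                collision_distance = config$collision_distance,
                                pixel_size = ps, frame_interval = fi)
        list(id = det$id[i], category = cl$category, pattern = cl$pattern,
             velocities = cl$velocities, trajectories = bt$trajectories)
      })
      dynamics <- Filter(Negate(is.null), dynamics)
    }
    stage <- "poles"
    poles <- NULL
    if (!is.null(series$channels) && length(series$channels) == 2) {
      bundle <- detect_bundle(series)
      if (!is.null(bundle))
        poles <- pole_analysis(series, bundle,
                               match_tolerance = config$consensus_tolerance)
    } else {
      message("single-channel input: pole analysis skipped")
    }
    list(detections = detections, tracks = tracks, boundaries = boundaries,
         metrics = metrics, regions = regions, dynamics = dynamics,
         poles = poles, config = config)
  }, error = function(e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e))
  })
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Locate an actomyosin bundle in the myosin channel
#'
#' The bundle axis is the straight line through the two myosin pole
#' populations: the two strongest compact detections in the temporal
#' mean of the myosin channel define the poles, and their connecting
#' line gives centre, orientation and half-length.
#'
#' @param series two-channel [image_series()].
#' @param channel channel holding the bundle (default `"myosin"`).
#' @param min_separation minimum pole separation in pixels (default 6).
#' @return one-row data.frame with `x`, `y`, `theta`, `half_length`, or
#'   NULL when no pole pair is found.
#' @export
detect_bundle <- function(series, channel = "myosin", min_separation = 6) {
  avg <- Reduce(`+`, lapply(seq_len(length(series)), get_frame,
                            series = series, channel = channel)) /
    length(series)
  det <- detect_adhesions(avg, scales = c(2, 3, 4), xis = 1, n_theta = 1)
  if (nrow(det) < 2) return(NULL)
  p1 <- det[1, ]
  sep <- sqrt((det$x - p1$x)^2 + (det$y - p1$y)^2)
  cand <- which(sep >= min_separation)
  if (!length(cand)) return(NULL)
  p2 <- det[cand[1], ]
  dx <- p2$x - p1$x; dy <- p2$y - p1$y
  data.frame(x = (p1$x + p2$x) / 2, y = (p1$y + p2$y) / 2,
             theta = (atan2(-dy, dx) * 180 / pi) %% 180,
             half_length = sqrt(dx^2 + dy^2) / 2)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(res$config)
  wcsv <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    df$config_hash <- hash
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(do.call(rbind, res$detections), "adhesions.csv")
  wcsv(res$tracks$tracks, "tracks.csv")
  wcsv(res$tracks$counts, "counts.csv")
  if (!is.null(res$metrics)) wcsv(res$metrics$per_frame, "front_metrics.csv")
  wcsv(res$regions, "regions.csv")
  contours <- lapply(seq_along(res$boundaries), function(t) {
    ct <- res$boundaries[[t]]$contour
    if (is.null(ct)) return(NULL)
    data.frame(frame = t, x = ct[, 1], y = ct[, 2])
  })
  wcsv(do.call(rbind, contours), "contours.csv")
  if (!is.null(res$dynamics) && length(res$dynamics)) {
    wcsv(data.frame(
      id = vapply(res$dynamics, `[[`, numeric(1), "id"),
      category = vapply(res$dynamics, `[[`, character(1), "category"),
      pattern = vapply(res$dynamics, `[[`, character(1), "pattern")),
      "dynamics.csv")
  }
  if (!is.null(res$poles)) {
    wcsv(res$poles$poles, "poles.csv")
    wcsv(res$poles$pairs, "pole_pairs.csv")
  }
  summary <- list(
    config = unclass(res$config), config_hash = hash,
    n_frames = length(res$detections),
    n_detections = vapply(res$detections, nrow, integer(1)),
    front_velocity_um_min =
      if (!is.null(res$metrics)) res$metrics$front_velocity$um_min else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
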