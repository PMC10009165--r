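#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames within a
#' displacement gate; no gap closing.  A detection whose mutual nearest
#' neighbor in the previous frame is farther than `max_disp` starts a new
#' track, and a track with no admissible continuation terminates.
#'
#' @param detections data.frame with columns frame, x_um, y_um (and
#'   optionally t_min).
#' @param max_disp maximum frame-to-frame displacement, um (> 0).
#' @param dt minutes per frame, used to fill t_min when absent (default 5,
#'   the migration-movie interval).
#' @return data.frame with columns track_id, frame, t_min, x_um, y_um.
#' @export
link_tracks <- function(detections, max_disp, dt = 5) {
  stopifnot(max_disp > 0, all(c("frame", "x_um", "y_um") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  if (!"t_min" %in% names(det)) det$t_min <- (det$frame - min(det$frame)) * dt
  frames <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  next_id <- 0L
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- which(det$frame == f)
    if (length(prev_idx) == 0) {
      det$track_id[cur_idx] <- next_id + seq_along(cur_idx)
      next_id <- next_id + length(cur_idx)
    } else {
      D <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(i, j)
                   sqrt((det$x_um[prev_idx[i]] - det$x_um[cur_idx[j]])^2 +
                        (det$y_um[prev_idx[i]] - det$y_um[cur_idx[j]])^2)))
      linked_cur <- rep(FALSE, length(cur_idx))
      for (i in seq_along(prev_idx)) {
        j <- which.min(D[i, ])
        if (length(j) == 1 && is.finite(D[i, j]) && D[i, j] <= max_disp &&
            which.min(D[, j]) == i) {
          det$track_id[cur_idx[j]] <- det$track_id[prev_idx[i]]
          linked_cur[j] <- TRUE
        }
      }
      for (j in which(!linked_cur)) {
        next_id <- next_id + 1L
        det$track_id[cur_idx[j]] <- next_id
      }
    }
    prev_idx <- cur_idx
  }
  det[, c("track_id", "frame", "t_min", "x_um", "y_um")]
}

#' Keep tracks longer than a minimum number of frames
#'
#' Tracks must persist for strictly more than `min_frames` frames (the
#' original analysis kept tracks of more than 5 frames, i.e. more than
#' 25 min at the 5-min interval).
#'
#' @param tracks data.frame with columns track_id, frame, t_min, x_um, y_um.
#' @param min_frames strict lower bound on frame count (default 5).
#' @return filtered data.frame.
#' @export
filter_tracks <- function(tracks, min_frames = 5L) {
  if (nrow(tracks) == 0) return(tracks)
  n <- table(tracks$track_id)
  keep <- names(n)[n > min_frames]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

one_track <- function(tracks, id) {
  tr <- tracks[tracks$track_id == id, , drop = FALSE]
  tr[order(tr$frame), , drop = FALSE]
}

#' Mean migration speed of a trajectory
#'
#' Mean over consecutive frames of the Euclidean step length divided by the
#' frame interval (per-step speed, not net displacement over total time).
#'
#' @param traj data.frame of one track, ordered by frame, with t_min, x_um,
#'   y_um.
#' @return speed in um/min.
#' @export
track_speed <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  dx <- diff(traj$x_um); dy <- diff(traj$y_um); dtm <- diff(traj$t_min)
  mean(sqrt(dx^2 + dy^2) / dtm)
}

#' Directionality ratio (persistence) of a trajectory
#'
#' Net displacement divided by total path length; 1 for a straight path, 0
#' for a closed loop.  Undefined (NA, with a warning) when the path length
#' is zero.
#'
#' @param traj data.frame of one track, ordered by frame.
#' @return value in [0, 1], or NA for a degenerate track.
#' @export
directionality_ratio <- function(traj) {
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  path <- sum(sqrt(dx^2 + dy^2))
  if (path == 0) {
    warning("directionality_ratio: zero path length")
    return(NA_real_)
  }
  net <- sqrt((traj$x_um[nrow(traj)] - traj$x_um[1])^2 +
              (traj$y_um[nrow(traj)] - traj$y_um[1])^2)
  net / path
}

#' Per-track migration metrics
#'
#' @param tracks data.frame with columns track_id, frame, t_min, x_um, y_um
#'   (already filtered with [filter_tracks()] if desired).
#' @return data.frame with one row per track: track_id, n_frames,
#'   speed_um_min, directionality_ratio, net_angle_rad.
#' @export
track_metrics <- function(tracks) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- one_track(tracks, id)
    data.frame(track_id = id, n_frames = nrow(tr),
               speed_um_min = if (nrow(tr) >= 2) track_speed(tr) else NA_real_,
               directionality_ratio = if (nrow(tr) >= 2)
                 suppressWarnings(directionality_ratio(tr)) else NA_real_,
               net_angle_rad = atan2(tr$y_um[nrow(tr)] - tr$y_um[1],
                                     tr$x_um[nrow(tr)] - tr$x_um[1]))
  })
  do.call(rbind, out)
}

#' Rose histogram of net-displacement directions
#'
#' Counts of per-track net-displacement angles in `n_bins` angular bins with
#' edges at -pi + k * 2pi / n_bins.
#'
#' @param tracks data.frame of tracks (or a [track_metrics()] result).
#' @param n_bins number of angular bins (>= 4).
#' @return object of class `rose_histogram`: list(counts, breaks, angles).
#' @export
rose_histogram <- function(tracks, n_bins = 12L) {
  stopifnot(n_bins >= 4)
  m <- if ("net_angle_rad" %in% names(tracks)) tracks else track_metrics(tracks)
  stopifnot(nrow(m) > 0)
  br <- -pi + (0:n_bins) * 2 * pi / n_bins
  a <- wrap_angle(m$net_angle_rad)
  a[a == pi] <- -pi  # wrap the closed upper edge into the first bin
  counts <- tabulate(findInterval(a, br, rightmost.closed = TRUE),
                     nbins = n_bins)
  structure(list(counts = counts, breaks = br, angles = a),
            class = "rose_histogram")
}

#' @export
plot.rose_histogram <- function(x, ...) {
  graphics::plot.new()
  r <- max(x$counts)
  graphics::plot.window(c(-r, r), c(-r, r), asp = 1)
  for (i in seq_along(x$counts)) {
    th <- seq(x$breaks[i], x$breaks[i + 1], length.out = 16)
    graphics::polygon(c(0, x$counts[i] * cos(th)),
                      c(0, x$counts[i] * sin(th)),
                      col = grDevices::gray(0.7), ...)
  }
  invisible(x)
}

#' Relative fiber length and shortening rate
#'
#' r(t) = L(t) / L(0) for a fiber that spans the full observation window
#' (fibers that do not last the whole movie are ineligible, matching the
#' original eligibility rule).  The mean shortening rate is the least-squares
#' slope of r(t) against time.
#'
#' @param trace data.frame with columns frame, t_s, length_um (one fiber).
#' @return data.frame with columns frame, t_s, rel_length, plus attributes
#'   `slope_per_s` (d r / d t) and `l0`.
#' @export
relative_fiber_length <- function(trace) {
  tr <- trace[order(trace$frame), , drop = FALSE]
  if (any(is.na(tr$length_um))) stop("relative_fiber_length: fiber must span the full window")
  l0 <- tr$length_um[1]
  if (l0 <= 0) stop("relative_fiber_length: L(0) must be > 0")
  r <- tr$length_um / l0
  slope <- stats::coef(stats::lm(r ~ tr$t_s))[[2]]
  out <- data.frame(frame = tr$frame, t_s = tr$t_s, rel_length = r)
  attr(out, "slope_per_s") <- slope
  attr(out, "l0") <- l0
  out
}

#' Pearson colocalization over a mask
#'
#' Pearson correlation of the two images over all masked pixels, with no
#' intensity threshold, as in whole-cell ROI colocalization analysis.
#'
#' @param img_a,img_b aligned numeric matrices.
#' @param mask logical matrix or [segment_cell()] result; NULL uses every
#'   pixel.
#' @return correlation in [-1, 1].
#' @export
pearson_coloc <- function(img_a, img_b, mask = NULL) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  m <- if (is.null(mask)) rep(TRUE, length(img_a))
       else if (inherits(mask, "cell_mask")) mask$mask else mask
  if (!any(m)) stop("pearson_coloc: empty mask")
  stats::cor(as.numeric(img_a[m]), as.numeric(img_b[m]))
}

#' Focal-adhesion morphometrics
#'
#' Per labeled object: area in um^2 (pixel count times pixel_size^2) and
#' circularity 4 * pi * A / P^2 (the ImageJ-style index; 1 = circle).  The
#' perimeter uses a Fourier low-pass smoothed contour (16 modes) to correct
#' the digitization bias of the traced pixel polygon, so a digital disk
#' scores ~1; single-pixel and 2-px objects are assigned circularity 1.
#' When a `fiber_mask` is supplied, only adhesions whose 1-px-dilated mask
#' intersects it are retained (the "associated with actin fibers" filter).
#'
#' @param labels integer label matrix of adhesion objects.
#' @param pixel_size um per px (> 0).
#' @param fiber_mask optional logical matrix of actin fibers.
#' @return data.frame with columns id, area_um2, circularity, centroid_row,
#'   centroid_col.
#' @export
adhesion_morphometrics <- function(labels, pixel_size, fiber_mask = NULL) {
  stopifnot(pixel_size > 0)
  n <- max(labels)
  out <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    lin <- which(labels == i)
    if (length(lin) == 0) next
    rows <- ((lin - 1L) %% nrow(labels)) + 1L
    cols <- ((lin - 1L) %/% nrow(labels)) + 1L
    if (!is.null(fiber_mask)) {
      sub <- crop_mask(rows, cols, pad = 2L)
      dil <- cpp_dilate(sub$mask, disk_kernel(1))
      w <- which(dil)
      rr <- pmin(pmax(((w - 1L) %% nrow(dil)) + sub$r0, 1L), nrow(labels))
      cc <- pmin(pmax(((w - 1L) %/% nrow(dil)) + sub$c0, 1L), ncol(labels))
      if (!any(fiber_mask[cbind(rr, cc)])) next
    }
    b <- trace_boundary(cbind(rows, cols))
    area_px <- length(rows)
    circ <- if (nrow(b) < 3) 1 else {
      per <- smooth_perimeter(b)
      min(4 * pi * area_px / per^2, 1 + 0.05)
    }
    kept <- kept + 1L
    out[[kept]] <- data.frame(id = i,
                              area_um2 = area_px * pixel_size^2,
                              circularity = circ,
                              centroid_row = mean(rows),
                              centroid_col = mean(cols))
  }
  if (kept == 0) return(data.frame(id = integer(0), area_um2 = numeric(0),
                                   circularity = numeric(0),
                                   centroid_row = numeric(0),
                                   centroid_col = numeric(0)))
  do.call(rbind, out[seq_len(kept)])
}

# Perimeter of the Fourier low-pass reconstruction of a boundary (16 modes),
# which removes the staircase bias of the raw pixel polygon.
smooth_perimeter <- function(boundary, n_modes = 16L, n_points = 256L) {
  rs <- resample_boundary(boundary, n_points)
  if (is.null(rs)) return(polygon_perimeter(boundary))
  z <- complex(real = rs[, 2], imaginary = rs[, 1])
  cf <- stats::fft(z) / n_points
  K <- n_modes %/% 2L
  keep <- c(1L, 2:(K + 1L), (n_points - K + 1L):n_points)
  cf[setdiff(seq_len(n_points), keep)] <- 0
  zs <- stats::fft(cf, inverse = TRUE)
  polygon_perimeter(cbind(Im(zs), Re(zs)))
}
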