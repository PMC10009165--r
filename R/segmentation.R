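#' Construct an image frame
#'
#' Bundles a 16-bit grayscale intensity matrix with its pixel calibration and
#' channel metadata.  Coordinates are (row, col) with the origin at the
#' top-left; CSV exports are 0-based, in-memory indices follow R's 1-based
#' convention.
#'
#' @param pixels numeric matrix of non-negative intensities in [0, 65535].
#' @param pixel_size pixel calibration in micrometers per pixel (> 0).
#' @param channel one of "septin", "cdc42ep1", "actin", "adhesion", "nuclear".
#' @param frame_index integer frame number within a movie.
#' @param t acquisition time in seconds (optional).
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size = 0.1,
                        channel = c("septin", "cdc42ep1", "actin",
                                    "adhesion", "nuclear"),
                        frame_index = 1L, t = NA_real_) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("image_frame: intensities must lie in [0, 65535]")
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel,
                 frame_index = as.integer(frame_index), t = t),
            class = "image_frame")
}

as_image_frame <- function(x, ...) {
  if (inherits(x, "image_frame")) x else image_frame(x, ...)
}

#' Pipeline configuration
#'
#' Houses every tunable of the classification pipeline.  Defaults are the
#' published values of the original analysis: structure threshold 2000
#' (septin; use 1500 for Cdc42ep1 data), Gaussian background sigma 5 px,
#' opening disk radius 7 px, minimum cell area 5000 px, structure area range
#' [10, 400] px, boundary approximation error cap 0.1 px, 30 + 30 Fourier
#' modes, 90% PCA variance target, DBSCAN eps = 2 with minPts = 3, refinement
#' over the 5 largest-area classes, and 3 merged classes.  Cell thresholds
#' were chosen manually per image in the original work and therefore have no
#' universal default; 12000 (the lower end of the published septin range) is
#' used unless overridden.
#'
#' @param cell_threshold intensity threshold for the cell mask (raw image).
#' @param structure_threshold intensity threshold for structures
#'   (background-subtracted image).
#' @param bg_sigma Gaussian background sigma, px.
#' @param open_radius opening disk radius for cell masks, px.
#' @param min_cell_area minimum cell-component area, px.
#' @param structure_area_range inclusive [min, max] object area, px.
#' @param boundary_err_max max mean boundary reconstruction error, px.
#' @param n_shape_modes number of Fourier shape amplitudes retained.
#' @param n_dist_modes number of Fourier distance-profile amplitudes retained.
#' @param pca_var_target cumulative explained-variance target in (0, 1].
#' @param dbscan_eps DBSCAN neighborhood radius in PCA space.
#' @param dbscan_min_pts DBSCAN core-point threshold (self included).
#' @param refine logical; run the optional bimodality refinement stage
#'   (used for Cdc42ep1 data in the original analysis, off for septin).
#' @param refine_top_k number of largest-mean-area classes considered for
#'   refinement.
#' @param merged_k number of merged classes.
#' @param seed integer seed governing every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_threshold = 12000,
                            structure_threshold = 2000,
                            bg_sigma = 5,
                            open_radius = 7,
                            min_cell_area = 5000,
                            structure_area_range = c(10, 400),
                            boundary_err_max = 0.1,
                            n_shape_modes = 30L,
                            n_dist_modes = 30L,
                            pca_var_target = 0.90,
                            dbscan_eps = 2,
                            dbscan_min_pts = 3L,
                            refine = FALSE,
                            refine_top_k = 5L,
                            merged_k = 3L,
                            seed = 1L) {
  if (cell_threshold <= 0 || structure_threshold <= 0)
    stop("pipeline_config: thresholds must be positive")
  if (length(structure_area_range) != 2 ||
      structure_area_range[1] > structure_area_range[2])
    stop("pipeline_config: structure_area_range must be an ordered pair")
  if (pca_var_target <= 0 || pca_var_target > 1)
    stop("pipeline_config: pca_var_target must lie in (0, 1]")
  if (bg_sigma <= 0 || dbscan_eps <= 0 || dbscan_min_pts < 1)
    stop("pipeline_config: bg_sigma, dbscan_eps, dbscan_min_pts out of range")
  structure(list(cell_threshold = cell_threshold,
                 structure_threshold = structure_threshold,
                 bg_sigma = bg_sigma, open_radius = open_radius,
                 min_cell_area = min_cell_area,
                 structure_area_range = structure_area_range,
                 boundary_err_max = boundary_err_max,
                 n_shape_modes = as.integer(n_shape_modes),
                 n_dist_modes = as.integer(n_dist_modes),
                 pca_var_target = pca_var_target,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_pts = as.integer(dbscan_min_pts),
                 refine = isTRUE(refine),
                 refine_top_k = as.integer(refine_top_k),
                 merged_k = as.integer(merged_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment the cell footprint
#'
#' Threshold at `cell_threshold` (inclusive, applied to the raw image), fill
#' interior holes, apply morphological opening with a radius-`open_radius`
#' disk, and remove connected components smaller than `min_cell_area` pixels.
#' An image with no surviving component yields an empty mask with a warning,
#' not an error.  An Otsu-based threshold suggestion is attached as an
#' attribute for logging but never applied automatically (thresholds were
#' chosen manually per image in the original analysis).
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param cell_threshold intensity threshold; defaults to the config value.
#' @param config a [pipeline_config()].
#' @return an object of class `cell_mask`: list(mask, threshold_used).
#' @export
segment_cell <- function(frame, cell_threshold = config$cell_threshold,
                         config = pipeline_config()) {
  frame <- as_image_frame(frame)
  img <- frame$pixels
  m <- img >= cell_threshold
  m <- fill_holes(m)
  m <- binary_opening(m, disk_kernel(config$open_radius))
  lab <- label_components(m, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(areas >= config$min_cell_area)
    m <- matrix(lab %in% keep, nrow(img), ncol(img))
  }
  if (!any(m)) warning("segment_cell: empty cell mask after filtering")
  structure(list(mask = m, threshold_used = cell_threshold),
            class = "cell_mask",
            otsu_suggestion = otsu_threshold(as.numeric(img)))
}

#' Local background subtraction
#'
#' Subtracts a Gaussian-smoothed copy of the image (sigma `bg_sigma`,
#' reflective boundary handling) from the image and clamps negatives to zero.
#' This evens the background so one structure threshold captures both bright
#' and dim structures.
#'
#' @param frame an [image_frame()] or numeric matrix.
#' @param bg_sigma smoothing sigma in px (default 5).
#' @return an `image_frame` with background-subtracted pixels; calibration
#'   metadata is preserved.
#' @export
subtract_background <- function(frame, bg_sigma = 5) {
  frame <- as_image_frame(frame)
  out <- frame$pixels - gaussian_blur(frame$pixels, bg_sigma)
  out[out < 0] <- 0
  frame$pixels <- out
  frame
}

#' Segment intracellular structures
#'
#' 8-connected components of (image >= threshold), restricted to the cell
#' mask.  A component with more than half of its pixels outside the mask is
#' excluded entirely; components straddling the mask edge are clipped to the
#' mask (if clipping disconnects a component, its largest piece is kept).
#' Components with area outside the inclusive `area_range` are excluded.
#' The outer boundary of each survivor is traced.
#'
#' @param bg_subtracted background-subtracted [image_frame()] (or matrix).
#' @param mask a [segment_cell()] result or logical matrix.
#' @param structure_threshold intensity threshold (inclusive).
#' @param area_range inclusive [min, max] area in px, default c(10, 400).
#' @return list of `structure_object`s, each with fields object_id, pixels
#'   (n x 2 row/col), boundary (outer boundary, cyclic, counter-clockwise),
#'   area, centroid, bbox.
#' @export
segment_structures <- function(bg_subtracted, mask,
                               structure_threshold = 2000,
                               area_range = c(10, 400)) {
  frame <- as_image_frame(bg_subtracted)
  img <- frame$pixels
  cm <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(all(dim(cm) == dim(img)))
  lab <- label_components(img >= structure_threshold, 8L)
  n <- max(lab)
  objs <- list()
  if (n == 0) return(objs)
  idx <- which(lab > 0L)
  ord <- order(lab[idx])
  idx <- idx[ord]
  runs <- split(idx, factor(lab[idx], levels = seq_len(n)))
  oid <- 0L
  nr <- nrow(img)
  for (k in seq_along(runs)) {
    lin <- runs[[k]]
    inside <- cm[lin]
    if (mean(inside) < 0.5) next  # > 50% of pixels outside the cell: excluded
    lin <- lin[inside]                     # clip to the mask
    rows <- ((lin - 1L) %% nr) + 1L
    cols <- ((lin - 1L) %/% nr) + 1L
    # keep the largest 8-connected piece if clipping disconnected the object
    if (length(lin) > 1L) {
      sub <- crop_mask(rows, cols)
      piece <- cpp_label(sub$mask, 8L)
      if (max(piece) > 1L) {
        sizes <- tabulate(piece[piece > 0L], nbins = max(piece))
        big <- which.max(sizes)
        keep <- piece[cbind(rows - sub$r0 + 1L, cols - sub$c0 + 1L)] == big
        rows <- rows[keep]; cols <- cols[keep]
      }
    }
    a <- length(rows)
    if (a < area_range[1] || a > area_range[2]) next
    oid <- oid + 1L
    objs[[oid]] <- new_structure_object(oid, rows, cols)
  }
  objs
}

# Crop a pixel set to a tight padded logical matrix; returns offsets.
crop_mask <- function(rows, cols, pad = 1L) {
  r0 <- min(rows) - pad; c0 <- min(cols) - pad
  m <- matrix(FALSE, max(rows) - r0 + 1L + pad, max(cols) - c0 + 1L + pad)
  m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  list(mask = m, r0 = r0, c0 = c0)
}

new_structure_object <- function(id, rows, cols) {
  b <- trace_boundary(cbind(rows, cols))
  structure(list(object_id = as.integer(id),
                 pixels = cbind(row = rows, col = cols),
                 boundary = b,
                 area = length(rows),
                 centroid = c(row = mean(rows), col = mean(cols)),
                 bbox = c(rmin = min(rows), rmax = max(rows),
                          cmin = min(cols), cmax = max(cols))),
            class = "structure_object")
}

#' Trace the outer boundary of an object
#'
#' Moore-neighbor tracing of the outer boundary of an 8-connected pixel set;
#' interior holes produce no boundary.  The returned sequence is cyclic
#' (the first point is not repeated) and ordered counter-clockwise in
#' standard x = col, y = -row orientation.  A single-pixel object yields a
#' degenerate 1-point boundary.
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates of one object.
#' @return m x 2 matrix of (row, col) boundary coordinates.
#' @export
trace_boundary <- function(pixels) {
  pixels <- as.matrix(pixels)
  stopifnot(nrow(pixels) >= 1, ncol(pixels) == 2)
  sub <- crop_mask(pixels[, 1], pixels[, 2])
  b <- cpp_trace_boundary(sub$mask)
  b[, 1] <- b[, 1] + sub$r0 - 1L
  b[, 2] <- b[, 2] + sub$c0 - 1L
  if (nrow(b) >= 3) {
    # signed area in (x = col, y = -row); enforce counter-clockwise (> 0)
    x <- b[, 2]; y <- -b[, 1]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    if (sum(x * y2 - x2 * y) / 2 < 0) b <- b[nrow(b):1, , drop = FALSE]
  }
  colnames(b) <- c("row", "col")
  b
}

# Perimeter of the cyclic boundary polygon (no digitization correction).
polygon_perimeter <- function(boundary) {
  if (nrow(boundary) < 2) return(0)
  d <- boundary - boundary[c(2:nrow(boundary), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}
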