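#' Region properties of a structure object
#'
#' The ten planar region properties used by the classification pipeline:
#' Area, ConvexArea, Eccentricity, EquivDiameter, Extent, FilledArea,
#' MajorAxisLength, MinorAxisLength, Perimeter and Solidity.  Ellipse axes
#' and eccentricity come from the second central moments of the pixel set
#' with the standard +1/12 per-pixel variance correction, so a single pixel
#' has Major = Minor = 4 * sqrt(1/12) > 0 and eccentricity 0.  Perimeter is
#' the length of the traced boundary polygon, with its digitization bias
#' accepted and documented.
#'
#' @param object a `structure_object` from [segment_structures()].
#' @return named numeric vector of length 10.
#' @export
region_features <- function(object) {
  px <- object$pixels
  n <- nrow(px)
  rows <- px[, 1]; cols <- px[, 2]
  area <- n

  # convex area: pixels of the bounding box whose center lies in the convex
  # hull of the object's pixel centers (union with the object itself)
  convex_area <- area
  if (n >= 3) {
    h <- grDevices::chull(cols, rows)
    if (length(h) >= 3) {
      hx <- cols[h]; hy <- rows[h]
      gx <- rep(min(cols):max(cols), each = max(rows) - min(rows) + 1L)
      gy <- rep(min(rows):max(rows), times = max(cols) - min(cols) + 1L)
      m <- length(h)
      inside <- rep(TRUE, length(gx))
      pos <- FALSE; neg <- FALSE
      cr <- matrix(0, length(gx), m)
      for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        cr[, i] <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
      }
      eps <- 1e-9
      inside <- apply(cr, 1, function(v) all(v >= -eps) || all(v <= eps))
      convex_area <- max(sum(inside), area)
    }
  }

  # ellipse-equivalent axes via second central moments (+1/12 correction)
  mr <- mean(rows); mc <- mean(cols)
  uyy <- mean((rows - mr)^2) + 1 / 12
  uxx <- mean((cols - mc)^2) + 1 / 12
  uxy <- mean((rows - mr) * (cols - mc))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0))
  ecc <- if (major > 0) sqrt(pmax(1 - (minor / major)^2, 0)) else 0

  filled <- {
    sub <- crop_mask(rows, cols)
    sum(fill_holes(sub$mask))
  }

  c(Area = area,
    ConvexArea = convex_area,
    Eccentricity = ecc,
    EquivDiameter = sqrt(4 * area / pi),
    Extent = area / ((max(rows) - min(rows) + 1) * (max(cols) - min(cols) + 1)),
    FilledArea = filled,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Perimeter = polygon_perimeter(object$boundary),
    Solidity = area / convex_area)
}

#' Neighbor-distance and intensity statistics
#'
#' For every boundary point of `object`, the Euclidean distance to the
#' nearest pixel of any *other* object in the frame (via the exact distance
#' transform of the union of the other objects), summarized as mean and
#' standard deviation; plus mean and standard deviation of the intensity of
#' the object's own pixels.  A frame holding a single object has no neighbor:
#' the distance features are set to the documented sentinel (the image
#' diagonal in px) with `lone = TRUE`.
#'
#' @param object a `structure_object`.
#' @param all_objects list of all `structure_object`s in the frame
#'   (including `object`).
#' @param image the intensity matrix the objects were segmented from
#'   (background-subtracted by default in the pipeline).
#' @return list with `values` (named numeric: NDistMean, NDistSD, IntMean,
#'   IntSD), `lone` flag, and `dist_map` (the distance transform, reusable for
#'   the distance-profile Fourier features; NULL for lone objects).
#' @export
neighbor_distance_features <- function(object, all_objects, image) {
  stopifnot(is.matrix(image))
  ints <- image[object$pixels]
  int_mean <- mean(ints)
  int_sd <- if (length(ints) > 1) stats::sd(ints) else 0
  others <- Filter(function(o) o$object_id != object$object_id, all_objects)
  if (length(others) == 0) {
    sentinel <- sqrt(nrow(image)^2 + ncol(image)^2)
    return(list(values = c(NDistMean = sentinel, NDistSD = 0,
                           IntMean = int_mean, IntSD = int_sd),
                lone = TRUE, dist_map = NULL, sentinel = sentinel))
  }
  other_mask <- matrix(FALSE, nrow(image), ncol(image))
  for (o in others) other_mask[o$pixels] <- TRUE
  dmap <- distance_transform(other_mask)
  dvals <- dmap[object$boundary]
  list(values = c(NDistMean = mean(dvals),
                  NDistSD = if (length(dvals) > 1) stats::sd(dvals) else 0,
                  IntMean = int_mean, IntSD = int_sd),
       lone = FALSE, dist_map = dmap, sentinel = NA_real_)
}

# Resample a cyclic boundary polygon to n_points arc-length-uniform points.
# The traversal is anchored at the vertex farthest from the boundary
# centroid (a rotation-equivariant choice), so congruent boundaries yield
# congruent samplings and the Fourier amplitudes are exactly rotation
# invariant.  Returns an n_points x 2 (row, col) matrix, or NULL for
# degenerate input.
resample_boundary <- function(boundary, n_points = 128L) {
  m <- nrow(boundary)
  if (m < 2) return(NULL)
  ctr <- colMeans(boundary)
  d2 <- round((boundary[, 1] - ctr[1])^2 + (boundary[, 2] - ctr[2])^2, 9)
  cand <- which(d2 == max(d2))
  i0 <- cand[1]
  if (length(cand) > 1) {
    # exact ties (common on integer grids): break by the lexicographically
    # largest centroid-distance sequence read from each candidate, which is
    # itself rotation invariant; remaining ties are true symmetries
    best <- NULL
    for (i in cand) {
      seq_i <- d2[c(i:m, seq_len(i - 1))]
      if (is.null(best) ||
          { cmpr <- seq_i - best
            nz <- which(cmpr != 0)
            length(nz) > 0 && cmpr[nz[1]] > 0 }) {
        best <- seq_i
        i0 <- i
      }
    }
  }
  if (i0 > 1) boundary <- boundary[c(i0:m, 1:(i0 - 1)), , drop = FALSE]
  closed <- rbind(boundary, boundary[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(m + 1), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[m + 1]
  if (L == 0) return(NULL)
  target <- seq(0, L, length.out = n_points + 1L)[-(n_points + 1L)]
  cbind(row = stats::approx(s, closed[, 1], xout = target)$y,
        col = stats::approx(s, closed[, 2], xout = target)$y)
}

#' Rotation-invariant Fourier shape descriptors
#'
#' The boundary is resampled to `n_points` arc-length-uniform points, treated
#' as the complex signal z = x + iy and Fourier transformed.  The translation
#' mode c0 is discarded; the retained features are |c_k| for
#' k in {+1, -1, +2, -2, ...} (n_modes values), which are invariant to
#' rotation (a rotation multiplies every c_k by a unit phase) and to the
#' choice of starting point.  The mean Euclidean distance between the
#' resampled points and the truncated-series reconstruction is reported as
#' `boundary_approx_error`; objects exceeding `err_max` (0.1 px in the
#' original analysis) are flagged excluded, never dropped silently.
#' Boundaries with fewer than 8 points are transformed as-is, with
#' unavailable modes set to 0 and error 0.
#'
#' @param boundary m x 2 (row, col) cyclic boundary from [trace_boundary()].
#' @param n_modes number of amplitudes returned (even; default 30).
#' @param err_max exclusion cap on the reconstruction error, px.
#' @param n_points resampling resolution (default 128).
#' @return list(amplitudes, boundary_approx_error, excluded, resampled).
#' @export
fourier_shape_features <- function(boundary, n_modes = 30L, err_max = 0.1,
                                   n_points = 128L) {
  n_modes <- as.integer(n_modes)
  K <- n_modes %/% 2L
  ks <- as.vector(rbind(seq_len(K), -seq_len(K)))  # +1,-1,+2,-2,...
  nm <- paste0("ShapeF_", ifelse(ks > 0, "p", "m"), abs(ks))
  amps <- stats::setNames(numeric(n_modes), nm)

  m <- nrow(boundary)
  if (m < 2) {
    return(list(amplitudes = amps, boundary_approx_error = 0,
                excluded = FALSE, resampled = boundary, degenerate = TRUE))
  }
  # complex signal in x = col, y = -row, so the counter-clockwise boundary of
  # a disk of radius r puts its energy in c_{+1} with |c_1| = r
  if (m < 8) {
    z <- complex(real = boundary[, 2], imaginary = -boundary[, 1])
    cf <- stats::fft(z) / m
    for (i in seq_along(ks)) {
      k <- ks[i]
      idx <- if (k >= 0) k else m + k
      if (idx >= 1 && idx <= m - 1) amps[i] <- Mod(cf[idx + 1])
    }
    return(list(amplitudes = amps, boundary_approx_error = 0,
                excluded = FALSE, resampled = boundary, degenerate = TRUE))
  }

  P <- as.integer(n_points)
  rs <- resample_boundary(boundary, P)
  z <- complex(real = rs[, 2], imaginary = -rs[, 1])
  cf <- stats::fft(z) / P
  idx <- ifelse(ks >= 0, ks, P + ks) + 1L
  amps[] <- Mod(cf[idx])

  # truncated reconstruction: c0 plus the kept modes
  j <- 0:(P - 1)
  zhat <- rep(cf[1], P)
  for (i in seq_along(ks))
    zhat <- zhat + cf[idx[i]] * exp(2i * pi * ks[i] * j / P)
  err <- mean(Mod(z - zhat))
  list(amplitudes = amps, boundary_approx_error = err,
       excluded = err > err_max, resampled = rs, degenerate = FALSE)
}

#' Fourier descriptors of the boundary distance profile
#'
#' Real DFT amplitudes |d_k|, k = 0..n_modes-1, of the periodic profile of
#' nearest-neighbor distances sampled along the resampled boundary (d_0 is
#' the profile mean).  A lone-object frame uses the sentinel-constant
#' profile, so d_0 equals the sentinel and all higher modes are 0.
#'
#' @param profile numeric vector of distances at the resampled boundary
#'   points.
#' @param n_modes number of amplitudes (default 30).
#' @return named numeric vector DistF_00 .. DistF_<n_modes-1>.
#' @export
fourier_distance_features <- function(profile, n_modes = 30L) {
  n_modes <- as.integer(n_modes)
  nm <- sprintf("DistF_%02d", 0:(n_modes - 1L))
  amps <- stats::setNames(numeric(n_modes), nm)
  P <- length(profile)
  if (P == 0) return(amps)
  d <- Mod(stats::fft(profile)) / P
  take <- seq_len(min(n_modes, P))
  amps[take] <- d[take]
  amps
}

#' Full per-object feature table for one frame
#'
#' Computes the complete measure set (10 region properties, 4
#' neighbor-distance/intensity statistics, `n_shape_modes` Fourier shape
#' amplitudes, `n_dist_modes` Fourier distance amplitudes = 74 by default)
#' for every segmented object of a frame, plus the QC columns
#' `boundary_err`, `excluded` and `lone`.
#'
#' @param objects list of `structure_object`s from [segment_structures()].
#' @param frame the background-subtracted [image_frame()] (intensity source).
#' @param config a [pipeline_config()].
#' @param image_id identifier copied into the provenance column.
#' @return data.frame, one row per object.
#' @export
object_features <- function(objects, frame, config = pipeline_config(),
                            image_id = 1L) {
  frame <- as_image_frame(frame)
  img <- frame$pixels
  if (length(objects) == 0) {
    return(data.frame(image_id = character(0), object_id = integer(0)))
  }
  sentinel <- sqrt(nrow(img)^2 + ncol(img)^2)
  rows <- vector("list", length(objects))
  for (i in seq_along(objects)) {
    obj <- objects[[i]]
    reg <- region_features(obj)
    nd <- neighbor_distance_features(obj, objects, img)
    sf <- fourier_shape_features(obj$boundary, config$n_shape_modes,
                                 config$boundary_err_max)
    if (nd$lone) {
      profile <- rep(sentinel, max(1L, nrow(sf$resampled)))
    } else if (is.null(sf$resampled) || nrow(sf$resampled) < 2) {
      profile <- rep(nd$values[["NDistMean"]], 1L)
    } else {
      profile <- bilinear_at(nd$dist_map, sf$resampled[, 1], sf$resampled[, 2])
    }
    df <- fourier_distance_features(profile, config$n_dist_modes)
    rows[[i]] <- data.frame(image_id = image_id,
                            object_id = obj$object_id,
                            t(reg), t(nd$values), t(sf$amplitudes), t(df),
                            boundary_err = sf$boundary_approx_error,
                            excluded = isTRUE(sf$excluded),
                            lone = nd$lone)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the morphometric feature columns
#'
#' @param config a [pipeline_config()].
#' @return character vector of feature column names (74 by default).
#' @export
feature_names <- function(config = pipeline_config()) {
  K <- config$n_shape_modes %/% 2L
  ks <- as.vector(rbind(seq_len(K), -seq_len(K)))
  c("Area", "ConvexArea", "Eccentricity", "EquivDiameter", "Extent",
    "FilledArea", "MajorAxisLength", "MinorAxisLength", "Perimeter",
    "Solidity", "NDistMean", "NDistSD", "IntMean", "IntSD",
    paste0("ShapeF_", ifelse(ks > 0, "p", "m"), abs(ks)),
    sprintf("DistF_%02d", 0:(config$n_dist_modes - 1L)))
}

#' Standardize a feature matrix
#'
#' Column-wise z-scores (subtract the mean, divide by the standard
#' deviation).  Zero-variance columns are dropped with a warning; the
#' standardization parameters are stored so held-out objects can be projected
#' with [apply_standardization()].
#'
#' @param X numeric matrix or data.frame of features (rows = objects).
#' @return object of class `std_features`: list(Z, center, scale, dropped).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("standardize_features: need at least 2 rows")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[scl == 0 | !is.finite(scl)]
  if (length(dropped) > 0)
    warning("standardize_features: dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(colnames(X), dropped)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2, scl[keep], "/")
  structure(list(Z = Z, center = center[keep], scale = scl[keep],
                 dropped = dropped), class = "std_features")
}

#' Apply stored standardization parameters to new data
#'
#' @param std a `std_features` object from [standardize_features()].
#' @param X numeric matrix/data.frame with (at least) the retained columns.
#' @return standardized matrix over the retained columns.
#' @export
apply_standardization <- function(std, X) {
  X <- as.matrix(X)[, names(std$center), drop = FALSE]
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}
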