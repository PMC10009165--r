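#' Disk-shaped structuring element
#'
#' Binary disk of the given radius: all pixels whose center lies within
#' `radius` of the origin.  Matches the disk used for morphological opening of
#' cell masks.
#'
#' @param radius disk radius in pixels (>= 0).
#' @return logical matrix of odd dimensions with the origin at the center.
#' @export
disk_kernel <- function(radius) {
  r <- max(0L, as.integer(floor(radius)))
  idx <- -r:r
  outer(idx, idx, function(a, b) a^2 + b^2 <= radius^2)
}

#' Gaussian smoothing of an intensity image
#'
#' Separable Gaussian filter with half-sample symmetric (reflective) boundary
#' handling, truncated at 4 sigma.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  cpp_gaussian_blur(img, sigma)
}

#' Binary erosion, dilation and opening
#'
#' Pixels outside the image count as background.
#'
#' @param mask logical matrix.
#' @param kernel logical structuring element with odd dimensions (origin at
#'   center), e.g. from [disk_kernel()].
#' @return logical matrix of the same dimensions.
#' @export
binary_erode <- function(mask, kernel) {
  storage.mode(mask) <- "logical"
  m <- cpp_erode(mask, kernel)
  dimnames(m) <- NULL
  m
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, kernel) {
  storage.mode(mask) <- "logical"
  cpp_dilate(mask, kernel)
}

#' @rdname binary_erode
#' @export
binary_opening <- function(mask, kernel) {
  binary_dilate(binary_erode(mask, kernel), kernel)
}

#' Connected-component labeling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the object convention used
#'   throughout the pipeline).
#' @return integer matrix; 0 is background, components numbered in raster
#'   (column-major) order of first encounter.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  storage.mode(mask) <- "logical"
  cpp_label(mask, as.integer(connectivity))
}

#' Fill interior holes of a binary mask
#'
#' A hole is a 4-connected background component that does not touch the image
#' border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set TRUE.
#' @export
fill_holes <- function(mask) {
  storage.mode(mask) <- "logical"
  bg <- cpp_label(!mask, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  border <- border[border != 0L]
  mask | (bg != 0L & !(bg %in% border))
}

#' Exact Euclidean distance transform
#'
#' Distance from every pixel to the nearest TRUE pixel (Felzenszwalb &
#' Huttenlocher exact algorithm).  If the mask has no TRUE pixel all distances
#' are `Inf`.
#'
#' @param mask logical matrix of feature pixels.
#' @return numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  d <- cpp_sqedt(mask)
  d[d >= 1e19] <- Inf
  sqrt(d)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance over a 256-bin histogram of the values.
#' Used as the parameter-free 1-D split in class refinement and as the logged
#' threshold suggestion for images.
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins.
#' @return threshold value; values > threshold fall in the upper class.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc[-n_bins])]
}
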