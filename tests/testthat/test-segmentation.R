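# Cell and structure segmentation: the published threshold, morphology and
# size-filter rules.

test_that("cell segmentation applies fill, opening and the 5000-px filter", {
  # all-zero frame: empty mask, warning not error
  expect_warning(cm <- segment_cell(matrix(0, 120, 120), 12000),
                 "empty cell mask")
  expect_false(any(cm$mask))

  # 64x64 (4096 px) and 80x80 (6400 px) squares: only the larger survives
  # the area filter; expected areas from the brute-force opening oracle
  img <- matrix(0, 220, 220)
  img[11:74, 11:74] <- 30000
  img[101:180, 101:180] <- 30000
  cm <- segment_cell(img, 24000)
  small_or <- brute_opening(img[1:90, 1:90] >= 24000, 7)
  big_or <- brute_opening(img[95:190, 95:190] >= 24000, 7)
  expect_lt(sum(small_or), 5000)    # the opened small square fails the filter
  expect_gt(sum(big_or), 5000)
  expect_equal(sum(cm$mask), sum(big_or))
  expect_false(any(cm$mask[1:90, 1:90]))

  # 100x100 solid square at 30000, threshold 24000: area equals the oracle
  img2 <- matrix(0, 140, 140)
  img2[21:120, 21:120] <- 30000
  cm2 <- segment_cell(img2, 24000)
  expect_equal(sum(cm2$mask), sum(brute_opening(img2 >= 24000, 7)))
})

test_that("cell segmentation is support-idempotent on smooth binary blobs", {
  m <- disk_mask(45)
  img <- ifelse(m, 30000, 0)
  cm <- segment_cell(img, 15000)
  expect_identical(unname(cm$mask), unname(m))
})

test_that("background subtraction removes offsets and keeps sharp spots", {
  # constant image -> ~0 everywhere
  out <- subtract_background(matrix(500, 60, 60), 5)
  expect_lt(max(out$pixels), 1e-9)

  # offset invariance on the interior
  withr::with_seed(5, {
    x <- matrix(runif(60 * 60, 0, 2000), 60, 60)
    a <- subtract_background(x, 5)$pixels
    b <- subtract_background(x + 800, 5)$pixels
    expect_lt(max(abs(a - b)[21:40, 21:40]), 1)
  })

  # bright 3x3 spot on a linear ramp: explicit two-term oracle
  n <- 81
  ramp <- matrix(rep(seq(0, 4000, length.out = n), each = n), n, n)
  img <- ramp
  img[40:42, 40:42] <- img[40:42, 40:42] + 8000
  out <- subtract_background(img, 5)$pixels
  ramp_only <- subtract_background(ramp, 5)$pixels
  expect_gt(out[41, 41], 0.8 * 8000)              # spot survives
  expect_lt(max(ramp_only[21:60, 21:60]), 50)     # ramp interior suppressed
})

test_that("structure segmentation enforces the inclusive 10-400 px area rule", {
  nr <- 120
  img <- matrix(0, nr, nr)
  mask <- matrix(TRUE, nr, nr)
  # components of exactly 9, 10, 400 and 401 px
  img[2, 2:10] <- 5000                           # 9 px -> excluded
  img[5, 11:20] <- 5000                          # 10 px -> kept
  img[21:40, 31:50] <- 5000                      # 400 px -> kept
  img[61:80, 31:50] <- 5000; img[81, 31] <- 5000 # 401 px -> excluded
  objs <- segment_structures(img, mask, 2000, c(10, 400))
  expect_equal(sort(vapply(objs, function(o) o$area, 0)), c(10, 400))
})

test_that("objects outside the cell mask are excluded, straddlers clipped", {
  img <- matrix(0, 60, 60)
  mask <- matrix(FALSE, 60, 60); mask[, 1:30] <- TRUE
  img[10:13, 40:47] <- 5000            # fully outside -> gone
  img[30:33, 27:34] <- 5000            # 50% inside -> clipped to the mask
  img[50:53, 5:12] <- 5000             # fully inside -> intact
  objs <- segment_structures(img, mask, 2000, c(10, 400))
  areas <- sort(vapply(objs, function(o) o$area, 0))
  expect_equal(areas, c(16, 32))
  for (o in objs) expect_true(all(mask[o$pixels]))
  # an object with > 50% outside is dropped entirely
  img2 <- matrix(0, 60, 60)
  img2[30:33, 28:37] <- 5000           # 40 px, 28 outside
  expect_length(segment_structures(img2, mask, 2000, c(10, 400)), 0)
})

test_that("raising the structure threshold never adds unimodal objects", {
  # for isolated single-peak structures the super-level sets are nested and
  # connected, so counts are non-increasing in the threshold (a noisy
  # plateau can split and violate this; see the methods vignette)
  withr::with_seed(6, {
    img <- matrix(0, 150, 150)
    # isolated single-peak blobs on a grid (overlap would create saddles,
    # which legitimately split as the threshold rises)
    centers <- expand.grid(r = c(25, 60, 95, 130), c = c(25, 60, 95, 130))
    for (k in seq_len(12)) {
      r0 <- centers$r[k]; c0 <- centers$c[k]
      amp <- runif(1, 3000, 9000); sg <- runif(1, 2, 4)
      patch <- outer(-10:10, -10:10, function(a, b)
        amp * exp(-(a^2 + b^2) / (2 * sg^2)))
      img[r0 + (-10:10), c0 + (-10:10)] <- patch
    }
    mask <- matrix(TRUE, 150, 150)
    counts <- vapply(c(1000, 2000, 3000, 4000, 6000, 8000), function(thr)
      length(segment_structures(img, mask, thr, c(1, 1e5))), 0L)
    expect_true(all(diff(counts) <= 0))
    # and the retained foreground itself is monotone
    fg <- vapply(c(1000, 2000, 4000), function(thr) sum(img >= thr), 0)
    expect_true(all(diff(fg) <= 0))
  })
})

test_that("boundary tracing is cyclic, outer-only and degenerate-safe", {
  # 3x3 solid square: 8 boundary pixels in cyclic order
  b <- trace_boundary(which(place_blob(matrix(FALSE, 5, 5), rep(2:4, 3),
                                       rep(2:4, each = 3)), arr.ind = TRUE))
  expect_equal(nrow(b), 8)
  steps <- sqrt(rowSums((b - b[c(2:8, 1), ])^2))
  expect_true(all(steps <= sqrt(2) + 1e-12))   # consecutive neighbors
  expect_equal(nrow(unique(b)), 8)

  # single pixel: degenerate 1-point boundary
  expect_equal(trace_boundary(matrix(c(3, 4), 1)),
               matrix(c(3L, 4L), 1, dimnames = list(NULL, c("row", "col"))))

  # annulus: only the outer boundary, no points on the hole rim
  a <- annulus_mask(6, 3)
  b2 <- trace_boundary(which(a, arr.ind = TRUE))
  ctr <- (nrow(a) + 1) / 2
  d <- sqrt((b2[, 1] - ctr)^2 + (b2[, 2] - ctr)^2)
  expect_true(all(d > 4.5))
})
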