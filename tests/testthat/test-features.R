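# Morphometric measures: region properties, neighbor distances, Fourier
# descriptors, standardization.

mk_obj <- function(mask, id = 1L) {
  px <- which(mask, arr.ind = TRUE)
  structmorph:::new_structure_object(id, px[, 1], px[, 2])
}

test_that("region properties on squares and disks", {
  sq <- mk_obj(place_blob(matrix(FALSE, 30, 30), rep(5:24, 20),
                          rep(5:24, each = 20)))
  f <- region_features(sq)
  expect_equal(f[["Area"]], 400)
  expect_equal(f[["FilledArea"]], 400)
  expect_equal(f[["Extent"]], 1)
  expect_equal(f[["Solidity"]], 1)

  # removing one interior pixel changes Area, not FilledArea
  m <- matrix(FALSE, 30, 30); m[5:24, 5:24] <- TRUE; m[15, 15] <- FALSE
  f2 <- region_features(mk_obj(m))
  expect_equal(f2[["Area"]], 399)
  expect_equal(f2[["FilledArea"]], 400)

  d <- region_features(mk_obj(disk_mask(10)))
  expect_lt(d[["Eccentricity"]], 0.1)
  expect_equal(d[["EquivDiameter"]], 2 * sqrt(d[["Area"]] / pi))

  # 1-px object: ellipse convention Major = Minor > 0, Ecc = 0
  p1 <- region_features(mk_obj(place_blob(matrix(FALSE, 5, 5), 3, 3)))
  expect_equal(p1[["MajorAxisLength"]], p1[["MinorAxisLength"]])
  expect_equal(p1[["MajorAxisLength"]], 4 * sqrt(1 / 12))
  expect_equal(p1[["Eccentricity"]], 0)
})

test_that("neighbor-distance and intensity statistics", {
  img <- matrix(1000, 20, 20)
  a <- structmorph:::new_structure_object(1L, 10L, 5L)
  b <- structmorph:::new_structure_object(2L, 10L, 10L)
  nd <- neighbor_distance_features(a, list(a, b), img)
  expect_equal(nd$values[["NDistMean"]], 5)
  expect_equal(nd$values[["NDistSD"]], 0)
  expect_equal(nd$values[["IntSD"]], 0)       # uniform intensity
  expect_false(nd$lone)

  lone <- neighbor_distance_features(a, list(a), img)
  expect_true(lone$lone)
  expect_equal(lone$values[["NDistMean"]], sqrt(2) * 20)  # image diagonal
})

test_that("Fourier shape descriptors: circle analytics and rotation", {
  # densely sampled continuous circle: |c1| = r, other amplitudes vanish
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  bnd <- cbind(row = -10 * sin(th), col = 10 * cos(th))
  ff <- fourier_shape_features(bnd)
  expect_equal(ff$amplitudes[["ShapeF_p1"]], 10, tolerance = 1e-6)
  expect_lt(max(ff$amplitudes[-1]), 1e-5 * 10)
  expect_false(ff$excluded)

  # 90-degree rotation leaves the amplitude vector unchanged
  m <- disk_mask(5) | place_blob(matrix(FALSE, 15, 15), 8, 1:8)
  px <- which(m, arr.ind = TRUE)
  rot <- cbind(px[, 2], nrow(m) + 1 - px[, 1])
  f0 <- fourier_shape_features(trace_boundary(px))
  f90 <- fourier_shape_features(trace_boundary(rot))
  expect_equal(f0$amplitudes, f90$amplitudes, tolerance = 1e-9)

  # exclusion flag mirrors the 0.1-px rule exactly
  wig <- cbind(row = -(10 + 0.6 * cos(20 * th[seq(1, 4000, 20)])) *
                 sin(th[seq(1, 4000, 20)]),
               col = (10 + 0.6 * cos(20 * th[seq(1, 4000, 20)])) *
                 cos(th[seq(1, 4000, 20)]))
  fw <- fourier_shape_features(wig)
  expect_gt(fw$boundary_approx_error, 0.1)
  expect_true(fw$excluded)
  expect_identical(ff$excluded, ff$boundary_approx_error > 0.1)
})

test_that("disk |c1| scales linearly with radius", {
  rs <- 5:20
  c1 <- vapply(rs, function(r)
    fourier_shape_features(trace_boundary(which(disk_mask(r),
      arr.ind = TRUE)))$amplitudes[["ShapeF_p1"]], 0)
  slope <- stats::coef(stats::lm(c1 ~ rs))[[2]]
  expect_lt(abs(slope - 1), 0.01)
})

test_that("distance-profile Fourier features match a direct DFT", {
  # constant profile: d0 = c, higher modes 0
  f <- fourier_distance_features(rep(7.5, 128))
  expect_equal(f[["DistF_00"]], 7.5)
  expect_lt(max(f[-1]), 1e-12)

  # pure cosine: single nonzero amplitude at k = 1
  s <- 0:127
  f2 <- fourier_distance_features(5 + 2 * cos(2 * pi * s / 128))
  expect_equal(f2[["DistF_00"]], 5)
  expect_equal(f2[["DistF_01"]], 1, tolerance = 1e-12)  # two-sided split
  expect_lt(max(f2[-c(1, 2)]), 1e-12)

  # random profile: equals the brute-force DFT moduli
  withr::with_seed(7, {
    p <- runif(128, 0, 10)
    expect_equal(unname(fourier_distance_features(p)),
                 Mod(brute_dft(p))[1:30], tolerance = 1e-10)
  })
})

test_that("distance profile of a two-object frame matches brute force", {
  img <- matrix(1000, 40, 40)
  m <- place_blob(matrix(FALSE, 40, 40), rep(10:14, 5), rep(10:14, each = 5))
  a <- mk_obj(m)
  b <- structmorph:::new_structure_object(2L, 30L, 30L)
  nd <- neighbor_distance_features(a, list(a, b), img)
  # sample the brute-force EDT of object b at the resampled boundary
  be <- brute_edt(place_blob(matrix(FALSE, 40, 40), 30, 30))
  rs <- fourier_shape_features(a$boundary)$resampled
  prof_pkg <- structmorph:::bilinear_at(nd$dist_map, rs[, 1], rs[, 2])
  prof_brute <- structmorph:::bilinear_at(be, rs[, 1], rs[, 2])
  expect_equal(prof_pkg, prof_brute, tolerance = 1e-10)
  expect_equal(unname(fourier_distance_features(prof_pkg)),
               Mod(brute_dft(prof_brute))[1:30], tolerance = 1e-10)
})

test_that("standardization: z-scores, dropped columns, reuse, errors", {
  withr::with_seed(8, {
    X <- cbind(a = rnorm(50, 5, 2), b = runif(50), c = rep(3, 50))
    expect_warning(std <- standardize_features(X), "zero-variance")
    expect_equal(std$dropped, "c")
    expect_lt(max(abs(colMeans(std$Z))), 1e-9)
    expect_lt(max(abs(apply(std$Z, 2, sd) - 1)), 1e-9)
    # applying stored parameters reproduces the matrix bit for bit
    expect_identical(apply_standardization(std, X), std$Z)
  })
  expect_error(standardize_features(matrix(1, 1, 3)), "at least 2 rows")
})

test_that("full feature vectors are invariant to rotation and translation", {
  cfg <- pipeline_config()
  base <- matrix(FALSE, 41, 41)
  base[15:20, 10:30] <- TRUE
  base[21:26, 10:15] <- TRUE              # an L-shaped object
  img <- matrix(1234, 41, 41)
  fv <- function(mask) {
    obj <- mk_obj(mask)
    object_features(list(obj), img, cfg)
  }
  f0 <- fv(base)
  # integer translation: everything except provenance identical
  shft <- matrix(FALSE, 41, 41)
  shft[cbind(which(base, arr.ind = TRUE)[, 1] + 3,
             which(base, arr.ind = TRUE)[, 2] + 5)] <- TRUE
  f1 <- fv(shft)
  fn <- feature_names(cfg)
  expect_equal(as.numeric(f0[, fn]), as.numeric(f1[, fn]), tolerance = 1e-9)
  # 180-degree rotation
  rot <- matrix(FALSE, 41, 41)
  pxb <- which(base, arr.ind = TRUE)
  rot[cbind(42 - pxb[, 1], 42 - pxb[, 2])] <- TRUE
  f2 <- fv(rot)
  expect_equal(as.numeric(f0[, fn]), as.numeric(f2[, fn]), tolerance = 1e-6)
})
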