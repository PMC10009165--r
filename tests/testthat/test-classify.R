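# PCA reduction, DBSCAN, bimodality refinement, class merging, area
# fractions.

test_that("fit_pca keeps the minimal component set reaching the target", {
  withr::with_seed(10, {
    # collinear 3-D data: one component explains everything
    t <- rnorm(100)
    X <- cbind(t, 2 * t, -t)
    expect_equal(fit_pca(X, 0.90)$n_kept, 1)

    # isotropic 2-D Gaussian: both components needed at 90%
    Y <- matrix(rnorm(2e4), ncol = 2)
    expect_equal(fit_pca(Y, 0.90)$n_kept, 2)

    # var_target 1 keeps the full rank
    expect_equal(fit_pca(X, 1.0)$n_kept, 1)
    expect_equal(fit_pca(Y, 1.0)$n_kept, 2)
  })
  expect_error(fit_pca(matrix(rnorm(20), 10), 0), "var_target")
  expect_error(fit_pca(matrix(rnorm(20), 10), 1.5), "var_target")
  # explained-variance ratios are non-increasing
  withr::with_seed(11, {
    p <- fit_pca(matrix(rnorm(600), ncol = 6), 0.9)
    expect_true(all(diff(p$ev_ratio) <= 1e-12))
  })
})

test_that("DBSCAN handles blobs, singletons and duplicate points", {
  withr::with_seed(12, {
    Z <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
               matrix(rnorm(40, 20, 0.3), ncol = 2))
    lab <- cluster_dbscan(Z, eps = 2, min_pts = 3)
    expect_equal(length(unique(lab)), 2)
    expect_true(all(lab != -1))
    expect_equal(length(unique(lab[1:20])), 1)
    expect_equal(length(unique(lab[21:40])), 1)
  })
  # an isolated point is noise
  Z2 <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(50, 50))
  expect_equal(cluster_dbscan(Z2, 1, 3)[4], -1L)
  # all points identical: one cluster
  expect_equal(cluster_dbscan(matrix(1, 10, 3), 0.5, 3), rep(1L, 10))
})

test_that("DBSCAN equals the brute-force reachability closure", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(20:120, 1)
      d <- sample(2:6, 1)
      k <- sample(1:4, 1)
      centers <- matrix(rnorm(k * d, sd = 6), ncol = d)
      Z <- centers[rep(seq_len(k), length.out = n), , drop = FALSE] +
        matrix(rnorm(n * d, sd = 2), ncol = d)
      eps <- runif(1, 0.5, 3)
      lab <- cluster_dbscan(Z, eps, 3)
      oracle <- brute_dbscan(Z, eps, 3)
      expect_identical(canon_labels(lab), canon_labels(oracle))
    }
  })
})

test_that("DBSCAN partition is invariant to input order", {
  withr::with_seed(14, {
    Z <- matrix(rnorm(200), ncol = 2)
    lab <- cluster_dbscan(Z, 0.8, 3)
    perm <- sample(nrow(Z))
    lab_p <- cluster_dbscan(Z[perm, ], 0.8, 3)
    expect_identical(lab[perm] == -1L, lab_p == -1L)
    # same partition: co-membership matrices agree
    comem <- function(l) outer(l, l, function(a, b) a == b & a != -1L)
    expect_identical(comem(lab[perm]), comem(lab_p))
  })
})

test_that("bimodality coefficient separates mixtures from Gaussians", {
  # population values: balanced mixture at +/-3 (sd 0.5) has b ~ 0.90,
  # a Gaussian has b ~ 1/3
  withr::with_seed(15, {
    mix <- c(rnorm(2000, -3, 0.5), rnorm(2000, 3, 0.5))
    expect_gt(bimodality_coefficient(mix), 5 / 9)
    expect_lt(bimodality_coefficient(rnorm(4000)), 5 / 9)
  })
})

test_that("refinement splits bimodal classes and spares unimodal ones", {
  withr::with_seed(16, {
    x <- c(rnorm(200, -3, 0.5), rnorm(200, 3, 0.5))
    Z <- cbind(x, rnorm(400))
    truth <- rep(1:2, each = 200)
    ref <- refine_classes(rep(1L, 400), Z, areas = rep(50, 400), seed = 21)
    expect_equal(length(unique(ref)), 2)
    agree <- max(mean((ref == ref[1]) == (truth == 1)),
                 mean((ref == ref[1]) == (truth == 2)))
    expect_gte(agree, 0.95)

    # unimodal class stays intact
    ref2 <- refine_classes(rep(1L, 400), cbind(rnorm(400), rnorm(400)),
                           rep(50, 400), seed = 21)
    expect_true(all(ref2 == 1L))

    # candidate selection ranks by mean object area, not population: a
    # bimodal class outside the top-k by area is never split
    xs <- c(rnorm(150, -3, 0.5), rnorm(150, 3, 0.5))
    Z3 <- rbind(cbind(xs, rnorm(300)),
                matrix(rnorm(2 * 6 * 10), ncol = 2))
    labs <- c(rep(1L, 300), rep(2:7, each = 10))
    areas <- c(rep(5, 300), rep(100, 60))   # class 1 smallest mean area
    ref3 <- refine_classes(labs, Z3, areas, top_k = 5, seed = 21)
    expect_true(all(ref3[1:300] == 1L))

    # tiny classes (< 6 members) are never split
    Z4 <- cbind(c(-3, -3, 3, 3, 3), rnorm(5))
    expect_true(all(refine_classes(rep(1L, 5), Z4, rep(10, 5),
                                   seed = 21) == 1L))
  })
})

test_that("class merging groups co-varying fraction columns", {
  withr::with_seed(17, {
    # three blocks of fine classes whose fractions covary within block
    n_img <- 12
    base <- cbind(runif(n_img, 1, 4), runif(n_img, 1, 4), runif(n_img, 1, 4))
    frac <- cbind(base[, 1] %o% c(0.6, 0.4),
                  base[, 2] %o% c(0.5, 0.3, 0.2),
                  base[, 3] %o% c(0.7, 0.3))
    frac <- frac / rowSums(frac)
    colnames(frac) <- paste0(1:7)
    mg <- merge_classes(frac, k = 3)
    g <- mg$mapping
    expect_equal(length(unique(g)), 3)
    expect_equal(length(unique(g[1:2])), 1)
    expect_equal(length(unique(g[3:5])), 1)
    expect_equal(length(unique(g[6:7])), 1)

    # identical fraction columns always merge
    f2 <- cbind(frac[, c(1, 1)], frac[, 3], frac[, 6])
    colnames(f2) <- paste0(1:4)
    expect_equal(length(unique(merge_classes(f2, 3)$mapping[1:2])), 1)
  })
  # fewer fine classes than groups: identity with a warning
  f3 <- matrix(runif(8), 4, 2, dimnames = list(NULL, c("1", "2")))
  expect_warning(mg3 <- merge_classes(f3, 3), "identity")
  expect_equal(unname(mg3$mapping), 1:2)
})

test_that("area fractions normalize over classified objects", {
  pr <- area_fractions(c(1L, 2L, 3L), c(10, 30, 60))
  expect_equal(unname(pr$fractions), c(0.1, 0.3, 0.6))
  expect_equal(pr$noise_fraction, 0)

  pr2 <- area_fractions(c(1L, 1L), c(5, 15))
  expect_equal(unname(pr2$fractions), 1.0)

  pr3 <- area_fractions(c(1L, 2L, -1L), c(40, 40, 20))
  expect_equal(sum(pr3$fractions), 1, tolerance = 1e-12)
  expect_equal(pr3$noise_fraction, 0.2)

  pr4 <- area_fractions(c(-1L, -1L), c(10, 10))
  expect_true(pr4$undefined)
  expect_true(all(is.na(pr4$fractions)))
})
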