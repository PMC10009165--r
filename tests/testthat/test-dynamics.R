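# Trajectory metrics, fiber shortening, colocalization, adhesion
# morphometry.

mk_track <- function(x, y, dt = 5, id = 1L) {
  data.frame(track_id = id, frame = seq_along(x), t_min = (seq_along(x) - 1) * dt,
             x_um = x, y_um = y)
}

test_that("directionality ratio: analytic cases", {
  expect_equal(directionality_ratio(mk_track(0:10, rep(0, 11))), 1.0)
  loop <- mk_track(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(directionality_ratio(loop), 0.0)
  # two equal perpendicular legs -> 1/sqrt(2)
  ell <- mk_track(c(0, 1, 1), c(0, 0, 1))
  expect_equal(directionality_ratio(ell), 1 / sqrt(2), tolerance = 1e-12)
  expect_warning(r <- directionality_ratio(mk_track(c(0, 0), c(0, 0))),
                 "zero path")
  expect_true(is.na(r))
})

test_that("track speed: analytic cases", {
  expect_equal(track_speed(mk_track(rep(2, 6), rep(3, 6))), 0)
  v <- 0.7  # um/min at dt = 5
  tr <- mk_track(seq(0, by = v * 5, length.out = 10), rep(0, 10))
  expect_equal(track_speed(tr), v, tolerance = 1e-12)
})

test_that("speed and directionality are invariant to rigid motions", {
  withr::with_seed(20, {
    tr <- mk_track(cumsum(rnorm(20)), cumsum(rnorm(20)))
    th <- 0.7
    rot <- tr
    rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 12
    rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 4
    expect_equal(track_speed(rot), track_speed(tr), tolerance = 1e-12)
    expect_equal(directionality_ratio(rot), directionality_ratio(tr),
                 tolerance = 1e-12)
  })
})

test_that("directionality ratio never exceeds 1 on random walks", {
  withr::with_seed(21, {
    dr <- replicate(10000, {
      tr <- mk_track(cumsum(rnorm(8)), cumsum(rnorm(8)))
      directionality_ratio(tr)
    })
    expect_true(all(dr <= 1 + 1e-12))
    expect_true(all(dr >= 0))
  })
})

test_that("track filter keeps only tracks longer than min_frames", {
  t5 <- mk_track(1:5, 1:5, id = 1L)
  t6 <- mk_track(1:6, 1:6, id = 2L)
  out <- filter_tracks(rbind(t5, t6), 5)
  expect_equal(unique(out$track_id), 2L)
  expect_equal(nrow(filter_tracks(t5[0, ], 5)), 0)
})

test_that("track linking: gates, crossovers, new tracks", {
  # one detection per frame within the gate: a single full-length track
  det <- data.frame(frame = 1:8, x_um = (1:8) * 2, y_um = 0)
  tr <- link_tracks(det, max_disp = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 8)

  # two distant parallel cells: two tracks, no crossover
  det2 <- rbind(data.frame(frame = rep(1:6, 2),
                           x_um = c((1:6) * 2, (1:6) * 2),
                           y_um = rep(c(0, 100), each = 6)))
  tr2 <- link_tracks(det2, max_disp = 5)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id))
    expect_equal(length(unique(tr2$y_um[tr2$track_id == id])), 1)

  # a jump beyond the gate terminates the track and starts a new one
  det3 <- data.frame(frame = 1:6, x_um = c(0, 2, 4, 50, 52, 54), y_um = 0)
  tr3 <- link_tracks(det3, max_disp = 5)
  expect_equal(length(unique(tr3$track_id)), 2)
})

test_that("rose histogram: conservation, binning, equivariance, drift", {
  # all tracks due east: one occupied bin
  tracks <- do.call(rbind, lapply(1:7, function(i)
    mk_track(0:6 + i, rep(i, 7), id = i)))
  rh <- rose_histogram(tracks, 12)
  expect_equal(sum(rh$counts), 7)
  expect_equal(sum(rh$counts > 0), 1)

  # rotating all tracks by one bin width shifts counts by one bin
  withr::with_seed(22, {
    m <- track_metrics(do.call(rbind, lapply(1:40, function(i)
      mk_track(cumsum(rnorm(8)), cumsum(rnorm(8)), id = i))))
    h0 <- rose_histogram(m, 12)
    w <- 2 * pi / 12
    m_rot <- m
    m_rot$net_angle_rad <- structmorph:::wrap_angle(m$net_angle_rad + w)
    h1 <- rose_histogram(m_rot, 12)
    expect_equal(h1$counts, h0$counts[c(12, 1:11)])
  })

  # shared drift: circular mean of net angles within 10 degrees
  wp <- walk_params(n_cells = 60, n_frames = 30, persistence = 0.8,
                    group_bias_direction = pi / 3, seed = 5)
  m2 <- track_metrics(gen_trajectories(wp))
  cm <- atan2(mean(sin(m2$net_angle_rad)), mean(cos(m2$net_angle_rad)))
  expect_lt(abs(structmorph:::wrap_angle(cm - pi / 3)), 10 * pi / 180)
})

test_that("relative fiber length and shortening slope", {
  cst <- gen_fiber_series(l0 = 20, shortening_rate = 0, noise_sd = 0)
  r <- relative_fiber_length(cst)
  expect_true(all(r$rel_length == 1))

  # 24 -> 12 um over 300 s: r(end) = 0.5, slope exact
  tr <- gen_fiber_series(l0 = 24, shortening_rate = 12 / 300, n_frames = 61,
                         dt = 5, noise_sd = 0)
  r2 <- relative_fiber_length(tr)
  expect_equal(r2$rel_length[1], 1)
  expect_equal(r2$rel_length[61], 0.5, tolerance = 1e-12)
  expect_equal(attr(r2, "slope_per_s"), -(12 / 300) / 24, tolerance = 1e-12)

  # noisy series: slope within 2 sd of the generating rate
  slopes <- vapply(1:20, function(s) {
    tn <- gen_fiber_series(24, 0.04, 61, 5, noise_sd = 0.5, seed = s)
    attr(relative_fiber_length(tn), "slope_per_s")
  }, 0)
  expect_lt(abs(mean(slopes) - (-0.04 / 24)), 2 * sd(slopes))
  # determinism of the noisy generator
  expect_identical(gen_fiber_series(24, 0.04, 61, 5, 0.5, seed = 3),
                   gen_fiber_series(24, 0.04, 61, 5, 0.5, seed = 3))
})

test_that("Pearson colocalization: exact and sampled cases", {
  withr::with_seed(23, {
    a <- matrix(runif(400, 0, 1000), 20, 20)
    expect_equal(pearson_coloc(a, a), 1.0, tolerance = 1e-12)
    expect_equal(pearson_coloc(a, -a + 2000), -1.0, tolerance = 1e-12)
  })
  p <- gen_coloc_pair(317, rho = 0.5, seed = 9)
  mask <- matrix(TRUE, 317, 317)
  mask[1, 1:150] <- FALSE          # mask with ~1e5 px
  expect_lt(abs(pearson_coloc(p$a, p$b, mask) - 0.5), 0.01)
})

test_that("adhesion morphometrics: circularity and calibration", {
  lab <- matrix(0L, 35, 35); lab[disk_mask(15)] <- 1L
  ad <- adhesion_morphometrics(lab, 0.1)
  expect_gte(ad$circularity, 0.95)
  expect_lte(ad$circularity, 1.05)
  expect_equal(ad$area_um2, sum(lab == 1) * 0.01)

  # 4:1 ellipse: within 0.07 of the Ramanujan closed form
  a <- 24; b <- 6
  m <- outer(-10:10, -30:30, function(r, c) (c / a)^2 + (r / b)^2 <= 1)
  lab2 <- matrix(0L, 21, 61); lab2[m] <- 1L
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  analytic <- 4 * pi * (pi * a * b) / P^2
  expect_lt(abs(adhesion_morphometrics(lab2, 0.1)$circularity - analytic),
            0.07)

  # area scales with the square of the pixel size, circularity does not
  ad1 <- adhesion_morphometrics(lab, 0.1)
  ad2 <- adhesion_morphometrics(lab, 0.2)
  expect_equal(ad2$area_um2, 4 * ad1$area_um2)
  expect_equal(ad2$circularity, ad1$circularity)

  # actin-association filter: only adhesions touching the fiber mask remain
  lab3 <- matrix(0L, 40, 40)
  lab3[5:8, 5:8] <- 1L
  lab3[25:28, 25:28] <- 2L
  fibers <- matrix(FALSE, 40, 40); fibers[9, 4:10] <- TRUE  # adjacent to obj 1
  kept <- adhesion_morphometrics(lab3, 0.1, fiber_mask = fibers)
  expect_equal(kept$id, 1L)
})

test_that("trajectory generator recovers its own parameters", {
  # persistence 1: collinear motion, DR exactly 1
  t1 <- gen_trajectories(walk_params(n_cells = 5, n_frames = 20,
                                     persistence = 1, seed = 2))
  m1 <- track_metrics(t1)
  expect_equal(m1$directionality_ratio, rep(1, 5), tolerance = 1e-9)

  # mean speed recovered within 5% (control-like 0.9 um/min, 49 frames)
  tv <- gen_trajectories(walk_params(n_cells = 100, n_frames = 49, dt = 5,
                                     mean_speed = 0.9, persistence = 0.5,
                                     seed = 3))
  mv <- track_metrics(tv)
  expect_lt(abs(mean(mv$speed_um_min) - 0.9) / 0.9, 0.05)

  # higher persistence gives higher mean directionality ratio
  dr_of <- function(p) {
    tr <- gen_trajectories(walk_params(n_cells = 200, n_frames = 30,
                                       persistence = p, seed = 4))
    mean(track_metrics(tr)$directionality_ratio)
  }
  expect_gt(dr_of(0.9), dr_of(0))
})
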