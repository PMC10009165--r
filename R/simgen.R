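#' Parameters of a synthetic structure scene
#'
#' The stated world the generator emulates: one cell (a bright elliptical
#' plateau) over a spatially graded background, containing dots/puncta,
#' short fragments, co-aligned filament bundles, clustered rings and
#' irregular aggregates, imaged with Poisson shot noise plus Gaussian read
#' noise and quantized to 16 bits.  Defaults: 512 x 512 px at 0.1 um/px;
#' background offset drawn from [12000, 24000] counts (the manual-threshold
#' regime of the original data) with a linear gradient; foreground amplitude
#' 10000 counts; ring outer diameters 0.49-1.35 um (the published range).
#' Default classes are deliberately stylized (monodisperse dots, fragments
#' and filaments; rings drawn from six discrete diameters spanning the
#' published range in equilateral clusters; filaments in parallel bundles):
#' this keeps every class within the resolving power of the published
#' clustering parameters at desk scale, so class mixtures are recoverable;
#' all knobs are configurable toward messier worlds.
#'
#' @param image_size image side in px (scalar, square images).
#' @param pixel_size um per px (> 0).
#' @param counts named counts per class, names among dot, fragment,
#'   filament, ring, aggregate; all >= 0.
#' @param foreground_intensity mean structure amplitude above its local
#'   background, counts.
#' @param bg_offset_range range the constant background offset is drawn
#'   from, counts.
#' @param bg_gradient_max max magnitude of each linear gradient coefficient,
#'   counts (edge-to-center).
#' @param noise_gain Poisson gain (variance = gain * expected counts).
#' @param read_sd Gaussian read noise sd, counts.
#' @param cell_elev intensity elevation of the cell plateau, counts.
#' @param dot_radius,fragment_length,filament_length,aggregate_radius
#'   geometry ranges, px.
#' @param fragment_width fragment rod width, px.
#' @param fragment_angle_mean,fragment_angle_sd fragment orientation
#'   (radians): fragments are broken filament pieces and by default retain
#'   the bundle orientation; set `fragment_angle_mean = NULL` for uniformly
#'   random orientations.
#' @param filament_curvature sd of the per-step heading change of filament
#'   paths, radians.
#' @param filament_angle_mean,filament_angle_sd shared orientation of
#'   filaments (radians): septin filaments co-align with stress fibers, so
#'   all filaments of a scene share one direction up to a small jitter.
#' @param filament_bundle_size range of filaments per parallel bundle.
#' @param filament_spacing center-to-center spacing within a bundle, px.
#' @param ring_diameter_um ring outer-diameter range, um.
#' @param ring_thickness ring annulus thickness, px.
#' @param ring_cluster_size range of rings per cluster (default: pairs).
#'   Rings crowd together (as around residual septin structures) and carry an
#'   exclusion halo so each ring's nearest neighbor is its sibling, making
#'   the neighbor-distance profile a deterministic function of the variant.
#' @param ring_gap edge-to-edge gap between paired rings, px.
#' @param intensity_jitter relative per-object amplitude jitter (uniform,
#'   +/- this fraction).
#' @param min_gap minimum gap enforced between objects, px (placement
#'   keeps objects resolvable by connected-component segmentation).
#' @param margin minimum distance of structures from the cell edge, px.
#' @param max_retries placement retries per object before erroring.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_size = 512L,
                         pixel_size = 0.1,
                         counts = c(dot = 150, fragment = 80, filament = 30,
                                    ring = 25, aggregate = 10),
                         foreground_intensity = 10000,
                         bg_offset_range = c(12000, 24000),
                         bg_gradient_max = 1000,
                         noise_gain = 2,
                         read_sd = 60,
                         cell_elev = 6000,
                         dot_radius = c(2, 2),
                         fragment_length = c(8, 8),
                         fragment_width = 2,
                         fragment_angle_mean = pi / 5,
                         fragment_angle_sd = 0,
                         filament_length = c(15, 15),
                         filament_curvature = 0,
                         filament_angle_mean = pi / 5,
                         filament_angle_sd = 0,
                         filament_bundle_size = c(4, 4),
                         filament_spacing = 6,
                         ring_diameter_um = c(0.49, 1.35),
                         ring_thickness = 2,
                         ring_cluster_size = c(2, 2),
                         ring_gap = 2,
                         aggregate_radius = c(5, 8),
                         intensity_jitter = 0.05,
                         min_gap = 2L,
                         margin = 20L,
                         max_retries = 100L) {
  full <- c(dot = 0, fragment = 0, filament = 0, ring = 0, aggregate = 0)
  if (length(counts) > 0) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(full)))
      stop("scene_params: counts must be named among ", paste(names(full), collapse = ", "))
    full[names(counts)] <- counts
  }
  if (any(full < 0)) stop("scene_params: counts must be >= 0")
  if (pixel_size <= 0) stop("scene_params: pixel_size must be > 0")
  if (ring_diameter_um[1] > ring_diameter_um[2])
    stop("scene_params: ring_diameter_um must be an ordered range")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 counts = full, foreground_intensity = foreground_intensity,
                 bg_offset_range = bg_offset_range,
                 bg_gradient_max = bg_gradient_max,
                 noise_gain = noise_gain, read_sd = read_sd,
                 cell_elev = cell_elev,
                 dot_radius = dot_radius, fragment_length = fragment_length,
                 fragment_width = fragment_width,
                 fragment_angle_mean = fragment_angle_mean,
                 fragment_angle_sd = fragment_angle_sd,
                 filament_length = filament_length,
                 filament_curvature = filament_curvature,
                 filament_angle_mean = filament_angle_mean,
                 filament_angle_sd = filament_angle_sd,
                 filament_bundle_size = filament_bundle_size,
                 filament_spacing = filament_spacing,
                 ring_diameter_um = ring_diameter_um,
                 ring_thickness = ring_thickness,
                 ring_cluster_size = ring_cluster_size,
                 ring_gap = ring_gap,
                 aggregate_radius = aggregate_radius,
                 intensity_jitter = intensity_jitter,
                 min_gap = as.integer(min_gap), margin = as.integer(margin),
                 max_retries = as.integer(max_retries)),
            class = "scene_params")
}

# --- shape primitives: (dr, dc) integer offset sets around the origin -------

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

shape_disk <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  list(px = as.matrix(g), geom = r)
}

shape_rod <- function(len, width, angle) {
  h <- ceiling(len / 2 + width)
  g <- expand.grid(dr = -h:h, dc = -h:h)
  u <- cos(angle) * g$dc + sin(angle) * g$dr
  v <- -sin(angle) * g$dc + cos(angle) * g$dr
  g <- g[abs(u) <= len / 2 & abs(v) <= width / 2, ]
  list(px = as.matrix(g), geom = len)
}

shape_ring <- function(r_out, thickness) {
  r_in <- max(r_out - thickness, 0.7)
  ri <- ceiling(r_out)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  d2 <- g$dr^2 + g$dc^2
  g <- g[d2 <= r_out^2 & d2 >= r_in^2, ]
  list(px = as.matrix(g), geom = 2 * r_out)
}

shape_filament <- function(len, curvature, angle_mean = NULL, angle_sd = 0) {
  step <- 0.5
  n <- ceiling(len / step)
  theta <- if (is.null(angle_mean)) stats::runif(1, 0, 2 * pi)
           else if (angle_sd > 0) stats::rnorm(1, angle_mean, angle_sd)
           else angle_mean
  th <- if (curvature > 0) theta + cumsum(stats::rnorm(n, 0, curvature * sqrt(step)))
        else rep(theta, n)
  r <- cumsum(step * sin(th))
  c <- cumsum(step * cos(th))
  pts <- unique(cbind(dr = round(r), dc = round(c)))
  # dilate to ~3 px width
  sub <- crop_mask(pts[, 1] - min(pts[, 1]) + 1L, pts[, 2] - min(pts[, 2]) + 1L,
                   pad = 2L)
  m <- cpp_dilate(sub$mask, disk_kernel(1))
  w <- which(m)
  rr <- ((w - 1L) %% nrow(m)) + 1L + sub$r0 - 1L + min(pts[, 1]) - 1L
  cc <- ((w - 1L) %/% nrow(m)) + 1L + sub$c0 - 1L + min(pts[, 2]) - 1L
  list(px = cbind(dr = rr - round(mean(rr)), dc = cc - round(mean(cc))),
       geom = len)
}

shape_aggregate <- function(r) {
  nh <- 3L
  amp <- stats::runif(nh, 0, 0.3 / nh)
  ph <- stats::runif(nh, 0, 2 * pi)
  ri <- ceiling(r * 1.3)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  th <- atan2(g$dr, g$dc)
  rad <- r * (1 + Reduce(`+`, lapply(seq_len(nh), function(k)
    amp[k] * cos((k + 1) * th + ph[k]))))
  g <- g[g$dr^2 + g$dc^2 <= rad^2, ]
  list(px = as.matrix(g), geom = r)
}

draw_shape <- function(class, p, geom = NULL) {
  switch(class,
    dot = shape_disk(if (is.null(geom)) runif1(p$dot_radius) else geom),
    fragment = shape_rod(if (is.null(geom)) runif1(p$fragment_length) else geom,
                         p$fragment_width,
                         if (is.null(p$fragment_angle_mean))
                           stats::runif(1, 0, pi)
                         else if (p$fragment_angle_sd > 0)
                           stats::rnorm(1, p$fragment_angle_mean,
                                        p$fragment_angle_sd)
                         else p$fragment_angle_mean),
    filament = shape_filament(if (is.null(geom)) runif1(p$filament_length) else geom,
                              p$filament_curvature,
                              p$filament_angle_mean, p$filament_angle_sd),
    ring = shape_ring((if (is.null(geom)) runif1(p$ring_diameter_um) else geom) /
                        p$pixel_size / 2,
                      p$ring_thickness),
    aggregate = shape_aggregate(if (is.null(geom)) runif1(p$aggregate_radius) else geom),
    stop("unknown class ", class))
}

# Stratified geometry variants: fragments, filaments and rings are drawn from
# a small discrete set of sizes spanning the configured range, cycled so every
# scene carries a near-identical variant composition.  This keeps the area
# fraction of each digitized variant proportional to its class's mixture
# share, which is what parameter-recovery validation measures.
variant_queue <- function(class, p, m) {
  if (m == 0) return(NULL)
  vals <- switch(class,
    fragment = seq(p$fragment_length[1], p$fragment_length[2], length.out = 3),
    filament = seq(p$filament_length[1], p$filament_length[2], length.out = 3),
    ring = seq(p$ring_diameter_um[1], p$ring_diameter_um[2], length.out = 6),
    NULL)
  if (is.null(vals)) return(NULL)
  sample(rep_len(vals, m))
}

# offsets of the shape dilated by the placement gap
gap_offsets <- function(px, gap) {
  if (gap <= 0) return(px)
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  sub <- crop_mask(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L, pad = gap + 1L)
  m <- cpp_dilate(sub$mask, disk_kernel(gap))
  w <- which(m)
  cbind(((w - 1L) %% nrow(m)) + 1L + sub$r0 - 1L + r0 - 1L,
        ((w - 1L) %/% nrow(m)) + 1L + sub$c0 - 1L + c0 - 1L)
}

#' Generate a synthetic structure scene with ground truth
#'
#' Pure function of (params, seed): identical inputs reproduce the identical
#' image and labels bit for bit.  Geometry is drawn first (one elliptical
#' cell; objects placed inside it with a minimum gap, largest classes first,
#' bounded retries), then the expected-count image is assembled and the
#' camera noise model applied: Poisson shot noise on expected counts (gain
#' `noise_gain`) plus Gaussian read noise, rounded and clipped to [0, 65535].
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return object of class `synthetic_scene`: list(image, truth_labels,
#'   truth_classes, truth, cell, params, seed, realized).
#' @export
gen_structure_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    n <- params$image_size
    offset <- runif1(params$bg_offset_range)
    ga <- stats::runif(1, -params$bg_gradient_max, params$bg_gradient_max)
    gb <- stats::runif(1, -params$bg_gradient_max, params$bg_gradient_max)
    xn <- matrix(rep(seq(-1, 1, length.out = n), each = n), n, n)
    yn <- matrix(rep(seq(-1, 1, length.out = n), times = n), n, n)
    bg <- offset + ga * xn + gb * yn

    # elliptical cell
    cx <- n / 2 + stats::runif(1, -n / 25, n / 25)
    cy <- n / 2 + stats::runif(1, -n / 25, n / 25)
    ax <- stats::runif(1, 0.30, 0.42) * n
    ay <- stats::runif(1, 0.30, 0.42) * n
    phi <- stats::runif(1, 0, pi)
    rows <- matrix(rep(seq_len(n), times = n), n, n)
    cols <- matrix(rep(seq_len(n), each = n), n, n)
    u <- cos(phi) * (cols - cx) + sin(phi) * (rows - cy)
    v <- -sin(phi) * (cols - cx) + cos(phi) * (rows - cy)
    cell <- (u / ax)^2 + (v / ay)^2 <= 1
    inner <- (u / pmax(ax - params$margin, 1))^2 +
             (v / pmax(ay - params$margin, 1))^2 <= 1

    labels <- matrix(0L, n, n)
    forbidden <- matrix(FALSE, n, n)
    classes <- character(0)
    geoms <- numeric(0)
    fgs <- numeric(0)
    allowed_lin <- which(inner)
    oid <- 0L
    order_classes <- c("ring", "aggregate", "filament", "fragment", "dot")
    for (cl in order_classes) {
      remaining <- params$counts[[cl]]
      queue <- variant_queue(cl, params, remaining)
      qi <- 0L
      while (remaining > 0) {
        # filaments come in parallel bundles at regular spacing; every other
        # class places one object at a time
        unit <- if (cl == "ring") {
          nc_ <- min(remaining,
                     sample(params$ring_cluster_size[1]:
                            params$ring_cluster_size[2], 1L))
          # axis-aligned pair directions keep the rounded sibling offset,
          # and hence the whole digitized configuration, identical for every
          # pair of a variant (digital annuli are 90-degree symmetric)
          ang <- sample(c(0, pi / 2, pi, 3 * pi / 2), 1)
          dia <- queue[qi + 1L] / params$pixel_size  # one variant per cluster
          # rings pair up inside an exclusion halo wide enough that every
          # boundary point's nearest neighbor is the sibling ring, so the
          # neighbor-distance profile is a deterministic function of the
          # variant
          halo <- ceiling(dia) + 4L
          Rc <- (dia + params$ring_gap) / 2
          lapply(seq_len(nc_), function(k) {
            s <- shape_ring(dia / 2, params$ring_thickness)
            a <- ang + 2 * pi * (k - 1) / nc_
            s$px[, 1] <- s$px[, 1] + round(Rc * sin(a))
            s$px[, 2] <- s$px[, 2] + round(Rc * cos(a))
            s$gap <- halo
            s
          })
        } else if (cl == "filament") {
          nb <- min(remaining,
                    sample(params$filament_bundle_size[1]:
                           params$filament_bundle_size[2], 1L))
          ang <- stats::rnorm(1, params$filament_angle_mean,
                              params$filament_angle_sd)
          lapply(seq_len(nb), function(k) {
            s <- shape_filament(queue[qi + k], params$filament_curvature,
                                ang, 0)
            off <- (k - (nb + 1) / 2) * params$filament_spacing
            s$px[, 1] <- s$px[, 1] + round(off * cos(ang))
            s$px[, 2] <- s$px[, 2] - round(off * sin(ang))
            # halo so edge filaments also see only their siblings
            s$gap <- as.integer(params$filament_spacing + 4L)
            s
          })
        } else {
          list(draw_shape(cl, params,
                          if (is.null(queue)) NULL else queue[qi + 1L]))
        }
        placed <- FALSE
        for (try in seq_len(params$max_retries)) {
          ctr <- allowed_lin[sample.int(length(allowed_lin), 1L)]
          cr <- ((ctr - 1L) %% n) + 1L
          cc <- ((ctr - 1L) %/% n) + 1L
          ok <- TRUE
          for (s in unit) {
            pr <- s$px[, 1] + cr; pc <- s$px[, 2] + cc
            if (min(pr) < 1 || max(pr) > n || min(pc) < 1 || max(pc) > n ||
                !all(inner[cbind(pr, pc)])) { ok <- FALSE; break }
            # no existing object within this shape's exclusion gap, and no
            # pixel inside a previously reserved halo
            gp <- gap_offsets(s$px, if (is.null(s$gap)) params$min_gap else s$gap)
            gr <- pmin(pmax(gp[, 1] + cr, 1L), n)
            gc <- pmin(pmax(gp[, 2] + cc, 1L), n)
            if (any(labels[cbind(gr, gc)] != 0L) ||
                any(forbidden[cbind(pr, pc)])) { ok <- FALSE; break }
          }
          if (!ok) next
          for (s in unit) {
            oid <- oid + 1L
            labels[cbind(s$px[, 1] + cr, s$px[, 2] + cc)] <- oid
            classes[oid] <- cl
            geoms[oid] <- s$geom
            fgs[oid] <- params$foreground_intensity *
              stats::runif(1, 1 - params$intensity_jitter,
                           1 + params$intensity_jitter)
            if (!is.null(s$gap)) {
              gp <- gap_offsets(s$px, s$gap)
              gr <- pmin(pmax(gp[, 1] + cr, 1L), n)
              gc <- pmin(pmax(gp[, 2] + cc, 1L), n)
              forbidden[cbind(gr, gc)] <- TRUE
            }
          }
          placed <- TRUE
          break
        }
        if (!placed)
          stop("gen_structure_scene: could not place object of class '", cl,
               "' after ", params$max_retries, " retries")
        remaining <- remaining - length(unit)
        qi <- qi + length(unit)
      }
    }

    expected <- bg + params$cell_elev * cell
    if (oid > 0) {
      w <- which(labels != 0L)
      expected[w] <- expected[w] + fgs[labels[w]]
    }
    img <- if (params$noise_gain > 0) {
      params$noise_gain *
        stats::rpois(n * n, as.vector(expected) / params$noise_gain)
    } else as.vector(expected)
    if (params$read_sd > 0) img <- img + stats::rnorm(n * n, 0, params$read_sd)
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), n, n)

    truth <- if (oid > 0) {
      data.frame(object_id = seq_len(oid), class = classes,
                 centroid_row = vapply(seq_len(oid), function(i)
                   mean(((which(labels == i) - 1L) %% n) + 1L), 0),
                 centroid_col = vapply(seq_len(oid), function(i)
                   mean(((which(labels == i) - 1L) %/% n) + 1L), 0),
                 area_px = as.vector(tabulate(labels[labels > 0L], nbins = oid)),
                 geom = geoms)
    } else {
      data.frame(object_id = integer(0), class = character(0),
                 centroid_row = numeric(0), centroid_col = numeric(0),
                 area_px = integer(0), geom = numeric(0))
    }
    structure(list(image = img, truth_labels = labels,
                   truth_classes = stats::setNames(classes, seq_len(oid)),
                   truth = truth, cell = cell, params = params,
                   seed = as.integer(seed),
                   realized = list(offset = offset, gradient = c(ga, gb),
                                   cell_center = c(cy, cx),
                                   cell_axes = c(ay, ax), cell_angle = phi)),
              class = "synthetic_scene")
  })
}

#' Pipeline configuration scaled to a synthetic scene
#'
#' Thresholds were chosen manually per image in the original analysis; for a
#' synthetic scene the natural manual choice is known from the generation
#' parameters: cell threshold halfway up the cell plateau, structure
#' threshold at the published default (2000 counts), which the default
#' foreground amplitude is designed to clear after background subtraction.
#'
#' @param scene a `synthetic_scene`.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
scene_config <- function(scene, ...) {
  stopifnot(inherits(scene, "synthetic_scene"))
  args <- list(...)
  if (is.null(args$cell_threshold))
    args$cell_threshold <- scene$realized$offset + scene$params$cell_elev / 2
  do.call(pipeline_config, args)
}

#' Parameters of persistent-random-walk trajectories
#'
#' Emulates tracked nuclei of migrating cells.  Defaults follow the imaging
#' protocol of the original migration movies: 5-minute frame interval over
#' 4 h (49 frames) and a control-like mean speed of 0.9 um/min.
#'
#' @param n_cells number of trajectories.
#' @param n_frames frames per trajectory.
#' @param dt minutes per frame (> 0).
#' @param mean_speed mean speed, um/min.
#' @param persistence directional correlation of successive steps in [0, 1]:
#'   1 = straight motion, 0 = uncorrelated step directions.
#' @param group_bias_direction optional shared drift angle (radians); NA for
#'   unbiased walks.
#' @param seed integer seed.
#' @return object of class `walk_params`.
#' @export
walk_params <- function(n_cells = 50L, n_frames = 49L, dt = 5,
                        mean_speed = 0.9, persistence = 0.5,
                        group_bias_direction = NA_real_, seed = 1L) {
  if (persistence < 0 || persistence > 1)
    stop("walk_params: persistence must lie in [0, 1]")
  if (dt <= 0) stop("walk_params: dt must be > 0")
  structure(list(n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames), dt = dt,
                 mean_speed = mean_speed, persistence = persistence,
                 group_bias_direction = group_bias_direction,
                 seed = as.integer(seed)),
            class = "walk_params")
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Generate persistent-random-walk trajectories
#'
#' Step lengths are Gamma-distributed with mean `mean_speed * dt` (CV 1/3);
#' headings evolve by uniform turns of half-width pi * (1 - persistence), so
#' persistence 1 gives collinear tracks and persistence 0 uncorrelated step
#' directions.  With a `group_bias_direction`, headings are additionally
#' pulled toward the shared drift angle.
#'
#' @param params a [walk_params()].
#' @return data.frame with columns track_id, frame, t_min, x_um, y_um.
#' @export
gen_trajectories <- function(params = walk_params()) {
  stopifnot(inherits(params, "walk_params"))
  p <- params
  with_seed(p$seed, {
    out <- vector("list", p$n_cells)
    half <- pi * (1 - p$persistence)
    shape <- 9
    for (i in seq_len(p$n_cells)) {
      x <- numeric(p$n_frames); y <- numeric(p$n_frames)
      x[1] <- stats::runif(1, 0, 300); y[1] <- stats::runif(1, 0, 300)
      th <- if (is.na(p$group_bias_direction)) stats::runif(1, -pi, pi)
            else p$group_bias_direction + stats::runif(1, -0.3, 0.3)
      for (f in 2:p$n_frames) {
        step <- stats::rgamma(1, shape = shape,
                              scale = p$mean_speed * p$dt / shape)
        x[f] <- x[f - 1] + step * cos(th)
        y[f] <- y[f - 1] + step * sin(th)
        if (half > 0) {
          th <- th + stats::runif(1, -half, half)
          if (!is.na(p$group_bias_direction))
            th <- th + 0.3 * wrap_angle(p$group_bias_direction - th)
        }
      }
      out[[i]] <- data.frame(track_id = i, frame = seq_len(p$n_frames),
                             t_min = (seq_len(p$n_frames) - 1) * p$dt,
                             x_um = x, y_um = y)
    }
    do.call(rbind, out)
  })
}

#' Generate a shortening-fiber length series
#'
#' length(t) = max(0, l0 - rate * t) + Gaussian noise, floored at 0.
#' Defaults mirror the contractility movies: 5-s frame interval for 5 min.
#'
#' @param l0 initial fiber length, um (> 0).
#' @param shortening_rate um/s.
#' @param n_frames number of frames (default 61: 5-s steps over 300 s).
#' @param dt seconds per frame.
#' @param noise_sd measurement noise sd, um.
#' @param seed integer seed.
#' @param fiber_id identifier.
#' @return data.frame of class `fiber_trace` with columns fiber_id, frame,
#'   t_s, length_um.
#' @export
gen_fiber_series <- function(l0 = 24, shortening_rate = 0.04, n_frames = 61L,
                             dt = 5, noise_sd = 0, seed = 1L, fiber_id = 1L) {
  if (l0 <= 0) stop("gen_fiber_series: l0 must be > 0")
  t_s <- (seq_len(n_frames) - 1) * dt
  len <- pmax(0, l0 - shortening_rate * t_s)
  if (noise_sd > 0)
    len <- with_seed(seed, pmax(0, len + stats::rnorm(n_frames, 0, noise_sd)))
  structure(data.frame(fiber_id = fiber_id, frame = seq_len(n_frames),
                       t_s = t_s, length_um = len),
            class = c("fiber_trace", "data.frame"))
}

#' Generate a correlated image pair for colocalization tests
#'
#' Two images whose population pixelwise correlation equals `rho` under a
#' bivariate Gaussian model, affinely rescaled to the 16-bit range (mean
#' 32768, sd 6000, rounded and clipped -- clipping at ~5.5 sd is
#' negligible).
#'
#' @param size side length of the square images (or c(nrow, ncol)).
#' @param rho target correlation in [-1, 1].
#' @param seed integer seed.
#' @return list(a, b) of integer-valued matrices.
#' @export
gen_coloc_pair <- function(size = 316L, rho = 0.5, seed = 1L) {
  if (rho < -1 || rho > 1) stop("gen_coloc_pair: rho must lie in [-1, 1]")
  dims <- if (length(size) == 1) c(size, size) else size[1:2]
  n <- prod(dims)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    q <- function(z) matrix(pmin(pmax(round(32768 + 6000 * z), 0), 65535),
                            dims[1], dims[2])
    list(a = q(z1), b = q(z2))
  })
}
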