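#' Run the full structure-classification pipeline
#'
#' Orchestrates segmentation, feature extraction, standardization, PCA,
#' DBSCAN clustering, optional bimodality refinement, class merging and
#' per-image area fractions over a batch of images:
#' segment_cell -> subtract_background -> segment_structures -> features ->
#' standardize -> fit_pca -> cluster_dbscan -> (refine) -> merge_classes ->
#' area_fractions.  Objects whose boundary reconstruction error exceeds the
#' configured cap are excluded from the analysis (flagged, kept in the
#' feature table).  With fewer than 3 images the merge stage degenerates to
#' the identity mapping with a warning.
#'
#' @param inputs list of `synthetic_scene`s, [image_frame()]s or matrices.
#' @param config a [pipeline_config()], a list of one config per image, or
#'   NULL (scenes then use [scene_config()], other inputs the defaults).
#' @param out_dir optional output directory; when given, writes objects.csv,
#'   features.csv, classes.csv, profiles.csv, model.json and manifest.json
#'   (partial outputs are removed if a stage fails).
#' @return object of class `classification_run`: list(profiles, classes,
#'   features, objects, pca, merge, config, manifest).
#' @export
run_classification <- function(inputs, config = NULL, out_dir = NULL) {
  if (inherits(inputs, c("synthetic_scene", "image_frame")) ||
      is.matrix(inputs)) inputs <- list(inputs)
  n_img <- length(inputs)
  if (n_img < 1) stop("run_classification: need at least 1 image")
  configs <- if (is.null(config)) {
    lapply(inputs, function(x)
      if (inherits(x, "synthetic_scene")) scene_config(x) else pipeline_config())
  } else if (inherits(config, "pipeline_config")) {
    rep(list(config), n_img)
  } else config
  stopifnot(length(configs) == n_img)
  cfg <- configs[[1]]  # global stages use the first config's tunables

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    on.exit(if (!is.null(out_dir) && length(written) > 0 &&
                !isTRUE(attr(written, "done"))) unlink(written), add = TRUE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  objects <- vector("list", n_img)
  feats <- vector("list", n_img)
  counts <- data.frame(image_id = seq_len(n_img), segmented = 0L,
                       excluded = 0L)
  for (i in seq_len(n_img)) {
    x <- inputs[[i]]
    frame <- if (inherits(x, "synthetic_scene")) {
      image_frame(x$image, pixel_size = x$params$pixel_size)
    } else as_image_frame(x)
    ci <- configs[[i]]
    mask <- stage("segment_cell", segment_cell(frame, config = ci))
    bg <- stage("subtract_background", subtract_background(frame, ci$bg_sigma))
    objs <- stage("segment_structures",
                  segment_structures(bg, mask, ci$structure_threshold,
                                     ci$structure_area_range))
    fi <- stage("features", object_features(objs, bg, ci, image_id = i))
    objects[[i]] <- objs
    feats[[i]] <- fi
    counts$segmented[i] <- length(objs)
    counts$excluded[i] <- if (nrow(fi) > 0) sum(fi$excluded) else 0L
  }
  features <- do.call(rbind, feats[vapply(feats, nrow, 0L) > 0])
  if (is.null(features) || nrow(features) == 0) {
    warning("run_classification: no objects segmented; profiles undefined")
    profiles <- data.frame(image_id = seq_len(n_img), noise_fraction = NA_real_,
                           undefined = TRUE)
    return(structure(list(profiles = profiles, classes = NULL,
                          features = features, objects = objects,
                          pca = NULL, merge = NULL, config = cfg,
                          manifest = NULL),
                     class = "classification_run"))
  }

  use <- !features$excluded
  fn <- intersect(feature_names(cfg), names(features))
  std <- stage("standardize",
               withCallingHandlers(standardize_features(features[use, fn]),
                                   warning = function(w) {
                                     message("run_classification: ",
                                             conditionMessage(w))
                                     invokeRestart("muffleWarning")
                                   }))
  pca <- stage("fit_pca", fit_pca(std$Z, cfg$pca_var_target))
  fine <- stage("cluster_dbscan",
                cluster_dbscan(pca$scores, cfg$dbscan_eps, cfg$dbscan_min_pts))
  if (cfg$refine)
    fine <- stage("refine_classes",
                  refine_classes(fine, pca$scores, features$Area[use],
                                 top_k = cfg$refine_top_k, seed = cfg$seed))

  # per-image area fractions over fine classes drive the merge
  img_of <- features$image_id[use]
  areas <- features$Area[use]
  fine_ids <- sort(unique(fine[fine != -1L]))
  merged <- rep(-1L, length(fine))
  merge <- NULL
  if (length(fine_ids) > 0) {
    frac <- t(vapply(seq_len(n_img), function(i) {
      sel <- img_of == i
      area_fractions(fine[sel], areas[sel], classes = fine_ids)$fractions
    }, numeric(length(fine_ids))))
    if (length(fine_ids) == 1) frac <- matrix(frac, ncol = 1)
    colnames(frac) <- fine_ids
    geometry <- data.frame(
      mean_area = vapply(fine_ids, function(k) mean(areas[fine == k]), 0),
      mean_eccentricity = vapply(fine_ids, function(k)
        mean(features$Eccentricity[use][fine == k]), 0),
      row.names = fine_ids)
    merge <- if (n_img >= 3 && length(fine_ids) >= cfg$merged_k) {
      stage("merge_classes",
            merge_classes(frac, k = cfg$merged_k, geometry = geometry))
    } else {
      if (n_img < 3)
        warning("run_classification: fewer than 3 images; fine classes not merged")
      structure(list(mapping = stats::setNames(seq_along(fine_ids),
                                               fine_ids),
                     group_summary = NULL), class = "class_merge")
    }
    merged[fine != -1L] <- merge$mapping[as.character(fine[fine != -1L])]
  }

  classes <- data.frame(image_id = img_of,
                        object_id = features$object_id[use],
                        fine = fine, merged = merged)
  merged_ids <- sort(unique(merged[merged != -1L]))
  profiles <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    sel <- img_of == i
    pr <- area_fractions(merged[sel], areas[sel], classes = merged_ids)
    out <- data.frame(image_id = i, noise_fraction = pr$noise_fraction,
                      undefined = pr$undefined)
    for (k in merged_ids) out[[paste0("class_", k)]] <- pr$fractions[[as.character(k)]]
    out
  }))

  manifest <- list(
    software = paste0("structmorph ",
                      as.character(utils::packageVersion("structmorph"))),
    seed = cfg$seed,
    config = unclass(cfg),
    n_images = n_img,
    counts = list(segmented = counts$segmented, excluded = counts$excluded,
                  classified = sum(fine != -1L), noise = sum(fine == -1L)))

  res <- structure(list(profiles = profiles, classes = classes,
                        features = features, objects = objects, pca = pca,
                        merge = merge, config = cfg, manifest = manifest),
                   class = "classification_run")

  if (!is.null(out_dir)) {
    paths <- file.path(out_dir, c("objects.csv", "features.csv", "classes.csv",
                                  "profiles.csv", "model.json",
                                  "manifest.json"))
    written <- paths
    for (i in seq_len(n_img))
      write_objects_csv(objects[[i]],
                        file.path(out_dir, sprintf("objects_%03d.csv", i)), i)
    write_table_csv(features, paths[2],
                    "features: one row per object; areas/lengths in px; Fourier amplitudes in px")
    write_table_csv(classes, paths[3],
                    "classes: fine/merged labels; -1 = noise (unclassified)")
    write_table_csv(profiles, paths[4],
                    "profiles: per-image area fraction of merged classes over classified objects; noise_fraction over all objects")
    jsonlite::write_json(list(ev_ratio = pca$ev_ratio, n_kept = pca$n_kept,
                              dbscan = list(eps = cfg$dbscan_eps,
                                            min_pts = cfg$dbscan_min_pts),
                              merge_mapping = as.list(merge$mapping)),
                         paths[5], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    jsonlite::write_json(manifest, paths[6], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    attr(written, "done") <- TRUE
  }
  res
}

#' Run the dynamics quantifications
#'
#' Applies the track-persistence filter, per-track speed/directionality
#' metrics and the rose histogram; optionally relative fiber length series
#' and Pearson colocalization.
#'
#' @param tracks data.frame of tracks or path to a tracks CSV
#'   (see [read_tracks_csv()]); NULL to skip.
#' @param fibers a fiber trace data.frame (or list of them); NULL to skip.
#' @param coloc list(a, b, mask) of aligned images (mask optional); NULL to
#'   skip.
#' @param min_frames strict track-length filter (default 5 frames).
#' @param n_bins rose-histogram bins.
#' @param out_dir optional output directory for tracks.csv, metrics.csv,
#'   fibers.csv, coloc.csv.
#' @return list(metrics, rose, fibers, coloc).
#' @export
run_dynamics <- function(tracks = NULL, fibers = NULL, coloc = NULL,
                         min_frames = 5L, n_bins = 12L, out_dir = NULL) {
  metrics <- NULL; rose <- NULL
  if (!is.null(tracks)) {
    if (is.character(tracks)) tracks <- read_tracks_csv(tracks)
    kept <- filter_tracks(tracks, min_frames)
    if (nrow(kept) == 0) {
      warning("run_dynamics: no tracks longer than ", min_frames, " frames")
      metrics <- data.frame(track_id = integer(0), n_frames = integer(0),
                            speed_um_min = numeric(0),
                            directionality_ratio = numeric(0),
                            net_angle_rad = numeric(0))
    } else {
      metrics <- track_metrics(kept)
      rose <- rose_histogram(metrics, n_bins)
    }
  }
  fib <- NULL
  if (!is.null(fibers)) {
    if (is.data.frame(fibers)) fibers <- list(fibers)
    fib <- do.call(rbind, lapply(fibers, function(f) {
      r <- relative_fiber_length(f)
      data.frame(fiber_id = f$fiber_id[1], frame = r$frame, t_s = r$t_s,
                 length_um = f[order(f$frame), "length_um"],
                 rel_length = r$rel_length,
                 slope_per_s = attr(r, "slope_per_s"))
    }))
  }
  col <- NULL
  if (!is.null(coloc)) {
    col <- data.frame(image_id = 1L,
                      pearson_r = pearson_coloc(coloc$a, coloc$b, coloc$mask))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(metrics))
      write_table_csv(metrics, file.path(out_dir, "metrics.csv"),
                      "per-track metrics: speed in um/min; directionality ratio dimensionless; angles in radians")
    if (!is.null(fib))
      write_table_csv(fib, file.path(out_dir, "fibers.csv"),
                      "fibers: lengths in um; rel_length = L(t)/L(0); slope in 1/s")
    if (!is.null(col))
      write_table_csv(col, file.path(out_dir, "coloc.csv"),
                      "Pearson correlation over masked pixels, no threshold")
  }
  list(metrics = metrics, rose = rose, fibers = fib, coloc = col)
}
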