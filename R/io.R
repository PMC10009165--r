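#' Read and write 16-bit PGM images
#'
#' Binary (P5) NetPBM grayscale with maxval 65535, the package's on-disk
#' image format.  Pixel (1,1) is the top-left corner; matrix rows are image
#' rows.
#'
#' @param path file path.
#' @return `read_pgm`: an integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "[[:space:]]+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  if (tok[1] != "P5") stop("read_pgm: not a binary PGM (P5) file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  size <- if (maxval > 255) 2L else 1L
  v <- readBin(con, "integer", n = w * h, size = size, signed = FALSE,
               endian = "big")
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' @param img numeric matrix with values in [0, 65535] (rounded on write).
#' @rdname read_pgm
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.integer(round(t(img))), con, size = 2L, endian = "big")
  invisible(path)
}

# write a data.frame with a units/conventions comment header
write_table_csv <- function(df, path, comment) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' CSV with columns track_id, frame, t_min, x_um, y_um (times in minutes,
#' positions in micrometers).  Reading validates every row and reports the
#' 1-based file line of the first malformed one.
#'
#' @param tracks data.frame of tracks.
#' @param path file path.
#' @return `read_tracks_csv`: the validated data.frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  write_table_csv(tracks[, c("track_id", "frame", "t_min", "x_um", "y_um")],
                  path,
                  "tracks: t_min in minutes; x_um, y_um in micrometers")
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  raw <- readLines(path)
  body <- !grepl("^#", raw)
  df <- utils::read.csv(textConnection(raw[body]), stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("read_tracks_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cl in need) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad) > 0) {
      line_no <- which(body)[bad[1] + 1L]  # +1 for the header line
      stop("read_tracks_csv: malformed value in column '", cl,
           "' at file line ", line_no)
    }
    df[[cl]] <- v
  }
  df
}

#' Write a synthetic scene to disk
#'
#' Writes image.pgm (16-bit grayscale), labels.pgm (integer label map),
#' truth.csv (object_id, class, centroid, area; 0-based row/col coordinates,
#' origin top-left) and params.json (generation-parameter echo, including
#' the seed).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm(scene$image, file.path(dir, "image.pgm"))
  write_pgm(scene$truth_labels, file.path(dir, "labels.pgm"))
  tr <- scene$truth
  tr$centroid_row <- tr$centroid_row - 1
  tr$centroid_col <- tr$centroid_col - 1
  write_table_csv(tr, file.path(dir, "truth.csv"),
                  "truth objects: centroid_row/centroid_col 0-based px, origin top-left; area_px in px; geom: class-specific size (px, rings: outer diameter px)")
  echo <- scene$params
  class(echo) <- NULL
  echo$seed <- scene$seed
  echo$realized <- scene$realized
  jsonlite::write_json(echo, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export segmented objects to CSV
#'
#' One row per object: frame/image id, object_id, area_px, centroid and
#' bounding box in 0-based (row, col) pixel coordinates, origin top-left.
#'
#' @param objects list of `structure_object`s.
#' @param path file path.
#' @param image_id identifier written to the image_id column.
#' @return the path, invisibly.
#' @export
write_objects_csv <- function(objects, path, image_id = 1L) {
  df <- do.call(rbind, lapply(objects, function(o)
    data.frame(image_id = image_id, object_id = o$object_id,
               area_px = o$area,
               centroid_row = o$centroid[["row"]] - 1,
               centroid_col = o$centroid[["col"]] - 1,
               bbox_rmin = o$bbox[["rmin"]] - 1L,
               bbox_rmax = o$bbox[["rmax"]] - 1L,
               bbox_cmin = o$bbox[["cmin"]] - 1L,
               bbox_cmax = o$bbox[["cmax"]] - 1L)))
  if (is.null(df)) df <- data.frame(image_id = integer(0))
  write_table_csv(df, path,
                  "objects: 0-based (row, col) px coordinates, origin top-left; areas in px")
}
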