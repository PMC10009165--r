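# Independent brute-force oracles.  These deliberately avoid the package's
# compiled code paths: set morphology by offset enumeration, DFTs by direct
# summation, DBSCAN by boolean reachability closure.

brute_disk_offsets <- function(radius) {
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

brute_erode <- function(mask, radius) {
  off <- brute_disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    rr <- r + off$dr; cc <- c + off$dc
    inside <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[r, c] <- all(inside) && all(mask[cbind(rr, cc)])
  }
  out
}

brute_dilate <- function(mask, radius) {
  off <- brute_disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    rr <- r + off$dr; cc <- c + off$dc
    keep <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

brute_opening <- function(mask, radius) brute_dilate(brute_erode(mask, radius), radius)

# direct DFT, 1/N normalization (matches the feature definitions)
brute_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)) / N, complex(1))
}

# distance of every pixel to the nearest TRUE pixel, by enumeration
brute_edt <- function(mask) {
  ft <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(ft) == 0) return(out)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    out[r, c] <- sqrt(min((ft[, 1] - r)^2 + (ft[, 2] - c)^2))
  out
}

# DBSCAN by reachability closure: core points from neighbor counts, clusters
# as fixed-point closure of core-core adjacency, borders to nearest core.
brute_dbscan <- function(Z, eps, min_pts) {
  n <- nrow(Z)
  D <- as.matrix(stats::dist(Z))
  A <- D <= eps + 1e-12
  core <- rowSums(A) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  Acc <- A & outer(core, core, "&")
  # transitive closure by repeated boolean multiplication
  R <- Acc | diag(n)
  repeat {
    R2 <- (R %*% R) > 0
    if (all(R2 == R)) break
    R <- R2
  }
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[core & R[i, ]] <- cl
  }
  for (i in which(!core)) {
    cand <- which(core & A[i, ])
    if (length(cand) == 0) next
    labels[i] <- labels[cand[which.min(D[i, cand])]]
  }
  labels
}

# canonical form of a labeling: clusters renumbered by first appearance
canon_labels <- function(labels) {
  out <- labels
  nxt <- 0L
  seen <- c()
  for (i in seq_along(labels)) {
    if (labels[i] == -1L) next
    if (!labels[i] %in% seen) {
      seen <- c(seen, labels[i])
    }
  }
  map <- stats::setNames(seq_along(seen), seen)
  out[labels != -1L] <- map[as.character(labels[labels != -1L])]
  out
}

# pixel mask helpers -------------------------------------------------------

disk_mask <- function(r, pad = 2, n = 2 * (ceiling(r) + pad) + 1) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(a, b) (a - ctr)^2 + (b - ctr)^2 <= r^2)
}

annulus_mask <- function(r_out, r_in, pad = 2) {
  n <- 2 * (ceiling(r_out) + pad) + 1
  disk_mask(r_out, n = n) & !disk_mask(r_in, n = n)
}

place_blob <- function(mask, rows, cols) {
  mask[cbind(rows, cols)] <- TRUE
  mask
}

lin_to_rc <- function(lin, nr) cbind(((lin - 1L) %% nr) + 1L,
                                     ((lin - 1L) %/% nr) + 1L)

# truth-class lookup and batch evaluation ----------------------------------

truth_classes_of <- function(scenes, result) {
  cls <- character(0)
  for (i in seq_along(scenes)) {
    for (o in result$objects[[i]]) {
      l <- scenes[[i]]$truth_labels[o$pixels]
      l <- l[l > 0]
      cls <- c(cls, if (length(l) > 0)
        scenes[[i]]$truth_classes[[as.character(l[1])]] else NA_character_)
    }
  }
  cls
}

# Object-level purity and area-fraction recovery for a classified scene
# batch.  Truth classes are mapped many-to-one onto merged classes by
# majority vote; purity is the share of classified objects whose merged
# class equals their truth class's image; fraction errors compare the truth
# area mixture (through the same mapping) with the estimated per-image
# profiles.
eval_class_recovery <- function(scenes, result) {
  cls <- truth_classes_of(scenes, result)
  use <- !result$features$excluded
  m <- result$classes$merged
  classified <- m != -1L
  map <- vapply(split(m[classified], cls[use][classified]),
                function(v) as.integer(names(which.max(table(v)))), 1L)
  purity <- mean(m[classified] == map[cls[use][classified]])
  errs <- c()
  groups <- sort(unique(m[classified]))
  for (i in seq_along(scenes)) {
    tr <- scenes[[i]]$truth
    gen <- vapply(groups, function(g)
      sum(tr$area_px[map[tr$class] == g]) / sum(tr$area_px), 0)
    est <- vapply(groups, function(g) {
      v <- result$profiles[i, paste0("class_", g)]
      if (is.null(v) || length(v) == 0) 0 else as.numeric(v)
    }, 0)
    errs <- c(errs, abs(gen - est))
  }
  list(purity = purity, max_fraction_error = max(errs))
}

# The default synthetic batch for end-to-end checks: 10 scenes drawn from
# three condition archetypes, mirroring the phenotypes the pipeline is meant
# to distinguish (filament-rich control-like cells, fragmented
# knockdown-like cells, ring-rich inhibitor-like cells), each with per-scene
# intensity jitter.  Structured mixtures like these are what make class
# merging by area-fraction co-alignment identifiable.
acceptance_batch <- function(n_scenes = 10, base_seed = 500) {
  arch <- list(c(dot = 150, fragment = 60, filament = 48, ring = 12),
               c(dot = 230, fragment = 140, filament = 12, ring = 9),
               c(dot = 120, fragment = 60, filament = 16, ring = 54))
  kind <- rep(1:3, length.out = n_scenes)
  withr::with_seed(11, lapply(seq_len(n_scenes), function(i) {
    cnt <- round(arch[[kind[i]]] * runif(1, 0.7, 1.3) *
                   runif(4, 0.85, 1.15))
    gen_structure_scene(scene_params(counts = cnt), seed = base_seed + i)
  }))
}
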