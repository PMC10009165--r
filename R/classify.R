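#' Principal-component reduction of the feature space
#'
#' Fits a PCA to the standardized feature matrix and keeps the smallest
#' number of leading components whose cumulative explained variance reaches
#' `var_target` (0.90 in the original analysis, where 17 components were
#' kept).
#'
#' @param X standardized feature matrix (rows = objects).
#' @param var_target cumulative explained-variance target in (0, 1].
#' @return object of class `pca_basis`: list(rotation, center, ev_ratio,
#'   n_kept, scores) where `scores` holds the projections of all rows onto
#'   the kept components.
#' @export
fit_pca <- function(X, var_target = 0.90) {
  if (var_target <= 0 || var_target > 1)
    stop("fit_pca: var_target must lie in (0, 1]")
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fit_pca: need at least 2 rows")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  n_kept <- which(cumsum(ev) >= var_target - 1e-12)[1]
  structure(list(rotation = p$rotation, center = p$center, ev_ratio = ev,
                 n_kept = n_kept,
                 scores = p$x[, seq_len(n_kept), drop = FALSE]),
            class = "pca_basis")
}

# Neighbor lists within eps (self included), computed in row blocks to bound
# memory.
eps_neighbors <- function(Z, eps, block = 512L) {
  n <- nrow(Z)
  nb <- vector("list", n)
  sq <- rowSums(Z^2)
  eps2 <- eps^2
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    D2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(Z[s:e, , drop = FALSE], Z)
    for (i in s:e) nb[[i]] <- which(D2[i - s + 1L, ] <= eps2 + 1e-12)
  }
  nb
}

#' DBSCAN clustering
#'
#' Standard density-based clustering with the Euclidean metric: a core point
#' has at least `min_pts` neighbors within `eps` (itself included); clusters
#' are the connected components of the core-core neighborhood graph; border
#' points (non-core points with a core within `eps`) are attached to the
#' cluster of their nearest core, which makes the partition independent of
#' the input order; everything else is noise, labeled -1.
#'
#' @param Z numeric matrix of projected coordinates (rows = points).
#' @param eps neighborhood radius (> 0); 2 in the original analysis.
#' @param min_pts core threshold (>= 1); 3 in the original analysis.
#' @return integer vector of labels: 1..k for clusters, -1 for noise.
#' @export
cluster_dbscan <- function(Z, eps = 2, min_pts = 3L) {
  stopifnot(eps > 0, min_pts >= 1)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n == 0) return(integer(0))
  nb <- eps_neighbors(Z, eps)
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      cand <- nb[[j]]
      cand <- cand[core[cand] & labels[cand] == -1L]
      labels[cand] <- cl
      queue <- c(queue, cand)
    }
  }
  # border points: nearest core within eps decides
  for (i in which(!core)) {
    cores_near <- nb[[i]][core[nb[[i]]]]
    if (length(cores_near) == 0) next
    d2 <- rowSums((Z[cores_near, , drop = FALSE] -
                   matrix(Z[i, ], length(cores_near), ncol(Z), byrow = TRUE))^2)
    labels[i] <- labels[cores_near[which.min(d2)]]
  }
  labels
}

#' Sample bimodality coefficient
#'
#' b = (skewness^2 + 1) / kurtosis with plain moment estimators (kurtosis is
#' non-excess, so a Gaussian gives b ~ 1/3).  Values above 5/9 suggest
#' bimodality.
#'
#' @param x numeric vector.
#' @return the coefficient, or NA for degenerate input.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2
  (g1^2 + 1) / kurt
}

# 1-D two-component Gaussian mixture by EM with random restarts.  Returns the
# component assignment (1 = smaller mean, 2 = larger mean).
gmm1d_split <- function(x, restarts = 10L, seed = 1L, max_iter = 200L,
                        tol = 1e-8) {
  n <- length(x)
  with_seed(seed, {
    best <- NULL; best_ll <- -Inf
    for (r in seq_len(restarts)) {
      mu <- sort(sample(x, 2))
      if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * (stats::sd(x) / 10 + 1e-6)
      s2 <- rep(stats::var(x) / 2 + 1e-12, 2)
      w <- c(0.5, 0.5)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
        d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        g <- d1 / tot
        ll <- sum(log(tot))
        if (abs(ll - ll_old) < tol) break
        ll_old <- ll
        n1 <- sum(g); n2 <- n - n1
        if (n1 < 1e-8 || n2 < 1e-8) break
        mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
        s2 <- c(sum(g * (x - mu[1])^2) / n1,
                sum((1 - g) * (x - mu[2])^2) / n2)
        s2 <- pmax(s2, 1e-12)
        w <- c(n1, n2) / n
      }
      if (ll_old > best_ll) {
        best_ll <- ll_old
        best <- list(mu = mu, s2 = s2, w = w)
      }
    }
    d1 <- best$w[1] * stats::dnorm(x, best$mu[1], sqrt(best$s2[1]))
    d2 <- best$w[2] * stats::dnorm(x, best$mu[2], sqrt(best$s2[2]))
    comp <- ifelse(d2 > d1, 2L, 1L)
    if (best$mu[1] > best$mu[2]) comp <- 3L - comp
    comp
  })
}

#' Bimodality-driven class refinement
#'
#' Optional stage (used for Cdc42ep1 data in the original analysis).  Among
#' the `top_k` classes with the largest mean object area, each class's most
#' bimodal principal component is identified with the bimodality coefficient
#' (cutoff 5/9); classes below the cutoff are left intact.  Of the classes
#' passing the cutoff, the two most populated are split by a two-component
#' Gaussian mixture on that component (fixed seed, 10 restarts); the rest
#' are split by Otsu thresholding of the component values.  Classes with
#' fewer than 6 members are never split.
#'
#' @param labels integer labels from [cluster_dbscan()] (-1 = noise).
#' @param Z projected coordinates used for clustering.
#' @param areas per-object areas (px), aligned with `labels`.
#' @param top_k number of largest-area classes examined (default 5).
#' @param seed RNG seed for the mixture fits.
#' @param cutoff bimodality cutoff (default 5/9).
#' @return integer vector of refined labels; new classes get fresh ids.
#' @export
refine_classes <- function(labels, Z, areas, top_k = 5L, seed = 1L,
                           cutoff = 5 / 9) {
  Z <- as.matrix(Z)
  stopifnot(length(labels) == nrow(Z), length(areas) == nrow(Z))
  classes <- sort(unique(labels[labels != -1L]))
  if (length(classes) == 0) return(labels)
  mean_area <- vapply(classes, function(k) mean(areas[labels == k]), 0)
  cand <- classes[order(mean_area, decreasing = TRUE)]
  cand <- utils::head(cand, top_k)
  pop <- vapply(cand, function(k) sum(labels == k), 0L)
  gmm_classes <- cand[order(pop, decreasing = TRUE)][seq_len(min(2L, length(cand)))]

  refined <- labels
  next_id <- max(labels) + 1L
  for (k in cand) {
    members <- which(labels == k)
    if (length(members) < 6) next
    b <- apply(Z[members, , drop = FALSE], 2, bimodality_coefficient)
    if (all(!is.finite(b))) next
    pc <- which.max(b)
    if (b[pc] <= cutoff) next
    v <- Z[members, pc]
    if (k %in% gmm_classes) {
      comp <- gmm1d_split(v, restarts = 10L, seed = seed + k)
    } else {
      thr <- otsu_threshold(v)
      comp <- ifelse(v > thr, 2L, 1L)
    }
    if (length(unique(comp)) < 2) next
    refined[members[comp == 2L]] <- next_id
    next_id <- next_id + 1L
  }
  refined
}

#' Merge fine classes by co-alignment of area-fraction loadings
#'
#' PCA is applied to the images-by-fine-classes area-fraction matrix; each
#' fine class is represented by its loading vector in the (PC1, PC2) plane,
#' normalized to unit length, and fine classes are grouped into `k` merged
#' classes by average-linkage hierarchical clustering of the cosine distance
#' (1 - dot product) between those unit vectors.  Classes whose fraction
#' columns are identical have identical loadings and always merge.
#'
#' @param fractions numeric matrix: rows = images, columns = fine classes
#'   (column names are the fine class ids), entries = per-image area
#'   fractions.
#' @param k number of merged classes (default 3).
#' @param geometry optional data.frame with per-fine-class summary columns
#'   (e.g. mean_area, mean_eccentricity), rownames = fine class ids; used
#'   only to attach advisory names to the merged groups.
#' @return object of class `class_merge`: list(mapping = named integer
#'   vector fine id -> merged group, group_summary).
#' @export
merge_classes <- function(fractions, k = 3L, geometry = NULL) {
  fractions <- as.matrix(fractions)
  fine <- colnames(fractions)
  if (is.null(fine)) fine <- as.character(seq_len(ncol(fractions)))
  if (ncol(fractions) < k) {
    warning("merge_classes: fewer fine classes than merged_k; identity mapping")
    mapping <- stats::setNames(seq_len(ncol(fractions)), fine)
    return(structure(list(mapping = mapping, group_summary = NULL),
                     class = "class_merge"))
  }
  if (nrow(fractions) < 3)
    stop("merge_classes: need at least 3 images")
  p <- stats::prcomp(fractions, center = TRUE, scale. = FALSE)
  nc <- min(2L, ncol(p$rotation))
  L <- p$rotation[, seq_len(nc), drop = FALSE]
  nrm <- sqrt(rowSums(L^2))
  nrm[nrm == 0] <- 1
  U <- L / nrm
  D <- 1 - tcrossprod(U)
  D[D < 0] <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  grp <- stats::cutree(hc, k = k)
  mapping <- stats::setNames(as.integer(grp), fine)
  group_summary <- NULL
  if (!is.null(geometry)) {
    geometry <- geometry[fine, , drop = FALSE]
    group_summary <- do.call(rbind, lapply(sort(unique(mapping)), function(g) {
      gm <- colMeans(geometry[mapping == g, , drop = FALSE], na.rm = TRUE)
      data.frame(group = g, t(gm))
    }))
    # advisory names by mean-area ranking: smallest = dots/small clusters,
    # largest = filaments/aggregates (septin vocabulary)
    if ("mean_area" %in% names(group_summary) && nrow(group_summary) == 3) {
      ord <- order(group_summary$mean_area)
      nm <- c("dots_small_clusters", "fragments", "filaments_aggregates")
      group_summary$name[ord] <- nm
    }
  }
  structure(list(mapping = mapping, group_summary = group_summary),
            class = "class_merge")
}

#' Per-image class area fractions
#'
#' For every merged class, the total area of its objects divided by the
#' total area of all classified objects of the image (so fractions sum to
#' 1).  Noise objects (label -1) are excluded from the fractions and their
#' area share of *all* objects is reported separately.
#'
#' @param merged integer vector of merged class labels per object (-1 =
#'   noise / unclassified).
#' @param areas numeric vector of object areas (px), aligned with `merged`.
#' @param classes class ids to report (default: sorted ids present anywhere;
#'   pass the full set to make profiles comparable across images).
#' @return object of class `class_profile`: list(fractions, noise_fraction,
#'   undefined).
#' @export
area_fractions <- function(merged, areas, classes = NULL) {
  stopifnot(length(merged) == length(areas))
  if (is.null(classes)) classes <- sort(unique(merged[merged != -1L]))
  classified <- merged != -1L
  tot_all <- sum(areas)
  tot_cls <- sum(areas[classified])
  if (tot_cls == 0) {
    return(structure(list(fractions = stats::setNames(
      rep(NA_real_, length(classes)), classes),
      noise_fraction = if (tot_all > 0) 1 else NA_real_,
      undefined = TRUE), class = "class_profile"))
  }
  fr <- vapply(classes, function(k) sum(areas[merged == k]) / tot_cls, 0)
  structure(list(fractions = stats::setNames(fr, classes),
                 noise_fraction = sum(areas[!classified]) / tot_all,
                 undefined = FALSE),
            class = "class_profile")
}
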