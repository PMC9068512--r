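# Conformational-cluster identification: coarse k-means on gate RMSD,
# t-SNE embedding of mixed angle/distance features, mean-shift seeding
# with an intentionally small bandwidth, two-cutoff hierarchical
# merging, circular cluster statistics and representative-frame
# selection.

#' Circular mean of angles in degrees
#' @param x Angles in degrees.
#' @return Mean direction in degrees in (-180, 180].
#' @export
circular_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular standard deviation of angles in degrees
#'
#' `sqrt(-2 log Rbar)` (radians) converted to degrees, where `Rbar` is
#' the mean resultant length.
#' @param x Angles in degrees.
#' @export
circular_sd <- function(x) {
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(max(rbar, 1e-300))) * 180 / pi
}

#' k-means clustering of gate conformations
#'
#' On a numeric feature matrix this is standard k-means (k-means++
#' style multi-start under the given seed, Euclidean metric).  On a
#' 3-D coordinate array (frames x atoms x 3) the metric is the gate
#' RMSD after per-pair optimal superposition, with Lloyd iterations in
#' which each centroid is the coordinate mean of its members after
#' superposing them onto the centroid.
#'
#' @param x Numeric matrix (frames x features) or 3-D array
#'   (frames x atoms x 3).
#' @param k Number of clusters (default 10).
#' @param seed Integer RNG seed.
#' @param max_iter Lloyd iteration cap.
#' @return List: `cluster` (per-frame id), `centers`, `sizes`.
#' @export
kmeans_gate <- function(x, k = 10, seed = 1L, max_iter = 100) {
  if (is.matrix(x)) {
    if (k > nrow(x)) stop("kmeans_gate: k exceeds number of frames")
    km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 10,
                                        iter.max = max_iter))
    return(list(cluster = km$cluster, centers = km$centers,
                sizes = as.integer(km$size)))
  }
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  n <- dim(x)[1]
  if (k > n) stop("kmeans_gate: k exceeds number of frames")
  dist_to <- function(i, cen) superpose_rmsd(x[i, , ], cen)
  with_seed(seed, {
    # k-means++ seeding under the RMSD metric
    cen_idx <- sample.int(n, 1)
    d2 <- vapply(seq_len(n), function(i) dist_to(i, x[cen_idx[1], , ])^2,
                 numeric(1))
    while (length(cen_idx) < k) {
      p <- d2 / sum(d2)
      nxt <- sample.int(n, 1, prob = p)
      cen_idx <- c(cen_idx, nxt)
      d2 <- pmin(d2, vapply(seq_len(n),
                            function(i) dist_to(i, x[nxt, , ])^2, numeric(1)))
    }
    centers <- lapply(cen_idx, function(i) x[i, , ])
    assign <- integer(n)
    for (iter in seq_len(max_iter)) {
      newass <- vapply(seq_len(n), function(i) {
        which.min(vapply(centers, function(cen) dist_to(i, cen), numeric(1)))
      }, integer(1))
      if (identical(newass, assign)) break
      assign <- newass
      for (c_ in seq_len(k)) {
        mem <- which(assign == c_)
        if (!length(mem)) next
        cen <- centers[[c_]]
        acc <- matrix(0, dim(x)[2], 3)
        for (i in mem) {
          xi <- x[i, , ]
          xc <- sweep(xi, 2, colMeans(xi))
          cc <- sweep(cen, 2, colMeans(cen))
          acc <- acc + xc %*% kabsch_rotation(xc, cc)
        }
        centers[[c_]] <- acc / length(mem)
      }
    }
    list(cluster = assign, centers = centers,
         sizes = as.integer(tabulate(assign, k)))
  })
}

#' t-SNE embedding of encoded gate features
#'
#' Exact-gradient t-distributed stochastic neighbour embedding into two
#' dimensions.  Deterministic under a fixed seed.  The contract on the
#' output is neighbourhood preservation -- for well-separated planted
#' clusters, nearest neighbours in the embedding share the cluster --
#' not any particular layout.
#'
#' @param x Encoded numeric matrix (see [encode_features()]).
#' @param perplexity Perplexity (default 30); at least 3 * perplexity
#'   points are required.
#' @param seed Integer RNG seed (default 0).
#' @param n_iter Gradient-descent iterations.
#' @param learning_rate,exaggeration Standard t-SNE tuning constants;
#'   early exaggeration is applied for the first quarter of the
#'   iterations.
#' @return n x 2 matrix of embedded coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, seed = 0L, n_iter = 400,
                       learning_rate = 200, exaggeration = 12) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (all(apply(x, 2, function(v) max(v) - min(v)) < 1e-12)) {
    warning("tsne_embed: degenerate all-identical input; single-point embedding")
    return(matrix(0, n, 2))
  }
  if (n < 3 * perplexity)
    stop("tsne_embed: need at least 3 * perplexity points (",
         3 * perplexity, "), got ", n)
  with_seed(seed,
            .tsne_cpp(x, perplexity, as.integer(n_iter), learning_rate,
                      exaggeration, as.integer(max(50, n_iter %/% 4))))
}

#' Mean-shift mode seeking on a 2-D embedding
#'
#' Flat-kernel mean shift: every point hill-climbs to a kernel mode;
#' converged modes closer than `bandwidth / 2` are merged.
#'
#' @param points n x 2 matrix.
#' @param bandwidth Kernel radius (> 0), in embedding units.
#' @return List: `centroids` (modes x 2), `labels` (per-point mode id).
#' @export
mean_shift_seed <- function(points, bandwidth) {
  if (bandwidth <= 0) stop("mean_shift_seed: bandwidth must be > 0")
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  .mean_shift_cpp(points, bandwidth, 500L, 1e-7)
}

#' Two-cutoff hierarchical merge of seeded clusters
#'
#' Iterates over all pairs of clusters; a pair whose centroids lie
#' within `centroid_cutoff` and whose closest pair of member points
#' lies within `point_cutoff` is merged.  Merging is transitive
#' (union-find) and iterated to a fixed point, so the operation never
#' increases the cluster count and is idempotent once no pair
#' qualifies.  Final labels are alphabetic by descending cluster size.
#'
#' @param points n x 2 embedded coordinates.
#' @param labels Integer seed-cluster ids (from [mean_shift_seed()]).
#' @param centroid_cutoff,point_cutoff Merge cutoffs (> 0) in embedding
#'   units.
#' @return List: `labels` (per-point letter), `sizes` (named, descending),
#'   `centroids` (per final cluster).
#' @export
hierarchical_merge <- function(points, labels, centroid_cutoff,
                               point_cutoff) {
  if (centroid_cutoff <= 0 || point_cutoff <= 0)
    stop("hierarchical_merge: cutoffs must be > 0")
  points <- as.matrix(points)
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  cent <- t(vapply(ids, function(id)
    colMeans(points[labels == id, , drop = FALSE]), numeric(2)))
  repeat {
    merged <- FALSE
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a || find(a) == find(b)) next
        dc <- sqrt(sum((cent[a, ] - cent[b, ])^2))
        if (dc > centroid_cutoff) next
        pa <- points[labels == ids[a], , drop = FALSE]
        pb <- points[labels == ids[b], , drop = FALSE]
        dmin <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                           outer(pa[, 2], pb[, 2], "-")^2))
        if (dmin <= point_cutoff) { union_(a, b); merged <- TRUE }
      }
    }
    if (!merged) break
  }
  root <- vapply(seq_along(ids), find, integer(1))
  grp <- root[match(labels, ids)]
  sizes <- sort(table(grp), decreasing = TRUE)
  letters_ext <- c(letters, as.vector(outer(letters, letters, paste0)))
  lab_map <- stats::setNames(letters_ext[seq_along(sizes)], names(sizes))
  out_labels <- unname(lab_map[as.character(grp)])
  cent_out <- t(vapply(names(sizes), function(g)
    colMeans(points[grp == as.integer(g), , drop = FALSE]), numeric(2)))
  rownames(cent_out) <- unname(lab_map[names(sizes)])
  list(labels = out_labels,
       sizes = stats::setNames(as.integer(sizes), unname(lab_map[names(sizes)])),
       centroids = cent_out)
}

#' Per-cluster feature statistics
#'
#' Mean and standard deviation of every feature within every cluster,
#' computed on the circle (angular mean, angular SD
#' `sqrt(-2 log Rbar)`) for angular features and in the ordinary way
#' for distances.
#'
#' @param features Raw feature matrix (frames x features).
#' @param labels Per-frame cluster labels.
#' @param angular_cols Names/indices of angular columns (degrees).
#' @return data.frame: cluster, feature, mean, sd, circular, n.
#' @export
cluster_stats <- function(features,
                          labels,
                          angular_cols = grepl("^chi", colnames(features))) {
  features <- as.matrix(features)
  if (is.character(angular_cols))
    angular_cols <- colnames(features) %in% angular_cols
  if (is.numeric(angular_cols))
    angular_cols <- seq_len(ncol(features)) %in% angular_cols
  out <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    if (!any(sel)) stop("cluster_stats: empty cluster ", cl)
    for (j in seq_len(ncol(features))) {
      x <- features[sel, j]
      circ <- angular_cols[j]
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, feature = colnames(features)[j],
        mean = if (circ) circular_mean(x) else mean(x),
        sd = if (circ) circular_sd(x) else stats::sd(x),
        circular = circ, n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Representative frame of a cluster
#'
#' The member frame whose raw feature vector is closest, in a
#' periodicity-aware Euclidean distance (angular coordinates compared
#' on the circle), to the cluster's mean feature vector (circular means
#' for angles).  Ties break to the earliest frame.
#'
#' @inheritParams cluster_stats
#' @return Named integer vector: representative frame index per
#'   cluster.
#' @export
representative_frame <- function(features, labels,
                                 angular_cols = grepl("^chi", colnames(features))) {
  features <- as.matrix(features)
  if (is.character(angular_cols))
    angular_cols <- colnames(features) %in% angular_cols
  if (is.numeric(angular_cols))
    angular_cols <- seq_len(ncol(features)) %in% angular_cols
  reps <- integer(0)
  for (cl in sort(unique(labels))) {
    sel <- which(labels == cl)
    if (!length(sel)) stop("representative_frame: empty cluster ", cl)
    ctr <- vapply(seq_len(ncol(features)), function(j) {
      x <- features[sel, j]
      if (angular_cols[j]) circular_mean(x) else mean(x)
    }, numeric(1))
    d2 <- vapply(sel, function(i) {
      diff <- features[i, ] - ctr
      diff[angular_cols] <- angle_diff(features[i, angular_cols], ctr[angular_cols])
      sum(diff^2)
    }, numeric(1))
    reps[as.character(cl)] <- sel[which.min(d2)]   # which.min: earliest tie
  }
  reps
}

#' Full unsupervised cluster identification
#'
#' Chains the pipeline: encode mixed features, embed with t-SNE, seed
#' clusters by mean-shift with a small bandwidth (a fraction of the
#' embedding bounding-box diagonal), merge with the two-cutoff
#' hierarchical rule, then compute circular statistics and
#' representative frames.
#'
#' @param features Raw feature matrix (frames x features).
#' @param angular_cols Names/indices of angular columns (degrees).
#' @param perplexity,seed,n_iter Passed to [tsne_embed()].  The default
#'   perplexity (100) is chosen for state recovery: smaller values let
#'   the exact-gradient embedding fragment a single conformational
#'   state into several islands.  It is reduced automatically when
#'   fewer than `3 * perplexity` points are embedded.
#' @param bandwidth_frac Mean-shift bandwidth as a fraction of the
#'   embedding bounding-box diagonal (default 0.02).
#' @param centroid_mult,point_mult Merge cutoffs as multiples of the
#'   bandwidth (defaults 4 and 1).
#' @param max_embed Frame count above which the embedding runs on a
#'   seeded landmark subset of this size, with the remaining frames
#'   assigned to the cluster of their nearest landmark in encoded
#'   feature space (default 2000).  Exact-gradient t-SNE is quadratic
#'   in the number of points, so this bounds the cost on long
#'   trajectories without changing the cluster structure of
#'   well-separated states.
#' @param min_cluster_frac Merged clusters holding fewer than this
#'   fraction of the embedded points (default 2%, at least 3 points)
#'   are treated as stray embedding islets rather than conformational
#'   states and dissolved into the nearest retained cluster; a state
#'   must occupy at least this fraction of frames to be reported.
#' @return Object of class `cluster_set`: per-frame `labels`, `sizes`,
#'   `stats`, `representative`, `embedding` (landmark frames only when
#'   landmarking is active), plus the parameters used.
#' @export
identify_clusters <- function(features,
                              angular_cols = grepl("^chi", colnames(features)),
                              perplexity = 100, seed = 0L, n_iter = 300,
                              bandwidth_frac = 0.02,
                              centroid_mult = 4, point_mult = 1,
                              max_embed = 2000, min_cluster_frac = 0.02) {
  enc <- encode_features(features, angular_cols)
  n <- nrow(enc)
  land <- if (n > max_embed)
    with_seed(seed, sort(sample.int(n, max_embed))) else seq_len(n)
  perp <- min(perplexity, floor((length(land) - 1) / 3))
  emb <- tsne_embed(enc[land, , drop = FALSE], perplexity = perp,
                    seed = seed, n_iter = n_iter)
  diag_len <- sqrt(sum((apply(emb, 2, max) - apply(emb, 2, min))^2))
  bw <- max(bandwidth_frac * diag_len, 1e-8)
  seeds <- mean_shift_seed(emb, bw)
  mg <- hierarchical_merge(emb, seeds$labels, centroid_mult * bw,
                           point_mult * bw)
  land_labels <- mg$labels
  # orphan handling: clusters supported by almost no points are stray
  # mean-shift modes, not conformational states; their members join
  # the nearest retained cluster
  floor_n <- max(3L, ceiling(min_cluster_frac * length(land)))
  sz0 <- table(land_labels)
  small <- names(sz0)[sz0 < floor_n]
  big <- setdiff(names(sz0), small)
  if (length(small) && length(big)) {
    keep_idx <- which(land_labels %in% big)
    stray <- which(land_labels %in% small)
    nn <- .nearest_ref_cpp(emb[stray, , drop = FALSE],
                           emb[keep_idx, , drop = FALSE])
    land_labels[stray] <- land_labels[keep_idx[nn]]
  }
  labels <- character(n)
  labels[land] <- land_labels
  if (length(land) < n) {
    rest <- setdiff(seq_len(n), land)
    nearest <- .nearest_ref_cpp(enc[rest, , drop = FALSE],
                                enc[land, , drop = FALSE])
    labels[rest] <- land_labels[nearest]
  }
  # re-letter alphabetically by descending full-membership size
  sz <- sort(table(labels), decreasing = TRUE)
  letters_ext <- c(letters, as.vector(outer(letters, letters, paste0)))
  remap <- stats::setNames(letters_ext[seq_along(sz)], names(sz))
  labels <- unname(remap[labels])
  sizes <- sort(table(labels), decreasing = TRUE)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  st <- cluster_stats(features, labels, angular_cols)
  reps <- representative_frame(features, labels, angular_cols)
  structure(list(labels = labels, sizes = sizes,
                 stats = st, representative = reps, embedding = emb,
                 landmarks = land, bandwidth = bw,
                 params = list(perplexity = perplexity, seed = seed,
                               n_iter = n_iter,
                               bandwidth_frac = bandwidth_frac,
                               centroid_mult = centroid_mult,
                               point_mult = point_mult,
                               max_embed = max_embed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d frames in %d clusters (bandwidth %.3g)\n",
              length(x$labels), length(x$sizes), x$bandwidth))
  print(x$sizes)
  invisible(x)
}
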