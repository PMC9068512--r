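test_that("circular statistics match closed forms exactly", {
  expect_equal(circular_mean(c(359, 1)), 0, tolerance = 1e-9)
  expect_equal(circular_mean(c(90)), 90, tolerance = 1e-12)
  expect_equal(circular_sd(c(90)), 0, tolerance = 1e-9)
  expect_equal(circular_sd(c(0, 90)),
               sqrt(-2 * log(cos(pi / 4))) * 180 / pi, tolerance = 1e-9)
  expect_equal(circular_mean(c(179, -179)), 180, tolerance = 1e-9)
})

test_that("k-means on features recovers planted partitions", {
  set.seed(31)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 8), ncol = 2))
  truth <- rep(1:2, each = 100)
  one <- kmeans_gate(x, k = 1, seed = 1)
  expect_equal(as.numeric(one$centers), colMeans(x), tolerance = 1e-9)
  two <- kmeans_gate(x, k = 2, seed = 1)
  expect_equal(label_purity(two$cluster, truth), 1)
  # duplication invariance: same structure, doubled counts
  dup <- kmeans_gate(rbind(x, x), k = 2, seed = 1)
  expect_equal(sort(dup$sizes), sort(two$sizes) * 2)
  expect_equal(label_purity(dup$cluster, rep(truth, 2)), 1)
  expect_error(kmeans_gate(x, k = 500), "exceeds")
})

test_that("coordinate k-means under the RMSD metric separates gate shapes", {
  open_ <- gen_gate_geometry(toy_gate_spec(
    bend_flags = c(FALSE, TRUE, FALSE, TRUE), bend_offset = 3))
  closed <- gen_gate_geometry(toy_gate_spec())
  sel <- select_atoms(closed, resno = 614:625, elety = "CA")
  arr <- array(0, c(40, length(sel), 3))
  truth <- rep(1:2, each = 20)
  set.seed(32)
  for (i in 1:40) {
    base <- if (truth[i] == 1) closed else open_
    arr[i, , ] <- as.matrix(base[sel, c("x", "y", "z")]) +
      matrix(rnorm(3 * length(sel), sd = 0.05), ncol = 3)
  }
  km <- kmeans_gate(arr, k = 2, seed = 2)
  expect_equal(label_purity(km$cluster, truth), 1)
})

test_that("the embedding is deterministic and preserves neighbourhoods", {
  set.seed(33)
  x <- rbind(matrix(rnorm(900, 0, 1), ncol = 3),
             matrix(rnorm(900, 10, 1), ncol = 3),
             matrix(rnorm(900, 0, 1), ncol = 3) +
               matrix(c(0, 0, 20), 300, 3, byrow = TRUE))
  truth <- rep(1:3, each = 300)
  e1 <- tsne_embed(x, perplexity = 30, seed = 7, n_iter = 250)
  e2 <- tsne_embed(x, perplexity = 30, seed = 7, n_iter = 250)
  expect_identical(e1, e2)
  # nearest-neighbour label agreement >= 0.95
  nn <- apply(as.matrix(dist(e1)), 1, function(d) order(d)[2])
  expect_gte(mean(truth[nn] == truth), 0.95)
  expect_warning(e0 <- tsne_embed(matrix(1, 120, 3)), "degenerate")
  expect_true(all(e0 == 0))
  expect_error(tsne_embed(matrix(rnorm(30), 10, 3), perplexity = 30),
               "at least")
})

test_that("mean-shift finds blob modes and matches a hill-climb oracle", {
  set.seed(34)
  blob <- matrix(rnorm(400, sd = 0.05), ncol = 2)
  ms <- mean_shift_seed(blob, bandwidth = 1)
  expect_equal(nrow(ms$centroids), 1L)
  expect_lt(max(abs(ms$centroids - matrix(colMeans(blob), 1))), 1e-6)
  two <- rbind(blob, sweep(blob, 2, c(-10, 0)))
  ms2 <- mean_shift_seed(two, bandwidth = 1)
  expect_equal(nrow(ms2$centroids), 2L)
  expect_error(mean_shift_seed(blob, bandwidth = 0), "bandwidth")
  # independent flat-kernel hill-climb per point, written in R
  grid <- as.matrix(expand.grid(x = c(0, 0.3, 5, 5.3), y = c(0, 0.3)))
  oracle_modes <- unique(t(apply(grid, 1, function(p) {
    for (i in 1:200) {
      w <- sqrt(colSums((t(grid) - p)^2)) <= 1
      np <- colMeans(grid[w, , drop = FALSE])
      if (sum((np - p)^2) < 1e-18) break
      p <- np
    }
    round(p, 6)
  })))
  msg <- mean_shift_seed(grid, bandwidth = 1)
  expect_equal(nrow(msg$centroids), nrow(oracle_modes))
  expect_equal(msg$centroids[order(msg$centroids[, 1]), ],
               oracle_modes[order(oracle_modes[, 1]), ],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("hierarchical merge applies the two-cutoff rule transitively", {
  set.seed(35)
  a <- matrix(rnorm(100, 0, 0.2), ncol = 2)
  b <- sweep(matrix(rnorm(100, 0, 0.2), ncol = 2), 2, c(3, 0))
  c_ <- sweep(matrix(rnorm(100, 0, 0.2), ncol = 2), 2, c(6, 0))
  far <- sweep(matrix(rnorm(100, 0, 0.2), ncol = 2), 2, c(30, 0))
  pts <- rbind(a, b, c_, far)
  lab <- rep(1:4, each = 50)
  # cutoffs too small: nothing merges
  keep <- hierarchical_merge(pts, lab, centroid_cutoff = 0.5,
                             point_cutoff = 0.1)
  expect_length(keep$sizes, 4L)
  # chain a-b close, b-c close, a-c far: all three merge, far stays
  mg <- hierarchical_merge(pts, lab, centroid_cutoff = 4, point_cutoff = 2.5)
  expect_length(mg$sizes, 2L)
  expect_equal(unname(mg$sizes), c(150L, 50L))
  # merge never increases the count and is idempotent at fixed point
  relab <- match(mg$labels, letters)
  again <- hierarchical_merge(pts, relab, centroid_cutoff = 4,
                              point_cutoff = 2.5)
  expect_length(again$sizes, 2L)
  expect_error(hierarchical_merge(pts, lab, -1, 1), "cutoffs")
})

test_that("cluster statistics are computed per cluster without leakage", {
  feats <- cbind(chi1 = c(359, 1, 90, 90), d = c(1, 3, 10, 12))
  labs <- c("a", "a", "b", "b")
  st <- cluster_stats(feats, labs)
  a_chi <- st[st$cluster == "a" & st$feature == "chi1", ]
  expect_equal(a_chi$mean, 0, tolerance = 1e-9)
  expect_true(a_chi$circular)
  b_d <- st[st$cluster == "b" & st$feature == "d", ]
  expect_equal(b_d$mean, 11)
  expect_equal(b_d$sd, sd(c(10, 12)))
  # recomputing from the raw member rows gives identical numbers
  direct <- circular_mean(feats[labs == "a", "chi1"])
  expect_equal(a_chi$mean, direct)
})

test_that("representative frames minimise periodicity-aware distance", {
  feats <- cbind(chi1 = c(170, -170, 0), d = c(1, 1, 1))
  # circular mean of {170, -170, 0} pulls toward 180; frame 1 or 2 win
  # over frame 3 despite naive arithmetic distance saying otherwise
  rep1 <- representative_frame(feats, rep("a", 3))
  expect_true(rep1[["a"]] %in% 1:2)
  # cluster of one
  expect_equal(unname(representative_frame(feats[3, , drop = FALSE], "z")), 1L)
  # symmetric tie breaks to the earlier frame
  tie <- cbind(chi1 = c(10, -10), d = c(5, 5))
  expect_equal(unname(representative_frame(tie, c("a", "a"))), 1L)
  # exhaustive oracle over members
  set.seed(36)
  f <- cbind(chi1 = runif(40, -180, 180), d = rnorm(40))
  labs <- rep(c("a", "b"), each = 20)
  got <- representative_frame(f, labs)
  for (cl in c("a", "b")) {
    sel <- which(labs == cl)
    ctr <- c(circular_mean(f[sel, 1]), mean(f[sel, 2]))
    d2 <- sapply(sel, function(i) {
      da <- ((f[i, 1] - ctr[1] + 180) %% 360) - 180
      da^2 + (f[i, 2] - ctr[2])^2
    })
    expect_equal(unname(got[[cl]]), sel[which.min(d2)])
  }
})

test_that("the full pipeline recovers well-separated planted clusters", {
  set.seed(37)
  x <- rbind(matrix(rnorm(150 * 11, 0), ncol = 11),
             matrix(rnorm(150 * 11, 10), ncol = 11),
             matrix(rnorm(150 * 11, -10), ncol = 11))
  colnames(x) <- paste0("f", 1:11)
  truth <- rep(1:3, each = 150)
  cs <- identify_clusters(x, angular_cols = rep(FALSE, 11), seed = 1)
  expect_equal(length(cs$sizes), 3L)
  expect_gte(label_purity(cs$labels, truth), 0.99)
})

test_that("a state wrapped across +/-180 degrees stays one cluster", {
  ctr <- rbind(c(chi1_A = 180, d = 10), c(chi1_A = 0, d = 16))
  tj <- gen_state_trajectory(ctr, sticky_transition(2), 600,
                             noise = c(8, 0.3), seed = 9)
  cs <- identify_clusters(tj$features, seed = 2)
  expect_equal(length(cs$sizes), 2L)
  expect_gte(label_purity(cs$labels, tj$labels), 0.99)
})
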