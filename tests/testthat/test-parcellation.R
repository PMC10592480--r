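test_that("assignment solver matches brute-force enumeration", {
  set.seed(21)
  for (n in c(2, 4, 5)) {
    for (rep in 1:20) {
      cost <- matrix(runif(n * n), n)
      got <- solve_assignment(cost)
      expect_true(all(sort(got) == seq_len(n)))
      expect_equal(sum(cost[cbind(seq_len(n), got)]),
                   brute_assignment(cost)$cost, tolerance = 1e-12)
    }
  }
})

test_that("correlation-distance k-means recovers planted blocks", {
  set.seed(22)
  n_per <- 25; Tn <- 300
  lat <- matrix(rnorm(4 * Tn), 4)
  X <- lat[rep(1:4, each = n_per), ] + matrix(rnorm(4 * n_per * Tn, sd = 0.4), 4 * n_per)
  truth <- rep(1:4, each = n_per)

  km <- cluster_hemisphere(X, 4, replicates = 10, seed = 1)
  expect_equal(ari(km$cluster, truth), 1)

  # permuting pixel order gives the identical partition up to relabeling
  perm <- sample(nrow(X))
  km2 <- cluster_hemisphere(X[perm, ], 4, replicates = 10, seed = 1)
  expect_true(same_partition(km2$cluster, truth[perm]))

  # k = 1: single cluster, centroid is the mean trace
  km1 <- cluster_hemisphere(X, 1, replicates = 2, seed = 1)
  expect_true(all(km1$cluster == 1))
  expect_equal(drop(km1$centroids), colMeans(X), tolerance = 1e-12)
})

test_that("mirroring and pairing recover bilateral structure", {
  # perfectly mirror-symmetric data: each ROI pairs with its geometric mirror
  set.seed(23)
  nr <- 12; nc <- 14
  hemi <- hemisphere_columns(nc)
  k <- 4; Tn <- 250
  lat <- matrix(rnorm(k * Tn), k)
  band <- rep(1:k, each = nr / k)        # 4 horizontal bands of left parcels
  labels_left <- matrix(0L, nr, nc)
  labels_left[, hemi$left] <- band
  lab_vec <- as.integer(labels_left[, hemi$left])
  half <- lat[lab_vec, ] + matrix(rnorm(length(lab_vec) * Tn, sd = 0.3),
                                  length(lab_vec))
  cl <- cluster_hemisphere(half, k, replicates = 5, seed = 2)
  labels_left[, hemi$left] <- matrix(cl$cluster, nr)
  # right-hemisphere data = exact mirrored copy of the left data
  left_img_idx <- matrix(seq_len(nr * length(hemi$left)), nr)
  data_right <- half[as.vector(left_img_idx[, rev(seq_along(hemi$left))]), ]
  pm <- mirror_and_pair(labels_left, cl$centroids, data_right, c(nr, nc), seed = 2)

  expect_s3_class(pm, "parcellation_map")
  expect_equal(pm$n_rois, 2 * k)
  # bijection covering all ROIs
  expect_setequal(c(pm$pairs), seq_len(2 * k))
  # pairing correlations are 1 for a mirrored copy
  expect_true(all(pm$provenance$pairing_correlation > 0.999))
  # each right ROI occupies the mirror image of its left partner
  lab <- pm$labels
  for (i in seq_len(k)) {
    left_mask <- lab[, hemi$left] == i
    right_mask <- lab[, rev(hemi$right)] == k + i
    expect_true(all(left_mask == right_mask))
  }
})

test_that("pairing equals the exhaustive assignment oracle", {
  set.seed(24)
  k <- 4; Tn <- 150
  L <- matrix(rnorm(k * Tn), k)
  R <- L[c(2, 4, 1, 3), ] + matrix(rnorm(k * Tn, sd = 0.5), k)
  S <- cor(t(L), t(R))
  got <- solve_assignment(-S)
  expect_equal(got, brute_assignment(-S)$perm)
})

test_that("cluster-count evaluation: exact mixtures, monotonicity, PCA bound", {
  set.seed(25)
  H <- matrix(rnorm(4 * 200), 4)
  W <- matrix(runif(30 * 4), 30)       # nonnegative mixtures
  M <- W %*% H

  ev <- evaluate_cluster_count(M, list(H))
  expect_lt(ev$residual, 1e-12 * sum(M^2))

  # residual nonincreasing over nested centroid sets; PCA explains at least
  # as much as NNLS at matched component count
  noisy <- M + matrix(rnorm(length(M), sd = 0.5), nrow(M))
  sets <- list(H[1:2, ], H[1:3, ], H)
  ev3 <- evaluate_cluster_count(noisy, sets)
  expect_true(all(diff(ev3$residual) <= 1e-8))
  expect_true(all(ev3$pca_varexp >= ev3$nnls_varexp - 1e-10))

  # per-pixel solutions match the projected-gradient oracle
  A <- t(H)
  for (p in c(1, 7, 30)) {
    w_lh <- nnls_solve(A, noisy[p, ])
    w_pg <- proj_grad_nnls(A, noisy[p, ])
    expect_lt(max(abs(w_lh - w_pg)), 1e-6)
  }

  expect_error(evaluate_cluster_count(M, list(rbind(H, 0))), "degenerate")
})

test_that("consensus mode map takes the per-pixel majority after relabeling", {
  set.seed(26)
  lab <- matrix(sample(1:3, 60, replace = TRUE), 6, 10)
  # identical maps: output equals input
  expect_identical(consensus_mode_map(list(lab, lab, lab)), lab)

  # 2 copies of A and a relabeled B: majority = A wherever the copies agree
  labB <- lab
  labB[1, 1:5] <- (lab[1, 1:5] %% 3L) + 1L
  perm <- c(3L, 1L, 2L)
  labB_perm <- matrix(perm[labB], 6, 10)   # same partition, different labels
  out <- consensus_mode_map(list(lab, lab, labB_perm))
  expect_identical(out, lab)

  # counting oracle: per-pixel mode over canonically relabeled maps
  maps <- list(lab, labB, matrix(sample(1:3, 60, replace = TRUE), 6, 10))
  out2 <- consensus_mode_map(maps, quality = c(2, 1, 3))
  # recompute by brute force
  relab <- list(lab, labB, NULL)
  O <- table(factor(maps[[3]], 1:3), factor(lab, 1:3))
  a <- solve_assignment(-unclass(O))
  relab[[3]] <- matrix(a[maps[[3]]], 6, 10)
  for (px in seq_len(60)) {
    votes <- c(relab[[1]][px], relab[[2]][px], relab[[3]][px])
    cnt <- tabulate(votes, 3)
    top <- which(cnt == max(cnt))
    expected <- if (length(top) == 1L) top else {
      ord <- c(2, 1, 3)   # quality order
      votes[ord][votes[ord] %in% top][1]
    }
    expect_equal(out2[px], expected)
  }

  expect_error(consensus_mode_map(list(lab, lab)), "at least 3")
  expect_error(consensus_mode_map(list(lab, lab, lab + 1L)), "n_rois")
})

test_that("subgroup clustering recovers planted blocks and group means", {
  set.seed(27)
  g <- 6; per <- 3; h <- g * per; n <- 2 * h
  # block-diagonal correlation map with 6 blocks per hemisphere
  block <- function() {
    m <- matrix(0.05, h, h)
    for (b in seq_len(g)) {
      idx <- ((b - 1) * per + 1):(b * per)
      m[idx, idx] <- 0.9
    }
    m
  }
  mean_corr <- rbind(cbind(block(), matrix(0.05, h, h)),
                     cbind(matrix(0.05, h, h), block()))
  diag(mean_corr) <- 1
  gs <- group_subregions(mean_corr, g, seed = 1)

  expect_length(gs$groups, n)
  expect_setequal(unique(gs$groups), 1:12)
  # groups equal planted blocks
  planted <- c(rep(1:g, each = per), rep(g + (1:g), each = per))
  expect_true(same_partition(gs$groups, planted))

  # reduced rows are exact group means
  for (grp in 1:12) {
    expect_equal(gs$reduced[grp, ],
                 colMeans(mean_corr[gs$groups == grp, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_error(group_subregions(mean_corr[1:10, 1:10], 6), "fewer ROIs")
})

test_that("end-to-end parcellation recovers planted parcels and pairs", {
  ses <- small_session()
  cfg <- ses$config
  bouts <- detect_bouts(ses$behavior$wheel_velocity, cfg$frame_rate)
  rest <- which(abs(ses$behavior$wheel_velocity) <= attr(bouts, "threshold"))
  parc <- suppressWarnings(
    parcellate_session(ses$truth$true_F, cfg$image_shape, 8,
                       replicates = 30, rest_frames = rest, seed = 11))
  tl <- as.integer(ses$truth$parcel_labels)
  el <- as.integer(parc$labels)
  m <- tl > 0
  expect_gte(ari(tl[m], el[m]), 0.9)

  # bilateral pairing matches the planted pairs exactly: the estimated label
  # of a right parcel is the partner of its left mirror's estimated label
  mapL <- vapply(1:8, function(i) unique(el[tl == i]), integer(1))
  mapR <- vapply(1:8, function(i) unique(el[tl == i + 8]), integer(1))
  expect_identical(mapR, mapL + 8L)
})
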