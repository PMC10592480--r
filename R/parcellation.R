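#' Parcellation map container
#'
#' @param labels full-image label matrix (0 = background); ROI labels are
#'   `1..n_rois` with left-hemisphere ROIs `1..k` and their right partners
#'   `k+1..2k` in paired order (`pairs[i, ] = c(i, k + i)`).
#' @param pairs two-column matrix of (left_id, right_id) bilateral pairs.
#' @param centroids optional ROI x time centroid matrix in data units.
#' @param provenance free-form list (seeds, replicates) recorded for
#'   reproducibility.
#' @return object of class `parcellation_map`.
#' @export
parcellation_map <- function(labels, pairs, centroids = NULL, provenance = list()) {
  labels <- as.matrix(labels)
  ids <- sort(unique(as.integer(labels[labels > 0])))
  n_rois <- length(ids)
  if (!identical(ids, seq_len(n_rois)))
    stop("ROI labels must be 1..n_rois without gaps", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) * 2L != n_rois ||
      !setequal(c(pairs), seq_len(n_rois)))
    stop("'pairs' must be a perfect matching covering all ROIs", call. = FALSE)
  structure(list(labels = labels, n_rois = n_rois, pairs = pairs,
                 centroids = centroids, provenance = provenance),
            class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  cat(sprintf("Parcellation: %d ROIs (%d bilateral pairs) on a %d x %d image\n",
              x$n_rois, nrow(x$pairs), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Hemisphere column ranges for a bilateral image
#'
#' The image is split into a left and a right hemisphere by a vertical
#' midline gap of `gap` columns centered on the image.
#'
#' @param n_cols image width in pixels.
#' @param gap midline gap width in pixels (default 2).
#' @return list with integer column vectors `left`, `right`, `gap`.
#' @export
hemisphere_columns <- function(n_cols, gap = 2L) {
  half <- (n_cols - gap) %/% 2L
  list(left = seq_len(half),
       gap = half + seq_len(gap),
       right = (half + gap + 1L):n_cols)
}

## column-major pixel indices of a column subset of an nr x nc image
hemi_pixel_index <- function(n_rows, cols) {
  as.vector(outer(seq_len(n_rows), (cols - 1L) * n_rows, "+"))
}

#' K-means clustering under correlation distance
#'
#' Lloyd iterations on per-pixel standardized traces with distance
#' `1 - Pearson(x, centroid)`, the 'correlation' metric of the parcellation
#' procedure. The best of `replicates` random restarts (by total
#' within-cluster correlation distance) is returned; empty clusters are
#' repaired by reseeding them with the worst-fit pixel.
#'
#' @param pixel_matrix pixel x time matrix; every row must be nonconstant.
#' @param k number of clusters (at full scale, 46 per hemisphere).
#' @param replicates number of random restarts (100 at full scale).
#' @param seed optional integer seed making the restarts deterministic.
#' @param init optional k x time matrix of initial centroids (data units);
#'   when supplied a single run is performed from it.
#' @param iter_max maximum Lloyd iterations per run.
#' @return list with `cluster` (per-pixel labels), `centroids` (k x time
#'   mean traces in data units), `objective` (total within-cluster
#'   correlation distance) and `iterations`.
#' @export
cluster_hemisphere <- function(pixel_matrix, k, replicates = 100L, seed = NULL,
                               init = NULL, iter_max = 100L) {
  X <- as.matrix(pixel_matrix)
  n <- nrow(X); Tn <- ncol(X)
  if (k >= n) stop("'k' must be smaller than the number of pixels", call. = FALSE)
  Xz <- standardize_rows(X)
  if (!is.null(seed)) set.seed(seed)
  one_run <- function(C0z) {
    assign_old <- integer(n)
    Cz <- C0z
    warned <- FALSE
    for (it in seq_len(iter_max)) {
      R <- tcrossprod(Xz, Cz) / (Tn - 1L)   # pixel x centroid Pearson
      R[is.na(R)] <- 0
      assign <- max.col(R, ties.method = "first")
      counts <- tabulate(assign, nbins = k)
      if (any(counts == 0L)) {
        fit <- R[cbind(seq_len(n), assign)]
        for (ck in which(counts == 0L)) {
          worst <- which.min(fit)
          assign[worst] <- ck
          fit[worst] <- Inf
        }
        counts <- tabulate(assign, nbins = k)
        if (!warned) { warning("empty cluster repaired by reseeding"); warned <- TRUE }
      }
      if (identical(assign, assign_old)) break
      assign_old <- assign
      Cm <- rowsum(Xz, assign) / counts
      Cz <- standardize_rows(Cm, na_ok = TRUE)
      Cz[is.na(Cz)] <- 0
    }
    R <- tcrossprod(Xz, Cz) / (Tn - 1L)
    R[is.na(R)] <- 0
    obj <- sum(1 - R[cbind(seq_len(n), assign)])
    list(cluster = assign, objective = obj, iterations = it)
  }
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (nrow(init) != k) stop("'init' must have k rows", call. = FALSE)
    Cz0 <- standardize_rows(init, na_ok = TRUE); Cz0[is.na(Cz0)] <- 0
    best <- one_run(Cz0)
  } else {
    best <- NULL
    for (r in seq_len(replicates)) {
      Cz0 <- Xz[sample.int(n, k), , drop = FALSE]
      run <- one_run(Cz0)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  }
  counts <- tabulate(best$cluster, nbins = k)
  centroids <- rowsum(X, best$cluster) / counts
  list(cluster = best$cluster, centroids = centroids,
       objective = best$objective, iterations = best$iterations)
}

#' Mirror a hemisphere parcellation and establish bilateral pairs
#'
#' The left-hemisphere cluster map is reflected across the midline onto the
#' right hemisphere, the reflected ROIs initialize a (single) k-means run on
#' the right-hemisphere data, and bilateral pairs are established by solving
#' the assignment problem that maximizes the temporal correlation between
#' left and right cluster centroids (ties broken by the spatial overlap of
#' the mirrored masks, folded in as an infinitesimal secondary objective).
#'
#' @param labels_left full-image label matrix with left-hemisphere labels
#'   `1..k` (0 elsewhere).
#' @param centroids_left k x time centroid matrix of the left clusters.
#' @param data_right pixel x time matrix of the right-hemisphere pixels in
#'   column-major order of the right hemisphere columns.
#' @param image_shape c(rows, cols) of the full image.
#' @param gap midline gap width in pixels.
#' @param seed optional seed (forwarded to the right-hemisphere k-means).
#' @return a [parcellation_map()] whose right ROI `k + i` is the bilateral
#'   partner of left ROI `i`, with `centroids` stacked in that order.
#' @export
mirror_and_pair <- function(labels_left, centroids_left, data_right,
                            image_shape, gap = 2L, seed = NULL) {
  nr <- image_shape[1]; nc <- image_shape[2]
  hemi <- hemisphere_columns(nc, gap)
  k <- nrow(centroids_left)
  lab_l <- as.matrix(labels_left)
  ## reflect: right column j maps to left column nc + 1 - j
  mirror_init <- as.integer(lab_l[, nc + 1L - hemi$right])
  if (any(mirror_init == 0L))
    stop("mirrored left labels do not cover the right hemisphere", call. = FALSE)
  if (length(mirror_init) != nrow(data_right))
    stop("'data_right' does not match the right-hemisphere geometry", call. = FALSE)
  C0 <- rowsum(as.matrix(data_right), mirror_init) / tabulate(mirror_init, k)
  km <- cluster_hemisphere(data_right, k, init = C0, seed = seed)
  ## pair by maximal centroid correlation (assignment problem)
  S <- stats::cor(t(centroids_left), t(km$centroids))
  S[is.na(S)] <- 0
  O <- table(factor(mirror_init, levels = seq_len(k)),
             factor(km$cluster, levels = seq_len(k)))
  cost <- -S - 1e-9 * unclass(O) / max(O)
  a <- solve_assignment(cost)           # a[i] = right cluster paired to left i
  ## assemble the full bilateral label image
  labels <- lab_l
  right_relabel <- integer(k)
  right_relabel[a] <- k + seq_len(k)    # right cluster a[i] -> label k + i
  labels[, hemi$right] <- matrix(right_relabel[km$cluster], nrow = nr)
  centroids <- rbind(centroids_left, km$centroids[a, , drop = FALSE])
  parcellation_map(labels,
                   pairs = cbind(left = seq_len(k), right = k + seq_len(k)),
                   centroids = centroids,
                   provenance = list(seed = seed,
                                     pairing_correlation = S[cbind(seq_len(k), a)]))
}

#' Parcellate a bilateral session
#'
#' Convenience wrapper running the full parcellation procedure on a pixel
#' stack: correlation-distance k-means on the left hemisphere (best of
#' `replicates` restarts), reflection onto the right hemisphere, right-side
#' clustering initialized from the mirrored map, and bilateral pairing.
#' Clustering is performed on rest-segment frames when `rest_frames` is
#' given, where the parcel structure is most clearly delineated.
#'
#' @param stack pixel x time matrix over the full image (column-major).
#' @param image_shape c(rows, cols).
#' @param k_per_hemisphere clusters per hemisphere (46 at full scale).
#' @param replicates restarts for the left-hemisphere clustering.
#' @param rest_frames optional frame indices to cluster on.
#' @param gap midline gap width.
#' @param seed integer seed.
#' @return a [parcellation_map()].
#' @export
parcellate_session <- function(stack, image_shape, k_per_hemisphere,
                               replicates = 100L, rest_frames = NULL,
                               gap = 2L, seed = NULL) {
  nr <- image_shape[1]; nc <- image_shape[2]
  hemi <- hemisphere_columns(nc, gap)
  stack <- as.matrix(stack)
  if (!is.null(rest_frames)) stack <- stack[, rest_frames, drop = FALSE]
  idx_l <- hemi_pixel_index(nr, hemi$left)
  idx_r <- hemi_pixel_index(nr, hemi$right)
  km_l <- cluster_hemisphere(stack[idx_l, , drop = FALSE], k_per_hemisphere,
                             replicates = replicates, seed = seed)
  labels_left <- matrix(0L, nr, nc)
  labels_left[, hemi$left] <- matrix(km_l$cluster, nrow = nr)
  mirror_and_pair(labels_left, km_l$centroids, stack[idx_r, , drop = FALSE],
                  image_shape, gap = gap, seed = seed)
}

#' Evaluate candidate cluster counts by NNLS reconstruction
#'
#' For each candidate centroid basis `H` (one set per candidate count N),
#' every pixel trace is fit by non-negative least squares on the centroid
#' time courses, \eqn{M(x,y,t) = \sum_n W(x,y)_n H(t)_n}, and the total
#' squared residual and fraction of signal energy explained are reported,
#' alongside the PCA (optimal rank-N) explained energy of the same data for
#' reference.
#'
#' @param data pixel x time matrix.
#' @param centroid_sets list of centroid matrices (N x time each).
#' @return data.frame with `n_centroids`, `residual`, `nnls_varexp`,
#'   `pca_varexp`.
#' @export
evaluate_cluster_count <- function(data, centroid_sets) {
  data <- as.matrix(data)
  if (!is.list(centroid_sets)) centroid_sets <- list(centroid_sets)
  total <- sum(data^2)
  sv <- svd(data, nu = 0, nv = 0)
  cum_pca <- cumsum(sv$d^2) / sum(sv$d^2)
  out <- lapply(centroid_sets, function(H) {
    H <- as.matrix(H)
    if (any(apply(H, 1L, stats::sd) == 0))
      stop("degenerate (constant) centroid in basis", call. = FALSE)
    A <- t(H)
    AtA <- crossprod(A)
    AtB <- tcrossprod(H, data)          # n x pixels
    res <- 0
    for (p in seq_len(nrow(data))) {
      w <- nnls_from_cross(AtA, AtB[, p])
      res <- res + sum(data[p, ]^2) - 2 * sum(w * AtB[, p]) +
        drop(crossprod(w, AtA %*% w))
    }
    res <- max(res, 0)
    n <- nrow(H)
    data.frame(n_centroids = n, residual = res,
               nnls_varexp = 1 - res / total,
               pca_varexp = cum_pca[min(n, length(cum_pca))])
  })
  do.call(rbind, out)
}

#' Consensus (mode) map over repeated parcellations
#'
#' Each repeated map is canonically relabeled onto the first by solving the
#' assignment problem on pixel-overlap counts, then the per-pixel modal
#' label is taken. Ties are resolved in favor of the map with the best
#' (lowest) `quality` score, e.g. its within-cluster distance.
#'
#' @param maps list (length >= 3) of [parcellation_map()]s or label images
#'   on identical geometry with identical ROI counts.
#' @param quality numeric vector, one (lower-is-better) score per map;
#'   defaults to input order.
#' @return a `parcellation_map` if the inputs carry pairs, else a label
#'   matrix.
#' @export
consensus_mode_map <- function(maps, quality = NULL) {
  if (length(maps) < 3L) stop("need at least 3 repeated maps", call. = FALSE)
  is_pm <- vapply(maps, inherits, logical(1), "parcellation_map")
  labs <- lapply(maps, function(m) if (inherits(m, "parcellation_map")) m$labels else as.matrix(m))
  dims <- vapply(labs, function(l) paste(dim(l), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("maps differ in geometry", call. = FALSE)
  ks <- vapply(labs, function(l) max(l), numeric(1))
  if (length(unique(ks)) != 1L) stop("maps differ in n_rois", call. = FALSE)
  k <- as.integer(ks[1])
  quality <- quality %||% seq_along(maps)
  ref <- labs[[1]]
  mask <- ref > 0L
  if (!all(vapply(labs, function(l) identical(l > 0L, mask), logical(1))))
    stop("maps differ in background mask", call. = FALSE)
  ## canonical relabeling onto the first map
  relab <- vector("list", length(labs))
  relab[[1]] <- ref[mask]
  for (m in seq_along(labs)[-1]) {
    lm <- labs[[m]][mask]
    O <- table(factor(lm, levels = seq_len(k)), factor(ref[mask], levels = seq_len(k)))
    a <- solve_assignment(-unclass(O))  # a[i]: ref label for map-m label i
    relab[[m]] <- a[lm]
  }
  npx <- sum(mask)
  counts <- matrix(0L, npx, k)
  for (m in seq_along(relab))
    counts[cbind(seq_len(npx), relab[[m]])] <- counts[cbind(seq_len(npx), relab[[m]])] + 1L
  maxc <- do.call(pmax, as.data.frame(counts))
  mode_lab <- rep(NA_integer_, npx)
  for (m in order(quality)) {
    sel <- is.na(mode_lab) & counts[cbind(seq_len(npx), relab[[m]])] == maxc
    mode_lab[sel] <- relab[[m]][sel]
  }
  out <- matrix(0L, nrow(ref), ncol(ref))
  out[mask] <- mode_lab
  if (is_pm[1]) parcellation_map(out, maps[[1]]$pairs,
                                 provenance = list(consensus_of = length(maps)))
  else out
}

#' Group ROIs into bilateral subregions
#'
#' Clusters the rows of a grand-average correlation map into
#' `per_hemisphere_groups` groups within each hemisphere (k-means), yielding
#' the a-f / a'-f' subregions used to arrange correlation maps for display,
#' and the reduced (group-mean row) map used for cortical projection. Right
#' groups are matched to left groups by the correlation of their group-mean
#' rows, so group `g + per_hemisphere_groups` is the contralateral partner
#' of group `g`.
#'
#' @param mean_corr symmetric ROI x ROI correlation map in paired order
#'   (left ROIs first).
#' @param per_hemisphere_groups groups per hemisphere (default 6).
#' @param seed optional seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return list with `groups` (length-n vector in 1..2*per_hemisphere_groups)
#'   and `reduced` (2*per_hemisphere_groups x n matrix of group-mean rows).
#' @export
group_subregions <- function(mean_corr, per_hemisphere_groups = 6L,
                             seed = NULL, nstart = 20L) {
  mean_corr <- as.matrix(mean_corr)
  n <- nrow(mean_corr)
  if (n %% 2L != 0L) stop("expected an even ROI count (paired hemispheres)", call. = FALSE)
  h <- n %/% 2L
  g <- as.integer(per_hemisphere_groups)
  if (h < g) stop("fewer ROIs per hemisphere than requested groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  left <- seq_len(h); right <- h + seq_len(h)
  km_l <- stats::kmeans(mean_corr[left, , drop = FALSE], centers = g, nstart = nstart)
  km_r <- stats::kmeans(mean_corr[right, , drop = FALSE], centers = g, nstart = nstart)
  ## canonical order: left groups by their first ROI; right matched to left
  ord_l <- order(vapply(seq_len(g), function(i) min(which(km_l$cluster == i)), numeric(1)))
  gl <- match(km_l$cluster, ord_l)
  S <- stats::cor(t(km_l$centers[ord_l, , drop = FALSE]), t(km_r$centers))
  S[is.na(S)] <- 0
  a <- solve_assignment(-S)             # a[i]: right group matched to left group i
  gr <- integer(h)
  for (i in seq_len(g)) gr[km_r$cluster == a[i]] <- g + i
  groups <- c(gl, gr)
  reduced <- rowsum(mean_corr, groups) / tabulate(groups, 2L * g)
  list(groups = groups, reduced = reduced)
}
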