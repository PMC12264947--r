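# K-means over reduced coordinates, elbow-based k selection, and medoid
# representative extraction.

# k-means++ seeding (Arthur & Vassilvitskii); assumes the RNG state is set
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(0, k, ncol(points))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- points[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(points, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      if (all(d2 == 0)) prob <- rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- points[idx, ]
      d2 <- pmin(d2, rowSums(sweep(points, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' K-means clustering with k-means++ seeding
#'
#' k-means++ initialization followed by Lloyd iterations
#' (via [stats::kmeans()]), best of `n_init` seeded restarts. Fully
#' deterministic given `seed`.
#'
#' @param points Numeric matrix or data frame of coordinates (a `frame`
#'   column, if present, is carried through to the labels).
#' @param k Number of clusters, `1 <= k <= n_points`.
#' @param seed Integer RNG seed.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @return A list of class `kmeans_fit`: `labels` tibble (`frame`,
#'   `cluster` in 1..k), `centers` (k x d), `inertia` (within-cluster sum of
#'   squares), `k`, `seed`.
#' @export
kmeans_fit <- function(points, k, seed = 1L, n_init = 10, max_iter = 300) {
  frame_ids <- NULL
  if (is.data.frame(points)) {
    frame_ids <- points$frame
    points <- as.matrix(points[, setdiff(names(points), "frame"), drop = FALSE])
  }
  n <- nrow(points)
  frame_ids <- frame_ids %||% seq_len(n)
  if (k < 1L || k > n) {
    abort_ed(sprintf("`k` must lie in 1..%d (the number of points).", n), "parameter")
  }
  if (k == 1L) {
    # closed form: the centroid; no iteration or RNG involved
    ctr <- matrix(colMeans(points), 1L, ncol(points),
      dimnames = list(NULL, colnames(points)))
    return(structure(
      list(
        labels = tibble::tibble(frame = frame_ids, cluster = 1L),
        centers = ctr,
        inertia = sum(sweep(points, 2L, ctr[1L, ])^2),
        k = 1L,
        seed = as.integer(seed)
      ),
      class = "kmeans_fit"
    ))
  }
  run_one <- function() {
    centers <- kmeanspp_centers(points, k)
    centers <- unique(centers)
    if (nrow(centers) < k) {
      # duplicated seeds (coincident points): pad with jittered copies
      extra <- centers[rep(1L, k - nrow(centers)), , drop = FALSE]
      centers <- rbind(centers, extra + 1e-9 * stats::rnorm(length(extra)))
    }
    fit <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = max_iter, algorithm = "Lloyd")
    )
    fit
  }
  best <- withr::with_seed(as.integer(seed), {
    fits <- lapply(seq_len(n_init), function(i) run_one())
    fits[[which.min(vapply(fits, function(f) f$tot.withinss, 0))]]
  })
  structure(
    list(
      labels = tibble::tibble(frame = frame_ids, cluster = as.integer(best$cluster)),
      centers = best$centers,
      inertia = best$tot.withinss,
      k = as.integer(k),
      seed = as.integer(seed)
    ),
    class = "kmeans_fit"
  )
}

#' Elbow selection of the cluster count
#'
#' Runs [kmeans_fit()] over `k_range` and selects the k of maximum discrete
#' curvature (second difference) of the log-inertia-vs-k curve. Working on
#' the log makes the curvature scale-invariant, so the elbow responds to
#' relative drops in within-cluster scatter rather than to the (always
#' dominant) absolute drop at small k. Linear inertia decay has its
#' largest log-curvature at the smallest interior k, which therefore also
#' serves as the degenerate-case fallback; ties break toward smaller k.
#'
#' @param points As in [kmeans_fit()].
#' @param k_range Increasing integer vector of candidate k (length >= 3).
#' @param seed Integer RNG seed.
#' @param ... Passed to [kmeans_fit()].
#' @return A list of class `elbow_curve`: `k` (selected), `curve` tibble
#'   (`k`, `inertia`, `curvature`).
#' @export
elbow_select <- function(points, k_range = 1:8, seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) {
    abort_ed("`k_range` must contain at least 3 values for curvature.", "insufficient_range")
  }
  inertia <- vapply(
    k_range,
    function(k) kmeans_fit(points, k, seed = seed, ...)$inertia,
    0
  )
  log_inertia <- log(pmax(inertia, 1e-12 * max(inertia[1], 1)))
  curv <- rep(NA_real_, length(k_range))
  interior <- 2:(length(k_range) - 1L)
  curv[interior] <- log_inertia[interior - 1L] - 2 * log_inertia[interior] +
    log_inertia[interior + 1L]
  pick <- interior[which.max(curv[interior])]
  structure(
    list(
      k = k_range[pick],
      curve = tibble::tibble(k = k_range, inertia = inertia, curvature = curv)
    ),
    class = "elbow_curve"
  )
}

# mean pairwise superposed RMSD from each member to all others
pairwise_rmsd_means <- function(coord_list, subset) {
  m <- length(coord_list)
  rmsd <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      r <- kabsch_superpose(coord_list[[i]], coord_list[[j]], subset = subset)$rmsd
      rmsd[i, j] <- r
      rmsd[j, i] <- r
    }
  }
  rowSums(rmsd) / (m - 1L)
}

#' Medoid representative frame of a set of conformations
#'
#' Returns the member frame minimizing the mean pairwise superposed RMSD to
#' all other members: a physically valid conformation, unlike a coordinate
#' average. Brute-force pairwise RMSD up to `max_exact` members; larger
#' sets are subsampled (seeded) before the brute-force pass.
#'
#' @param ensemble An `ensemble`.
#' @param member_frames 1-based frame indices of the set.
#' @param subset Atom indices for the superposition (default backbone).
#' @param max_exact Largest member count handled exactly (default 2000).
#' @param seed Seed for the subsampling fallback.
#' @return The selected frame index (one of `member_frames`).
#' @export
medoid_representative <- function(ensemble, member_frames, subset = NULL,
                                  max_exact = 2000, seed = 1L) {
  member_frames <- check_frames(ensemble, member_frames)
  if (length(member_frames) == 1L) {
    return(member_frames)
  }
  pool <- member_frames
  if (length(pool) > max_exact) {
    pool <- withr::with_seed(as.integer(seed), sort(sample(pool, max_exact)))
  }
  subset <- subset %||% backbone_atom_indices(ensemble)
  coord_list <- lapply(pool, function(f) frame_coords(ensemble, f))
  means <- pairwise_rmsd_means(coord_list, subset)
  pool[which.min(means)]
}

#' Full per-group clustering pipeline
#'
#' The chain applied to each scrutinized conformation-parameter group:
#' dihedral featurization of the group's frames, PCA to `n_components`,
#' elbow selection of k, k-means, and a medoid representative per cluster.
#' Reproducible from one seed.
#'
#' @param ensemble An `ensemble`.
#' @param groups A [decompose()] result.
#' @param group_label Which group to process.
#' @param k_range Candidate cluster counts (clipped, with a warning, when
#'   the group is smaller than its maximum).
#' @param n_components PCA components fed to clustering (default 2, as
#'   plotted; exposed because the choice is not fundamental).
#' @param seed Integer RNG seed.
#' @return A list of class `cluster_pipeline`: `pca`, `elbow`, `kmeans`,
#'   and `representatives` (tibble `cluster`, `frame`, with frame indices
#'   in the original ensemble numbering).
#' @export
cluster_group_pipeline <- function(ensemble, groups, group_label,
                                   k_range = 1:8, n_components = 2, seed = 1L) {
  frames <- group_frames(groups, group_label)
  sub <- subset_frames(ensemble, frames)
  if (max(k_range) > length(frames)) {
    warn(sprintf(
      "Group %s has %d frames; clipping k_range below its size.",
      group_label, length(frames)
    ))
    k_range <- k_range[k_range <= length(frames)]
  }
  feats <- dihedral_features(sub)
  proj <- pca_project(feats, n_components = n_components)
  pts <- proj$scores
  identical_frames <- all(apply(as.matrix(pts[, -1, drop = FALSE]), 2L, stats::sd) < 1e-12)
  if (identical_frames) {
    elbow <- NULL
    km <- kmeans_fit(pts, 1L, seed = seed)
  } else {
    elbow <- elbow_select(pts, k_range = k_range, seed = seed)
    km <- kmeans_fit(pts, elbow$k, seed = seed)
  }
  reps <- vapply(sort(unique(km$labels$cluster)), function(cl) {
    local_frames <- km$labels$frame[km$labels$cluster == cl]
    medoid_representative(sub, local_frames, seed = seed)
  }, 0L)
  structure(
    list(
      group = group_label,
      pca = proj,
      elbow = elbow,
      kmeans = km,
      representatives = tibble::tibble(
        cluster = sort(unique(km$labels$cluster)),
        frame = frames[reps]
      )
    ),
    class = "cluster_pipeline"
  )
}
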