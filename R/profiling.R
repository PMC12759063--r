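#' Sliding-window multivariate motility features
#'
#' Converts a uniformly sampled track into the four-feature time series that
#' feeds dynamic time warping: per window of `window_s / dt_s` time points
#' (five points of 10 s by default), sliding one sample at a time, it
#' computes
#' \itemize{
#'   \item directionality of the window,
#'   \item square displacement `|p_end - p_start|^2` (um^2),
#'   \item mean speed (window path length / window duration, um/min),
#'   \item an arrest feature `1 / (MSD_w + epsilon)` where `MSD_w` is the
#'     mean squared displacement of the window's points from its start.
#' }
#' The inverse-MSD arrest feature avoids the heavy discretization a
#' threshold-based arrest coefficient suffers on five-point windows; the
#' epsilon floor keeps it finite on perfectly arrested windows.
#'
#' @param track An `ivtk_track` uniformly sampled at `dt_s`.
#' @param window_s Window span in seconds.
#' @param dt_s Sampling interval in seconds.
#' @param epsilon_um2 Floor added to `MSD_w` (um^2).
#' @return An object of class `ivtk_feature_series`: list with `track_id`,
#'   `features` (W x 4 matrix, W = S - points_per_window + 1) and
#'   `window_start_times` (seconds).
#' @export
window_features <- function(track, window_s = 50, dt_s = 10, epsilon_um2 = 1e-3) {
  validate_track(track)
  if (!is_uniform_track(track))
    stop("window_features requires a uniformly sampled track; resample_track() first")
  dt_actual <- diff(track$points$t)[1]
  if (abs(dt_actual - dt_s) > 1e-6 * dt_s)
    stop("track is sampled at ", dt_actual, " s, not the requested ", dt_s, " s")
  n_pts <- as.integer(round(window_s / dt_s))
  if (n_pts < 2L) stop("window must span at least 2 samples")
  s <- nrow(track$points)
  if (s < n_pts) stop("track '", track$track_id, "' shorter than one window")
  p <- track_coords(track)
  n_win <- s - n_pts + 1L
  feat <- matrix(NA_real_, n_win, 4,
                 dimnames = list(NULL, c("directionality", "square_displacement",
                                         "mean_speed", "arrest")))
  dur_min <- (n_pts - 1L) * dt_s / 60
  step_len <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-s, , drop = FALSE])^2))
  for (w in seq_len(n_win)) {
    idx <- w:(w + n_pts - 1L)
    sub <- p[idx, , drop = FALSE]
    disp_vec <- sub[n_pts, ] - sub[1, ]
    disp <- sqrt(sum(disp_vec^2))
    plen <- sum(step_len[w:(w + n_pts - 2L)])
    sq_from_start <- rowSums(sweep(sub, 2, sub[1, ])^2)
    feat[w, ] <- c(if (plen > 0) disp / plen else 0,
                   disp^2,
                   plen / dur_min,
                   1 / (mean(sq_from_start) + epsilon_um2))
  }
  structure(list(track_id = track$track_id, features = feat,
                 window_start_times = track$points$t[seq_len(n_win)]),
            class = "ivtk_feature_series")
}

#' Z-score feature series over the pooled windows of all tracks
#'
#' Normalization is pooled across tracks (per feature dimension, over every
#' window of every track) rather than per track, so that absolute magnitudes
#' -- an arrested track's low speeds, a directed track's high square
#' displacements -- remain distinguishable after scaling. A zero-variance
#' feature maps to all zeros.
#'
#' @param series_list List of `ivtk_feature_series`.
#' @return List with `series` (normalized copies), `center` and `scale`
#'   (named per-feature mean and SD used).
#' @export
normalize_features <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  pooled <- do.call(rbind, lapply(series_list, function(s) s$features))
  if (nrow(pooled) < 2) stop("need >= 2 windows in total to normalize")
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, stats::sd)
  out <- lapply(series_list, apply_feature_normalization, center = center, scale = scale)
  list(series = out, center = center, scale = scale)
}

#' Apply a stored feature normalization to a series
#' @param series An `ivtk_feature_series`.
#' @param center,scale Named per-feature means and SDs from
#'   [normalize_features()].
#' @return The normalized `ivtk_feature_series`; zero-SD features map to 0.
#' @export
apply_feature_normalization <- function(series, center, scale) {
  f <- sweep(series$features, 2, center)
  safe_scale <- ifelse(scale > 0, scale, 1)
  f <- sweep(f, 2, safe_scale, "/")
  f[, scale == 0] <- 0
  series$features <- f
  series
}

#' Dependent multivariate DTW distance between two feature series
#'
#' One warping path is computed over the vector-valued series with Euclidean
#' local cost between feature vectors and no band constraint; the distance is
#' the cumulative cost of the optimal alignment. Alignment lets series of
#' different lengths (tracks of different durations) be compared.
#'
#' @param a,b `ivtk_feature_series` objects or plain numeric matrices
#'   (windows x features) with matching feature dimension.
#' @return Non-negative DTW distance.
#' @export
dtw_distance <- function(a, b) {
  ma <- if (inherits(a, "ivtk_feature_series")) a$features else as.matrix(a)
  mb <- if (inherits(b, "ivtk_feature_series")) b$features else as.matrix(b)
  if (nrow(ma) == 0 || nrow(mb) == 0) stop("empty feature series")
  dtw_dist_cpp(ma, mb)
}

#' Pairwise DTW distance matrix
#'
#' @param series_list List of `ivtk_feature_series` (or matrices).
#' @return Symmetric N x N matrix with zero diagonal, dimnames set to track
#'   ids where available.
#' @export
dtw_distance_matrix <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  mats <- lapply(series_list, function(s)
    if (inherits(s, "ivtk_feature_series")) s$features else as.matrix(s))
  if (any(vapply(mats, nrow, integer(1)) == 0)) stop("empty feature series")
  D <- dtw_matrix_cpp(mats)
  ids <- vapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (inherits(s, "ivtk_feature_series")) s$track_id else paste0("series", i)
  }, character(1))
  dimnames(D) <- list(ids, ids)
  stopifnot(all(is.finite(D)), all(D >= 0), isTRUE(all.equal(D, t(D))))
  D
}

#' Embed a distance matrix in 2D
#'
#' Projects the N x N DTW distance matrix to two dimensions by classical
#' metric multidimensional scaling (principal coordinates), a deterministic
#' embedding that preserves the large-scale separation structure the
#' downstream density-peak clustering relies on. Downstream results depend
#' only on neighborhood structure, not exact coordinates.
#'
#' Before scaling, distances are locally rescaled as
#' `D_ij / sqrt(s_i * s_j)`, where `s_i` is the distance from point `i` to
#' its `local_k`-th nearest neighbor. This equalizes per-cluster density so
#' that a very tight group of near-identical series does not dominate the
#' distance scale, mirroring the local-connectivity normalization of
#' neighbor-graph embeddings. Set `local_k = 0` to disable.
#'
#' @param D Symmetric distance matrix.
#' @param seed Recorded in the result for provenance; the embedding itself is
#'   deterministic.
#' @param local_k Neighbor order used for local distance scaling (0 = none).
#' @return An object of class `ivtk_embedding`: list with `coords` (N x 2),
#'   `method` and `seed`.
#' @export
embed_tracks <- function(D, seed = 42L, local_k = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 tracks to embed")
  if (local_k > 0) {
    kk <- min(as.integer(local_k), n - 1L)
    s <- vapply(seq_len(n), function(i) sort(D[i, -i])[kk], numeric(1))
    floor_s <- if (any(s > 0)) min(s[s > 0]) else 1
    s[s == 0] <- floor_s
    D <- D / sqrt(outer(s, s))
    diag(D) <- 0
  }
  coords <- stats::cmdscale(D, k = 2)
  if (ncol(coords) < 2)  # degenerate geometry collapses to 1D
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, method = "cmdscale", seed = as.integer(seed)),
            class = "ivtk_embedding")
}

#' Density-peak clustering with graph-based assignment
#'
#' Implements clustering by fast search of density peaks, followed by
#' shortest-path assignment on a pruned proximity graph:
#' \enumerate{
#'   \item coordinates are min-max normalized per axis to [0, 1];
#'   \item local density `rho_i = sum_j exp(-(d_ij / d_c)^2)` with the kernel
#'     scale `d_c` set to the `dc_percentile` quantile of pairwise distances;
#'   \item `delta_i` = distance to the nearest point of higher density (the
#'     global density maximum takes its largest distance to any point);
#'   \item the `k` points with the highest `gamma = rho * delta` become
#'     cluster centers;
#'   \item remaining points join the center of minimal shortest-path cost on
#'     the graph whose edges connect pairs closer than `prune_threshold`
#'     (edge weight = distance); points unreachable from every center fall
#'     back to the nearest center by direct distance.
#' }
#' The pruning threshold is interpreted in the min-max-normalized
#' coordinates, making it scale-free. Density ties break to the lower point
#' index and center ties by `gamma` then index, so results are
#' deterministic.
#'
#' @param points N x 2 coordinate matrix or an `ivtk_embedding`.
#' @param k Number of clusters, `1 <= k <= N`.
#' @param prune_threshold Maximum edge length kept in the assignment graph
#'   (normalized coordinates).
#' @param dc_percentile Quantile of pairwise distances used as `d_c`.
#' @return An object of class `ivtk_clusters`: list with `label` (1..k, in
#'   decreasing center `gamma` order), `rho`, `delta`, `gamma`, `centers`
#'   (point indices), `d_c`, `prune_threshold` and `coords_norm`.
#' @export
density_peak_cluster <- function(points, k, prune_threshold = 0.1,
                                 dc_percentile = 0.02) {
  pts <- if (inherits(points, "ivtk_embedding")) points$coords else as.matrix(points)
  n <- nrow(pts)
  stopifnot(k >= 1, n >= 1)
  if (k > n) stop("k = ", k, " exceeds the number of points (", n, ")")
  # min-max normalize each axis; constant axes collapse to 0
  norm <- apply(pts, 2, function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  })
  norm <- matrix(norm, nrow = n)
  d <- as.matrix(stats::dist(norm))
  pd <- d[upper.tri(d)]
  d_c <- if (length(pd)) stats::quantile(pd, probs = dc_percentile, names = FALSE) else 1
  if (d_c <= 0) d_c <- max(min(pd[pd > 0], na.rm = TRUE) / 2, .Machine$double.eps)
  if (!is.finite(d_c)) d_c <- 1   # all points coincident
  rho <- rowSums(exp(-(d / d_c)^2)) - 1  # exclude self term
  # density order with index tie-break: earlier index counts as denser
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  delta[ord[1]] <- max(d[ord[1], ])
  if (n > 1) for (r in 2:n) {
    i <- ord[r]
    delta[i] <- min(d[i, ord[1:(r - 1)]])
  }
  gamma <- rho * delta
  centers <- order(-gamma, seq_len(n))[seq_len(k)]
  # pruned proximity graph; shortest-path costs from each center
  keep <- d <= prune_threshold
  diag(keep) <- FALSE
  adj <- d * keep
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sp <- igraph::distances(g, v = centers, weights = igraph::E(g)$weight)
  label <- integer(n)
  for (i in seq_len(n)) {
    costs <- sp[, i]
    if (all(is.infinite(costs))) {
      label[i] <- which.min(d[centers, i])
    } else {
      label[i] <- which.min(costs)  # ties -> higher-gamma center
    }
  }
  label[centers] <- seq_len(k)
  structure(list(label = label, rho = rho, delta = delta, gamma = gamma,
                 centers = centers, d_c = d_c,
                 prune_threshold = prune_threshold, coords_norm = norm),
            class = "ivtk_clusters")
}

#' @export
print.ivtk_clusters <- function(x, ...) {
  cat(sprintf("<ivtk_clusters> %d points, %d clusters, d_c = %.4g\n",
              length(x$label), length(x$centers), x$d_c))
  print(table(cluster = x$label))
  invisible(x)
}

#' Per-cluster motility profiles
#'
#' For each cluster, the mean of each motility metric over its member
#' tracks, then min-max normalized across clusters per metric so each row of
#' the profile spans [0, 1] -- the normalization used to draw comparable
#' radar charts. With a single cluster the normalization is degenerate and
#' all values are defined as 0.5. A metric constant across clusters also
#' maps to 0.5.
#'
#' @param clusters An `ivtk_clusters` (or an integer label vector).
#' @param records Motility record data.frame, one row per point in the same
#'   order as the clustering input.
#' @param metrics Character vector of record columns to profile.
#' @return List with `mean` (k x metrics matrix of raw means) and
#'   `normalized` (same shape, min-max across clusters).
#' @export
cluster_profile <- function(clusters, records,
                            metrics = c("speed", "directionality",
                                        "arrest_coefficient", "displacement",
                                        "path_length")) {
  label <- if (inherits(clusters, "ivtk_clusters")) clusters$label else as.integer(clusters)
  stopifnot(length(label) == nrow(records))
  k <- if (inherits(clusters, "ivtk_clusters")) length(clusters$centers) else max(label)
  if (!all(seq_len(k) %in% label))
    stop("empty cluster(s): ", paste(setdiff(seq_len(k), unique(label)), collapse = ", "))
  miss <- setdiff(metrics, names(records))
  if (length(miss)) stop("records lack metric column(s): ", paste(miss, collapse = ", "))
  m <- sapply(metrics, function(col)
    tapply(records[[col]], factor(label, levels = seq_len(k)), mean))
  m <- matrix(m, nrow = k, dimnames = list(paste0("cluster", seq_len(k)), metrics))
  normd <- apply(m, 2, function(v) {
    r <- range(v)
    if (k == 1 || r[2] <= r[1]) return(rep(0.5, k))
    (v - r[1]) / (r[2] - r[1])
  })
  normd <- matrix(normd, nrow = k, dimnames = dimnames(m))
  list(mean = m, normalized = normd)
}

#' Full motility-pattern profiling pipeline
#'
#' Composes the end-to-end analysis: duration filter (>= `min_duration_s`),
#' resampling to a uniform `dt_s` grid, sliding-window feature extraction,
#' pooled z-score normalization, multivariate DTW distance matrix, 2D
#' embedding, density-peak clustering into `k` groups, and per-cluster
#' profiles. All intermediate artifacts are returned.
#'
#' @param tracks List of `ivtk_track` objects.
#' @param k Number of clusters.
#' @param min_duration_s Duration filter (s).
#' @param dt_s Resampling interval (s).
#' @param window_s Feature window span (s).
#' @param epsilon_um2 Arrest-feature floor (um^2).
#' @param prune_threshold Graph pruning threshold (normalized coordinates).
#' @param arrest_threshold Arrest-coefficient speed threshold (um/min) for
#'   the per-track records.
#' @param seed Seed recorded with the embedding.
#' @return List with `tracks` (surviving, resampled), `features`,
#'   `normalization`, `distance_matrix`, `embedding`, `clusters`, `records`,
#'   `profile` and `params`.
#' @export
profile_pipeline <- function(tracks, k = 10, min_duration_s = 500, dt_s = 10,
                             window_s = 50, epsilon_um2 = 1e-3,
                             prune_threshold = 0.1, arrest_threshold = 2,
                             seed = 42L) {
  kept <- filter_by_duration(tracks, min_duration_s)
  if (length(kept) < 2) stop("fewer than 2 tracks survive the duration filter")
  res <- lapply(kept, resample_track, dt = dt_s)
  feats <- lapply(res, window_features, window_s = window_s, dt_s = dt_s,
                  epsilon_um2 = epsilon_um2)
  normed <- normalize_features(feats)
  D <- dtw_distance_matrix(normed$series)
  emb <- embed_tracks(D, seed = seed)
  cl <- density_peak_cluster(emb, k = k, prune_threshold = prune_threshold)
  recs <- motility_records(res, arrest_threshold = arrest_threshold)
  prof <- cluster_profile(cl, recs)
  list(tracks = res, features = normed$series, normalization = normed[c("center", "scale")],
       distance_matrix = D, embedding = emb, clusters = cl, records = recs,
       profile = prof,
       params = list(k = k, min_duration_s = min_duration_s, dt_s = dt_s,
                     window_s = window_s, epsilon_um2 = epsilon_um2,
                     prune_threshold = prune_threshold,
                     arrest_threshold = arrest_threshold, seed = seed))
}
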