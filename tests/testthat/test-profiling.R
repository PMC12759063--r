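test_that("window count is S - 4 for five-sample windows", {
  tr <- resample_track(gen_track("brownian", duration_s = 500, dt_s = 10, seed = 1), 10)
  wf <- window_features(tr)
  expect_equal(nrow(wf$features), 47)  # 51 samples
  set.seed(31)
  for (i in 1:10) {
    s <- sample(5:80, 1)
    tr <- gen_track("brownian", duration_s = (s - 1) * 10, dt_s = 10, seed = NULL)
    expect_equal(nrow(window_features(tr)$features), s - 4)
  }
  short <- gen_track("brownian", duration_s = 30, dt_s = 10, seed = 2)
  expect_error(window_features(short), "shorter than one window")
})

test_that("window features hit their analytic values on archetypal motion", {
  straight <- straight_track(n = 21, dt = 10, v_um_min = 6)
  wf <- window_features(straight)
  expect_true(all(abs(wf$features[, "directionality"] - 1) < 1e-12))
  expect_true(all(abs(wf$features[, "mean_speed"] - 6) < 1e-12))
  # 4 steps of 1 um in 40 s: square displacement 16 um^2
  expect_true(all(abs(wf$features[, "square_displacement"] - 16) < 1e-12))

  frozen <- track(t = seq(0, 100, 10), x = rep(2, 11), y = rep(5, 11))
  wf0 <- window_features(frozen, epsilon_um2 = 1e-3)
  expect_true(all(wf0$features[, "arrest"] == 1000))  # 1 / epsilon cap
})

test_that("pooled z-score normalization has zero mean, unit SD, and replays on held-out data", {
  set.seed(32)
  series <- lapply(1:6, function(i)
    window_features(gen_track("brownian", duration_s = 400, dt_s = 10, seed = NULL,
                              track_id = paste0("b", i))))
  norm <- normalize_features(series)
  pooled <- do.call(rbind, lapply(norm$series, function(s) s$features))
  expect_equal(unname(colMeans(pooled)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 4), tolerance = 1e-9)

  held <- window_features(gen_track("directed", duration_s = 400, dt_s = 10, seed = 9))
  replayed <- apply_feature_normalization(held, norm$center, norm$scale)
  expect_equal(replayed$features,
               sweep(sweep(held$features, 2, norm$center), 2, norm$scale, "/"))

  # constant feature column degenerates to zero
  s_const <- list(structure(list(track_id = "c", features = cbind(a = rep(3, 5), b = 1:5),
                                 window_start_times = 1:5), class = "ivtk_feature_series"))
  n2 <- normalize_features(s_const)
  expect_true(all(n2$series[[1]]$features[, "a"] == 0))
})

test_that("DTW is a zero-diagonal symmetric distance bounded by lock-step cost", {
  set.seed(33)
  for (i in 1:20) {
    a <- matrix(rnorm(sample(2:6, 1) * 4), ncol = 4)
    b <- matrix(rnorm(sample(2:6, 1) * 4), ncol = 4)
    expect_equal(dtw_distance(a, a), 0)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
  for (i in 1:10) {
    n <- sample(2:6, 1)
    a <- matrix(rnorm(n * 4), ncol = 4)
    b <- matrix(rnorm(n * 4), ncol = 4)
    lockstep <- sum(sqrt(rowSums((a - b)^2)))
    expect_lte(dtw_distance(a, b), lockstep + 1e-12)
  }
})

test_that("DTW matches the brute-force recursion on short series", {
  set.seed(34)
  for (i in 1:20) {
    a <- matrix(rnorm(sample(1:6, 1) * 4), ncol = 4)
    b <- matrix(rnorm(sample(1:6, 1) * 4), ncol = 4)
    expect_equal(dtw_distance(a, b), dtw_brute(a, b), tolerance = 1e-12)
  }
})

test_that("distance matrices satisfy their invariants with track ids attached", {
  set.seed(35)
  series <- lapply(1:8, function(i)
    window_features(gen_track("brownian", duration_s = 300, dt_s = 10, seed = NULL,
                              track_id = paste0("b", i))))
  D <- dtw_distance_matrix(series)
  expect_equal(dim(D), c(8, 8))
  expect_equal(diag(D), setNames(rep(0, 8), paste0("b", 1:8)))
  expect_equal(D, t(D))
  expect_true(all(D >= 0) && all(is.finite(D)))
  expect_equal(rownames(D), paste0("b", 1:8))
})

test_that("the 2D embedding is finite, deterministic, and separation-preserving", {
  set.seed(42)
  n_per <- 15
  labels <- rep(1:2, each = n_per)
  # block distance structure: between-group 10x within-group
  D <- matrix(10, 2 * n_per, 2 * n_per)
  D[1:n_per, 1:n_per] <- 1
  D[(n_per + 1):(2 * n_per), (n_per + 1):(2 * n_per)] <- 1
  diag(D) <- 0
  e1 <- embed_tracks(D, seed = 42)
  e2 <- embed_tracks(D, seed = 42)
  expect_equal(dim(e1$coords), c(30, 2))
  expect_true(all(is.finite(e1$coords)))
  expect_identical(e1$coords, e2$coords)
  expect_gt(mean_silhouette(e1$coords, labels), 0.5)
  expect_error(embed_tracks(matrix(0, 2, 2)), "at least 3")
})

test_that("density peaks recover planted blobs exactly", {
  set.seed(13)
  centers <- rbind(c(0.2, 0.2), c(0.2, 0.7), c(0.7, 0.45))
  pts <- do.call(rbind, lapply(1:3, function(g)
    cbind(rnorm(50, centers[g, 1], 0.02), rnorm(50, centers[g, 2], 0.02))))
  truth <- rep(1:3, each = 50)
  cl <- density_peak_cluster(pts, k = 3)
  expect_equal(ari(cl$label, truth), 1.0)
  expect_length(unique(cl$label), 3)
  expect_equal(cl$label[cl$centers], 1:3)
  # gamma of centers dominates the top-k selection
  expect_true(min(cl$gamma[cl$centers]) >= sort(cl$gamma, decreasing = TRUE)[3] - 1e-12)

  one <- density_peak_cluster(pts, k = 1)
  expect_true(all(one$label == 1))
  expect_error(density_peak_cluster(pts[1:5, ], k = 6), "exceeds")
})

test_that("graph assignment matches exhaustive shortest paths on tiny inputs", {
  set.seed(36)
  for (rep in 1:5) {
    pts <- matrix(runif(16), ncol = 2)  # 8 points
    k <- sample(2:3, 1)
    thr <- 0.45
    cl <- density_peak_cluster(pts, k = k, prune_threshold = thr)
    # oracle: min-max normalize, Floyd-Warshall over pruned graph
    norm <- apply(pts, 2, function(v) (v - min(v)) / (max(v) - min(v)))
    d <- as.matrix(dist(norm))
    w <- d; w[d > thr] <- Inf
    sp <- floyd_warshall(w)
    lab <- integer(8)
    for (i in 1:8) {
      costs <- sp[cl$centers, i]
      lab[i] <- if (all(is.infinite(costs))) which.min(d[cl$centers, i])
                else which.min(costs)
    }
    lab[cl$centers] <- seq_len(k)
    expect_equal(cl$label, lab)
  }
})

test_that("with no pruning, separated convex blobs reduce to nearest-center assignment", {
  set.seed(37)
  centers <- rbind(c(0.15, 0.15), c(0.85, 0.85))
  pts <- do.call(rbind, lapply(1:2, function(g)
    cbind(rnorm(40, centers[g, 1], 0.03), rnorm(40, centers[g, 2], 0.03))))
  cl <- density_peak_cluster(pts, k = 2, prune_threshold = Inf)
  norm <- apply(pts, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  d <- as.matrix(dist(norm))
  nearest <- apply(d[cl$centers, ], 2, which.min)
  expect_equal(cl$label, unname(nearest))
})

test_that("cluster profiles min-max normalize across clusters", {
  recs <- data.frame(speed = c(2, 2, 8, 8), directionality = c(0.5, 0.5, 0.5, 0.5),
                     arrest_coefficient = c(0.1, 0.1, 0.1, 0.1),
                     displacement = c(1, 1, 1, 1), path_length = c(4, 4, 4, 4))
  prof <- cluster_profile(c(1L, 1L, 2L, 2L), recs)
  expect_equal(unname(prof$normalized[, "speed"]), c(0, 1))
  expect_true(all(prof$normalized[, "directionality"] == 0.5))  # constant metric
  expect_equal(unname(prof$mean[, "speed"]), c(2, 8))

  single <- cluster_profile(rep(1L, 4), recs)
  expect_true(all(single$normalized == 0.5))
  expect_error(cluster_profile(c(1L, 1L, 3L, 3L), recs), "empty")
})

test_that("the pipeline recovers planted archetypes and is deterministic", {
  co <- gen_cohort(n_per = 30, seed = 21, duration_s = 600, dt_s = 10)
  res1 <- profile_pipeline(co$tracks, k = 4, seed = 42)
  res2 <- profile_pipeline(co$tracks, k = 4, seed = 42)
  expect_identical(res1$clusters$label, res2$clusters$label)
  expect_gte(ari(res1$clusters$label, co$labels$archetype), 0.6)

  # cluster dominated by directed tracks peaks the directionality profile;
  # the arrested-dominated cluster peaks the arrest profile
  maj <- function(arch) {
    tab <- table(res1$clusters$label[co$labels$archetype == arch])
    as.integer(names(tab)[which.max(tab)])
  }
  norm <- res1$profile$normalized
  expect_equal(unname(norm[maj("directed"), "directionality"]), 1)
  expect_equal(unname(norm[maj("arrested"), "arrest_coefficient"]), 1)
  expect_error(profile_pipeline(co$tracks[1], k = 2), "fewer than 2")
})
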