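rand_stack <- function(nt = 3, nz = 4, ny = 8, nx = 8, max_int = 100) {
  image_stack(array(runif(nt * nz * ny * nx, 0, max_int), dim = c(nt, nz, ny, nx)))
}

test_that("maximum intensity projection equals the per-pixel max over z", {
  set.seed(9)
  flat <- rand_stack(nz = 1)
  expect_equal(max_intensity_projection(flat),
               array(flat$data[, 1, , ], dim = dim(flat$data)[c(1, 3, 4)]))
  st <- rand_stack()
  st$data[2, 3, 5, 6] <- 1e5
  mip <- max_intensity_projection(st)
  expect_equal(mip[2, 5, 6], 1e5)
  for (i in 1:10) {
    st <- rand_stack()
    mip <- max_intensity_projection(st)
    d <- dim(st$data)
    oracle <- array(0, d[c(1, 3, 4)])
    for (ti in 1:d[1]) for (y in 1:d[3]) for (x in 1:d[4])
      oracle[ti, y, x] <- max(st$data[ti, , y, x])
    expect_equal(mip, oracle)
  }
})

test_that("8-bit normalization follows the quantile rule", {
  set.seed(10)
  movie <- array(runif(4 * 16 * 16, 0, 1000), dim = c(4, 16, 16))
  out <- normalize_8bit(movie, 0.01)
  q <- quantile(movie, 0.99, names = FALSE)
  expect_true(all(out >= 0 & out <= 255))
  expect_true(all(out[movie >= q] == 255))
  expect_equal(mean(out == 255), 0.01, tolerance = 0.3)

  expect_true(all(normalize_8bit(array(7, dim = c(2, 4, 4))) == 0))

  pure <- normalize_8bit(movie, 0)
  expect_equal(max(pure), 255)
  expect_equal(min(pure), 0)
  # monotone below the clip quantile
  v <- as.vector(movie); o <- as.vector(out)
  sel <- v < q
  expect_true(all(diff(o[sel][order(v[sel])]) >= 0))
})

test_that("saturation index counts pixels in [245, 255]", {
  expect_equal(saturation_index(array(255, dim = c(2, 3, 3))), 1)
  expect_equal(saturation_index(array(244, dim = c(2, 3, 3))), 0)
  half <- array(c(250, 100), dim = c(2, 4, 4))
  expect_equal(saturation_index(half), 0.5)
})

test_that("photobleaching index equals the closed-form OLS slope", {
  const <- array(42, dim = c(5, 4, 4))
  expect_equal(photobleaching_index(const), 0)
  ramp <- array(rep(10:1, times = 16), dim = c(10, 4, 4))  # T varies fastest
  expect_equal(photobleaching_index(ramp), -1)
  set.seed(12)
  means <- 100 * exp(-0.1 * (0:9)) # exponential bleaching
  movie <- array(rep(means, 16), dim = c(10, 4, 4))
  idx <- 0:9
  slope_oracle <- sum((idx - mean(idx)) * (means - mean(means))) / sum((idx - mean(idx))^2)
  expect_equal(photobleaching_index(movie), slope_oracle)
  expect_error(photobleaching_index(array(1, dim = c(1, 4, 4))), "frames")
})

test_that("signal variation is the CV of frame means and is scale invariant", {
  expect_equal(signal_variation_index(array(5, dim = c(4, 3, 3))), 0)
  alt <- array(rep(c(10, 20), 8), dim = c(16, 2, 2))
  # frame means alternate 10 and 20: population SD 5, mean 15
  expect_equal(signal_variation_index(alt), 1 / 3)
  expect_equal(signal_variation_index(alt * 10), signal_variation_index(alt))
})

test_that("contrast index is zero for a self-referencing movie and matches its formula", {
  bimodal <- array(rep(c(0, 255), 200), dim = c(4, 10, 10))
  expect_equal(contrast_index(bimodal), 0)
  set.seed(13)
  lowdr <- array(runif(400, 100, 140), dim = c(4, 10, 10))
  p <- quantile(lowdr, c(0.01, 0.99), names = FALSE)
  full <- range(lowdr)
  ref <- pmin(pmax((lowdr - p[1]) / (p[2] - p[1]) * (full[2] - full[1]) + full[1],
                   full[1]), full[2])
  oracle <- abs(var(as.vector(ref)) - var(as.vector(lowdr))) / var(as.vector(ref))
  expect_equal(contrast_index(lowdr), oracle)
  expect_gte(contrast_index(lowdr), 0)
  expect_error(contrast_index(array(1, dim = c(2, 3, 3))), "constant")
})

test_that("noise index matches a direct PSNR computation and decreases with noise", {
  expect_identical(noise_index(array(9, dim = c(2, 6, 6))), Inf)
  set.seed(5)
  base <- array(100, dim = c(2, 12, 12))
  add_impulses <- function(movie, n, amp) {
    idx <- sample(length(movie), n)
    movie[idx] <- pmin(movie[idx] + amp, 255)
    movie
  }
  noisy <- add_impulses(base, 30, 80)
  got <- noise_index(noisy)
  filt <- noisy
  for (ti in 1:2) filt[ti, , ] <- median3x3_oracle(noisy[ti, , ])
  mse <- mean((noisy - filt)^2)
  expect_equal(got, 10 * log10(255^2 / mse))
  psnrs <- vapply(c(10, 40, 120), function(n) noise_index(add_impulses(base, n, 80)),
                  numeric(1))
  expect_true(all(diff(psnrs) < 0))
})

test_that("quality composite is high for clean movies, lower with artifacts, and bounded", {
  pair <- gen_quality_pair(seed = 3)
  clean <- quality_report(pair$clean)
  bad <- quality_report(pair$artifacted)
  expect_gt(clean$composite, 0.9)
  expect_lt(bad$composite, clean$composite)
  expect_true(all(clean$goodness >= 0 & clean$goodness <= 1))
  expect_equal(clean$composite, mean(clean$goodness))

  set.seed(14)
  for (i in 1:50) {
    st <- rand_stack(nt = 3, nz = 2, ny = 8, nx = 8, max_int = runif(1, 1, 5000))
    comp <- quality_report(st)$composite
    expect_true(comp >= 0 && comp <= 1)
  }
})

test_that("composite degrades monotonically with each injected artifact", {
  set.seed(7)
  trks <- lapply(1:4, function(i)
    gen_track("brownian", speed_mean = 6, duration_s = 190, dt_s = 10, dim = 3,
              origin = c(runif(1, 16, 30), runif(1, 16, 30), 4),
              track_id = paste0("c", i)))
  trks <- lapply(trks, function(tr) {
    tr$points$x <- pmin(pmax(tr$points$x, 4), 38)
    tr$points$y <- pmin(pmax(tr$points$y, 4), 38)
    tr$points$z <- pmin(pmax(tr$points$z, 0), 8)
    tr
  })
  mk <- function(...) gen_movie(trks, dims = c(20, 5, 48, 48),
                                voxel_size_um = c(1, 1, 2), blob_amplitude = 100,
                                background = 10, seed = 5, ...)$stack
  comp <- function(st) quality_report(st)$composite
  severities <- list(
    bleach = sapply(c(0, 0.04, 0.08), function(b) comp(mk(bleach_rate = b))),
    noise = sapply(c(0, 10, 20), function(n) comp(mk(noise_sd = n))),
    saturation = sapply(c(Inf, 60, 30), function(s) comp(mk(saturation_level = s))),
    drift = sapply(c(0, 0.2, 0.4), function(d) comp(mk(drift_um_per_frame = c(d, 0)))))
  for (nm in names(severities))
    expect_true(all(diff(severities[[nm]]) < 0), label = paste("monotone", nm))
})

test_that("z estimation is exact on noiseless blobs at every depth", {
  for (z_true in 0:14) {
    tr3d <- track(t = c(0, 10, 20), x = c(10, 12, 14), y = c(10, 10, 12),
                  z = rep(z_true * 2, 3), track_id = "b")
    mv <- gen_movie(list(tr3d), dims = c(3, 15, 24, 24), voxel_size_um = c(1, 1, 2),
                    noise_sd = 0)
    tr2d <- track(t = c(0, 10, 20), x = c(10, 12, 14), y = c(10, 10, 12))
    est <- estimate_z(tr2d, mv$stack)
    expect_equal(est$z_index, rep(z_true, 3))
    expect_equal(est$z_um, rep(z_true * 2, 3))
  }
})

test_that("z estimation separates blobs, breaks ties low, and validates inputs", {
  trA <- track(t = c(0, 10), x = c(5, 5), y = c(5, 5), z = c(4, 4), track_id = "A")
  trB <- track(t = c(0, 10), x = c(20, 20), y = c(20, 20), z = c(16, 16), track_id = "B")
  mv <- gen_movie(list(trA, trB), dims = c(2, 11, 26, 26), voxel_size_um = c(1, 1, 2))
  for (tr in list(trA, trB)) {
    tr2d <- track(t = tr$points$t, x = tr$points$x, y = tr$points$y,
                  track_id = tr$track_id)
    est <- estimate_z(tr2d, mv$stack)
    expect_equal(est$z_um, tr$points$z)
  }
  # all-equal z profile: lowest index wins
  flat <- image_stack(array(3, dim = c(1, 6, 6, 6)))
  est <- estimate_z(track(t = 0, x = 2, y = 2), flat)
  expect_equal(est$z_index, 0L)

  st <- image_stack(array(1, dim = c(2, 3, 8, 8)), frame_interval_s = 10)
  expect_error(estimate_z(track(t = c(0, 35), x = c(1, 1), y = c(1, 1)), st), "frame")
  expect_error(estimate_z(track(t = c(0, 10), x = c(1, 100), y = c(1, 1)), st), "bounds")
})

test_that("z validation matches the coefficient-of-determination definition", {
  truth <- c(2, 4, 6, 8, 10)
  expect_equal(validate_z(truth, truth), 1)
  expect_equal(validate_z(rep(mean(truth), 5), truth), 0)
  expect_error(validate_z(c(1, 2), c(3, 3)), "constant")
})

test_that("TIFF stack IO round-trips intensities", {
  set.seed(20)
  st <- image_stack(array(sample(0:65535, 2 * 3 * 8 * 8, replace = TRUE),
                          dim = c(2, 3, 8, 8)),
                    voxel_size_um = c(1, 1, 2), frame_interval_s = 10)
  path <- tempfile(fileext = ".tiff")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path, n_z = 3, voxel_size_um = c(1, 1, 2),
                          frame_interval_s = 10)
  expect_equal(back$data, st$data)
  expect_error(read_stack_tiff(path, n_z = 5, voxel_size_um = c(1, 1, 2),
                               frame_interval_s = 10), "multiple")
})
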