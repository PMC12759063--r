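#' Construct a 3D+time image stack
#'
#' @param data Numeric array ordered T x Z x Y x X (Z may be 1); intensities
#'   must be non-negative and finite.
#' @param voxel_size_um Numeric length-3 vector: micrometres per voxel along
#'   (x, y, z).
#' @param frame_interval_s Seconds between consecutive time points.
#' @param bit_depth Source bit depth (informational; rendering always
#'   normalizes to 8 bits).
#' @return An object of class `ivtk_stack`.
#' @export
image_stack <- function(data, voxel_size_um = c(1, 1, 1), frame_interval_s = 10,
                        bit_depth = 16L) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1")
  if (any(voxel_size_um <= 0) || frame_interval_s <= 0)
    stop("voxel sizes and frame interval must be positive")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 bit_depth = as.integer(bit_depth)),
            class = "ivtk_stack")
}

#' @export
print.ivtk_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ivtk_stack> T=%d Z=%d Y=%d X=%d, voxel %.3g x %.3g x %.3g um, dt %.3g s\n",
              d[1], d[2], d[3], d[4], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3], x$frame_interval_s))
  invisible(x)
}

#' Read an image stack from a multi-page TIFF
#'
#' Pages must be ordered time-major (all z slices of frame 1, then frame 2,
#' ...). TIFF files carry no voxel-size or frame-interval tags this reader
#' trusts, so those must be supplied; the reader refuses to guess.
#'
#' @param path TIFF file path.
#' @param n_z Number of z slices per time point.
#' @param voxel_size_um Micrometres per voxel along (x, y, z).
#' @param frame_interval_s Seconds between frames.
#' @return An `ivtk_stack`.
#' @export
read_stack_tiff <- function(path, n_z, voxel_size_um, frame_interval_s) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(n_z) || missing(voxel_size_um) || missing(frame_interval_s))
    stop("TIFF stacks carry no trusted metadata: supply n_z, voxel_size_um and frame_interval_s")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) %% n_z != 0)
    stop("page count ", length(pages), " is not a multiple of n_z = ", n_z)
  n_t <- length(pages) %/% n_z
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(n_t, n_z, ny, nx))
  for (ti in seq_len(n_t)) for (zi in seq_len(n_z))
    arr[ti, zi, , ] <- pages[[(ti - 1) * n_z + zi]]
  image_stack(arr, voxel_size_um = voxel_size_um,
              frame_interval_s = frame_interval_s,
              bit_depth = attr(pages[[1]], "bits.per.sample") %||% 16L)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written time-major (T then Z), as 16-bit grayscale scaled by the
#' stack's value range `[0, 2^bit_depth - 1]`.
#'
#' @param stack An `ivtk_stack`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  maxval <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) {
    pages[[k]] <- pmin(stack$data[ti, zi, , ] / maxval, 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum intensity projection over z
#'
#' Collapses a T x Z x Y x X stack to a T x Y x X movie by taking, per time
#' point and (y, x) pixel, the maximum intensity across z.
#'
#' @param stack An `ivtk_stack`.
#' @return Numeric array T x Y x X.
#' @export
max_intensity_projection <- function(stack) {
  d <- dim(stack$data)
  if (d[2] == 1L) {
    out <- array(stack$data[, 1, , ], dim = d[c(1, 3, 4)])
    return(out)
  }
  apply(stack$data, c(1, 3, 4), max)
}

#' Normalize a movie to 8 bits, discarding saturated pixels
#'
#' Linearly maps `[min, q]` to `[0, 255]`, where `q` is the
#' `1 - saturate_fraction` quantile over the whole movie, and clips values
#' above `q` to 255. The 1% default reproduces the platform's rendering rule
#' of discarding the brightest 1% of pixels when setting the display range.
#' A constant movie maps to all zeros.
#'
#' @param movie Numeric array (any shape; typically T x Y x X).
#' @param saturate_fraction Fraction of top pixels to saturate, in [0, 1).
#' @return Array of the same shape with integer values in 0..255.
#' @export
normalize_8bit <- function(movie, saturate_fraction = 0.01) {
  stopifnot(saturate_fraction >= 0, saturate_fraction < 1)
  lo <- min(movie)
  q <- stats::quantile(movie, probs = 1 - saturate_fraction, names = FALSE)
  if (q <= lo) {
    out <- array(0, dim = dim(movie) %||% length(movie))
    return(out)
  }
  scaled <- (movie - lo) / (q - lo)
  out <- round(pmin(scaled, 1) * 255)
  array(out, dim = dim(movie) %||% length(movie))
}

#' Saturation index
#'
#' Fraction of pixels of an 8-bit movie with values in [245, 255] inclusive.
#'
#' @param movie_8bit 8-bit movie (values in 0..255).
#' @return Fraction in [0, 1].
#' @export
saturation_index <- function(movie_8bit) {
  mean(movie_8bit >= 245 & movie_8bit <= 255)
}

#' Photobleaching index
#'
#' Ordinary-least-squares slope of per-frame mean intensity against frame
#' index: a negative slope quantifies progressive loss of fluorescence over
#' the acquisition.
#'
#' @param movie Numeric array T x Y x X with >= 2 frames.
#' @return Slope in intensity units per frame.
#' @export
photobleaching_index <- function(movie) {
  n_t <- dim(movie)[1]
  if (is.null(n_t) || n_t < 2L) stop("photobleaching index needs >= 2 frames")
  means <- apply(movie, 1, mean)
  idx <- seq_len(n_t) - 1
  unname(stats::coef(stats::lm(means ~ idx))[2])
}

#' Signal variation index
#'
#' Coefficient of variation of the per-frame mean intensities (population
#' standard deviation divided by the overall mean): a scale-free measure of
#' how much the global signal level fluctuates over the video. Defined as 0
#' when the overall mean is 0.
#'
#' @param movie Numeric array T x Y x X with >= 2 frames.
#' @return Dimensionless CV >= 0.
#' @export
signal_variation_index <- function(movie) {
  n_t <- dim(movie)[1]
  if (is.null(n_t) || n_t < 2L) stop("signal variation index needs >= 2 frames")
  means <- apply(movie, 1, mean)
  mu <- mean(means)
  if (mu == 0) return(0)
  sqrt(mean((means - mu)^2)) / mu
}

# Contrast-optimized reference: linear stretch of the 1st-99th intensity
# percentiles onto the full range of the input, clipped.
contrast_reference <- function(movie, lower = 0.01, upper = 0.99) {
  p <- stats::quantile(movie, probs = c(lower, upper), names = FALSE)
  if (p[2] <= p[1]) stop("contrast reference undefined for (near-)constant movie")
  full <- range(movie)
  ref <- (movie - p[1]) / (p[2] - p[1]) * (full[2] - full[1]) + full[1]
  pmin(pmax(ref, full[1]), full[2])
}

#' Contrast index
#'
#' Compares the movie's pixel-intensity variance with that of an
#' automatically contrast-optimized reference (a linear stretch mapping the
#' 1st-99th percentiles to the full range, consistent with the rendering's
#' 1% saturation rule): `|Var(ref) - Var(original)| / Var(ref)`. Zero means
#' the movie already uses its dynamic range optimally; larger values mean
#' poorer contrast.
#'
#' @param movie Numeric, non-constant movie array.
#' @param lower,upper Stretch percentiles for the reference.
#' @return Non-negative dimensionless index.
#' @export
contrast_index <- function(movie, lower = 0.01, upper = 0.99) {
  if (min(movie) == max(movie)) stop("contrast index undefined for constant movie")
  ref <- contrast_reference(movie, lower, upper)
  v_ref <- stats::var(as.vector(ref))
  abs(v_ref - stats::var(as.vector(movie))) / v_ref
}

#' Noise index (PSNR against a median-filtered reference)
#'
#' Peak signal-to-noise ratio, in dB, between the 8-bit movie and a
#' per-frame 3x3 median-filtered copy (reflected borders):
#' `10 log10(255^2 / MSE)`. Higher means cleaner; a perfectly clean movie
#' (MSE 0) reports `Inf`.
#'
#' @param movie_8bit 8-bit movie array T x Y x X.
#' @return PSNR in dB (possibly `Inf`).
#' @export
noise_index <- function(movie_8bit) {
  n_t <- dim(movie_8bit)[1]
  if (is.null(n_t)) stop("noise index expects a T x Y x X movie")
  sq_err <- 0
  for (ti in seq_len(n_t)) {
    frame <- movie_8bit[ti, , ]
    filt <- median3x3_cpp(frame)
    sq_err <- sq_err + sum((frame - filt)^2)
  }
  mse <- sq_err / length(movie_8bit)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Video quality report
#'
#' Computes the five quality indices -- contrast (CR), noise (NR),
#' photobleaching (PB), saturation (SAT) and signal variation (SV) -- on the
#' 8-bit-normalized maximum intensity projection of the stack, the same
#' rendering the platform displays, then maps each to a goodness subscore in
#' [0, 1] and averages them into a composite score.
#'
#' Goodness mappings: `CR_good = 1 - min(CR, 1)`;
#' `NR_good = min(PSNR / psnr_ref_db, 1)` (infinite PSNR maps to 1);
#' `PB_good = 1 - min(max(0, -slope) * (T - 1) / mu0, 1)` where `mu0` is the
#' first-frame mean, i.e. the fractional intensity loss over the whole movie;
#' `SAT_good = 1 - SAT`; `SV_good = 1 - min(CV, 1)`. The composite is the
#' unweighted mean of the five (weights configurable).
#'
#' @param stack An `ivtk_stack` (single channel).
#' @param channel Channel selector; this build handles single-channel stacks,
#'   so only 1 is accepted.
#' @param saturate_fraction Rendering saturation fraction (see
#'   [normalize_8bit()]).
#' @param psnr_ref_db PSNR (dB) regarded as fully clean.
#' @param weights Optional length-5 non-negative weights for
#'   (CR, NR, PB, SAT, SV); default equal.
#' @return A list of class `ivtk_quality_report` with elements `raw`
#'   (the five indices), `goodness` (five subscores in [0, 1]), `composite`
#'   and `params`.
#' @export
quality_report <- function(stack, channel = 1L, saturate_fraction = 0.01,
                           psnr_ref_db = 50, weights = NULL) {
  if (!identical(as.integer(channel), 1L))
    stop("single-channel stacks only; channel must be 1")
  movie <- normalize_8bit(max_intensity_projection(stack), saturate_fraction)
  n_t <- dim(movie)[1]
  raw <- list(
    contrast_index = contrast_index(movie),
    noise_psnr_db = noise_index(movie),
    photobleach_slope = photobleaching_index(movie),
    saturation_fraction = saturation_index(movie),
    signal_variation_cv = signal_variation_index(movie))
  mu0 <- mean(movie[1, , ])
  pb_loss <- if (mu0 > 0) max(0, -raw$photobleach_slope) * (n_t - 1) / mu0 else 0
  goodness <- c(
    CR = 1 - min(raw$contrast_index, 1),
    NR = if (is.infinite(raw$noise_psnr_db)) 1 else min(raw$noise_psnr_db / psnr_ref_db, 1),
    PB = 1 - min(pb_loss, 1),
    SAT = 1 - raw$saturation_fraction,
    SV = 1 - min(raw$signal_variation_cv, 1))
  if (is.null(weights)) weights <- rep(1, 5)
  stopifnot(length(weights) == 5, all(weights >= 0), sum(weights) > 0)
  composite <- sum(goodness * weights) / sum(weights)
  structure(list(raw = raw, goodness = goodness, composite = unname(composite),
                 params = list(saturate_fraction = saturate_fraction,
                               psnr_ref_db = psnr_ref_db, weights = weights)),
            class = "ivtk_quality_report")
}

#' @export
print.ivtk_quality_report <- function(x, ...) {
  cat(sprintf("video quality composite: %.3f\n", x$composite))
  g <- x$goodness
  cat(sprintf("  CR %.3f  NR %.3f  PB %.3f  SAT %.3f  SV %.3f\n",
              g["CR"], g["NR"], g["PB"], g["SAT"], g["SV"]))
  invisible(x)
}

#' Recover z coordinates for a 2D track from a 3D+time stack
#'
#' For each track point, the z slice is the argmax of intensity over z at the
#' nearest pixel to the point's (x, y) in the matching frame -- the plane a
#' maximum intensity projection would have drawn that pixel from. Ties go to
#' the lowest z index (deterministic). Micrometre coordinates convert to
#' 0-based pixel indices by half-up rounding; timestamps must fall on the
#' stack's frame grid.
#'
#' @param track2d An `ivtk_track` without z.
#' @param stack An `ivtk_stack`.
#' @return A list of class `ivtk_z_estimate` with `z_index` (0-based
#'   integers), `z_um`, and `track3d` (the input track with z filled in).
#' @export
estimate_z <- function(track2d, stack) {
  validate_track(track2d)
  d <- dim(stack$data)
  vx <- stack$voxel_size_um
  t <- track2d$points$t
  frame_f <- t / stack$frame_interval_s
  frame <- round(frame_f)
  if (any(abs(frame_f - frame) > 1e-6))
    stop("timestamp(s) do not fall on the stack's frame grid: ",
         paste(utils::head(t[abs(frame_f - frame) > 1e-6], 3), collapse = ", "))
  if (any(frame < 0 | frame >= d[1]))
    stop("timestamp(s) outside the stack's time range")
  px <- floor(track2d$points$x / vx[1] + 0.5)
  py <- floor(track2d$points$y / vx[2] + 0.5)
  if (any(px < 0 | px >= d[4] | py < 0 | py >= d[3]))
    stop("track coordinate(s) outside the image bounds")
  z_index <- integer(length(t))
  for (i in seq_along(t)) {
    prof <- stack$data[frame[i] + 1L, , py[i] + 1L, px[i] + 1L]
    z_index[i] <- which.max(prof) - 1L   # which.max returns first max: lowest z
  }
  z_um <- z_index * vx[3]
  tr3d <- track(t = t, x = track2d$points$x, y = track2d$points$y, z = z_um,
                track_id = track2d$track_id, video_id = track2d$video_id,
                cell_type = track2d$cell_type,
                frame_interval_s = track2d$frame_interval_s)
  structure(list(z_index = z_index, z_um = z_um, track3d = tr3d),
            class = "ivtk_z_estimate")
}

#' Coefficient of determination between estimated and true z
#'
#' `R^2 = 1 - SS_res / SS_tot` of the estimates against ground truth; 1 for
#' perfect recovery, 0 for an estimator no better than the truth's mean. An
#' R^2 above 0.8 is conventionally taken as accurate z estimation.
#'
#' @param estimated Estimated z coordinates (um).
#' @param truth Ground-truth z coordinates (um), same length, non-constant.
#' @return R^2 (<= 1, possibly negative).
#' @export
validate_z <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("ground-truth z is constant; R^2 undefined")
  1 - sum((truth - estimated)^2) / ss_tot
}
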