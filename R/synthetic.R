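# Runs a generator under a temporary RNG state when a seed is given, so
# generators are pure functions of spec + seed without clobbering the
# caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cell track of a given motility archetype
#'
#' Discrete-time step models for the four motility archetypes the profiling
#' pipeline is validated against:
#' \describe{
#'   \item{directed}{persistent velocity: constant step length with small
#'     Gaussian turning noise; `persistence` is the expected directional
#'     correlation `E[cos(turn)]` per step.}
#'   \item{arrested}{isotropic Gaussian jitter of SD `jitter_sd` around a
#'     fixed point.}
#'   \item{brownian}{isotropic uncorrelated Gaussian steps whose mean step
#'     length matches `speed_mean`.}
#'   \item{run_and_pause}{a two-state Markov chain alternating directed runs
#'     and arrested pauses, entering pause at rate `pause_rate` and
#'     resuming at rate `run_rate` (per second).}
#' }
#'
#' @param mode One of `"directed"`, `"arrested"`, `"brownian"`,
#'   `"run_and_pause"`.
#' @param speed_mean Mean speed while moving, um/min.
#' @param persistence Directional correlation per step, in [0, 1]
#'   (directed / run phases).
#' @param jitter_sd Positional jitter SD, um (arrested / pause phases).
#' @param pause_rate,run_rate Switching rates, 1/s (`run_and_pause` only).
#' @param duration_s Track duration, s.
#' @param dt_s Sampling interval, s.
#' @param dim 2 or 3 spatial dimensions; in 3D the z axis performs a slow
#'   smooth walk.
#' @param origin Starting position (recycled to `dim`), um.
#' @param seed Optional integer; same seed, same track.
#' @param track_id,video_id,cell_type Metadata for the produced track.
#' @return An `ivtk_track` with attribute `"archetype"` set to `mode`.
#' @export
gen_track <- function(mode = c("directed", "arrested", "brownian", "run_and_pause"),
                      speed_mean = 10, persistence = 0.99, jitter_sd = 0.1,
                      pause_rate = 0.01, run_rate = 0.01,
                      duration_s = 600, dt_s = 10, dim = 2, origin = 100,
                      seed = NULL, track_id = "sim1", video_id = "sim",
                      cell_type = mode[1]) {
  mode <- match.arg(mode)
  stopifnot(persistence >= 0, persistence <= 1, pause_rate >= 0, run_rate >= 0,
            jitter_sd >= 0, speed_mean >= 0, duration_s >= dt_s, dt_s > 0,
            dim %in% c(2, 3))
  with_seed(seed, {
    n_steps <- floor(duration_s / dt_s)
    t <- seq(0, by = dt_s, length.out = n_steps + 1)
    step_len <- speed_mean * dt_s / 60
    origin <- rep_len(origin, dim)
    # turning-noise SD realizing E[cos(turn)] = persistence (wrapped normal)
    turn_sd <- if (persistence >= 1) 0 else sqrt(-2 * log(max(persistence, 1e-12)))
    p <- matrix(0, n_steps + 1, dim)
    p[1, ] <- origin
    if (mode == "arrested") {
      p <- matrix(rep(origin, each = n_steps + 1), ncol = dim) +
        matrix(stats::rnorm((n_steps + 1) * dim, 0, jitter_sd), ncol = dim)
      p[1, ] <- origin
    } else if (mode == "brownian") {
      sigma <- step_len / sqrt(pi / 2)  # E|N2(0, sigma I)| = sigma sqrt(pi/2)
      steps <- matrix(stats::rnorm(n_steps * 2, 0, sigma), ncol = 2)
      xy <- apply(steps, 2, cumsum)
      p[-1, 1:2] <- sweep(matrix(xy, ncol = 2), 2, origin[1:2], "+")
      p[1, ] <- origin
    } else {
      theta <- stats::runif(1, 0, 2 * pi)
      state_run <- TRUE
      p_pause <- 1 - exp(-pause_rate * dt_s)
      p_resume <- 1 - exp(-run_rate * dt_s)
      for (i in seq_len(n_steps)) {
        if (mode == "run_and_pause") {
          if (state_run && stats::runif(1) < p_pause) state_run <- FALSE
          else if (!state_run && stats::runif(1) < p_resume) state_run <- TRUE
        }
        if (mode == "directed" || state_run) {
          theta <- theta + stats::rnorm(1, 0, turn_sd)
          p[i + 1, 1:2] <- p[i, 1:2] + step_len * c(cos(theta), sin(theta))
        } else {
          p[i + 1, 1:2] <- p[i, 1:2] + stats::rnorm(2, 0, jitter_sd)
        }
      }
    }
    if (dim == 3 && mode != "arrested") {
      zstep <- stats::rnorm(n_steps, 0, step_len / 4)
      p[-1, 3] <- origin[3] + cumsum(zstep)
    }
    tr <- track(t = t, x = p[, 1], y = p[, 2],
                z = if (dim == 3) p[, 3] else NULL,
                track_id = track_id, video_id = video_id,
                cell_type = cell_type, frame_interval_s = dt_s)
    attr(tr, "archetype") <- mode
    tr
  })
}

#' Generate a labeled cohort of archetypal tracks
#'
#' @param n_per Tracks per archetype.
#' @param modes Archetypes to include.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param ... Further arguments passed to [gen_track()] (e.g. `duration_s`,
#'   `dt_s`, `dim`).
#' @return List with `tracks` (list of `ivtk_track`) and `labels`
#'   (data.frame `track_id`, `archetype`).
#' @export
gen_cohort <- function(n_per = 30,
                       modes = c("directed", "arrested", "brownian", "run_and_pause"),
                       seed = 21L, ...) {
  stopifnot(n_per >= 1, length(modes) >= 1)
  with_seed(seed, {
    tracks <- list()
    labels <- data.frame(track_id = character(0), archetype = character(0),
                         stringsAsFactors = FALSE)
    idx <- 0L
    for (m in modes) for (i in seq_len(n_per)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", m, i)
      tracks[[idx]] <- gen_track(mode = m, track_id = id, seed = NULL, ...)
      labels <- rbind(labels, data.frame(track_id = id, archetype = m,
                                         stringsAsFactors = FALSE))
    }
    names(tracks) <- labels$track_id
    list(tracks = tracks, labels = labels)
  })
}

# Render one separable 3D Gaussian blob into a Z x Y x X frame.
# Voxel centers sit at index * voxel (0-based indices, um).
render_blob <- function(dz, dy, dx, center_um, voxel, sigma_xy, sigma_z, amplitude) {
  zc <- (seq_len(dz) - 1) * voxel[3]
  yc <- (seq_len(dy) - 1) * voxel[2]
  xc <- (seq_len(dx) - 1) * voxel[1]
  gz <- exp(-(zc - center_um[3])^2 / (2 * sigma_z^2))
  gy <- exp(-(yc - center_um[2])^2 / (2 * sigma_xy^2))
  gx <- exp(-(xc - center_um[1])^2 / (2 * sigma_xy^2))
  amplitude * (gz %o% gy %o% gx)
}

#' Render synthetic 3D+time blob movies from tracks
#'
#' Each frame is `background` plus one 3D Gaussian blob per track, centered
#' on the track's true position at that frame time, scaled by
#' `(1 - bleach_rate)^frame`, translated by a uniform field drift, with
#' additive Gaussian noise (clamped at 0). The ground truth returned records
#' the rendered (post-drift) blob centers per frame.
#'
#' @param tracks3d List of 3D `ivtk_track` objects (z present); positions are
#'   linearly interpolated at frame times.
#' @param dims Integer T, Z, Y, X.
#' @param voxel_size_um Micrometres per voxel (x, y, z).
#' @param frame_interval_s Seconds per frame.
#' @param blob_sigma_um Lateral blob SD, um.
#' @param blob_sigma_z_um Axial blob SD, um.
#' @param blob_amplitude Peak blob intensity above background.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param bleach_rate Fractional intensity loss per frame, in [0, 1).
#' @param drift_um_per_frame Length-2 (x, y) field drift per frame, um.
#' @param saturation_level Detector ceiling: intensities are clipped here
#'   after rendering (`Inf` = no clipping). Setting it below the blob peak
#'   flattens blob tops and raises the rendered movie's saturation fraction.
#' @param seed Optional integer seed for the noise.
#' @return List with `stack` (an `ivtk_stack`) and `truth` (data.frame
#'   `track_id, frame, t, x, y, z` of rendered centers, um).
#' @export
gen_movie <- function(tracks3d, dims = c(30, 15, 64, 64),
                      voxel_size_um = c(1, 1, 2), frame_interval_s = 10,
                      blob_sigma_um = 2, blob_sigma_z_um = 3,
                      blob_amplitude = 100, background = 10, noise_sd = 0,
                      bleach_rate = 0, drift_um_per_frame = c(0, 0),
                      saturation_level = Inf, seed = NULL) {
  stopifnot(length(dims) == 4, all(dims >= 1), noise_sd >= 0,
            bleach_rate >= 0, bleach_rate < 1)
  lapply(tracks3d, function(tr) {
    validate_track(tr)
    if (!track_has_z(tr)) stop("gen_movie needs 3D tracks (z present)")
  })
  with_seed(seed, {
    nt <- dims[1]; nz <- dims[2]; ny <- dims[3]; nx <- dims[4]
    arr <- array(background, dim = dims)
    frame_t <- (seq_len(nt) - 1) * frame_interval_s
    lim <- c((nx - 1) * voxel_size_um[1], (ny - 1) * voxel_size_um[2],
             (nz - 1) * voxel_size_um[3])
    truth <- list()
    for (tr in tracks3d) {
      cx <- stats::approx(tr$points$t, tr$points$x, xout = frame_t, rule = 2)$y
      cy <- stats::approx(tr$points$t, tr$points$y, xout = frame_t, rule = 2)$y
      cz <- stats::approx(tr$points$t, tr$points$z, xout = frame_t, rule = 2)$y
      cx <- cx + (seq_len(nt) - 1) * drift_um_per_frame[1]
      cy <- cy + (seq_len(nt) - 1) * drift_um_per_frame[2]
      oob <- which(cx < 0 | cx > lim[1] | cy < 0 | cy > lim[2] | cz < 0 | cz > lim[3])
      if (length(oob))
        stop("track '", tr$track_id, "' leaves the volume at frame(s) ",
             paste(utils::head(oob, 5), collapse = ", "))
      for (f in seq_len(nt)) {
        blob <- render_blob(nz, ny, nx, c(cx[f], cy[f], cz[f]), voxel_size_um,
                            blob_sigma_um, blob_sigma_z_um,
                            blob_amplitude * (1 - bleach_rate)^(f - 1))
        arr[f, , , ] <- arr[f, , , ] + blob
      }
      truth[[tr$track_id]] <- data.frame(track_id = tr$track_id,
                                         frame = seq_len(nt) - 1L,
                                         t = frame_t, x = cx, y = cy, z = cz,
                                         stringsAsFactors = FALSE)
    }
    if (is.finite(saturation_level)) arr[arr > saturation_level] <- saturation_level
    if (noise_sd > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0, noise_sd), dim = dims)
    arr[arr < 0] <- 0
    list(stack = image_stack(arr, voxel_size_um = voxel_size_um,
                             frame_interval_s = frame_interval_s),
         truth = do.call(rbind, truth))
  })
}

#' Synthetic z-recovery benchmark case
#'
#' One Gaussian blob follows a 3D track whose z coordinate performs a
#' reflected random walk on the slice grid (so ground-truth z is always a
#' slice position), while x and y perform a persistent walk. The blob is
#' rendered with additive noise at the requested signal-to-noise ratio
#' (blob amplitude / noise SD); at `snr = Inf` the movie is noiseless and
#' the maximum-intensity z lookup recovers z exactly.
#'
#' @param seed Integer seed.
#' @param dims Stack dimensions T, Z, Y, X (Z >= 2).
#' @param voxel_size_um Micrometres per voxel (x, y, z).
#' @param frame_interval_s Seconds per frame.
#' @param snr Blob amplitude divided by noise SD; `Inf` for noiseless.
#' @return List with `stack`, `track2d` (the true (x, y, t) as an
#'   `ivtk_track`) and `truth_z_um` (true z per point).
#' @export
gen_zrecovery_case <- function(seed = 1L, dims = c(30, 15, 64, 64),
                               voxel_size_um = c(1, 1, 2),
                               frame_interval_s = 10, snr = 5) {
  with_seed(seed, {
    nt <- dims[1]; nz <- dims[2]
    # persistent lateral walk kept away from the borders
    margin <- 8
    span_x <- (dims[4] - 1) * voxel_size_um[1] - 2 * margin
    span_y <- (dims[3] - 1) * voxel_size_um[2] - 2 * margin
    x <- y <- numeric(nt)
    x[1] <- margin + stats::runif(1) * span_x
    y[1] <- margin + stats::runif(1) * span_y
    theta <- stats::runif(1, 0, 2 * pi)
    step <- 1.2  # um per frame
    for (f in 2:nt) {
      theta <- theta + stats::rnorm(1, 0, 0.4)
      x[f] <- min(max(x[f - 1] + step * cos(theta), margin), margin + span_x)
      y[f] <- min(max(y[f - 1] + step * sin(theta), margin), margin + span_y)
    }
    # z: reflected random walk on slice indices, +-1 or 0 per frame
    zi <- integer(nt)
    zi[1] <- sample.int(nz, 1) - 1L
    for (f in 2:nt) {
      zi[f] <- zi[f - 1] + sample(c(-1L, 0L, 1L), 1)
      if (zi[f] < 0L) zi[f] <- 1L
      if (zi[f] >= nz) zi[f] <- nz - 2L
    }
    z <- zi * voxel_size_um[3]
    t <- (seq_len(nt) - 1) * frame_interval_s
    tr3d <- track(t = t, x = x, y = y, z = z, track_id = paste0("zcase", seed),
                  video_id = paste0("zmovie", seed), frame_interval_s = frame_interval_s)
    amplitude <- 100
    noise_sd <- if (is.infinite(snr)) 0 else amplitude / snr
    mv <- gen_movie(list(tr3d), dims = dims, voxel_size_um = voxel_size_um,
                    frame_interval_s = frame_interval_s,
                    blob_amplitude = amplitude, background = 10,
                    noise_sd = noise_sd, seed = NULL)
    tr2d <- track(t = t, x = x, y = y, track_id = tr3d$track_id,
                  video_id = tr3d$video_id, frame_interval_s = frame_interval_s)
    list(stack = mv$stack, track2d = tr2d, truth_z_um = z)
  })
}

#' Matched clean/artifacted movie pair
#'
#' Renders the same blob content twice: once clean (no bleaching, no drift,
#' no noise, amplitudes within range) and once with photobleaching, field
#' drift and additive noise injected. Used to check that the composite
#' quality score orders a stable recording above an artifacted one.
#'
#' @param seed Integer seed; the pair is bit-reproducible from it.
#' @param dims Stack dimensions T, Z, Y, X.
#' @param bleach_rate,noise_sd,drift_um_per_frame Artifact severities for
#'   the degraded copy.
#' @return List with `clean` and `artifacted`, each an `ivtk_stack`.
#' @export
gen_quality_pair <- function(seed = 1L, dims = c(20, 5, 48, 48),
                             bleach_rate = 0.08, noise_sd = 15,
                             drift_um_per_frame = c(0.25, 0.15)) {
  with_seed(seed, {
    n_cells <- 4
    dur <- (dims[1] - 1) * 10
    trks <- lapply(seq_len(n_cells), function(i)
      gen_track(mode = "brownian", speed_mean = 6, duration_s = dur, dt_s = 10,
                dim = 3, origin = c(stats::runif(1, 14, 34), stats::runif(1, 14, 34),
                                    stats::runif(1, 2, 6)),
                seed = NULL, track_id = paste0("cell", i)))
    # clamp tracks into the volume
    lim <- c((dims[4] - 1) * 1, (dims[3] - 1) * 1, (dims[2] - 1) * 2)
    trks <- lapply(trks, function(tr) {
      tr$points$x <- pmin(pmax(tr$points$x, 2), lim[1] - 8)
      tr$points$y <- pmin(pmax(tr$points$y, 2), lim[2] - 8)
      tr$points$z <- pmin(pmax(tr$points$z, 0), lim[3])
      tr
    })
    clean <- gen_movie(trks, dims = dims, voxel_size_um = c(1, 1, 2),
                       frame_interval_s = 10, blob_amplitude = 100,
                       background = 10, noise_sd = 0, bleach_rate = 0,
                       drift_um_per_frame = c(0, 0), seed = NULL)
    bad <- gen_movie(trks, dims = dims, voxel_size_um = c(1, 1, 2),
                     frame_interval_s = 10, blob_amplitude = 100,
                     background = 10, noise_sd = noise_sd,
                     bleach_rate = bleach_rate,
                     drift_um_per_frame = drift_um_per_frame, seed = NULL)
    list(clean = clean$stack, artifacted = bad$stack)
  })
}
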