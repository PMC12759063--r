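#' Mean track speed
#'
#' Speed is the track path length (sum of consecutive Euclidean step lengths,
#' over whatever axes the track has) divided by track duration in minutes.
#'
#' @param track An `ivtk_track` with >= 2 points and positive duration.
#' @return Speed in um/min.
#' @export
track_speed <- function(track) {
  validate_track(track)
  if (nrow(track$points) < 2L) stop("speed needs >= 2 points")
  dur_min <- track_duration(track) / 60
  if (dur_min <= 0) stop("zero track duration")
  sum(track_steps(track)$len) / dur_min
}

#' Track path length
#' @param track An `ivtk_track`.
#' @return Total path length in um (0 for a single point).
#' @export
path_length <- function(track) sum(track_steps(track)$len)

#' Net displacement
#' @param track An `ivtk_track`.
#' @return Euclidean distance between first and last point, um.
#' @export
displacement <- function(track) {
  p <- track_coords(track)
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' Directionality (straightness / confinement ratio)
#'
#' Net displacement divided by path length, in [0, 1]: 1 for perfectly
#' straight monotone motion, 0 for a closed loop. Defined as 0 when the path
#' length is 0 (stationary track).
#'
#' @param track An `ivtk_track` with >= 2 points.
#' @return Dimensionless scalar in [0, 1].
#' @export
directionality <- function(track) {
  validate_track(track)
  if (nrow(track$points) < 2L) stop("directionality needs >= 2 points")
  pl <- path_length(track)
  if (pl == 0) return(0)
  displacement(track) / pl
}

#' Square displacement from the starting point
#'
#' Per time point, the squared Euclidean distance to the track's initial
#' position; the first element is always 0.
#'
#' @param track An `ivtk_track`.
#' @return Numeric vector of um^2, one element per point.
#' @export
square_displacement <- function(track) {
  p <- track_coords(track)
  rowSums(sweep(p, 2, p[1, ])^2)
}

#' Arrest coefficient
#'
#' The duration-weighted fraction of a track's time during which the
#' instantaneous speed (step length / step duration) is strictly below
#' `speed_threshold`: 1 means fully arrested, 0 never arrested. For
#' equal-duration steps this reduces to the plain fraction of slow steps.
#' The 2 um/min default is a common literature threshold for leukocyte
#' arrest and is configurable.
#'
#' @param track An `ivtk_track` with >= 2 points.
#' @param speed_threshold Arrest threshold in um/min.
#' @return Dimensionless scalar in [0, 1].
#' @export
arrest_coefficient <- function(track, speed_threshold = 2) {
  validate_track(track)
  if (nrow(track$points) < 2L) stop("arrest coefficient needs >= 2 points")
  st <- track_steps(track)
  inst_speed <- st$len / (st$dt / 60)
  sum(st$dt[inst_speed < speed_threshold]) / sum(st$dt)
}

#' Mean squared displacement by time lag
#'
#' `MSD(k)` is the mean over all overlapping pairs of points k samples apart
#' of their squared separation. Linear in lag for diffusive motion, quadratic
#' for ballistic motion. Requires uniform sampling.
#'
#' @param track A uniformly sampled `ivtk_track`.
#' @param max_lag Largest lag in samples; must be < number of points.
#' @return Numeric vector of um^2 for lags `0:max_lag` (MSD(0) = 0).
#' @export
msd <- function(track, max_lag) {
  validate_track(track)
  if (!is_uniform_track(track)) stop("msd requires a uniformly sampled track")
  n <- nrow(track$points)
  stopifnot(max_lag < n, max_lag >= 0)
  p <- track_coords(track)
  vapply(0:max_lag, function(k) {
    if (k == 0) return(0)
    d <- p[(k + 1):n, , drop = FALSE] - p[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Velocity autocovariance by time lag
#'
#' `acov(k)` is the mean dot product between step-velocity vectors k steps
#' apart; `acov(0)` is the mean squared instantaneous speed. Near zero at
#' positive lags for uncorrelated (Brownian) motion, positive for persistent
#' motion. Requires uniform sampling.
#'
#' @param track A uniformly sampled `ivtk_track`.
#' @param max_lag Largest lag in steps; must be < number of steps.
#' @return Numeric vector of (um/min)^2 for lags `0:max_lag`.
#' @export
velocity_autocovariance <- function(track, max_lag) {
  validate_track(track)
  if (!is_uniform_track(track)) stop("velocity autocovariance requires uniform sampling")
  st <- track_steps(track)
  n_steps <- nrow(st$vec)
  stopifnot(max_lag < n_steps, max_lag >= 0)
  v <- st$vec / (st$dt / 60)  # um/min step velocities
  vapply(0:max_lag, function(k) {
    i <- 1:(n_steps - k)
    mean(rowSums(v[i, , drop = FALSE] * v[i + k, , drop = FALSE]))
  }, numeric(1))
}

#' Mean turning angle
#'
#' Mean angle, in degrees within [0, 180], between consecutive step vectors.
#' Zero-length steps have no direction and are skipped.
#'
#' @param track An `ivtk_track` with >= 3 points.
#' @return Mean turning angle in degrees.
#' @export
mean_turning_angle <- function(track) {
  validate_track(track)
  if (nrow(track$points) < 3L) stop("turning angle needs >= 3 points")
  st <- track_steps(track)
  keep <- st$len > 0
  vec <- st$vec[keep, , drop = FALSE]
  if (nrow(vec) < 2L) stop("fewer than 2 non-zero steps; turning angle undefined")
  n <- nrow(vec)
  a <- vec[-n, , drop = FALSE]
  b <- vec[-1, , drop = FALSE]
  cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  mean(acos(cosang)) * 180 / pi
}

#' Per-track motility record
#'
#' Computes the standard per-track motility metrics in one pass. The record
#' carries a dimensionality flag (`dims`) because metrics from 2D-projected
#' and full 3D tracks are not directly comparable.
#'
#' @param track An `ivtk_track`.
#' @param arrest_threshold Arrest-coefficient speed threshold, um/min.
#' @return A one-row data.frame with columns `track_id, video_id, cell_type,
#'   dims, speed, directionality, arrest_coefficient, displacement,
#'   path_length, duration_min, mean_turning_angle`.
#' @export
motility_record <- function(track, arrest_threshold = 2) {
  data.frame(
    track_id = track$track_id,
    video_id = track$video_id,
    cell_type = track$cell_type,
    dims = if (track_has_z(track)) 3L else 2L,
    speed = track_speed(track),
    directionality = directionality(track),
    arrest_coefficient = arrest_coefficient(track, arrest_threshold),
    displacement = displacement(track),
    path_length = path_length(track),
    duration_min = track_duration(track) / 60,
    mean_turning_angle = if (nrow(track$points) >= 3L)
      tryCatch(mean_turning_angle(track), error = function(e) NA_real_)
    else NA_real_,
    stringsAsFactors = FALSE)
}

#' Motility records for a collection of tracks
#' @param tracks List of `ivtk_track` objects.
#' @param arrest_threshold Arrest-coefficient speed threshold, um/min.
#' @return A data.frame with one [motility_record()] row per track.
#' @export
motility_records <- function(tracks, arrest_threshold = 2) {
  if (!length(tracks)) stop("no tracks")
  dims <- vapply(tracks, track_has_z, logical(1))
  if (any(dims) && !all(dims))
    warning("mixing 2D and 3D tracks in one record table; metrics are not directly comparable")
  out <- do.call(rbind, lapply(tracks, motility_record, arrest_threshold = arrest_threshold))
  rownames(out) <- NULL
  out
}

#' Control-based residual speeds
#'
#' Removes per-video acquisition effects before pooling speeds across videos:
#' each track's residual speed is its speed minus the mean speed of the
#' control population in the same video. Control tracks therefore have
#' per-video mean residual exactly 0, and residuals of test populations can
#' be pooled and compared with stock statistics.
#'
#' @param records A motility record data.frame with columns `video_id`,
#'   `speed` and a population column.
#' @param control_population Label of the control population.
#' @param population_col Name of the column holding population labels
#'   (default `"cell_type"`).
#' @return `records` with an added `residual_speed` column.
#' @export
residual_speeds <- function(records, control_population, population_col = "cell_type") {
  stopifnot(all(c("video_id", "speed", population_col) %in% names(records)))
  pop <- records[[population_col]]
  ctrl_mean <- tapply(records$speed[pop == control_population],
                      records$video_id[pop == control_population], mean)
  videos <- unique(records$video_id)
  missing_ctrl <- setdiff(videos, names(ctrl_mean))
  if (length(missing_ctrl))
    stop("video(s) without control tracks: ", paste(missing_ctrl, collapse = ", "))
  records$residual_speed <- records$speed - unname(ctrl_mean[records$video_id])
  records
}

#' Fit an exponential decay of measured speed versus sampling interval
#'
#' Fits `speed = a * exp(b * dt)` by nonlinear least squares
#' (Levenberg-Marquardt), initialized from a log-linear fit on the positive
#' speeds. This is the single-exponential ("exp1") model describing how
#' measured speed decays as the interval between acquisitions grows.
#'
#' @param dt_s Sampling intervals in seconds (>= 3 distinct values).
#' @param speed Measured speeds in um/min, same length.
#' @return A list of class `ivtk_decay_fit` with `a` (um/min), `b` (1/s,
#'   negative for decay) and `residual_rmse` (um/min).
#' @export
fit_speed_decay <- function(dt_s, speed) {
  stopifnot(length(dt_s) == length(speed), length(dt_s) >= 3)
  if (length(unique(dt_s)) < 3)
    stop("need >= 3 distinct sampling intervals to fit a decay")
  if (stats::sd(speed) == 0)   # constant data: exact degenerate fit
    return(structure(list(a = speed[1], b = 0, residual_rmse = 0),
                     class = "ivtk_decay_fit"))
  pos <- speed > 0
  if (sum(pos) >= 2) {
    lin <- stats::lm(log(speed[pos]) ~ dt_s[pos])
    start <- list(a = exp(unname(stats::coef(lin)[1])), b = unname(stats::coef(lin)[2]))
  } else {
    start <- list(a = max(speed, 1e-6), b = -1e-3)
  }
  df <- data.frame(dt_s = dt_s, speed = speed)
  fit <- minpack.lm::nlsLM(speed ~ a * exp(b * dt_s), data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 residual_rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "ivtk_decay_fit")
}

#' @export
print.ivtk_decay_fit <- function(x, ...) {
  cat(sprintf("exp1 fit: speed = %.4g * exp(%.4g * dt)   RMSE %.4g um/min\n",
              x$a, x$b, x$residual_rmse))
  invisible(x)
}
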