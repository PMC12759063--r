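#' Construct a cell track
#'
#' A track is the time-ordered sequence of one cell's centroid positions, in
#' micrometres and seconds, together with identity metadata. It is the unit of
#' all motility analysis in this package.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   all >= 0.
#' @param x,y Numeric vectors of centroid coordinates in micrometres.
#' @param z Optional numeric vector of z coordinates in micrometres. Either
#'   present for all points or absent entirely.
#' @param track_id Character scalar identifying the track.
#' @param video_id Character scalar identifying the source video.
#' @param cell_type Free-text cell type label (e.g. "CD8 T cell").
#' @param frame_interval_s Optional native sampling interval in seconds.
#'
#' @return An object of class `ivtk_track`: a list with elements `track_id`,
#'   `video_id`, `cell_type`, `frame_interval_s` and `points` (a data.frame
#'   with columns `t`, `x`, `y` and optionally `z`).
#' @export
#' @examples
#' tr <- track(t = c(0, 10, 20), x = c(0, 1, 2), y = c(0, 0, 0))
#' track_duration(tr)
track <- function(t, x, y, z = NULL, track_id = "track1", video_id = "video1",
                  cell_type = "unknown", frame_interval_s = NULL) {
  pts <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) pts$z <- as.numeric(z)
  obj <- structure(
    list(track_id = as.character(track_id),
         video_id = as.character(video_id),
         cell_type = as.character(cell_type),
         frame_interval_s = if (is.null(frame_interval_s)) NULL else as.numeric(frame_interval_s),
         points = pts),
    class = "ivtk_track")
  validate_track(obj)
}

#' Validate a track's invariants
#'
#' Checks that points are non-empty, timestamps strictly increasing and
#' non-negative, all coordinates finite, and z either present for all points
#' or absent for all.
#'
#' @param track An `ivtk_track`.
#' @return The track, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_track <- function(track) {
  stopifnot(inherits(track, "ivtk_track"))
  pts <- track$points
  if (nrow(pts) == 0L)
    stop("track '", track$track_id, "': points must be non-empty")
  if (any(!is.finite(pts$t)) || any(pts$t < 0))
    stop("track '", track$track_id, "': timestamps must be finite and >= 0")
  if (nrow(pts) > 1L && any(diff(pts$t) <= 0))
    stop("track '", track$track_id, "': timestamps must be strictly increasing")
  coord_cols <- intersect(c("x", "y", "z"), names(pts))
  for (cc in coord_cols) {
    if (any(!is.finite(pts[[cc]])))
      stop("track '", track$track_id, "': non-finite ", cc, " coordinate")
  }
  if (!is.null(track$frame_interval_s) &&
      (!is.finite(track$frame_interval_s) || track$frame_interval_s <= 0))
    stop("track '", track$track_id, "': frame_interval_s must be positive")
  invisible(track)
}

#' @export
print.ivtk_track <- function(x, ...) {
  dims <- if (track_has_z(x)) "3D" else "2D"
  cat(sprintf("<ivtk_track %s> %s, %s, %d points (%s), %.0f s\n",
              x$track_id, x$video_id, x$cell_type, nrow(x$points), dims,
              track_duration(x)))
  invisible(x)
}

#' Does a track carry z coordinates?
#' @param track An `ivtk_track`.
#' @return Logical scalar.
#' @export
track_has_z <- function(track) "z" %in% names(track$points)

#' Track duration in seconds
#'
#' Durations are always computed from timestamps, never point counts, so
#' irregularly sampled tracks are handled correctly.
#'
#' @param track An `ivtk_track`.
#' @return Duration `t_last - t_first` in seconds.
#' @export
track_duration <- function(track) {
  t <- track$points$t
  t[length(t)] - t[1]
}

#' Coordinate matrix of a track
#' @param track An `ivtk_track`.
#' @return Numeric matrix with one row per point and columns for the axes the
#'   track has (x, y and optionally z), in micrometres.
#' @export
track_coords <- function(track) {
  cols <- intersect(c("x", "y", "z"), names(track$points))
  as.matrix(track$points[, cols, drop = FALSE])
}

#' Is a track uniformly sampled?
#' @param track An `ivtk_track`.
#' @param tol Relative tolerance on the step spread.
#' @return Logical scalar; single-step tracks count as uniform.
#' @export
is_uniform_track <- function(track, tol = 1e-6) {
  dt <- diff(track$points$t)
  if (length(dt) <= 1L) return(TRUE)
  (max(dt) - min(dt)) <= tol * mean(dt)
}

# Step lengths (µm) and step durations (s) between consecutive points.
track_steps <- function(track) {
  p <- track_coords(track)
  n <- nrow(p)
  if (n < 2L) return(list(len = numeric(0), dt = numeric(0), vec = p[0, , drop = FALSE]))
  vec <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  list(len = sqrt(rowSums(vec^2)), dt = diff(track$points$t), vec = vec)
}
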