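#' Read cell tracks from a file
#'
#' Supports three dialects:
#' \describe{
#'   \item{`native_csv`}{The package's own lossless schema: columns
#'     `track_id, video_id, cell_type, t_s, x_um, y_um` and optionally `z_um`,
#'     one row per point, UTF-8, header required.}
#'   \item{`trackmate_csv`}{TrackMate-style spot export with columns
#'     `TRACK_ID`, `POSITION_X/Y` (optionally `POSITION_Z`) and either
#'     `POSITION_T` (seconds) or `FRAME`; when only `FRAME` is present a
#'     `frame_interval_s` argument is required and t = frame * interval.}
#'   \item{`immunemap_json`}{A JSON array of records, each with track metadata
#'     and a `points` array of `{t, x, y, z}` objects. A top-level or
#'     per-record `time_units` field of "s" (seconds) or "frames" is
#'     required; files with frame-indexed time must also state
#'     `frame_interval_s`. Files that state neither are refused as ambiguous.}
#' }
#' All positions are micrometres and all times seconds after loading.
#'
#' @param path Path to the file.
#' @param dialect One of `"native_csv"`, `"trackmate_csv"`, `"immunemap_json"`.
#' @param frame_interval_s Frame interval in seconds, needed when the file
#'   indexes time by frame number.
#' @return A list of [track()] objects, points sorted by time, one per
#'   distinct track identifier.
#' @export
read_tracks <- function(path, dialect = c("native_csv", "trackmate_csv", "immunemap_json"),
                        frame_interval_s = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         native_csv = read_tracks_native(path),
         trackmate_csv = read_tracks_trackmate(path, frame_interval_s),
         immunemap_json = read_tracks_json(path, frame_interval_s))
}

# Build validated tracks from a long data.frame of points with metadata,
# checking for duplicate timestamps and sorting by time.
tracks_from_long <- function(df, frame_interval_s = NULL) {
  split_idx <- split(seq_len(nrow(df)), df$track_id)
  lapply(split_idx, function(idx) {
    d <- df[idx, , drop = FALSE]
    d <- d[order(d$t), , drop = FALSE]
    if (anyDuplicated(d$t))
      stop("duplicate timestamp for track '", d$track_id[1], "'")
    if (any(diff(d$t) <= 0))
      stop("non-monotone timestamps for track '", d$track_id[1], "'")
    track(t = d$t, x = d$x, y = d$y,
          z = if ("z" %in% names(d)) d$z else NULL,
          track_id = d$track_id[1], video_id = d$video_id[1],
          cell_type = d$cell_type[1], frame_interval_s = frame_interval_s)
  })
}

read_tracks_native <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "video_id", "cell_type", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("native CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$t_s) | !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  out <- data.frame(track_id = as.character(df$track_id),
                    video_id = as.character(df$video_id),
                    cell_type = as.character(df$cell_type),
                    t = df$t_s, x = df$x_um, y = df$y_um,
                    stringsAsFactors = FALSE)
  if ("z_um" %in% names(df) && !all(is.na(df$z_um))) {
    if (any(is.na(df$z_um)))
      stop("z_um present for some rows but not all")
    out$z <- df$z_um
  }
  tracks_from_long(out)
}

read_tracks_trackmate <- function(path, frame_interval_s) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # TrackMate exports often carry 2-3 extra header rows of units; drop
  # non-numeric leading rows.
  if (nrow(df) && any(is.na(suppressWarnings(as.numeric(df$POSITION_X))))) {
    numeric_ok <- !is.na(suppressWarnings(as.numeric(df$POSITION_X)))
    df <- df[numeric_ok, , drop = FALSE]
  }
  req <- c("TRACK_ID", "POSITION_X", "POSITION_Y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("TrackMate CSV missing column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(c("POSITION_X", "POSITION_Y", "POSITION_Z", "POSITION_T", "FRAME"),
                       names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  if ("POSITION_T" %in% names(df)) {
    t <- df$POSITION_T
  } else if ("FRAME" %in% names(df)) {
    if (is.null(frame_interval_s))
      stop("TrackMate file has FRAME but no POSITION_T; supply frame_interval_s")
    t <- df$FRAME * frame_interval_s
  } else stop("TrackMate CSV needs POSITION_T or FRAME")
  out <- data.frame(track_id = as.character(df$TRACK_ID),
                    video_id = tools::file_path_sans_ext(basename(path)),
                    cell_type = "unknown",
                    t = t, x = df$POSITION_X, y = df$POSITION_Y,
                    stringsAsFactors = FALSE)
  if ("POSITION_Z" %in% names(df)) out$z <- df$POSITION_Z
  tracks_from_long(out, frame_interval_s = frame_interval_s)
}

read_tracks_json <- function(path, frame_interval_s) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(recs$tracks)) { top_units <- recs$time_units; recs <- recs$tracks }
  else top_units <- NULL
  out <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    units <- if (!is.null(r$time_units)) r$time_units else top_units
    if (is.null(units))
      stop("JSON record ", i, " has no time_units field ('s' or 'frames'); ",
           "refusing ambiguous file")
    pts <- r$points
    if (is.null(pts) || !length(pts)) stop("JSON record ", i, " has no points")
    t <- vapply(pts, function(p) as.numeric(p$t), numeric(1))
    if (identical(units, "frames")) {
      fi <- if (!is.null(r$frame_interval_s)) as.numeric(r$frame_interval_s) else frame_interval_s
      if (is.null(fi)) stop("JSON record ", i, " is frame-indexed but states no frame_interval_s")
      t <- t * fi
    } else if (!identical(units, "s")) {
      stop("JSON record ", i, ": unknown time_units '", units, "'")
    }
    zs <- lapply(pts, function(p) p$z)
    has_z <- all(!vapply(zs, is.null, logical(1)))
    track(t = t,
          x = vapply(pts, function(p) as.numeric(p$x), numeric(1)),
          y = vapply(pts, function(p) as.numeric(p$y), numeric(1)),
          z = if (has_z) vapply(zs, as.numeric, numeric(1)) else NULL,
          track_id = if (!is.null(r$track_id)) r$track_id else paste0("track", i),
          video_id = if (!is.null(r$video_id)) r$video_id else "video1",
          cell_type = if (!is.null(r$cell_type)) r$cell_type else "unknown",
          frame_interval_s = if (!is.null(r$frame_interval_s)) as.numeric(r$frame_interval_s) else frame_interval_s)
  })
  names(out) <- vapply(out, function(tr) tr$track_id, character(1))
  out
}

#' Write cell tracks to a file
#'
#' Writable dialects are `native_csv` and `immunemap_json`. A
#' read-after-write round trip reproduces the tracks up to float formatting
#' (coordinates within 1e-6 um). The z column/field is present when every
#' track has z and omitted when none does; mixing is an error.
#'
#' @param tracks List of [track()] objects (may be empty).
#' @param path Output path.
#' @param dialect `"native_csv"` or `"immunemap_json"`.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path, dialect = c("native_csv", "immunemap_json")) {
  dialect <- match.arg(dialect)
  lapply(tracks, validate_track)
  has_z <- vapply(tracks, track_has_z, logical(1))
  if (length(tracks) && any(has_z) && !all(has_z))
    stop("cannot mix tracks with and without z in one file")
  with_z <- length(tracks) > 0L && all(has_z)
  if (dialect == "native_csv") {
    rows <- lapply(tracks, function(tr) {
      d <- data.frame(track_id = tr$track_id, video_id = tr$video_id,
                      cell_type = tr$cell_type, t_s = tr$points$t,
                      x_um = tr$points$x, y_um = tr$points$y,
                      stringsAsFactors = FALSE)
      if (with_z) d$z_um <- tr$points$z
      d
    })
    hdr <- c("track_id", "video_id", "cell_type", "t_s", "x_um", "y_um",
             if (with_z) "z_um")
    df <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(hdr))), hdr)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(tracks, function(tr) {
      pts <- lapply(seq_len(nrow(tr$points)), function(i) {
        p <- tr$points[i, ]
        out <- list(t = p$t, x = p$x, y = p$y)
        if (with_z) out$z <- p$z
        out
      })
      rec <- list(track_id = tr$track_id, video_id = tr$video_id,
                  cell_type = tr$cell_type, time_units = "s", points = pts)
      if (!is.null(tr$frame_interval_s)) rec$frame_interval_s <- tr$frame_interval_s
      rec
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Resample a track onto a uniform time grid
#'
#' Linearly interpolates centroid coordinates per axis onto the grid
#' `t_first, t_first + dt, ...` up to the last grid point not after the last
#' timestamp. No extrapolation occurs; the grid is anchored at the first
#' timestamp, preserving relative timing. The 10 s default matches the
#' uniform sampling used before windowed feature extraction.
#'
#' @param track An `ivtk_track` with at least 2 points.
#' @param dt Target sampling interval in seconds.
#' @return A resampled `ivtk_track` with `frame_interval_s = dt`.
#' @export
resample_track <- function(track, dt = 10) {
  validate_track(track)
  if (nrow(track$points) < 2L) stop("cannot resample a single-point track")
  stopifnot(dt > 0)
  t0 <- track$points$t[1]
  t1 <- track$points$t[nrow(track$points)]
  grid <- seq(t0, t1 + dt / 2, by = dt)
  grid <- grid[grid <= t1 + 1e-9]
  interp <- function(v) stats::approx(track$points$t, v, xout = grid, rule = 1)$y
  track(t = grid, x = interp(track$points$x), y = interp(track$points$y),
        z = if (track_has_z(track)) interp(track$points$z) else NULL,
        track_id = track$track_id, video_id = track$video_id,
        cell_type = track$cell_type, frame_interval_s = dt)
}

#' Keep tracks at least a minimum duration long
#'
#' Duration is computed from timestamps (`t_last - t_first`), and the bound
#' is inclusive. The 500 s default is the duration filter applied before
#' motility-pattern profiling.
#'
#' @param tracks List of tracks.
#' @param min_duration_s Minimum duration in seconds.
#' @return The sublist of tracks with duration >= `min_duration_s`.
#' @export
filter_by_duration <- function(tracks, min_duration_s = 500) {
  keep <- vapply(tracks, function(tr) track_duration(tr) >= min_duration_s, logical(1))
  tracks[keep]
}

#' Split a track into fixed-duration fragments
#'
#' Produces consecutive, non-overlapping fragments each spanning exactly
#' `fragment_duration_s` by timestamp; the trailing remainder shorter than
#' the window is discarded, so all fragments are comparable. Fragment ids
#' suffix the parent id (`<id>_f1`, `<id>_f2`, ...).
#'
#' @param track An `ivtk_track`.
#' @param fragment_duration_s Fragment span in seconds.
#' @return A (possibly empty) list of fragment tracks.
#' @export
fragment_track <- function(track, fragment_duration_s = 500) {
  stopifnot(fragment_duration_s > 0)
  validate_track(track)
  t <- track$points$t
  t0 <- t[1]
  n_frag <- floor((t[length(t)] - t0) / fragment_duration_s + 1e-9)
  if (n_frag < 1) return(list())
  out <- vector("list", n_frag)
  for (k in seq_len(n_frag)) {
    lo <- t0 + (k - 1) * fragment_duration_s
    hi <- lo + fragment_duration_s
    idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
    sub <- track$points[idx, , drop = FALSE]
    out[[k]] <- track(t = sub$t, x = sub$x, y = sub$y,
                      z = if (track_has_z(track)) sub$z else NULL,
                      track_id = paste0(track$track_id, "_f", k),
                      video_id = track$video_id, cell_type = track$cell_type,
                      frame_interval_s = track$frame_interval_s)
  }
  out
}

#' Temporally subsample a uniform track
#'
#' Keeps every `factor`-th point starting from the first, multiplying the
#' effective sampling interval by `factor`. Used to study how coarser
#' temporal resolution biases motility metrics.
#'
#' @param track A uniformly sampled `ivtk_track`.
#' @param factor Positive integer subsampling factor.
#' @return The subsampled `ivtk_track`.
#' @export
subsample_track <- function(track, factor) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  if (!is_uniform_track(track))
    stop("track '", track$track_id, "' is not uniformly sampled; resample_track() first")
  if (factor == 1) return(track)
  idx <- seq(1, nrow(track$points), by = factor)
  sub <- track$points[idx, , drop = FALSE]
  dt <- if (!is.null(track$frame_interval_s)) track$frame_interval_s * factor else NULL
  track(t = sub$t, x = sub$x, y = sub$y,
        z = if (track_has_z(track)) sub$z else NULL,
        track_id = track$track_id, video_id = track$video_id,
        cell_type = track$cell_type, frame_interval_s = dt)
}

#' Extract fixed-length tracklets with controlled overlap
#'
#' Tracklets equalize track duration before metric comparison: each has
#' exactly `n_steps` steps (`n_steps + 1` points) and successive start
#' indices are spaced by `n_steps - max_overlap` points. An incomplete final
#' window is dropped. Defaults (20 steps, at most 15 overlapping) match the
#' tracklet extraction used for cross-video motility comparison.
#'
#' @param track An `ivtk_track`.
#' @param n_steps Steps per tracklet (>= 1).
#' @param max_overlap Maximum overlapping steps between consecutive
#'   tracklets; `0 <= max_overlap < n_steps`.
#' @return A (possibly empty) list of tracklet tracks with ids
#'   `<id>_t1`, `<id>_t2`, ...
#' @export
extract_tracklets <- function(track, n_steps = 20, max_overlap = 15) {
  stopifnot(n_steps >= 1, max_overlap >= 0, max_overlap < n_steps)
  validate_track(track)
  n_pts <- nrow(track$points)
  stride <- n_steps - max_overlap
  starts <- seq(1L, n_pts, by = stride)
  starts <- starts[starts + n_steps <= n_pts]
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + n_steps)
    sub <- track$points[idx, , drop = FALSE]
    track(t = sub$t, x = sub$x, y = sub$y,
          z = if (track_has_z(track)) sub$z else NULL,
          track_id = paste0(track$track_id, "_t", k),
          video_id = track$video_id, cell_type = track$cell_type,
          frame_interval_s = track$frame_interval_s)
  })
}
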