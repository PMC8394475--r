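# Trajectory containers, CSV dialects, and marker-based pose reconstruction.

POSE_CSV_HEADER <- c(
  "time_s", "pos_sag_mm", "pos_trans_mm", "pos_long_mm",
  "rot_flex_deg", "rot_latflex_deg", "rot_rot_deg"
)

#' Construct a head pose track
#'
#' A pose track is the common container for one device's recording of one
#' trial: a time base in seconds plus three position channels (mm, lab frame)
#' and three rotation channels (degrees).  Positions follow the anatomical
#' axes: sagittal (front-back), transversal (side-to-side), longitudinal
#' (vertical, gravity-aligned).  Rotations are flexion (nodding), lateral
#' flexion (ear-to-shoulder) and rotation (yaw), from the intrinsic Euler
#' sequence rotation -> flexion -> lateral flexion.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param pos_sagittal,pos_transversal,pos_longitudinal positions in mm.
#' @param rot_flexion,rot_lateral_flexion,rot_rotation rotations in degrees.
#' @param device `"tg"` (training game, instrument under test) or
#'   `"reference"` (optoelectronic motion-capture system).
#' @param nominal_rate nominal sampling rate in Hz (30 for the training game,
#'   120 for the reference system).
#' @param gap optional logical vector flagging frames with no valid pose
#'   (e.g. marker occlusion); flagged frames carry `NA` channels.
#' @return An object of class `pose_track`: a data frame with columns
#'   `time`, the six channels and `gap`, plus attributes `device` and
#'   `nominal_rate`.
#' @examples
#' t <- seq(0, 1, by = 1 / 30)
#' trk <- pose_track(t, sin(t), 0 * t, 1700 + 0 * t, 0 * t, 0 * t, 0 * t,
#'   device = "tg", nominal_rate = 30)
#' @export
pose_track <- function(time, pos_sagittal, pos_transversal, pos_longitudinal,
                       rot_flexion, rot_lateral_flexion, rot_rotation,
                       device = c("tg", "reference"), nominal_rate,
                       gap = NULL) {
  device <- match.arg(device)
  d <- data.frame(
    time = as.numeric(time),
    pos_sagittal = as.numeric(pos_sagittal),
    pos_transversal = as.numeric(pos_transversal),
    pos_longitudinal = as.numeric(pos_longitudinal),
    rot_flexion = as.numeric(rot_flexion),
    rot_lateral_flexion = as.numeric(rot_lateral_flexion),
    rot_rotation = as.numeric(rot_rotation)
  )
  d$gap <- if (is.null(gap)) rep(FALSE, nrow(d)) else as.logical(gap)
  attr(d, "device") <- device
  attr(d, "nominal_rate") <- as.numeric(nominal_rate)
  class(d) <- c("pose_track", "data.frame")
  validate_pose_track(d)
}

#' Validate a pose track's invariants
#'
#' Checks strictly increasing time, equal channel lengths and that the median
#' sampling interval is within 20% of `1/nominal_rate`.
#'
#' @param track a `pose_track`.
#' @return The track, invisibly unchanged, or an error.
#' @export
validate_pose_track <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  rate <- attr(track, "nominal_rate")
  if (!is.numeric(rate) || rate <= 0) stop("nominal_rate must be > 0")
  t <- track$time
  if (anyNA(t)) stop("timestamps contain NA")
  if (length(t) >= 2L) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop(sprintf("time not strictly increasing at row %d", bad[1] + 1L))
    }
    med <- stats::median(dt)
    if (abs(med - 1 / rate) > 0.2 / rate) {
      stop(sprintf(
        "median sampling interval %.4g s deviates more than 20%% from nominal 1/%g s",
        med, rate
      ))
    }
  }
  ok <- !track$gap
  for (ch in ALL_CHANNELS) {
    if (anyNA(track[[ch]][ok])) stop(sprintf("channel %s has NA outside gaps", ch))
  }
  track
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf(
    "<pose_track> device=%s rate=%g Hz n=%d span=[%.3f, %.3f] s gaps=%d\n",
    attr(x, "device"), attr(x, "nominal_rate"), nrow(x),
    if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA,
    sum(x$gap)
  ))
  invisible(x)
}

#' Duration of a pose track in seconds
#' @param track a `pose_track`.
#' @return numeric scalar, `max(time) - min(time)`.
#' @export
track_duration <- function(track) {
  if (nrow(track) < 2L) return(0)
  max(track$time) - min(track$time)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a pose track to CSV
#'
#' Dialect: header
#' `time_s,pos_sag_mm,pos_trans_mm,pos_long_mm,rot_flex_deg,rot_latflex_deg,rot_rot_deg`,
#' comma separator, `.` decimal point regardless of locale, full double
#' precision (round trips bit-exactly through [read_pose_csv()]).
#'
#' @param track a `pose_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  if (nrow(track) == 0L) stop("refusing to write an empty track")
  cols <- c("time", ALL_CHANNELS)
  m <- vapply(cols, function(ch) fmt_full(track[[ch]]), character(nrow(track)))
  m <- matrix(m, nrow = nrow(track))
  lines <- c(
    paste(POSE_CSV_HEADER, collapse = ","),
    apply(m, 1L, paste, collapse = ",")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

strict_numeric <- function(x, col, path) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !(trimws(x) %in% c("NA", "", "NaN")))
  if (length(bad)) {
    stop(sprintf(
      "malformed numeric value %s in column %s of %s (row %d)",
      dQuote(x[bad[1]]), col, path, bad[1]
    ))
  }
  y
}

#' Read a pose track from CSV
#'
#' Strict reader for the dialect written by [write_pose_csv()]: a missing
#' column is a format error naming the column; a non-monotone timestamp is a
#' validation error with the first offending row; malformed numerics are
#' never silently coerced.
#'
#' @param path input file path.
#' @param device,nominal_rate metadata to attach; `nominal_rate = NULL`
#'   estimates the rate from the median sampling interval.
#' @return a `pose_track`.
#' @export
read_pose_csv <- function(path, device = c("tg", "reference"),
                          nominal_rate = NULL) {
  device <- match.arg(device)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(POSE_CSV_HEADER, names(raw))
  if (length(missing)) {
    stop(sprintf("format error: missing column(s) %s in %s",
                 paste(missing, collapse = ", "), path))
  }
  vals <- lapply(POSE_CSV_HEADER, function(col) strict_numeric(raw[[col]], col, path))
  names(vals) <- c("time", ALL_CHANNELS)
  if (is.null(nominal_rate)) {
    dt <- stats::median(diff(vals$time))
    if (!is.finite(dt) || dt <= 0) stop("cannot estimate sampling rate")
    # round to mHz so a 30 Hz file yields exactly 30, not 1/(1/30) in floats
    nominal_rate <- round(1 / dt, 3)
  }
  gap <- Reduce(`|`, lapply(vals[ALL_CHANNELS], is.na))
  do.call(pose_track, c(vals, list(
    device = device, nominal_rate = nominal_rate, gap = gap
  )))
}

#' Construct a marker track (reference-system raw form)
#'
#' @param time numeric timestamps in seconds.
#' @param markers named list of exactly four n-by-3 matrices (columns x, y, z
#'   in mm, lab frame), one per labelled reflective marker on the headset.
#' @param gap optional n-by-4 logical matrix flagging occluded
#'   (missing) marker samples; inferred from NA rows when omitted.
#' @return an object of class `marker_track`.
#' @export
marker_track <- function(time, markers, gap = NULL) {
  if (length(markers) != 4L) stop("exactly four marker labels required")
  labels <- names(markers)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("marker labels must be unique and non-empty")
  }
  n <- length(time)
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3L) stop("each marker needs an n-by-3 matrix")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  if (is.null(gap)) {
    gap <- vapply(markers, function(m) rowSums(is.na(m)) > 0, logical(n))
    gap <- matrix(gap, nrow = n, dimnames = list(NULL, labels))
  }
  structure(
    list(time = as.numeric(time), markers = markers, gap = gap,
         labels = labels),
    class = "marker_track"
  )
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf(
    "<marker_track> markers=%s n=%d occluded frames=%d\n",
    paste(x$labels, collapse = ","), length(x$time),
    sum(rowSums(x$gap) > 0)
  ))
  invisible(x)
}

#' Headset marker model
#'
#' Local coordinates (mm, headset frame) of the four reflective markers.  The
#' default is a 100 x 60 mm rectangle matching a phone-on-headset footprint,
#' centred on the origin, with Vicon-style head labels.  Markers are coplanar
#' in the local z = 0 plane; the out-of-plane direction is fixed by requiring
#' a proper rotation (det +1) in the rigid fit.
#'
#' @param coords named list of length-3 numeric local coordinates; exactly
#'   four markers, pairwise distances > 10 mm.
#' @return object of class `hmd_marker_model`: a 4-by-3 matrix with row names.
#' @export
hmd_marker_model <- function(coords = list(
                               LFHD = c(50, 30, 0), RFHD = c(50, -30, 0),
                               LBHD = c(-50, 30, 0), RBHD = c(-50, -30, 0)
                             )) {
  if (length(coords) != 4L) stop("exactly four markers required")
  labels <- names(coords)
  if (is.null(labels) || anyDuplicated(labels)) stop("labels must be unique")
  m <- do.call(rbind, lapply(coords, as.numeric))
  if (ncol(m) != 3L) stop("each marker needs 3 local coordinates")
  rownames(m) <- labels
  dd <- as.matrix(stats::dist(m))
  if (any(dd[upper.tri(dd)] <= 10)) stop("pairwise marker distances must exceed 10 mm")
  class(m) <- c("hmd_marker_model", class(m))
  m
}

#' Kabsch rigid rotation fitting centred model points to centred observations
#' @noRd
kabsch <- function(model_c, obs_c) {
  H <- t(model_c) %*% obs_c
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Reconstruct the headset pose from marker trajectories
#'
#' Position is the centroid of the visible markers (mm); orientation is the
#' rotation of a least-squares rigid (Kabsch) fit of the marker model to the
#' observed markers, decomposed into flexion / lateral flexion / rotation in
#' the package Euler convention.  Frames with fewer than three visible
#' markers, or with a degenerate (collinear) visible set, become gaps.
#'
#' @param markers a `marker_track`.
#' @param model an `hmd_marker_model`; labels must match the track's.
#' @param nominal_rate sampling rate to attach (Hz); default 120.
#' @return a `pose_track` with `device = "reference"`; gap frames carry NA.
#' @export
pose_from_markers <- function(markers, model = hmd_marker_model(),
                              nominal_rate = 120) {
  stopifnot(inherits(markers, "marker_track"))
  labels <- markers$labels
  if (!setequal(labels, rownames(model))) {
    stop("marker labels do not match the model")
  }
  model <- unclass(model)[labels, , drop = FALSE]
  n <- length(markers$time)
  pos <- matrix(NA_real_, n, 3)
  ang <- matrix(NA_real_, n, 3)
  gap <- rep(FALSE, n)
  obs_all <- array(NA_real_, c(n, 4, 3))
  for (j in seq_along(labels)) obs_all[, j, ] <- markers$markers[[j]]
  for (i in seq_len(n)) {
    vis <- which(!markers$gap[i, ])
    if (length(vis) < 3L) {
      gap[i] <- TRUE
      next
    }
    obs <- matrix(obs_all[i, vis, ], ncol = 3)
    mod <- model[vis, , drop = FALSE]
    obs_cent <- colMeans(obs)
    mod_cent <- colMeans(mod)
    obs_c <- sweep(obs, 2, obs_cent)
    mod_c <- sweep(mod, 2, mod_cent)
    # collinear visible set: rank of centred model/observation < 2
    if (svd(mod_c)$d[2] < 1e-8 || svd(obs_c)$d[2] < 1e-8) {
      gap[i] <- TRUE
      next
    }
    R <- kabsch(mod_c, obs_c)
    pos[i, ] <- obs_cent
    ang[i, ] <- matrix_to_euler(R)
  }
  pose_track(
    time = markers$time,
    pos_sagittal = pos[, 1], pos_transversal = pos[, 2],
    pos_longitudinal = pos[, 3],
    rot_flexion = ang[, 1], rot_lateral_flexion = ang[, 2],
    rot_rotation = ang[, 3],
    device = "reference", nominal_rate = nominal_rate, gap = gap
  )
}

#' Fill short occlusion gaps by linear interpolation
#'
#' Gaps of duration at most `max_gap` seconds are filled channel-wise by
#' linear interpolation between the bounding valid samples; longer gaps (and
#' gaps touching either end of the recording) keep their flag and are
#' excluded from downstream metrics.
#'
#' @param track a `pose_track` with flagged gaps.
#' @param max_gap maximum gap duration to fill, in seconds.
#' @return a `pose_track` with short gaps filled.
#' @export
interpolate_gaps <- function(track, max_gap = 0.2) {
  stopifnot(inherits(track, "pose_track"))
  g <- track$gap
  if (!any(g)) return(track)
  if (all(g)) {
    warning("track consists entirely of gaps; returned unchanged")
    return(track)
  }
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    if (i0 == 1L || i1 == nrow(track)) next  # edge gap: nothing to bridge
    span <- track$time[i1 + 1L] - track$time[i0 - 1L]
    if (span > max_gap) next
    idx <- i0:i1
    for (ch in ALL_CHANNELS) {
      y0 <- track[[ch]][i0 - 1L]
      y1 <- track[[ch]][i1 + 1L]
      w <- (track$time[idx] - track$time[i0 - 1L]) / span
      track[[ch]][idx] <- y0 + w * (y1 - y0)
    }
    track$gap[idx] <- FALSE
  }
  track
}

#' Write a marker track to CSV
#'
#' Dialect: `time_s,<label>_x_mm,<label>_y_mm,<label>_z_mm` for each of the
#' four labels; occluded samples are written as empty fields.
#'
#' @param markers a `marker_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_track"))
  header <- c("time_s", unlist(lapply(
    markers$labels, function(l) paste0(l, "_", c("x", "y", "z"), "_mm")
  )))
  n <- length(markers$time)
  cols <- list(fmt_full(markers$time))
  for (j in seq_along(markers$labels)) {
    m <- markers$markers[[j]]
    for (k in 1:3) {
      v <- fmt_full(m[, k])
      v[markers$gap[, j] | is.na(m[, k])] <- ""
      cols <- c(cols, list(v))
    }
  }
  lines <- c(
    paste(header, collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a marker track from CSV (dialect of [write_marker_csv()])
#'
#' @param path input file path.
#' @return a `marker_track`; empty fields become occlusion gaps.
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"time_s" %in% names(raw)) stop("format error: missing column time_s")
  xcols <- grep("_x_mm$", names(raw), value = TRUE)
  labels <- sub("_x_mm$", "", xcols)
  if (length(labels) != 4L) stop("expected exactly four marker labels")
  time <- strict_numeric(raw$time_s, "time_s", path)
  markers <- lapply(labels, function(l) {
    cbind(
      x = strict_numeric(raw[[paste0(l, "_x_mm")]], paste0(l, "_x_mm"), path),
      y = strict_numeric(raw[[paste0(l, "_y_mm")]], paste0(l, "_y_mm"), path),
      z = strict_numeric(raw[[paste0(l, "_z_mm")]], paste0(l, "_z_mm"), path)
    )
  })
  names(markers) <- labels
  marker_track(time, markers)
}
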