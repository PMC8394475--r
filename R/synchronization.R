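# Time and frame registration of the two streams: resampling, lag
# estimation by normalized cross-correlation on the nod landmark, and
# signed-permutation frame alignment.

#' Resample a pose track onto a target time grid
#'
#' All channels are linearly interpolated; rotation channels are unwrapped
#' first so interpolation never crosses a +/-180 degree seam.  Requests
#' outside the track's time span are an error (no extrapolation).
#'
#' @param track a `pose_track`.
#' @param target_times numeric vector of times (s) within the track span.
#' @return a `pose_track` on the target grid, same device metadata; the
#'   nominal rate is re-estimated from the target grid.
#' @export
resample <- function(track, target_times) {
  stopifnot(inherits(track, "pose_track"))
  t <- track$time
  if (length(target_times) == 0L) stop("empty target grid")
  if (min(target_times) < min(t) - 1e-9 || max(target_times) > max(t) + 1e-9) {
    stop(sprintf(
      "extrapolation request: target span [%.3f, %.3f] exceeds track span [%.3f, %.3f]",
      min(target_times), max(target_times), min(t), max(t)
    ))
  }
  vals <- lapply(ALL_CHANNELS, function(ch) {
    y <- track[[ch]]
    if (ch %in% ROTATION_CHANNELS) y <- unwrap_deg(y)
    stats::approx(t, y, xout = target_times, rule = 2)$y
  })
  names(vals) <- ALL_CHANNELS
  dt <- stats::median(diff(target_times))
  rate <- if (is.finite(dt) && dt > 0) 1 / dt else attr(track, "nominal_rate")
  do.call(pose_track, c(list(time = target_times), vals, list(
    device = attr(track, "device"), nominal_rate = rate
  )))
}

#' Shift a track's clock
#'
#' Subtracts `lag` from every timestamp, moving a stream estimated to be
#' `lag` seconds behind the reference onto the reference time base.
#'
#' @param track a `pose_track`.
#' @param lag seconds (positive = stream was behind).
#' @return the shifted `pose_track`.
#' @export
apply_lag <- function(track, lag) {
  track$time <- track$time - lag
  track
}

#' Estimate the clock lag between the two streams
#'
#' Normalized cross-correlation of one mean-removed channel (by default the
#' flexion channel, where the five-nod synchronization movement lives; the
#' longitudinal position is the fallback).  Both streams are compared on the
#' training-game time grid (the coarser stream).  The lag maximizing the
#' correlation over integer-sample shifts in `+/- search_window` is refined
#' to sub-sample precision by parabolic interpolation of the correlation
#' peak.  Positive lag means the training-game stream is behind the
#' reference.
#'
#' @param tg,ref `pose_track`s covering at least the nod segment.
#' @param channel channel name to correlate.
#' @param search_window half-width of the lag search, s.
#' @return object of class `sync_result`: list with `lag` (s), `peak_corr`,
#'   `channel`, `search_window` and `low_confidence` (TRUE, with a warning,
#'   when `peak_corr < 0.5`).
#' @export
estimate_lag <- function(tg, ref, channel = "rot_flexion", search_window = 3) {
  stopifnot(inherits(tg, "pose_track"), inherits(ref, "pose_track"))
  if (!channel %in% ALL_CHANNELS) stop("unknown channel: ", channel)
  y_tg <- tg[[channel]]
  y_ref <- ref[[channel]]
  if (stats::sd(y_tg) < 1e-12 || stats::sd(y_ref) < 1e-12) {
    stop(sprintf("channel %s has zero variance; lag undefined", channel))
  }
  if (channel %in% ROTATION_CHANNELS) {
    y_tg <- unwrap_deg(y_tg)
    y_ref <- unwrap_deg(y_ref)
  }
  dt <- 1 / attr(tg, "nominal_rate")
  kmax <- max(1L, ceiling(search_window / dt))
  ks <- (-kmax):kmax
  cors <- vapply(ks, function(k) {
    shifted <- tg$time - k * dt
    yr <- stats::approx(ref$time, y_ref, xout = shifted, rule = 1)$y
    ok <- !is.na(yr)
    if (sum(ok) < 10L) return(NA_real_)
    a <- y_tg[ok]
    b <- yr[ok]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(cors))) stop("no overlapping samples within the search window")
  i <- which.max(cors)
  lag <- ks[i] * dt
  peak <- cors[i]
  # parabolic sub-sample refinement on the three points around the peak
  if (i > 1L && i < length(ks) && !is.na(cors[i - 1]) && !is.na(cors[i + 1])) {
    denom <- cors[i - 1] - 2 * cors[i] + cors[i + 1]
    if (abs(denom) > 1e-12) {
      delta <- 0.5 * (cors[i - 1] - cors[i + 1]) / denom
      if (abs(delta) <= 1) lag <- lag + delta * dt
    }
  }
  lag <- max(-search_window, min(search_window, lag))
  res <- structure(
    list(lag = lag, peak_corr = peak, channel = channel,
         search_window = search_window, low_confidence = peak < 0.5),
    class = "sync_result"
  )
  if (res$low_confidence) {
    warning(sprintf(
      "low-confidence synchronization: peak correlation %.3f < 0.5", peak
    ))
  }
  res
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> lag=%.4f s peak_corr=%.3f channel=%s window=+/-%g s%s\n",
    x$lag, x$peak_corr, x$channel, x$search_window,
    if (x$low_confidence) " [LOW CONFIDENCE]" else ""
  ))
  invisible(x)
}

#' All 48 signed axis permutations
#'
#' The 3x3 orthogonal matrices with entries in \{-1, 0, 1\} and exactly one
#' nonzero entry per row and column: 6 permutations x 8 sign patterns.
#'
#' @return list of 48 matrices.
#' @export
signed_permutations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  out <- vector("list", 48L)
  n <- 0L
  for (p in perms) {
    for (r in seq_len(nrow(signs))) {
      P <- matrix(0, 3, 3)
      for (row in 1:3) P[row, p[row]] <- signs[r, row]
      n <- n + 1L
      out[[n]] <- P
    }
  }
  out
}

#' Apply a signed axis map and offset to a track's position channels
#'
#' `pos_new = P %*% pos_old + offset`, row order (sagittal, transversal,
#' longitudinal).  Used to inject and to undo world-frame mismatches.
#'
#' @param track a `pose_track`.
#' @param P 3x3 signed permutation matrix.
#' @param offset length-3 numeric, mm.
#' @return the transformed `pose_track`.
#' @export
apply_axis_map <- function(track, P, offset = c(0, 0, 0)) {
  pos <- as.matrix(track[, POSITION_CHANNELS])
  pos <- pos %*% t(P) + matrix(offset, nrow(pos), 3, byrow = TRUE)
  track$pos_sagittal <- pos[, 1]
  track$pos_transversal <- pos[, 2]
  track$pos_longitudinal <- pos[, 3]
  track
}

#' Register the training-game frame onto the reference frame
#'
#' The training game's world frame is gravity-aligned by its inertial unit,
#' so its axes can differ from the lab frame at most by a signed axis
#' relabeling plus a translation.  The signed permutation maximizing the sum
#' of per-axis Pearson correlations between the (lag-corrected, common-grid)
#' streams is selected among all 48 candidates, then per-axis mean
#' differences are removed.  Rotation channels get a per-channel mean-offset
#' correction (`rot_offset`) so a constant yaw mismatch does not contaminate
#' rotation metrics.  A full free-rotation Procrustes fit is available with
#' `free_rotation = TRUE`.
#'
#' @param tg,ref `pose_track`s, lag-corrected and on a common grid (equal
#'   lengths).
#' @param free_rotation if TRUE, fit an unconstrained rotation (Kabsch on
#'   mean-centred positions) instead of a signed permutation.
#' @param ambiguity_tol relative score separation under which the choice of
#'   permutation is declared ambiguous (error).
#' @return list with `tg` (the aligned track) and `alignment` (class
#'   `frame_alignment`: `axis_map`, `static_offset`, `rot_offset`,
#'   `score`).
#' @export
align_frames <- function(tg, ref, free_rotation = FALSE, ambiguity_tol = 0.01) {
  stopifnot(inherits(tg, "pose_track"), inherits(ref, "pose_track"))
  if (nrow(tg) != nrow(ref)) {
    stop("streams must be on a common grid (run overlap_crop first)")
  }
  pos_tg <- as.matrix(tg[, POSITION_CHANNELS])
  pos_ref <- as.matrix(ref[, POSITION_CHANNELS])
  ctg <- sweep(pos_tg, 2, colMeans(pos_tg))
  cref <- sweep(pos_ref, 2, colMeans(pos_ref))

  if (free_rotation) {
    P <- kabsch(ctg, cref)  # rotation mapping tg -> ref
  } else {
    sd_tg <- apply(ctg, 2, stats::sd)
    sd_ref <- apply(cref, 2, stats::sd)
    cross <- crossprod(ctg, cref) / (nrow(ctg) - 1)  # covariance matrix
    cand <- signed_permutations()
    scores <- vapply(cand, function(P) {
      s <- 0
      for (axis in 1:3) {
        j <- which(P[axis, ] != 0)
        if (sd_tg[j] < 1e-12 || sd_ref[axis] < 1e-12) next
        s <- s + P[axis, j] * cross[j, axis] / (sd_tg[j] * sd_ref[axis])
      }
      s
    }, numeric(1))
    ord <- order(scores, decreasing = TRUE)
    best <- scores[ord[1]]
    second <- scores[ord[2]]
    if (best - second < ambiguity_tol * max(abs(best), 1e-9)) {
      stop(sprintf(
        "ambiguous frame alignment: top scores %.4f and %.4f within %.0f%%",
        best, second, 100 * ambiguity_tol
      ))
    }
    P <- cand[[ord[1]]]
  }

  mapped <- pos_tg %*% t(P)
  static_offset <- colMeans(pos_ref) - colMeans(mapped)
  aligned <- apply_axis_map(tg, P, static_offset)

  rot_offset <- vapply(ROTATION_CHANNELS, function(ch) {
    mean(ref[[ch]]) - mean(aligned[[ch]])
  }, numeric(1))
  for (ch in ROTATION_CHANNELS) aligned[[ch]] <- aligned[[ch]] + rot_offset[ch]

  score <- if (free_rotation) NA_real_ else best
  alignment <- structure(
    list(axis_map = P, static_offset = static_offset,
         rot_offset = rot_offset, score = score,
         free_rotation = free_rotation),
    class = "frame_alignment"
  )
  list(tg = aligned, alignment = alignment)
}

#' @export
print.frame_alignment <- function(x, ...) {
  cat("<frame_alignment>\n axis_map:\n")
  print(unname(x$axis_map))
  cat(sprintf(" static_offset (mm): %s\n rot_offset (deg): %s\n",
              paste(sprintf("%.1f", x$static_offset), collapse = ", "),
              paste(sprintf("%.2f", x$rot_offset), collapse = ", ")))
  invisible(x)
}

#' Crop both streams to their common time span on a common grid
#'
#' The common grid is the training-game timestamps falling inside the
#' overlap (the coarser stream; no detail is invented at the reference
#' rate).  The reference stream is linearly resampled onto that grid, so
#' both returned tracks have identical timestamps and equal length.
#'
#' @param tg,ref `pose_track`s, lag already applied.
#' @return list with `tg` and `ref` on the common grid.
#' @export
overlap_crop <- function(tg, ref) {
  stopifnot(inherits(tg, "pose_track"), inherits(ref, "pose_track"))
  lo <- max(min(tg$time), min(ref$time))
  hi <- min(max(tg$time), max(ref$time))
  if (hi <= lo) stop("streams have no overlapping time span")
  keep <- tg$time >= lo - 1e-12 & tg$time <= hi + 1e-12
  if (!any(keep)) stop("no training-game samples in the overlap")
  grid <- tg$time[keep]
  tg_c <- tg[keep, , drop = FALSE]
  attr(tg_c, "device") <- attr(tg, "device")
  attr(tg_c, "nominal_rate") <- attr(tg, "nominal_rate")
  class(tg_c) <- c("pose_track", "data.frame")
  ref_c <- resample(ref, grid)
  attr(ref_c, "device") <- attr(ref, "device")
  list(tg = tg_c, ref = ref_c)
}
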