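# Repetition segmentation, time-independent amplitude extraction,
# height-scaled exercise recognition, and cross-system rep pairing.

EXERCISES <- c("squat", "side_step", "step_up")

#' Primary movement axis of an exercise
#'
#' The axis with the largest excursion: transversal for the side-step,
#' longitudinal for the squat and the step-up.
#'
#' @param exercise one of `"squat"`, `"side_step"`, `"step_up"`.
#' @return `"transversal"` or `"longitudinal"`.
#' @export
primary_axis <- function(exercise) {
  switch(as.character(exercise),
    side_step = "transversal",
    squat = "longitudinal",
    step_up = "longitudinal",
    stop("unknown exercise label: ", exercise)
  )
}

axis_channel <- function(axis) {
  switch(axis,
    sagittal = "pos_sagittal",
    transversal = "pos_transversal",
    longitudinal = "pos_longitudinal",
    stop("unknown axis: ", axis)
  )
}

#' Height-scaled recognition thresholds
#'
#' Displacement thresholds as fractions of subject height, used both to
#' recognize which exercise a movement segment contains and to detect
#' repetitions without ground-truth labels.  Defaults are chosen so that the
#' default synthetic displacements exceed them with at least a 2x margin.
#'
#' @param squat_frac,step_up_frac,side_step_frac fractions of height in (0,1).
#' @param min_rep_duration minimum time between repetition peaks, s.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(squat_frac = 0.10, step_up_frac = 0.07,
                          side_step_frac = 0.10, min_rep_duration = 0.8) {
  fr <- c(squat_frac, step_up_frac, side_step_frac)
  if (any(fr <= 0) || any(fr >= 1)) stop("threshold fractions must lie in (0,1)")
  structure(
    list(squat_frac = squat_frac, step_up_frac = step_up_frac,
         side_step_frac = side_step_frac,
         min_rep_duration = min_rep_duration),
    class = "threshold_set"
  )
}

threshold_of <- function(thresholds, exercise, height) {
  height * switch(exercise,
    squat = thresholds$squat_frac,
    step_up = thresholds$step_up_frac,
    side_step = thresholds$side_step_frac
  )
}

# one repetition per contiguous super-threshold excursion: runs of
# s > 0.1 * thr (the near-baseline crossings) whose maximum reaches thr and
# whose duration reaches min_dur samples.  A flat plateau (step-up hold) is
# a single region regardless of how many noisy local maxima sit on it.
excursion_regions <- function(s, thr, min_dur) {
  r <- rle(s > 0.1 * thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    i0 <- starts[k]
    i1 <- ends[k]
    if (i1 - i0 + 1L < min_dur) next
    if (max(s[i0:i1]) < thr) next
    out[[length(out) + 1L]] <- c(i0, i1)
  }
  out
}

#' Segment exercise repetitions
#'
#' With a ground-truth segment table (synthetic data), intervals are copied
#' from the labels.  Without labels, excursions on each exercise's primary
#' axis are detected as contiguous regions above the near-baseline level
#' (10% of the height-scaled threshold) whose maximum reaches the full
#' threshold and whose duration reaches `min_rep_duration`; each region is
#' one repetition and its interval spans the surrounding threshold
#' crossings, so a flat step-up plateau counts once however many noisy
#' local maxima it carries.  Baselines are the per-channel medians (the
#' subject stands most of the time).  When detections of different
#' exercises overlap in time, the one with the larger threshold-normalized
#' excursion wins.
#'
#' @param track an aligned, cropped `pose_track`.
#' @param protocol_labels optional data frame with columns `label`,
#'   `start_s`, `end_s` (e.g. `ground_truth$segments` or a sidecar CSV).
#' @param height subject height, mm (required without labels).
#' @param thresholds a [threshold_set()].
#' @return data frame of class `exercise_reps` with columns `exercise`,
#'   `source`, `start_s`, `end_s`, `axis`; possibly zero rows.
#' @export
segment_repetitions <- function(track, protocol_labels = NULL, height = NULL,
                                thresholds = threshold_set()) {
  stopifnot(inherits(track, "pose_track"))
  source <- attr(track, "device")
  if (!is.null(protocol_labels)) {
    lab <- protocol_labels
    lab$exercise <- ifelse(grepl("^side_step", lab$label), "side_step", lab$label)
    lab <- lab[lab$exercise %in% EXERCISES, , drop = FALSE]
    lo <- min(track$time)
    hi <- max(track$time)
    lab <- lab[lab$start_s >= lo - 1e-9 & lab$end_s <= hi + 1e-9, , drop = FALSE]
    reps <- data.frame(
      exercise = lab$exercise,
      source = source,
      start_s = lab$start_s,
      end_s = lab$end_s,
      axis = vapply(lab$exercise, primary_axis, character(1)),
      stringsAsFactors = FALSE
    )
    rownames(reps) <- NULL
    class(reps) <- c("exercise_reps", "data.frame")
    return(reps)
  }
  if (is.null(height)) stop("height is required for label-free segmentation")
  t <- track$time
  dt <- stats::median(diff(t))
  min_sep <- max(1L, round(thresholds$min_rep_duration / dt))
  base_long <- stats::median(track$pos_longitudinal)
  base_trans <- stats::median(track$pos_transversal)
  signals <- list(
    squat = base_long - track$pos_longitudinal,
    step_up = track$pos_longitudinal - base_long,
    side_step = abs(track$pos_transversal - base_trans)
  )
  out <- list()
  for (ex in EXERCISES) {
    thr <- threshold_of(thresholds, ex, height)
    s <- signals[[ex]]
    for (iv in excursion_regions(s, thr, min_sep)) {
      out[[length(out) + 1L]] <- data.frame(
        exercise = ex, source = source,
        start_s = t[iv[1]], end_s = t[iv[2]],
        axis = primary_axis(ex),
        score = max(s[iv[1]:iv[2]]) / thr,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    reps <- data.frame(
      exercise = character(0), source = character(0),
      start_s = numeric(0), end_s = numeric(0), axis = character(0),
      stringsAsFactors = FALSE
    )
    class(reps) <- c("exercise_reps", "data.frame")
    return(reps)
  }
  reps <- do.call(rbind, out)
  # precedence across exercises: larger threshold-normalized excursion wins
  reps <- reps[order(-reps$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(reps))
  for (i in seq_len(nrow(reps))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(reps))) {
      if (j == i || !keep[j]) next
      if (reps$exercise[i] != reps$exercise[j] &&
          reps$start_s[j] < reps$end_s[i] && reps$start_s[i] < reps$end_s[j]) {
        keep[j] <- FALSE
      }
    }
  }
  reps <- reps[keep, setdiff(names(reps), "score"), drop = FALSE]
  reps <- reps[order(reps$start_s), , drop = FALSE]
  rownames(reps) <- NULL
  class(reps) <- c("exercise_reps", "data.frame")
  reps
}

#' Time-independent repetition amplitude
#'
#' Maximum minus minimum of the axis channel within the interval, each
#' extremum located independently of when it occurs.  Gap frames are
#' excluded.
#'
#' @param track a `pose_track`.
#' @param interval length-2 numeric `(start_s, end_s)` within the track span.
#' @param axis `"sagittal"`, `"transversal"` or `"longitudinal"`.
#' @return amplitude in mm (>= 0).
#' @export
rep_amplitude <- function(track, interval, axis) {
  stopifnot(inherits(track, "pose_track"), length(interval) == 2L)
  if (interval[2] <= interval[1]) stop("empty interval")
  idx <- which(track$time >= interval[1] - 1e-9 &
                 track$time <= interval[2] + 1e-9 & !track$gap)
  if (!length(idx)) stop("interval contains no valid samples")
  y <- track[[axis_channel(axis)]][idx]
  max(y) - min(y)
}

#' Append per-rep amplitudes to a segmentation table
#'
#' @param track the `pose_track` the reps were segmented from.
#' @param reps an `exercise_reps` table.
#' @return the table with an `amplitude_mm` column.
#' @export
add_amplitudes <- function(track, reps) {
  reps$amplitude_mm <- vapply(seq_len(nrow(reps)), function(i) {
    rep_amplitude(track, c(reps$start_s[i], reps$end_s[i]), reps$axis[i])
  }, numeric(1))
  reps
}

#' Recognize the exercise contained in a movement segment
#'
#' Signed excursions relative to the segment-edge baseline are compared with
#' the height-scaled thresholds on each exercise's primary axis: downward
#' longitudinal for the squat, upward longitudinal for the step-up, absolute
#' transversal for the side-step.  Among exercises whose threshold is
#' exceeded, the largest threshold-normalized excursion wins (deterministic
#' precedence); `NA` if no threshold is reached.
#'
#' @param track a `pose_track`.
#' @param interval length-2 numeric `(start_s, end_s)`.
#' @param height subject height, mm.
#' @param thresholds a [threshold_set()].
#' @return an exercise label, or `NA_character_`.
#' @export
recognize_exercise <- function(track, interval, height,
                               thresholds = threshold_set()) {
  stopifnot(height > 0)
  idx <- which(track$time >= interval[1] - 1e-9 &
                 track$time <= interval[2] + 1e-9 & !track$gap)
  if (length(idx) < 2L) return(NA_character_)
  long <- track$pos_longitudinal[idx]
  trans <- track$pos_transversal[idx]
  base_long <- (long[1] + long[length(long)]) / 2
  base_trans <- (trans[1] + trans[length(trans)]) / 2
  excursions <- c(
    squat = base_long - min(long),
    step_up = max(long) - base_long,
    side_step = max(abs(trans - base_trans))
  )
  scores <- vapply(names(excursions), function(ex) {
    excursions[[ex]] / threshold_of(thresholds, ex, height)
  }, numeric(1))
  if (all(scores < 1)) return(NA_character_)
  names(scores)[which.max(scores)]
}

interval_overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Pair repetitions across the two systems
#'
#' Greedy matching by maximal interval overlap within the same exercise
#' label: the available pair with the largest overlap is matched first,
#' until no overlapping pair remains.  Unmatched repetitions from either
#' system are reported separately.
#'
#' @param tg_reps,ref_reps `exercise_reps` tables with `amplitude_mm`
#'   (see [add_amplitudes()]), from synchronized tracks.
#' @return object of class `paired_amplitudes`: list with `pairs` (data
#'   frame `exercise, tg_amplitude, ref_amplitude, start_s, end_s,
#'   overlap_s`), `unmatched_tg`, `unmatched_ref`.
#' @export
pair_amplitudes <- function(tg_reps, ref_reps) {
  nt <- nrow(tg_reps)
  nr <- nrow(ref_reps)
  ov <- matrix(0, nt, nr)
  if (nt && nr) {
    for (i in seq_len(nt)) {
      same <- tg_reps$exercise[i] == ref_reps$exercise
      ov[i, same] <- interval_overlap(
        tg_reps$start_s[i], tg_reps$end_s[i],
        ref_reps$start_s[same], ref_reps$end_s[same]
      )
    }
  }
  pairs <- list()
  used_t <- rep(FALSE, nt)
  used_r <- rep(FALSE, nr)
  while (any(ov > 0)) {
    k <- arrayInd(which.max(ov), dim(ov))
    i <- k[1]
    j <- k[2]
    pairs[[length(pairs) + 1L]] <- data.frame(
      exercise = ref_reps$exercise[j],
      tg_amplitude = tg_reps$amplitude_mm[i],
      ref_amplitude = ref_reps$amplitude_mm[j],
      start_s = ref_reps$start_s[j], end_s = ref_reps$end_s[j],
      overlap_s = ov[i, j],
      stringsAsFactors = FALSE
    )
    used_t[i] <- TRUE
    used_r[j] <- TRUE
    ov[i, ] <- 0
    ov[, j] <- 0
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    exercise = character(0), tg_amplitude = numeric(0),
    ref_amplitude = numeric(0), start_s = numeric(0), end_s = numeric(0),
    overlap_s = numeric(0), stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$start_s), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs,
         unmatched_tg = tg_reps[!used_t, , drop = FALSE],
         unmatched_ref = ref_reps[!used_r, , drop = FALSE]),
    class = "paired_amplitudes"
  )
}

#' @export
print.paired_amplitudes <- function(x, ...) {
  cat(sprintf(
    "<paired_amplitudes> matched=%d unmatched tg=%d ref=%d\n",
    nrow(x$pairs), nrow(x$unmatched_tg), nrow(x$unmatched_ref)
  ))
  invisible(x)
}

#' Write a repetition table as CSV
#' @param reps an `exercise_reps` table (with amplitudes).
#' @param path output path; columns
#'   `exercise,source,start_s,end_s,axis,amplitude_mm`.
#' @return `path`, invisibly.
#' @export
write_reps_csv <- function(reps, path) {
  cols <- c("exercise", "source", "start_s", "end_s", "axis", "amplitude_mm")
  cols <- intersect(cols, names(reps))
  utils::write.csv(as.data.frame(reps)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
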