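# Synthetic study generator: ground-truth head trajectories following the
# two-trial exercise protocol, degraded into paired reference (120 Hz) and
# training-game (30 Hz) recordings with controlled noise, lag and frame
# misalignment.

#' Draw a synthetic subject
#'
#' Body height is drawn from a normal law with mean 1750 mm and sd 100 mm
#' (the study population: 175 +/- 10 cm), truncated to \[1400, 2100\] mm by
#' rejection.  The height scales exercise displacements and recognition
#' thresholds downstream.
#'
#' @param seed integer seed; the same seed always yields the same profile.
#' @param subject_id optional id token; default derived from the seed.
#' @return object of class `subject_profile`: list with `subject_id`,
#'   `height` (mm) and `seed`.
#' @examples
#' generate_subject(7)
#' @export
generate_subject <- function(seed, subject_id = sprintf("S%04d", seed %% 10000L)) {
  height <- with_seed(derive_seed(seed, 0L), {
    h <- stats::rnorm(1, 1750, 100)
    while (h < 1400 || h > 2100) h <- stats::rnorm(1, 1750, 100)
    h
  })
  structure(
    list(subject_id = subject_id, height = height, seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' The scripted Trial-1 protocol
#'
#' Synchronization nods, then 3 squats, 3 side-steps to the right and back,
#' 3 step-ups, 3 side-steps to the left and back.  Each out-and-back
#' side-step excursion counts as one repetition, so a full Trial 1 holds
#' 3 squats, 6 side-steps and 3 step-ups.
#'
#' @return character vector of segment labels in execution order.
#' @export
trial1_protocol <- function() {
  c("nod", rep("squat", 3), rep("side_step_right", 3),
    rep("step_up", 3), rep("side_step_left", 3))
}

#' Generator configuration
#'
#' Holds every knob of the synthetic world: the protocol, per-exercise
#' displacements, the two sampling rates, sensor noise levels, the injected
#' clock lag and world-frame mismatch between the two systems.
#'
#' @param protocol character vector of segment labels (`nod`, `squat`,
#'   `side_step_right`, `side_step_left`, `step_up`), or a data frame with
#'   columns `label`, `start_s`, `end_s` for explicit (non-overlapping)
#'   timing.
#' @param squat_depth_frac squat depth as a fraction of subject height.
#' @param step_height step-up board height, mm.
#' @param sidestep_width lateral side-step excursion, mm.
#' @param nod_amplitude peak head-flexion angle of the synchronization nods,
#'   degrees.
#' @param nod_count number of nods in the synchronization movement.
#' @param nod_duration duration of the nod segment, s.
#' @param rep_duration duration of one exercise repetition, s.
#' @param lead_in,tail idle (standing) time before the nods and after the
#'   last exercise, s.
#' @param ref_rate,tg_rate sampling rates of the reference system and the
#'   training game, Hz.
#' @param ref_noise_sd per-channel position noise of the reference system,
#'   mm (sub-millimetre by default, matching optoelectronic accuracy).
#' @param tg_noise_sd,tg_rot_noise_sd per-channel position (mm) and rotation
#'   (deg) noise of the training game.
#' @param injected_lag clock offset, s; positive means the training game
#'   stream lags behind the reference.
#' @param frame_rotation length-3 rotation (deg) of the training-game world
#'   frame about the sagittal/transversal/longitudinal axes.
#' @param frame_offset length-3 translation (mm) of the training-game world
#'   frame.
#' @param drift_rate linear position drift of the training game, mm/s per
#'   axis; 0 by default (no relevant drift over trials of a few minutes).
#' @param seed integer seed for all degradation noise.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(protocol = trial1_protocol(),
                             squat_depth_frac = 0.20,
                             step_height = 200,
                             sidestep_width = 300,
                             nod_amplitude = 20,
                             nod_count = 5,
                             nod_duration = 5,
                             rep_duration = 3,
                             lead_in = 2,
                             tail = 2,
                             ref_rate = 120,
                             tg_rate = 30,
                             ref_noise_sd = 0.5,
                             tg_noise_sd = 20,
                             tg_rot_noise_sd = 0.6,
                             injected_lag = 0,
                             frame_rotation = c(0, 0, 0),
                             frame_offset = c(0, 0, 0),
                             drift_rate = 0,
                             seed = 1L) {
  cfg <- list(
    protocol = protocol, squat_depth_frac = squat_depth_frac,
    step_height = step_height, sidestep_width = sidestep_width,
    nod_amplitude = nod_amplitude, nod_count = nod_count,
    nod_duration = nod_duration, rep_duration = rep_duration,
    lead_in = lead_in, tail = tail,
    ref_rate = ref_rate, tg_rate = tg_rate,
    ref_noise_sd = ref_noise_sd, tg_noise_sd = tg_noise_sd,
    tg_rot_noise_sd = tg_rot_noise_sd,
    injected_lag = injected_lag,
    frame_rotation = as.numeric(frame_rotation),
    frame_offset = as.numeric(frame_offset),
    drift_rate = drift_rate, seed = as.integer(seed)
  )
  if (cfg$ref_rate <= 0 || cfg$tg_rate <= 0) stop("rates must be > 0")
  if (cfg$ref_noise_sd < 0 || cfg$tg_noise_sd < 0 || cfg$tg_rot_noise_sd < 0) {
    stop("noise sds must be >= 0")
  }
  if (is.data.frame(protocol)) {
    if (!all(c("label", "start_s", "end_s") %in% names(protocol))) {
      stop("explicit protocol needs columns label, start_s, end_s")
    }
    if (nrow(protocol) == 0L) stop("protocol must be non-empty")
    o <- order(protocol$start_s)
    p <- protocol[o, ]
    if (any(p$end_s <= p$start_s)) stop("segment durations must be positive")
    if (nrow(p) > 1L && any(p$start_s[-1] < p$end_s[-nrow(p)] - 1e-12)) {
      stop("protocol segments overlap")
    }
  } else {
    if (length(protocol) == 0L) stop("protocol must be non-empty")
    known <- c("nod", "squat", "side_step_right", "side_step_left", "step_up")
    bad <- setdiff(protocol, known)
    if (length(bad)) stop("unknown protocol labels: ", paste(bad, collapse = ", "))
  }
  if (length(cfg$frame_rotation) != 3L || length(cfg$frame_offset) != 3L) {
    stop("frame_rotation and frame_offset must have length 3")
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Read a generator configuration from JSON
#' @param path JSON file with any subset of [generator_config()] arguments.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(generator_config, args)
}

# raised-cosine bump: 0 -> 1 -> 0 over tau in [0,1], C1 at both ends
rc_bump <- function(tau) 0.5 * (1 - cos(2 * pi * tau))
# raised-cosine step 0 -> 1 over u in [0,1]
rc_step <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

# trapezoid with raised-cosine edges occupying fraction r at each end
rc_plateau <- function(tau, r = 0.3) {
  up <- rc_step(tau / r)
  down <- rc_step((1 - tau) / r)
  pmin(up, down)
}

#' Build the segment table for a label-vector protocol
#' @noRd
protocol_segments <- function(cfg) {
  if (is.data.frame(cfg$protocol)) {
    seg <- cfg$protocol[order(cfg$protocol$start_s), c("label", "start_s", "end_s")]
    rownames(seg) <- NULL
    return(seg)
  }
  durs <- ifelse(cfg$protocol == "nod", cfg$nod_duration, cfg$rep_duration)
  starts <- cfg$lead_in + cumsum(c(0, durs[-length(durs)]))
  data.frame(
    label = cfg$protocol,
    start_s = starts,
    end_s = starts + durs,
    stringsAsFactors = FALSE
  )
}

#' Generate a noise-free ground-truth head trajectory
#'
#' Lays the protocol segments out on the time axis (idle lead-in, contiguous
#' segments, idle tail) and builds a C1 lab-frame trajectory from
#' raised-cosine motion primitives: five sinusoidal nods in the flexion
#' channel (with a small coupled sagittal/longitudinal translation so
#' position-based cross-correlation can also lock on), squats as downward
#' longitudinal dips of `squat_depth_frac * height`, step-ups as longitudinal
#' plateaus of `step_height`, side-steps as out-and-back transversal
#' excursions of `sidestep_width`.  The head baseline stands at
#' `0.93 * height` longitudinally.
#'
#' @param profile a `subject_profile`.
#' @param config a `generator_config`.
#' @return object of class `ground_truth`: list with `fun` (vectorized
#'   closed-form evaluator, time -> 6 channels), `track` (the trajectory
#'   sampled noise-free at the reference rate), `segments` (segment table
#'   with labels, intervals, primary axis and true amplitude per
#'   repetition), `duration`, `profile`, `config`.
#' @export
generate_ground_truth <- function(profile, config) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "generator_config"))
  seg <- protocol_segments(config)
  if (nrow(seg) > 1L && any(seg$start_s[-1] < seg$end_s[-nrow(seg)] - 1e-12)) {
    stop("protocol segments overlap")
  }
  height <- profile$height
  base_long <- 0.93 * height
  duration <- max(seg$end_s) + config$tail

  amp_of <- function(label) {
    switch(label,
      squat = config$squat_depth_frac * height,
      step_up = config$step_height,
      side_step_right = config$sidestep_width,
      side_step_left = config$sidestep_width,
      nod = config$nod_amplitude,
      0
    )
  }
  seg$exercise <- ifelse(grepl("^side_step", seg$label), "side_step", seg$label)
  seg$axis <- vapply(seg$exercise, function(l) {
    switch(l, squat = , step_up = "longitudinal",
           side_step = "transversal", NA_character_)
  }, character(1))
  seg$true_amplitude <- vapply(seg$label, amp_of, numeric(1))
  seg$true_amplitude[!seg$exercise %in% c("squat", "step_up", "side_step")] <- NA_real_

  fun <- function(t) {
    n <- length(t)
    out <- matrix(0, n, 6, dimnames = list(NULL, ALL_CHANNELS))
    out[, "pos_longitudinal"] <- base_long
    # one pass: map every sample to its protocol segment (0 = before first)
    seg_of <- findInterval(t, seg$start_s)
    members <- split(seq_len(n), seg_of)
    members[["0"]] <- NULL
    for (key in names(members)) {
      i <- as.integer(key)
      if (i > nrow(seg)) next
      s0 <- seg$start_s[i]
      s1 <- seg$end_s[i]
      idx <- members[[key]]
      idx <- idx[t[idx] < s1]  # explicit protocols may leave gaps
      if (!length(idx)) next
      tau <- (t[idx] - s0) / (s1 - s0)
      lab <- seg$label[i]
      if (lab == "nod") {
        unit <- rc_bump(tau) * sin(2 * pi * config$nod_count * tau)
        # coupled translation scales with the nod: +/-20 mm at the default
        # 20 degree amplitude, vanishing for a zero-amplitude nod
        couple <- config$nod_amplitude / 20
        out[idx, "rot_flexion"] <- config$nod_amplitude * unit
        out[idx, "pos_sagittal"] <- out[idx, "pos_sagittal"] + 20 * couple * unit
        out[idx, "pos_longitudinal"] <- out[idx, "pos_longitudinal"] -
          10 * couple * unit^2
      } else if (lab == "squat") {
        out[idx, "pos_longitudinal"] <- out[idx, "pos_longitudinal"] -
          config$squat_depth_frac * height * rc_bump(tau)
      } else if (lab == "step_up") {
        out[idx, "pos_longitudinal"] <- out[idx, "pos_longitudinal"] +
          config$step_height * rc_plateau(tau)
      } else if (lab == "side_step_right") {
        out[idx, "pos_transversal"] <- out[idx, "pos_transversal"] -
          config$sidestep_width * rc_bump(tau)
      } else if (lab == "side_step_left") {
        out[idx, "pos_transversal"] <- out[idx, "pos_transversal"] +
          config$sidestep_width * rc_bump(tau)
      }
    }
    out
  }

  times <- seq(0, duration, by = 1 / config$ref_rate)
  vals <- fun(times)
  track <- pose_track(
    time = times,
    pos_sagittal = vals[, 1], pos_transversal = vals[, 2],
    pos_longitudinal = vals[, 3],
    rot_flexion = vals[, 4], rot_lateral_flexion = vals[, 5],
    rot_rotation = vals[, 6],
    device = "reference", nominal_rate = config$ref_rate
  )
  structure(
    list(fun = fun, track = track, segments = seg, duration = duration,
         profile = profile, config = config),
    class = "ground_truth"
  )
}

#' Sample the ground truth as a reference-system recording
#'
#' The closed-form ground truth is evaluated on the reference-rate grid
#' (timestamps starting at 0) with additive zero-mean Gaussian noise of sd
#' `ref_noise_sd` on each position channel.
#'
#' @param truth a `ground_truth`.
#' @param config a `generator_config` (usually `truth$config`).
#' @return a `pose_track` with `device = "reference"`.
#' @export
degrade_to_reference <- function(truth, config = truth$config) {
  times <- seq(0, truth$duration, by = 1 / config$ref_rate)
  vals <- truth$fun(times)
  n <- length(times)
  if (config$ref_noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, 1L),
                       matrix(stats::rnorm(3 * n, 0, config$ref_noise_sd), n, 3))
    vals[, 1:3] <- vals[, 1:3] + noise
  }
  pose_track(
    time = times,
    pos_sagittal = vals[, 1], pos_transversal = vals[, 2],
    pos_longitudinal = vals[, 3],
    rot_flexion = vals[, 4], rot_lateral_flexion = vals[, 5],
    rot_rotation = vals[, 6],
    device = "reference", nominal_rate = config$ref_rate
  )
}

#' Sample the ground truth as a training-game recording
#'
#' The training-game stream sees the same motion `injected_lag` seconds
#' later on its own clock, expressed in a misaligned world frame (rotation
#' `frame_rotation`, translation `frame_offset`), sampled at `tg_rate` with
#' additive Gaussian position and rotation noise and an optional linear
#' drift on every position channel.  Before the motion starts (lagged time
#' below 0) the stream holds the initial pose.
#'
#' @param truth a `ground_truth`.
#' @param config a `generator_config` (usually `truth$config`).
#' @return a `pose_track` with `device = "tg"`.
#' @export
degrade_to_tg <- function(truth, config = truth$config) {
  times <- seq(0, truth$duration, by = 1 / config$tg_rate)
  src <- pmin(pmax(times - config$injected_lag, 0), truth$duration)
  vals <- truth$fun(src)
  n <- length(times)

  rotated <- any(config$frame_rotation != 0)
  if (rotated || any(config$frame_offset != 0)) {
    R <- rot_z(config$frame_rotation[3]) %*%
      rot_y(config$frame_rotation[2]) %*%
      rot_x(config$frame_rotation[1])
    vals[, 1:3] <- vals[, 1:3] %*% t(R) +
      matrix(config$frame_offset, n, 3, byrow = TRUE)
    if (rotated) {
      for (i in seq_len(n)) {
        Rp <- euler_to_matrix(vals[i, 4], vals[i, 5], vals[i, 6])
        vals[i, 4:6] <- matrix_to_euler(R %*% Rp)
      }
    }
  }
  if (config$tg_noise_sd > 0 || config$tg_rot_noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, 2L), {
      cbind(
        matrix(stats::rnorm(3 * n, 0, config$tg_noise_sd), n, 3),
        matrix(stats::rnorm(3 * n, 0, config$tg_rot_noise_sd), n, 3)
      )
    })
    vals <- vals + noise
  }
  if (config$drift_rate != 0) {
    vals[, 1:3] <- vals[, 1:3] + config$drift_rate * times
  }
  pose_track(
    time = times,
    pos_sagittal = vals[, 1], pos_transversal = vals[, 2],
    pos_longitudinal = vals[, 3],
    rot_flexion = vals[, 4], rot_lateral_flexion = vals[, 5],
    rot_rotation = vals[, 6],
    device = "tg", nominal_rate = config$tg_rate
  )
}

#' Write ground-truth segment labels as a sidecar CSV
#' @param truth a `ground_truth`.
#' @param path output path; columns `segment,label,start_s,end_s`.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(truth, path) {
  seg <- truth$segments
  out <- data.frame(
    segment = seq_len(nrow(seg)), label = seg$label,
    start_s = seg$start_s, end_s = seg$end_s
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a segment sidecar CSV written by [write_segments_csv()]
#' @param path input path.
#' @return data frame with columns `segment,label,start_s,end_s`.
#' @export
read_segments_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Randomized free-play protocol for Trial 2
#'
#' Emulates about one minute of game play: synchronization nods followed by
#' exercises in random order until the target duration is reached.
#'
#' @param seed integer seed.
#' @param target_duration nominal play time, s (default 60).
#' @param jitter half-width of the uniform duration jitter, s (default 10).
#' @param rep_duration duration of one repetition, s.
#' @param nod_duration duration of the nod segment, s.
#' @return character vector of segment labels.
#' @export
free_play_protocol <- function(seed, target_duration = 60, jitter = 10,
                               rep_duration = 3, nod_duration = 5) {
  with_seed(derive_seed(seed, 3L), {
    total <- stats::runif(1, target_duration - jitter, target_duration + jitter)
    n_reps <- max(1L, round((total - nod_duration) / rep_duration))
    pool <- c("squat", "side_step_right", "side_step_left", "step_up")
    c("nod", sample(pool, n_reps, replace = TRUE))
  })
}
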