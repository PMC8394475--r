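test_that("primary axes follow the exercise definitions", {
  expect_identical(primary_axis("side_step"), "transversal")
  expect_identical(primary_axis("squat"), "longitudinal")
  expect_identical(primary_axis("step_up"), "longitudinal")
  expect_error(primary_axis("lunge"), "unknown")
})

test_that("label-guided segmentation reproduces the scripted protocol counts", {
  tr <- make_trial(71, protocol = trial1_protocol(), tg_noise_sd = 10)
  reps <- segment_repetitions(tr$tg, tr$truth$segments)
  expect_equal(sum(reps$exercise == "squat"), 3)
  expect_equal(sum(reps$exercise == "side_step"), 6)
  expect_equal(sum(reps$exercise == "step_up"), 3)
  expect_true(all(reps$axis == vapply(reps$exercise, primary_axis, "")))
})

test_that("label-free segmentation finds the same repetitions", {
  tr <- make_trial(72, protocol = trial1_protocol(), tg_noise_sd = 5,
                   ref_noise_sd = 0, injected_lag = 0)
  reps <- segment_repetitions(tr$tg, height = tr$profile$height)
  expect_equal(sum(reps$exercise == "squat"), 3)
  expect_equal(sum(reps$exercise == "side_step"), 6)
  expect_equal(sum(reps$exercise == "step_up"), 3)

  # detected intervals overlap the true segments
  seg <- tr$truth$segments
  seg <- seg[!is.na(seg$axis), ]
  for (i in seq_len(nrow(seg))) {
    hits <- reps$exercise == seg$exercise[i] &
      reps$start_s < seg$end_s[i] & reps$end_s > seg$start_s[i]
    expect_equal(sum(hits), 1)
  }
})

test_that("constant and sub-threshold tracks yield no repetitions", {
  t <- seq(0, 30, by = 1 / 30)
  flat <- pose_track(t, 0 * t, 0 * t, 1600 + 0 * t, 0 * t, 0 * t, 0 * t,
                     device = "tg", nominal_rate = 30)
  expect_equal(nrow(segment_repetitions(flat, height = 1750)), 0)

  # pure noise well below thresholds: false-positive rate < 1%
  set.seed(88)
  n_false <- 0
  n_total <- 0
  for (k in 1:25) {
    noisy <- pose_track(t, rnorm(length(t), 0, 20), rnorm(length(t), 0, 20),
                        1600 + rnorm(length(t), 0, 20),
                        0 * t, 0 * t, 0 * t,
                        device = "tg", nominal_rate = 30)
    n_false <- n_false + nrow(segment_repetitions(noisy, height = 1750))
    n_total <- n_total + 3  # three exercises scanned per track
  }
  expect_lt(n_false / n_total, 0.01)
})

test_that("repetition amplitude is the time-independent range", {
  t <- seq(0, 2, by = 1 / 30)
  ramp <- pose_track(t, 0 * t, 0 * t, 175 * t, 0 * t, 0 * t, 0 * t,
                     device = "tg", nominal_rate = 30)
  expect_equal(rep_amplitude(ramp, c(0, 2), "longitudinal"), 350)

  flat <- pose_track(t, 0 * t, 0 * t, 0 * t, 0 * t, 0 * t, 0 * t,
                     device = "tg", nominal_rate = 30)
  expect_equal(rep_amplitude(flat, c(0, 2), "longitudinal"), 0)
  expect_error(rep_amplitude(flat, c(1, 1), "longitudinal"), "empty")

  # invariance to sample reordering / time reversal (property)
  tr <- make_trial(73, tg_noise_sd = 10)
  seg <- tr$truth$segments
  i <- which(seg$label == "squat")[1]
  a0 <- rep_amplitude(tr$tg, c(seg$start_s[i], seg$end_s[i]), "longitudinal")
  rev_tg <- tr$tg
  idx <- which(rev_tg$time >= seg$start_s[i] & rev_tg$time <= seg$end_s[i])
  rev_tg$pos_longitudinal[idx] <- rev(rev_tg$pos_longitudinal[idx])
  expect_equal(rep_amplitude(rev_tg, c(seg$start_s[i], seg$end_s[i]),
                             "longitudinal"), a0)
  set.seed(1)
  rev_tg$pos_longitudinal[idx] <- sample(rev_tg$pos_longitudinal[idx])
  expect_equal(rep_amplitude(rev_tg, c(seg$start_s[i], seg$end_s[i]),
                             "longitudinal"), a0)
})

test_that("noisy squat amplitudes stay near the configured depth", {
  # raised-cosine squat of depth 350 with 5 mm frame noise: errors stay
  # within the Monte-Carlo-checked envelope for the max-min estimator
  profile <- generate_subject(74)
  cfg <- generator_config(protocol = c("nod", rep("squat", 3)),
                          squat_depth_frac = 350 / profile$height,
                          tg_noise_sd = 5, tg_rot_noise_sd = 0,
                          ref_noise_sd = 0, injected_lag = 0, seed = 74)
  truth <- generate_ground_truth(profile, cfg)
  tg <- degrade_to_tg(truth, cfg)
  reps <- add_amplitudes(tg, segment_repetitions(tg, truth$segments))
  sq <- reps[reps$exercise == "squat", ]
  expect_equal(nrow(sq), 3)
  expect_true(all(abs(sq$amplitude_mm - 350) < 3 * 5 * sqrt(2)))
})

test_that("height-scaled recognition labels the generated exercises", {
  thr <- threshold_set(squat_frac = 0.10, step_up_frac = 0.07,
                       side_step_frac = 0.10)
  # direct threshold-rule cases
  t <- seq(0, 3, by = 1 / 30)
  dip <- pose_track(t, 0 * t, 0 * t, 1600 - 0.2 * 1750 * arval:::rc_bump(t / 3),
                    0 * t, 0 * t, 0 * t, device = "tg", nominal_rate = 30)
  expect_identical(recognize_exercise(dip, c(0, 3), 1750, thr), "squat")

  side <- pose_track(t, 0 * t, 300 * arval:::rc_bump(t / 3), 1600 + 0 * t,
                     0 * t, 0 * t, 0 * t, device = "tg", nominal_rate = 30)
  expect_identical(recognize_exercise(side, c(0, 3), 1750, thr), "side_step")

  flat <- pose_track(t, 0 * t, 0 * t, 1600 + 0 * t, 0 * t, 0 * t, 0 * t,
                     device = "tg", nominal_rate = 30)
  expect_true(is.na(recognize_exercise(flat, c(0, 3), 1750, thr)))

  # generator segments reproduce their labels across seeds
  for (seed in c(81, 82, 83, 84, 85)) {
    tr <- make_trial(seed, protocol = trial1_protocol(), tg_noise_sd = 10,
                     injected_lag = 0)
    seg <- tr$truth$segments
    seg <- seg[!is.na(seg$axis), ]
    got <- vapply(seq_len(nrow(seg)), function(i) {
      recognize_exercise(tr$tg, c(seg$start_s[i], seg$end_s[i]),
                         tr$profile$height)
    }, character(1))
    expect_identical(got, seg$exercise)
  }
})

test_that("pairing matches by interval overlap and reports unmatched reps", {
  tr <- make_trial(91, protocol = trial1_protocol(), tg_noise_sd = 5,
                   injected_lag = 0)
  reps_tg <- add_amplitudes(tr$tg, segment_repetitions(tr$tg, tr$truth$segments))
  reps_ref <- add_amplitudes(tr$ref, segment_repetitions(tr$ref, tr$truth$segments))

  paired <- pair_amplitudes(reps_tg, reps_ref)
  expect_equal(nrow(paired$pairs), 12)
  expect_equal(nrow(paired$unmatched_tg), 0)
  expect_equal(nrow(paired$unmatched_ref), 0)

  # identical lists pair amplitude to itself
  self <- pair_amplitudes(reps_ref, reps_ref)
  expect_equal(self$pairs$tg_amplitude, self$pairs$ref_amplitude)

  # a missing tg rep leaves the reference rep unmatched
  paired2 <- pair_amplitudes(reps_tg[-1, ], reps_ref)
  expect_equal(nrow(paired2$pairs), 11)
  expect_equal(nrow(paired2$unmatched_ref), 1)

  # jittered intervals: greedy matching equals exhaustive optimal assignment
  set.seed(92)
  for (rep_i in 1:10) {
    base <- data.frame(
      exercise = "squat",
      source = "tg",
      start_s = c(0, 3, 6, 9) + runif(4, -0.2, 0.2),
      end_s = c(3, 6, 9, 12) + runif(4, -0.2, 0.2),
      axis = "longitudinal",
      amplitude_mm = runif(4, 300, 400),
      stringsAsFactors = FALSE
    )
    other <- base
    other$source <- "reference"
    other$start_s <- other$start_s + runif(4, -0.2, 0.2)
    other$end_s <- other$end_s + runif(4, -0.2, 0.2)
    got <- pair_amplitudes(base, other)
    opt <- oracle_best_assignment(base, other)
    expect_equal(nrow(got$pairs), sum(!is.na(opt$map)))
    # the greedy total overlap equals the optimal total (jitter << spacing)
    expect_equal(sum(got$pairs$overlap_s), opt$total, tolerance = 1e-9)
  }
})
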