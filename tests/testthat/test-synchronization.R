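test_that("resampling is exact on constants and ramps, accurate on sines", {
  # constant and linear channels interpolate exactly
  trk <- ramp_track(n = 121, rate = 120)
  grid <- seq(0.05, 0.9, by = 1 / 30)
  out <- resample(trk, grid)
  expect_equal(out$pos_sagittal, grid, tolerance = 1e-12)
  expect_equal(out$pos_transversal, 2 * grid, tolerance = 1e-12)
  expect_equal(out$rot_flexion, rep(0, length(grid)))

  # 1 Hz sine sampled at 120 Hz, resampled to a 30 Hz grid: < 0.1% of amplitude
  t120 <- seq(0, 5, by = 1 / 120)
  sine <- pose_track(t120, sin(2 * pi * t120), 0 * t120, 0 * t120,
                     0 * t120, 0 * t120, 0 * t120,
                     device = "reference", nominal_rate = 120)
  t30 <- seq(0.004, 4.99, by = 1 / 30)
  out <- resample(sine, t30)
  expect_lt(max(abs(out$pos_sagittal - sin(2 * pi * t30))), 1e-3)

  # extrapolation is refused
  expect_error(resample(sine, c(-1, 0, 1)), "extrapolation")
})

test_that("rotation channels resample across the wrap seam", {
  t <- seq(0, 1, by = 0.1)
  yaw <- seq(170, 190, length.out = length(t))
  yaw_wrapped <- ifelse(yaw > 180, yaw - 360, yaw)
  trk <- pose_track(t, 0 * t, 0 * t, 0 * t, 0 * t, 0 * t, yaw_wrapped,
                    device = "tg", nominal_rate = 10)
  out <- resample(trk, c(0.45, 0.55))
  # unwrapped interpolation passes through 180, not through 0
  expect_equal(out$rot_rotation, c(179, 181), tolerance = 1e-9)
})

test_that("lag estimation recovers injected lags and matches the brute-force oracle", {
  # identical tracks: zero lag, perfect correlation
  tr <- make_trial(51, tg_noise_sd = 0, tg_rot_noise_sd = 0, ref_noise_sd = 0)
  s <- estimate_lag(tr$tg, tr$tg)
  expect_equal(s$lag, 0)
  expect_equal(s$peak_corr, 1, tolerance = 1e-12)

  # injected 0.5 s, noisy: estimate within one training-game sample,
  # integer part agreeing with the exhaustive-search oracle
  tr <- make_trial(52, tg_noise_sd = 10, tg_rot_noise_sd = 0.5,
                   injected_lag = 0.5)
  s <- estimate_lag(tr$tg, tr$ref)
  expect_lt(abs(s$lag - 0.5), 1 / 30)
  expect_equal(round(s$lag * 30) / 30,
               oracle_lag(tr$tg, tr$ref, "rot_flexion", 3),
               tolerance = 1e-9)

  # shift equivariance: re-stamping the tg samples delta later moves the
  # estimate by delta (within a sample)
  for (delta in c(-1, 0.4, 1.5)) {
    tg_shift <- tr$tg
    tg_shift$time <- tg_shift$time + delta
    s3 <- estimate_lag(tg_shift, tr$ref)
    expect_lt(abs(s3$lag - (0.5 + delta)), 1.5 / 30)
  }
})

test_that("degenerate lag inputs are rejected or flagged", {
  tr <- make_trial(53)
  flat <- tr$tg
  flat$rot_flexion <- 0
  expect_error(estimate_lag(flat, tr$ref), "zero variance")

  # uncorrelated noise: low-confidence warning
  set.seed(77)
  t <- seq(0, 20, by = 1 / 30)
  mk <- function() pose_track(t, rnorm(length(t)), 0 * t, 0 * t,
                              rnorm(length(t)), 0 * t, 0 * t,
                              device = "tg", nominal_rate = 30)
  expect_warning(s <- estimate_lag(mk(), mk()), "low-confidence")
  expect_true(s$low_confidence)
})

test_that("frame alignment recovers signed permutations and offsets", {
  tr <- make_trial(61, tg_noise_sd = 0, tg_rot_noise_sd = 0, ref_noise_sd = 0,
                   injected_lag = 0)
  crop <- overlap_crop(tr$tg, tr$ref)

  # already aligned: identity permutation, near-zero offset
  al <- align_frames(crop$tg, crop$ref)
  expect_equal(al$alignment$axis_map, diag(3))
  expect_lt(max(abs(al$alignment$static_offset)), 1e-6)

  # swapped axes recovered (swap is its own inverse up to transpose)
  P_swap <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  tg_swapped <- apply_axis_map(crop$tg, P_swap)
  al <- align_frames(tg_swapped, crop$ref)
  expect_equal(al$alignment$axis_map, t(P_swap))
  expect_equal(al$tg$pos_sagittal, crop$ref$pos_sagittal, tolerance = 1e-6)

  # constant +500 mm longitudinal offset
  tg_off <- apply_axis_map(crop$tg, diag(3), c(0, 0, 500))
  al <- align_frames(tg_off, crop$ref)
  expect_equal(al$alignment$axis_map, diag(3))
  expect_equal(unname(al$alignment$static_offset[3]), -500, tolerance = 1e-6)

  # idempotent: a second pass is the identity
  al2 <- align_frames(al$tg, crop$ref)
  expect_equal(al2$alignment$axis_map, diag(3))
  expect_lt(max(abs(al2$alignment$static_offset)), 1e-6)
})

test_that("all 48 signed permutations are distinct and orthogonal", {
  Ps <- signed_permutations()
  expect_length(Ps, 48)
  expect_length(unique(lapply(Ps, as.vector)), 48)
  for (P in Ps) {
    expect_equal(P %*% t(P), diag(3))
    expect_true(all(abs(P) %in% c(0, 1)))
  }
})

test_that("ambiguous alignments raise an error listing the tie", {
  # two identical sinusoids on two axes: sagittal/transversal indistinguishable
  t <- seq(0, 10, by = 1 / 30)
  y <- sin(2 * pi * t)
  mk <- function(dev) pose_track(t, y, y, 0 * t, 0 * t, 0 * t, 0 * t,
                                 device = dev, nominal_rate = 30)
  expect_error(align_frames(mk("tg"), mk("reference")), "ambiguous")
})

test_that("free-rotation registration undoes an arbitrary rotation", {
  tr <- make_trial(62, tg_noise_sd = 0, tg_rot_noise_sd = 0, ref_noise_sd = 0,
                   injected_lag = 0)
  crop <- overlap_crop(tr$tg, tr$ref)
  R <- arval:::euler_to_matrix(10, -20, 35)
  pos <- as.matrix(crop$tg[, c("pos_sagittal", "pos_transversal",
                               "pos_longitudinal")]) %*% t(R)
  tg_rot <- crop$tg
  tg_rot$pos_sagittal <- pos[, 1]
  tg_rot$pos_transversal <- pos[, 2]
  tg_rot$pos_longitudinal <- pos[, 3]
  al <- align_frames(tg_rot, crop$ref, free_rotation = TRUE)
  expect_equal(al$tg$pos_longitudinal, crop$ref$pos_longitudinal,
               tolerance = 1e-6)
})

test_that("overlap cropping yields equal-length tracks on the tg grid", {
  tr <- make_trial(63, injected_lag = 0)
  crop <- overlap_crop(tr$tg, tr$ref)
  expect_identical(crop$tg$time, crop$ref$time)
  expect_equal(nrow(crop$tg), nrow(crop$ref))

  # partial overlap: length tracks the overlap duration
  tg_late <- tr$tg
  tg_late$time <- tg_late$time + 5
  crop2 <- overlap_crop(tg_late, tr$ref)
  expect_equal(nrow(crop2$tg),
               floor((max(tr$ref$time) - 5) * 30) + 1, tolerance = 1)

  # disjoint spans: error
  tg_far <- tr$tg
  tg_far$time <- tg_far$time + 1000
  expect_error(overlap_crop(tg_far, tr$ref), "no overlapping")
})
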