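test_that("MAD and RMSE behave on exact, offset and noisy pairs", {
  a <- c(1, 2, 3, 4.5)
  expect_equal(mad_stat(a, a), c(mean = 0, sd = 0))
  expect_equal(rmse(a, a), 0)
  expect_equal(mad_stat(a, a + 7), c(mean = 7, sd = 0))
  expect_equal(rmse(a, a + 7), 7)
  expect_error(mad_stat(1:3, 1:4), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  # N(0, 20) differences: folded-normal mean 20*sqrt(2/pi), rms 20
  set.seed(101)
  x <- rnorm(1e6)
  a <- x
  b <- x + rnorm(1e6, 0, 20)
  m <- mad_stat(a, b)
  expect_lt(abs(m[["mean"]] / (20 * sqrt(2 / pi)) - 1), 0.01)
  expect_lt(abs(rmse(a, b) / 20 - 1), 0.01)

  # power-mean inequality on random inputs (property)
  for (k in 1:20) {
    u <- rnorm(50)
    v <- rnorm(50, sd = runif(1, 0.1, 10))
    expect_gte(rmse(u, v), mad_stat(u, v)[["mean"]])
  }
})

test_that("MARD is the mean relative amplitude error", {
  p <- data.frame(tg_amplitude = c(510, 510), ref_amplitude = c(500, 500))
  expect_equal(as.numeric(mard(p)), 0.02)
  p2 <- data.frame(tg_amplitude = c(90, 220), ref_amplitude = c(100, 200))
  expect_equal(as.numeric(mard(p2)), 0.10)
  p3 <- data.frame(tg_amplitude = c(90, 220, 5), ref_amplitude = c(100, 200, 0))
  expect_warning(m3 <- mard(p3), "excluded")
  expect_equal(as.numeric(m3), 0.10)
  expect_equal(attr(m3, "n_excluded"), 1L)
})

test_that("Spearman matches brute-force rank arithmetic including ties", {
  x <- 1:8
  expect_equal(spearman(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")

  # 6-point set with a tie: direct midrank formula to 1e-10
  a <- c(1, 2, 2, 4, 5, 6)
  b <- c(2, 1, 4, 3, 6, 5)
  s <- spearman(a, b)
  expect_equal(s$rho, oracle_spearman_rho(a, b), tolerance = 1e-10)

  # no ties: classical sum-of-squared-differences formula
  set.seed(11)
  u <- sample(100, 12)
  v <- sample(100, 12)
  expect_equal(spearman(u, v)$rho, oracle_spearman_d2(u, v), tolerance = 1e-10)

  # p via the t approximation
  n <- 12
  rho <- spearman(u, v)$rho
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(spearman(u, v)$p, 2 * pt(-abs(tval), n - 2), tolerance = 1e-12)
})

test_that("ICC(2,1) matches the ANOVA oracle and behaves at the extremes", {
  # hand-checked 6x2 table against explicit mean-squares arithmetic
  x <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  got <- icc_agreement(data.frame(tg_amplitude = x[, 1], ref_amplitude = x[, 2]))
  expect_equal(got$icc, oracle_icc(x), tolerance = 1e-10)

  # perfect agreement
  p <- data.frame(tg_amplitude = c(1, 2, 3, 4, 5), ref_amplitude = c(1, 2, 3, 4, 5))
  expect_equal(icc_agreement(p)$icc, 1)

  # independent noise: near zero
  set.seed(12)
  q <- data.frame(tg_amplitude = rnorm(200), ref_amplitude = rnorm(200))
  expect_lt(abs(icc_agreement(q)$icc), 0.15)

  # degenerate input
  expect_error(
    icc_agreement(data.frame(tg_amplitude = rep(1, 6), ref_amplitude = rep(1, 6))),
    "zero total variance"
  )

  # confidence interval brackets the estimate
  ic <- icc_agreement(data.frame(tg_amplitude = x[, 1] + 0.1 * x[, 2],
                                 ref_amplitude = x[, 1]))
  expect_true(ic$ci_low <= ic$icc && ic$icc <= ic$ci_high)
})

test_that("Lilliefors-corrected KS rejects non-normal and requires n >= 5", {
  expect_error(ks_normality(1:4), "at least 5")
  expect_error(ks_normality(rep(2, 10)), "constant")

  set.seed(13)
  out <- ks_normality(runif(500))
  expect_lt(out$p, 0.01)

  out2 <- ks_normality(rnorm(500))
  expect_gt(out2$p, 0.01)
})

test_that("non-parametric Bland-Altman uses median and percentile limits", {
  p <- data.frame(tg_amplitude = c(1, 2, 3, 4, 5), ref_amplitude = c(1, 2, 3, 4, 5))
  ba <- bland_altman_np(p)
  expect_equal(ba$ba_median, 0)
  expect_equal(ba$ba_loa_low, 0)
  expect_equal(ba$ba_loa_high, 0)
  expect_error(bland_altman_np(p[1:3, ]), "at least 4")

  # diffs {-2,-1,0,1,2}: hand-evaluated type-7 percentiles
  q <- data.frame(tg_amplitude = c(-2, -1, 0, 1, 2), ref_amplitude = rep(0, 5))
  ba <- bland_altman_np(q)
  expect_equal(ba$ba_median, 0)
  expect_equal(ba$ba_loa_low, -1.9)   # (n-1)*0.025 + 1 = 1.1th order statistic
  expect_equal(ba$ba_loa_high, 1.9)

  # large-sample normal: limits approach +/- 1.96 sigma
  set.seed(14)
  sigma <- 7
  d <- rnorm(1e5, 0, sigma)
  r <- data.frame(tg_amplitude = d, ref_amplitude = 0)
  ba <- bland_altman_np(r)
  expect_lt(abs(ba$ba_loa_low / (-1.96 * sigma) - 1), 0.02)
  expect_lt(abs(ba$ba_loa_high / (1.96 * sigma) - 1), 0.02)
  inside <- mean(d >= ba$ba_loa_low & d <= ba$ba_loa_high)
  expect_lt(abs(inside - 0.95), 1e-3)

  # parametric variant behind the flag
  bap <- bland_altman_np(r, parametric = TRUE)
  expect_equal(bap$ba_loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-9)
})

test_that("Fisher-z sample size reproduces the study calculation", {
  expect_equal(sample_size_correlation(0.5, 0.05, 0.2), 29L)
  expect_equal(sample_size_correlation(0.999999, 0.05, 0.2), 4L)
  expect_error(sample_size_correlation(0), "between 0 and 1")
  expect_error(sample_size_correlation(1.2), "between 0 and 1")

  # r = 0.3: returned n is power-sufficient, n - 1 is not (Fisher-z test)
  n <- sample_size_correlation(0.3, 0.05, 0.2)
  expect_equal(n, 85L)
  power_z <- function(n, r) {
    pnorm(sqrt(n - 3) * atanh(r) - qnorm(0.975))
  }
  expect_gte(power_z(n, 0.3), 0.8)
  expect_lt(power_z(n - 1, 0.3), 0.8)

  # simulation oracle: empirical power of the Fisher-z test at the returned
  # n agrees with the analytic power used above
  set.seed(15)
  nsim <- 4000
  rejections <- 0
  r <- 0.3
  for (i in seq_len(nsim)) {
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    z <- atanh(cor(x, y)) * sqrt(n - 3)
    if (abs(z) > qnorm(0.975)) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / nsim - power_z(n, r)), 0.025)
})

test_that("agreement statistics are invariant to pair reordering", {
  set.seed(16)
  p <- data.frame(
    exercise = "squat",
    tg_amplitude = rnorm(20, 350, 30),
    ref_amplitude = rnorm(20, 350, 30)
  )
  shuffled <- p[sample(nrow(p)), ]
  expect_equal(as.numeric(mard(p)), as.numeric(mard(shuffled)))
  expect_equal(spearman(p$tg_amplitude, p$ref_amplitude)$rho,
               spearman(shuffled$tg_amplitude, shuffled$ref_amplitude)$rho)
  expect_equal(icc_agreement(p)$icc, icc_agreement(shuffled)$icc)
  expect_equal(bland_altman_np(p)$ba_median, bland_altman_np(shuffled)$ba_median)
})

test_that("trajectory agreement pools trials and respects RMSE >= MAD", {
  tr <- make_trial(17, tg_noise_sd = 12, injected_lag = 0)
  crop <- overlap_crop(tr$tg, tr$ref)
  d1 <- channel_diffs(crop$tg, crop$ref)
  tab1 <- trajectory_agreement(d1)
  expect_equal(nrow(tab1), 6)
  expect_true(all(tab1$rmse >= tab1$mad_mean))
  tab2 <- trajectory_agreement(list(d1, d1), n_trials = 2)
  expect_equal(tab2$n_frames[1], 2 * nrow(d1))
  expect_equal(tab2$mad_mean, tab1$mad_mean)
})
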