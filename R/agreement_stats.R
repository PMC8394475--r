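# Method-comparison statistics: MAD, RMSE, MARD, Spearman, ICC(2,1),
# Lilliefors-corrected KS normality, non-parametric Bland-Altman, and the
# Fisher-z sample-size calculation.

#' Mean absolute difference between paired series
#'
#' `d_i = |a_i - b_i|`; returns the mean and the sample standard deviation
#' of the absolute differences.  Note the sd can exceed the mean: absolute
#' differences are folded, strongly right-skewed quantities.
#'
#' @param a,b numeric vectors of equal length >= 1.
#' @return named numeric vector `c(mean, sd)`; `sd` is `0` for length-1
#'   input.
#' @export
mad_stat <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!length(a)) stop("empty input")
  d <- abs(a - b)
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Root mean square error between paired series
#'
#' @param a,b numeric vectors of equal length >= 1.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!length(a)) stop("empty input")
  sqrt(mean((a - b)^2))
}

pairs_table <- function(pairs) {
  if (inherits(pairs, "paired_amplitudes")) pairs <- pairs$pairs
  stopifnot(all(c("tg_amplitude", "ref_amplitude") %in% names(pairs)))
  pairs
}

#' Mean absolute relative difference of paired amplitudes
#'
#' Mean over repetitions of `|tg - ref| / ref`.  Repetitions with a
#' non-positive reference amplitude are excluded with a warning; the count
#' of exclusions is attached as attribute `n_excluded`.
#'
#' @param pairs a `paired_amplitudes` object or a data frame with columns
#'   `tg_amplitude`, `ref_amplitude`.
#' @return the MARD as a dimensionless fraction.
#' @export
mard <- function(pairs) {
  p <- pairs_table(pairs)
  bad <- p$ref_amplitude <= 0
  if (any(bad)) {
    warning(sprintf("%d repetition(s) with non-positive reference amplitude excluded", sum(bad)))
    p <- p[!bad, , drop = FALSE]
  }
  if (!nrow(p)) stop("no repetitions with positive reference amplitude")
  out <- mean(abs(p$tg_amplitude - p$ref_amplitude) / p$ref_amplitude)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use average (midrank) resolution of ties; rho is the Pearson
#' correlation of the ranks; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param a,b numeric vectors, equal length n >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant input: correlation undefined")
  }
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement,
#' single measure
#'
#' The two measurement systems are treated as two random raters scoring the
#' same repetitions.  The coefficient is computed from the mean squares of
#' the two-way ANOVA decomposition,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the standard F-based 95% confidence interval and the p-value from
#' the F test of between-subject variance (`MSR/MSE` on n-1 and
#' (n-1)(k-1) degrees of freedom).
#'
#' @param pairs a `paired_amplitudes` object or data frame with columns
#'   `tg_amplitude`, `ref_amplitude`; n >= 5 repetitions.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `p`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(pairs, conf_level = 0.95) {
  p <- pairs_table(pairs)
  x <- cbind(p$tg_amplitude, p$ref_amplitude)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 5L) stop("need at least 5 repetitions")
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-12) stop("degenerate input: zero total variance")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  if (mse <= 1e-12 * max(msr, 1) && msc <= 1e-12 * max(msr, 1)) {
    # the two systems agree exactly on every repetition
    return(list(icc = 1, ci_low = 1, ci_high = 1, p = 0,
                msr = msr, msc = msc, mse = mse))
  }

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  fval <- msr / mse
  pval <- stats::pf(fval, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, p = pval,
       msr = msr, msc = msc, mse = mse)
}

# cache of Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by sample size
.arval_ks_env <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

lilliefors_null <- function(n, nreps = 10000L) {
  key <- sprintf("n%d_r%d", n, nreps)
  if (!is.null(.arval_ks_env[[key]])) return(.arval_ks_env[[key]])
  null <- with_seed(derive_seed(20260917L, n), {
    vapply(seq_len(nreps), function(i) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
  null <- sort(null)
  .arval_ks_env[[key]] <- null
  null
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' Tests the composite hypothesis of normality with mean and sd estimated
#' from the sample.  Because the parameters are estimated, the classical KS
#' null distribution does not apply; the p-value comes from a seeded
#' Monte-Carlo null table (10^4 replicates per sample size, computed once
#' and cached), as `(1 + #\{D* >= D\}) / (reps + 1)`.
#'
#' @param x numeric sample, n >= 5, non-constant.
#' @param nreps Monte-Carlo replicates for the null table.
#' @return list with `statistic` (the Lilliefors D) and `p`.
#' @export
ks_normality <- function(x, nreps = 10000L) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant input")
  d <- lilliefors_stat(x)
  null <- lilliefors_null(n, nreps)
  p <- (1 + sum(null >= d)) / (length(null) + 1)
  list(statistic = d, p = p)
}

#' Non-parametric Bland-Altman summary
#'
#' Differences are `tg - ref` per repetition (the instrument under test
#' minus the reference); the bias is the median difference, the limits of
#' agreement are the 2.5th and 97.5th percentiles of the differences
#' (linear-interpolation percentile definition).  Means `(tg + ref)/2` and
#' differences are returned as plot-ready arrays.  A parametric variant
#' (`mean +/- 1.96 sd`) is available behind `parametric = TRUE`.
#'
#' @param pairs a `paired_amplitudes` object or data frame with columns
#'   `tg_amplitude`, `ref_amplitude`; n >= 4.
#' @param parametric if TRUE use mean and `+/- 1.96 sd` limits instead.
#' @return list with `ba_median`, `ba_loa_low`, `ba_loa_high`, `means`,
#'   `diffs`.
#' @export
bland_altman_np <- function(pairs, parametric = FALSE) {
  p <- pairs_table(pairs)
  if (nrow(p) < 4L) stop("need at least 4 repetitions for percentile limits")
  diffs <- p$tg_amplitude - p$ref_amplitude
  means <- (p$tg_amplitude + p$ref_amplitude) / 2
  if (parametric) {
    m <- mean(diffs)
    s <- stats::sd(diffs)
    list(ba_median = m, ba_loa_low = m - 1.96 * s, ba_loa_high = m + 1.96 * s,
         means = means, diffs = diffs)
  } else {
    list(
      ba_median = stats::median(diffs),
      ba_loa_low = pctl(diffs, 0.025),
      ba_loa_high = pctl(diffs, 0.975),
      means = means, diffs = diffs
    )
  }
}

#' Sample size for detecting a correlation (Fisher z)
#'
#' Number of subjects needed to detect an expected correlation `r` against
#' zero in a two-sided test at level `alpha` with power `1 - beta`, from
#' the Fisher z transformation:
#' `n = ((z_{1-alpha/2} + z_{1-beta}) / atanh(r))^2 + 3`,
#' rounded to the nearest integer (the Fisher-z formula slightly
#' overshoots the exact bivariate-normal power calculation, so rounding,
#' not ceiling, reproduces standard power-software output; e.g. r = 0.5,
#' alpha = 0.05, power 0.8 gives 29).  A floor of 4 applies (the
#' transformation needs n - 3 >= 1).
#'
#' @param r expected correlation, 0 < r < 1.
#' @param alpha two-sided type-I error level.
#' @param beta type-II error level (power = 1 - beta).
#' @return required number of subjects (integer).
#' @export
sample_size_correlation <- function(r, alpha = 0.05, beta = 0.2) {
  if (r <= 0 || r >= 1) stop("r must lie strictly between 0 and 1")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must lie strictly between 0 and 1")
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta)
  n <- (z / atanh(r))^2 + 3
  max(4L, as.integer(round(n)))
}

#' Per-frame channel differences between two aligned tracks
#'
#' @param tg,ref `pose_track`s on a common grid (equal length).
#' @return matrix (n x 6) of `tg - ref` per channel; rows where either
#'   track has a gap are dropped.
#' @export
channel_diffs <- function(tg, ref) {
  if (nrow(tg) != nrow(ref)) stop("tracks must be on a common grid")
  ok <- !tg$gap & !ref$gap
  d <- vapply(ALL_CHANNELS, function(ch) tg[[ch]][ok] - ref[[ch]][ok],
              numeric(sum(ok)))
  matrix(d, ncol = 6, dimnames = list(NULL, ALL_CHANNELS))
}

#' Trajectory agreement table (positions and rotations)
#'
#' Pools per-frame differences (one matrix per trial, stacked) and reports
#' the mean and sd of the pooled absolute differences plus the RMSE, per
#' channel: three position rows in mm, three rotation rows in degrees.
#'
#' @param diffs a matrix from [channel_diffs()] or a list of such matrices
#'   (one per trial) to pool.
#' @param n_trials number of trials pooled (recorded in the table).
#' @return data frame of class `trajectory_agreement` with columns
#'   `channel`, `unit`, `mad_mean`, `mad_sd`, `rmse`, `n_frames`,
#'   `n_trials`.
#' @export
trajectory_agreement <- function(diffs, n_trials = if (is.list(diffs)) length(diffs) else 1L) {
  if (is.list(diffs)) diffs <- do.call(rbind, diffs)
  stopifnot(is.matrix(diffs), ncol(diffs) == 6L)
  out <- data.frame(
    channel = ALL_CHANNELS,
    unit = rep(c("mm", "deg"), each = 3L),
    mad_mean = NA_real_, mad_sd = NA_real_, rmse = NA_real_,
    n_frames = nrow(diffs), n_trials = n_trials,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(6L)) {
    d <- abs(diffs[, i])
    out$mad_mean[i] <- mean(d)
    out$mad_sd[i] <- if (length(d) > 1L) stats::sd(d) else 0
    out$rmse[i] <- sqrt(mean(d^2))
  }
  class(out) <- c("trajectory_agreement", "data.frame")
  out
}

#' Amplitude agreement battery per exercise
#'
#' For each exercise present in the paired repetitions: MAD (mean and sd of
#' absolute differences), RMSE, MARD, Spearman rho with p, ICC(2,1) with
#' 95% CI and p, KS/Lilliefors normality p-values of both systems'
#' amplitudes, and the non-parametric Bland-Altman median and limits of
#' agreement.  Statistics needing more repetitions than available are NA.
#'
#' @param pairs a `paired_amplitudes` object or its `pairs` data frame.
#' @return data frame of class `amplitude_agreement`, one row per exercise.
#' @export
amplitude_agreement <- function(pairs) {
  p <- pairs_table(pairs)
  rows <- lapply(sort(unique(p$exercise)), function(ex) {
    q <- p[p$exercise == ex, , drop = FALSE]
    n <- nrow(q)
    m <- mad_stat(q$tg_amplitude, q$ref_amplitude)
    row <- data.frame(
      exercise = ex, n_reps = n,
      mad_mean = m[["mean"]], mad_sd = m[["sd"]],
      rmse = rmse(q$tg_amplitude, q$ref_amplitude),
      mard = mean(abs(q$tg_amplitude - q$ref_amplitude) / q$ref_amplitude),
      spearman_rho = NA_real_, spearman_p = NA_real_,
      icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
      icc_p = NA_real_,
      ks_p_tg = NA_real_, ks_p_ref = NA_real_,
      ba_median = NA_real_, ba_loa_low = NA_real_, ba_loa_high = NA_real_,
      stringsAsFactors = FALSE
    )
    if (n >= 3L && stats::sd(q$tg_amplitude) > 0 && stats::sd(q$ref_amplitude) > 0) {
      s <- spearman(q$tg_amplitude, q$ref_amplitude)
      row$spearman_rho <- s$rho
      row$spearman_p <- s$p
    } else if (n >= 3L) {
      # identical or constant amplitudes: perfect monotone agreement
      if (all(q$tg_amplitude == q$ref_amplitude)) {
        row$spearman_rho <- 1
        row$spearman_p <- 0
      }
    }
    if (n >= 5L) {
      ic <- tryCatch(icc_agreement(q), error = function(e) NULL)
      if (is.null(ic) && all(q$tg_amplitude == q$ref_amplitude)) {
        # degenerate but perfectly agreeing
        ic <- list(icc = 1, ci_low = 1, ci_high = 1, p = 0)
      }
      if (!is.null(ic)) {
        row$icc <- ic$icc
        row$icc_ci_low <- ic$ci_low
        row$icc_ci_high <- ic$ci_high
        row$icc_p <- ic$p
      }
      if (stats::sd(q$tg_amplitude) > 0) {
        row$ks_p_tg <- ks_normality(q$tg_amplitude)$p
      }
      if (stats::sd(q$ref_amplitude) > 0) {
        row$ks_p_ref <- ks_normality(q$ref_amplitude)$p
      }
    }
    if (n >= 4L) {
      ba <- bland_altman_np(q)
      row$ba_median <- ba$ba_median
      row$ba_loa_low <- ba$ba_loa_low
      row$ba_loa_high <- ba$ba_loa_high
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("amplitude_agreement", "data.frame")
  out
}
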