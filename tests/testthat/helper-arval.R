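# Shared fixtures and independent oracles (brute-force implementations kept
# deliberately separate from the package internals they check).

# A short recording: nods plus one repetition of each exercise.
short_protocol <- function() {
  c("nod", "squat", "side_step_right", "step_up")
}

make_trial <- function(seed = 1, protocol = short_protocol(), ...) {
  profile <- generate_subject(seed)
  cfg <- generator_config(protocol = protocol, seed = seed + 5000L, ...)
  truth <- generate_ground_truth(profile, cfg)
  list(
    profile = profile, cfg = cfg, truth = truth,
    ref = degrade_to_reference(truth, cfg),
    tg = degrade_to_tg(truth, cfg)
  )
}

# constant-pose config: a single zero-amplitude "nod" segment of the given
# duration (used for pure-noise calibration)
static_config <- function(duration, ...) {
  generator_config(
    protocol = data.frame(label = "nod", start_s = 0, end_s = duration),
    nod_amplitude = 0, lead_in = 0, tail = 0, ...
  )
}

ramp_track <- function(n = 61, rate = 30, slope = c(1, 2, 3), device = "tg") {
  t <- (seq_len(n) - 1) / rate
  pose_track(t, slope[1] * t, slope[2] * t, slope[3] * t,
             0 * t, 0 * t, 0 * t, device = device, nominal_rate = rate)
}

# --- oracles -------------------------------------------------------------

# Spearman rho by direct rank arithmetic (midranks for ties), and the
# no-tie Sum-of-squared-rank-differences formula
oracle_spearman_rho <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}
oracle_spearman_d2 <- function(a, b) {
  n <- length(a)
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# ICC(2,1) by explicit two-way ANOVA mean squares arithmetic
oracle_icc <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - k * sum((rowMeans(x) - grand)^2) -
            n * sum((colMeans(x) - grand)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# brute-force integer-lag cross-correlation (no refinement): both streams
# resampled to the tg grid, Pearson correlation at every shift
oracle_lag <- function(tg, ref, channel, window) {
  dt <- 1 / attr(tg, "nominal_rate")
  ks <- seq(-ceiling(window / dt), ceiling(window / dt))
  best <- -Inf
  best_lag <- NA
  for (k in ks) {
    yr <- approx(ref$time, ref[[channel]], xout = tg$time - k * dt)$y
    ok <- !is.na(yr)
    if (sum(ok) < 10) next
    if (sd(tg[[channel]][ok]) == 0 || sd(yr[ok]) == 0) next
    r <- cor(tg[[channel]][ok], yr[ok])
    if (r > best) {
      best <- r
      best_lag <- k * dt
    }
  }
  best_lag
}

# optimal assignment by exhaustive enumeration (small instances), maximizing
# total interval overlap within one exercise label
oracle_best_assignment <- function(tg_reps, ref_reps) {
  stopifnot(nrow(tg_reps) <= 6)
  ov <- function(i, j) {
    max(0, min(tg_reps$end_s[i], ref_reps$end_s[j]) -
          max(tg_reps$start_s[i], ref_reps$start_s[j]))
  }
  n <- nrow(tg_reps)
  m <- nrow(ref_reps)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  best_map <- NULL
  for (p in perms(seq_len(m))) {
    tot <- 0
    map <- integer(0)
    for (i in seq_len(min(n, m))) {
      o <- ov(i, p[i])
      if (o > 0 && tg_reps$exercise[i] == ref_reps$exercise[p[i]]) {
        tot <- tot + o
        map <- c(map, p[i])
      } else {
        map <- c(map, NA)
      }
    }
    if (tot > best) {
      best <- tot
      best_map <- map
    }
  }
  list(total = best, map = best_map)
}
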