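# End-to-end orchestration: synthetic study generation, per-trial
# processing (sync -> frame alignment -> metrics -> repetitions), pooled
# agreement report.

config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validation run configuration
#'
#' @param mode `"synthetic"` (generate the cohort in memory) or `"files"`
#'   (read a study manifest written by [make_study()] or assembled by
#'   hand).
#' @param n_subjects number of subjects in a synthetic cohort.
#' @param base_config a [generator_config()]; its `protocol` is replaced by
#'   the scripted Trial-1 protocol and a randomized free-play Trial-2
#'   protocol per subject.
#' @param manifest for `mode = "files"`: path to a `manifest.csv` or a data
#'   frame with columns `trial_id`, `subject_id`, `trial` (1 or 2),
#'   `height_mm`, `tg_csv`, `ref_csv`, `segments_csv` (optional, may be
#'   `NA` for label-free segmentation).
#' @param thresholds a [threshold_set()].
#' @param sync_channel channel for cross-correlation lag estimation.
#' @param sync_window lag search half-width, s.
#' @param max_gap occlusion gap fill limit, s.
#' @param use_labels use ground-truth segment labels for repetition
#'   segmentation when available (otherwise label-free peak detection).
#' @param include_trial2 include Trial-2 free-play in trajectory metrics.
#' @param include_trial2_amplitudes also include Trial 2 in amplitude
#'   pairing (off by default: amplitudes come from the scripted trial).
#' @param corrupt_trials character vector of trial ids whose training-game
#'   stream is corrupted in synthetic mode (they must be skipped, mirroring
#'   a recording failure).
#' @param seed master seed for the cohort.
#' @param verbose print per-stage log lines.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       n_subjects = 30L,
                       base_config = generator_config(),
                       manifest = NULL,
                       thresholds = threshold_set(),
                       sync_channel = "rot_flexion",
                       sync_window = 3,
                       max_gap = 0.2,
                       use_labels = TRUE,
                       include_trial2 = TRUE,
                       include_trial2_amplitudes = FALSE,
                       corrupt_trials = character(0),
                       seed = 1L,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(manifest)) {
    stop("mode 'files' requires a manifest")
  }
  structure(
    list(mode = mode, n_subjects = as.integer(n_subjects),
         base_config = base_config, manifest = manifest,
         thresholds = thresholds, sync_channel = sync_channel,
         sync_window = sync_window, max_gap = max_gap,
         use_labels = use_labels, include_trial2 = include_trial2,
         include_trial2_amplitudes = include_trial2_amplitudes,
         corrupt_trials = corrupt_trials, seed = as.integer(seed),
         verbose = verbose),
    class = "run_config"
  )
}

log_line <- function(config, trial_id, stage, msg) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %s: %s", trial_id, stage, msg))
  }
}

#' Generator configuration for one synthetic trial
#' @noRd
trial_generator_config <- function(base, protocol, seed) {
  cfg <- base
  cfg$protocol <- protocol
  cfg$seed <- seed
  class(cfg) <- "generator_config"
  cfg
}

#' Generate one synthetic trial (truth + degraded pair)
#' @noRd
synth_trial <- function(profile, base_config, trial, master_seed, subject_index) {
  stream <- if (trial == 1L) 1000L else 2000L
  seed <- derive_seed(master_seed, stream + subject_index)
  protocol <- if (trial == 1L) {
    trial1_protocol()
  } else {
    free_play_protocol(seed,
                       rep_duration = base_config$rep_duration,
                       nod_duration = base_config$nod_duration)
  }
  cfg <- trial_generator_config(base_config, protocol, seed)
  truth <- generate_ground_truth(profile, cfg)
  list(
    truth = truth,
    ref = degrade_to_reference(truth, cfg),
    tg = degrade_to_tg(truth, cfg),
    labels = truth$segments,
    config = cfg
  )
}

corrupt_track <- function(track) {
  n <- nrow(track)
  idx <- seq(max(1L, n %/% 3L), n)
  for (ch in ALL_CHANNELS) track[[ch]][idx] <- NA_real_
  track
}

#' Process one trial through the full pipeline
#'
#' Gap interpolation, lag estimation on the nod landmark, lag application,
#' overlap cropping onto the training-game grid, signed-permutation frame
#' alignment, per-frame channel differences, repetition segmentation on
#' both streams, amplitude extraction and cross-system pairing.
#'
#' @param tg,ref `pose_track`s for the trial.
#' @param height subject height, mm.
#' @param config a [run_config()].
#' @param labels optional ground-truth segment table.
#' @param trial_id id used in log lines and errors.
#' @return list with `sync`, `alignment`, `diffs`, `tg_reps`, `ref_reps`,
#'   `paired`, `n_frames`, `warnings`.
#' @export
process_trial <- function(tg, ref, height, config = run_config(),
                          labels = NULL, trial_id = "trial") {
  warns <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  validate_pose_track(tg)
  validate_pose_track(ref)
  tg <- collect(interpolate_gaps(tg, config$max_gap))
  ref <- collect(interpolate_gaps(ref, config$max_gap))
  log_line(config, trial_id, "sync", "estimating lag")
  sync <- collect(estimate_lag(tg, ref, channel = config$sync_channel,
                               search_window = config$sync_window))
  tg <- apply_lag(tg, sync$lag)
  crop <- overlap_crop(tg, ref)
  al <- align_frames(crop$tg, crop$ref)
  log_line(config, trial_id, "align",
           sprintf("lag=%.3f s score=%.2f", sync$lag, al$alignment$score))
  diffs <- channel_diffs(al$tg, crop$ref)

  lab <- if (isTRUE(config$use_labels)) labels else NULL
  tg_reps <- segment_repetitions(al$tg, protocol_labels = lab,
                                 height = height, thresholds = config$thresholds)
  ref_reps <- segment_repetitions(crop$ref, protocol_labels = lab,
                                  height = height, thresholds = config$thresholds)
  tg_reps <- add_amplitudes(al$tg, tg_reps)
  ref_reps <- add_amplitudes(crop$ref, ref_reps)
  paired <- pair_amplitudes(tg_reps, ref_reps)
  log_line(config, trial_id, "reps",
           sprintf("%d paired repetitions", nrow(paired$pairs)))
  list(sync = sync, alignment = al$alignment, diffs = diffs,
       tg_reps = tg_reps, ref_reps = ref_reps, paired = paired,
       n_frames = nrow(diffs), warnings = warns)
}

#' Run the full validation study
#'
#' Executes the end-to-end comparison of the training-game stream against
#' the reference stream for every trial of the cohort: generate or load,
#' synchronize, register frames, pool per-frame trajectory differences,
#' segment and pair exercise repetitions, and compute the agreement
#' battery.  A trial whose data fail validation (e.g. a corrupted
#' recording) is skipped and logged as excluded; the report states how many
#' trials were analyzed.
#'
#' @param config a [run_config()].
#' @return object of class `agreement_report`: list with `counts`, `sync`
#'   (per-trial lag table), `trajectory` (pooled over analyzed trials),
#'   `trajectory_trial1` (scripted trials only), `amplitude` (per-exercise
#'   battery), `pairs` (paired repetition table), `excluded`, `warnings`,
#'   `provenance`.
#' @export
run_validation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  trials <- build_trial_list(config)
  diffs_all <- list()
  diffs_t1 <- list()
  sync_rows <- list()
  pair_rows <- list()
  excluded <- character(0)
  warns <- character(0)
  rep_counts <- c(squat = 0L, side_step = 0L, step_up = 0L)

  for (tr in trials) {
    res <- tryCatch(
      process_trial(tr$tg, tr$ref, tr$height, config,
                    labels = tr$labels, trial_id = tr$trial_id),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      excluded <- c(excluded, sprintf("%s: %s", tr$trial_id, conditionMessage(res)))
      log_line(config, tr$trial_id, "exclude", conditionMessage(res))
      next
    }
    warns <- c(warns, res$warnings)
    include_traj <- tr$trial == 1L || isTRUE(config$include_trial2)
    if (include_traj) {
      diffs_all[[length(diffs_all) + 1L]] <- res$diffs
    }
    if (tr$trial == 1L) diffs_t1[[length(diffs_t1) + 1L]] <- res$diffs
    sync_rows[[length(sync_rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, subject_id = tr$subject_id, trial = tr$trial,
      lag_s = res$sync$lag, peak_corr = res$sync$peak_corr,
      low_confidence = res$sync$low_confidence,
      align_score = res$alignment$score,
      n_frames = res$n_frames,
      stringsAsFactors = FALSE
    )
    use_amp <- tr$trial == 1L || isTRUE(config$include_trial2_amplitudes)
    if (use_amp && nrow(res$paired$pairs)) {
      p <- res$paired$pairs
      p$trial_id <- tr$trial_id
      pair_rows[[length(pair_rows) + 1L]] <- p
      tab <- table(p$exercise)
      for (ex in names(tab)) rep_counts[ex] <- rep_counts[ex] + tab[[ex]]
    }
  }

  sync_tab <- if (length(sync_rows)) do.call(rbind, sync_rows) else NULL
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  traj <- if (length(diffs_all)) {
    trajectory_agreement(diffs_all, n_trials = length(diffs_all))
  } else NULL
  traj_t1 <- if (length(diffs_t1)) {
    trajectory_agreement(diffs_t1, n_trials = length(diffs_t1))
  } else NULL
  amp <- if (!is.null(pairs) && nrow(pairs)) amplitude_agreement(pairs) else NULL

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "manifest")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  structure(
    list(
      counts = list(
        n_trials_total = length(trials),
        n_trials_analyzed = length(trials) - length(excluded),
        n_trials_excluded = length(excluded),
        n_subjects = length(unique(vapply(trials, `[[`, "", "subject_id"))),
        n_reps = as.list(rep_counts),
        n_frames_pooled = if (is.null(traj)) 0L else traj$n_frames[1]
      ),
      sync = sync_tab,
      trajectory = traj,
      trajectory_trial1 = traj_t1,
      amplitude = amp,
      pairs = pairs,
      excluded = excluded,
      warnings = warns,
      provenance = list(
        package_version = as.character(utils::packageVersion("arval")),
        seed = config$seed,
        mode = config$mode,
        config_hash = config_hash(as.character(cfg_json))
      )
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d/%d trials analyzed, %d paired repetitions\n",
    x$counts$n_trials_analyzed, x$counts$n_trials_total,
    sum(unlist(x$counts$n_reps))
  ))
  if (!is.null(x$trajectory)) {
    cat("Pooled trajectory agreement:\n")
    print(as.data.frame(x$trajectory), digits = 4)
  }
  if (!is.null(x$amplitude)) {
    cat("Amplitude agreement per exercise:\n")
    print(as.data.frame(
      x$amplitude[, c("exercise", "n_reps", "mad_mean", "mad_sd", "rmse",
                      "mard", "spearman_rho", "icc")]
    ), digits = 4)
  }
  invisible(x)
}

#' Assemble the in-memory trial list for a run
#' @noRd
build_trial_list <- function(config) {
  if (config$mode == "synthetic") {
    trials <- list()
    for (i in seq_len(config$n_subjects)) {
      profile <- generate_subject(derive_seed(config$seed, i), subject_id = sprintf("S%02d", i))
      for (trial in 1:2) {
        st <- synth_trial(profile, config$base_config, trial,
                          config$seed, i)
        trial_id <- sprintf("%s_T%d", profile$subject_id, trial)
        tg <- st$tg
        if (trial_id %in% config$corrupt_trials) tg <- corrupt_track(tg)
        trials[[length(trials) + 1L]] <- list(
          trial_id = trial_id, subject_id = profile$subject_id,
          trial = trial, height = profile$height,
          tg = tg, ref = st$ref, labels = st$labels
        )
      }
    }
    trials
  } else {
    man <- config$manifest
    if (is.character(man)) man <- utils::read.csv(man, stringsAsFactors = FALSE)
    need <- c("trial_id", "subject_id", "trial", "height_mm", "tg_csv", "ref_csv")
    missing <- setdiff(need, names(man))
    if (length(missing)) {
      stop("manifest missing column(s): ", paste(missing, collapse = ", "))
    }
    lapply(seq_len(nrow(man)), function(i) {
      labels <- NULL
      if ("segments_csv" %in% names(man) && !is.na(man$segments_csv[i]) &&
          nzchar(man$segments_csv[i])) {
        labels <- read_segments_csv(man$segments_csv[i])
      }
      list(
        trial_id = man$trial_id[i], subject_id = man$subject_id[i],
        trial = as.integer(man$trial[i]), height = man$height_mm[i],
        tg = read_pose_csv(man$tg_csv[i], device = "tg"),
        ref = read_pose_csv(man$ref_csv[i], device = "reference"),
        labels = labels
      )
    })
  }
}

#' Materialize a synthetic study as a file tree
#'
#' For each subject, writes the scripted Trial-1 and free-play Trial-2
#' recording pairs (training-game and reference pose CSVs) plus the
#' ground-truth segment sidecars, and a `manifest.csv` that
#' [run_validation()] can consume in `"files"` mode.
#'
#' @param config a [run_config()] with `mode = "synthetic"`.
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame, invisibly; written as
#'   `<out_dir>/manifest.csv`.
#' @export
make_study <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"), config$mode == "synthetic")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    profile <- generate_subject(derive_seed(config$seed, i), subject_id = sprintf("S%02d", i))
    sdir <- file.path(out_dir, profile$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (trial in 1:2) {
      st <- synth_trial(profile, config$base_config, trial, config$seed, i)
      trial_id <- sprintf("%s_T%d", profile$subject_id, trial)
      tg_path <- file.path(sdir, sprintf("T%d_tg.csv", trial))
      ref_path <- file.path(sdir, sprintf("T%d_ref.csv", trial))
      seg_path <- file.path(sdir, sprintf("T%d_segments.csv", trial))
      tg <- st$tg
      if (trial_id %in% config$corrupt_trials) tg <- corrupt_track(tg)
      write_pose_csv(tg, tg_path)
      write_pose_csv(st$ref, ref_path)
      write_segments_csv(st$truth, seg_path)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = trial_id, subject_id = profile$subject_id, trial = trial,
        height_mm = profile$height, tg_csv = tg_path, ref_csv = ref_path,
        segments_csv = seg_path, stringsAsFactors = FALSE
      )
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' Write the report bundle
#'
#' `report.json` plus CSV tables mirroring the study report layout: pooled
#' position trajectory agreement (`table3.csv`), rotation trajectory
#' agreement (`table4.csv`), per-exercise amplitude battery
#' (`table5.csv`), and one Bland-Altman plot-data CSV per exercise
#' (`bland_altman_<exercise>.csv`, comment header with the median and
#' limits of agreement, then `mean_mm,diff_mm` rows).
#'
#' @param report an `agreement_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_agreement_report <- function(report, out_dir) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- jsonlite::toJSON(
    list(
      provenance = report$provenance,
      counts = report$counts,
      sync = report$sync,
      trajectory = report$trajectory,
      trajectory_trial1 = report$trajectory_trial1,
      amplitude = report$amplitude,
      excluded = report$excluded,
      warnings = report$warnings
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE
  )
  writeLines(json, file.path(out_dir, "report.json"))
  if (!is.null(report$trajectory)) {
    tr <- as.data.frame(report$trajectory)
    utils::write.csv(tr[tr$unit == "mm", ], file.path(out_dir, "table3.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(tr[tr$unit == "deg", ], file.path(out_dir, "table4.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$amplitude)) {
    utils::write.csv(as.data.frame(report$amplitude),
                     file.path(out_dir, "table5.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$pairs) && nrow(report$pairs)) {
    for (ex in unique(report$pairs$exercise)) {
      q <- report$pairs[report$pairs$exercise == ex, , drop = FALSE]
      if (nrow(q) < 4L) next
      ba <- bland_altman_np(q)
      path <- file.path(out_dir, sprintf("bland_altman_%s.csv", ex))
      con <- file(path, open = "wt")
      writeLines(sprintf("# exercise=%s median_mm=%.6g loa_low_mm=%.6g loa_high_mm=%.6g",
                         ex, ba$ba_median, ba$ba_loa_low, ba$ba_loa_high), con)
      writeLines("mean_mm,diff_mm", con)
      writeLines(sprintf("%.10g,%.10g", ba$means, ba$diffs), con)
      close(con)
    }
  }
  invisible(out_dir)
}
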