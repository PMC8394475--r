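# arval

Agreement analysis for smartphone AR head-tracking validation.

Rehabilitation exercise games running on a phone-in-headset rig track the
player's head pose at ~30 Hz in an arbitrary, inertially gravity-aligned
world frame. Before such a device can be trusted to measure exercise
amplitude (how deep a squat, how wide a side-step), its tracking must be
validated against an optoelectronic motion-capture reference recording
reflective headset markers at 120 Hz in the lab frame. `arval` implements
that validation end to end, for real recordings or for a fully synthetic
study with known ground truth:

* **trajectory I/O** — strict CSV dialects for pose and marker tracks;
  rigid (Kabsch) pose reconstruction from four headset markers with
  occlusion handling;
* **synchronization** — lag estimation by normalized cross-correlation on
  the five-nod landmark with sub-sample refinement; signed-permutation
  world-frame registration; resampling onto the common 30 Hz grid;
* **exercise analysis** — repetition segmentation with height-scaled
  thresholds, time-independent amplitudes (max − min on the exercise's
  primary axis), cross-system pairing;
* **agreement statistics** — MAD ± SD and RMSE per channel,
  MARD = mean(|TG − ref| / ref), Spearman's ρ, ICC(2,1) with 95% CI,
  Lilliefors-corrected Kolmogorov–Smirnov normality, non-parametric
  Bland–Altman (median bias, 2.5th/97.5th-percentile limits of agreement),
  and the Fisher-z sample size
  n = ((z₁₋α/₂ + z₁₋β)/atanh r)² + 3;
* **synthetic study generator** — raised-cosine motion primitives following
  the scripted two-trial protocol, degraded into paired recordings with
  controlled noise, lag, frame mismatch and optional drift.

## Worked example

Simulate a 10-subject study (two trials each), run the whole pipeline and
inspect the agreement report:

```r
library(arval)

cfg <- run_config(
  n_subjects  = 10,
  seed        = 1,
  base_config = generator_config(injected_lag = 0.3, tg_noise_sd = 20)
)
report <- run_validation(cfg)
print(report)
#> <agreement_report> 20/20 trials analyzed, 120 paired repetitions
#> Pooled trajectory agreement:
#>               channel unit mad_mean  mad_sd    rmse n_frames n_trials
#> 1        pos_sagittal   mm  15.9324 12.0751 19.9911    32860       20
#> 2     pos_transversal   mm  15.9923 12.1531 20.0860    32860       20
#> 3    pos_longitudinal   mm  15.9948 12.0189 20.0071    32860       20
#> 4         rot_flexion  deg   0.4788  0.3633  0.6010    32860       20
#> 5 rot_lateral_flexion  deg   0.4806  0.3613  0.6013    32860       20
#> 6        rot_rotation  deg   0.4768  0.3625  0.5989    32860       20
#> Amplitude agreement per exercise:
#>    exercise n_reps mad_mean mad_sd  rmse   mard spearman_rho        icc
#> 1 side_step     60    61.44  14.53 63.10 0.2045     -0.01917  5.324e-05
#> 2     squat     30    57.59  12.00 58.79 0.1606      0.84872  1.504e-01
#> 3   step_up     30    70.62  15.86 72.33 0.3512     -0.19555 -5.922e-04
```

Reading this: with 20 mm of white position noise injected into the
training-game stream, the pooled per-axis MAD settles at the folded-normal
mean 20·√(2/π) ≈ 15.96 mm and the RMSE at 20 mm — the pipeline recovers the
injected 0.3 s lag and the frame alignment, so nothing but the noise is
left. Repetition amplitudes (max − min over each repetition) inflate under
white frame noise, visible in the per-exercise MAD; the squat is the only
exercise whose true amplitude varies across subjects (0.2 × height), hence
the only informative ρ/ICC in a synthetic cohort. `write_agreement_report()`
writes `report.json`, the trajectory and amplitude tables, and per-exercise
Bland–Altman plot data.

The same run works from files: `make_study(cfg, "study/")` writes per-trial
pose CSVs plus ground-truth segment sidecars and a `manifest.csv`, and
`run_validation(run_config(mode = "files", manifest = "study/manifest.csv"))`
reproduces the in-memory results bit for bit. A thin CLI over those two
functions is at `inst/scripts/arval.R` (`simulate` / `run` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the full synthetic
validation run above plus the study's analytic sample-size number
(`sample_size_correlation(0.5, 0.05, 0.2)`), and writes the JSON summary to
`--out`.

## Vignette

`vignettes/arval-methods.Rmd` documents the model and its assumptions, the
statistical conventions (ICC variant, percentile definition, Euler
sequence, Lilliefors null tables), what the synthetic generator does and
does not emulate, and known limitations of the max − min amplitude
estimator under white noise.
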