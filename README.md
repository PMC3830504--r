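# oculog

Auto-calibrating detection and classification of saccades and blinks from
two-channel electro-oculography (EOG), with no user calibration step.

EOG is routinely co-recorded with EEG: skin electrodes around the eyes pick
up the corneo-retinal standing potential, so gaze rotations appear as steps
in the horizontal (`EOG_h = right − left`) and vertical
(`EOG_v = up − down`) derivations, and blinks as large positive transients
on `EOG_v`. Classical velocity-threshold saccade detection needs a
voltage-to-degree calibration that long, free-viewing recordings rarely
have. **oculog** removes that requirement: every amplitude threshold is
estimated from the recording itself, so hours of otherwise-unusable EOG can
be scored for eye-movement events automatically.

## The algorithm

1. **Artifact removal.** Baseline drift (electrode polarization, skin
   impedance) is modelled per channel by a degree-20 least-squares
   polynomial over normalized time and subtracted; high-frequency noise is
   removed by Haar wavelet truncation, zeroing every detail level whose
   band lies above 100 Hz. Differentiation then yields the eye-velocity
   signals `EOG_h_diff`, `EOG_v_diff` (µV/s).
2. **Auto-calibration.** For each detection channel (|`EOG_h_diff`|,
   |`EOG_v_diff`|, and the positive part of `EOG_v` for blinks), all local
   peak amplitudes are sorted ascending and scaled to [0, 1], giving the
   curve `D = [d_1, …, d_N]`. Isolated artifact peaks are trimmed from the
   top while successive gaps are ≥ 0.03. Two straight lines are fit to
   `D_n = [d_1…d_n]` and `D_p = [d_{n+1}…d_N]` for every split `n`; the
   split minimizing the summed least-squares error is the knee between the
   dense noise floor and the sparse event peaks, and the threshold is
   placed 2 % above the knee amplitude.
3. **Feature extraction.** Local extrema above threshold become *bounded
   peaks*: each is delimited by the first samples at or below 10 % of its
   amplitude (left/right bounds LB, RB), the right search absorbing
   double peaks by promotion, with a 0.80 s maximum peak duration. Blinks
   are up-and-down velocity pairs within 1.2 s whose intervening positional
   up-peak exceeds the blink threshold.
4. **Classification.** Five classes: horizontal, vertical and oblique
   saccades (h and v candidates overlapping in time), blinks, and
   horizontal saccades coinciding with a blink. Optional physiological
   duration filters (30–80 ms for saccades) suppress residual false
   positives.
5. **Measures.** Per event: duration, peak velocity (µV/s, and deg/s after
   gain calibration from reference saccades of known amplitude),
   acceleration/deceleration, amplitude, and eye closing/opening times for
   blinks.

A ground-truth synthetic EOG generator (main-sequence saccades, asymmetric
blink pulses, drift, broadband noise, powerline pickup, artifact spikes)
and an event-matching evaluator (sensitivity, false-positive rate,
confusion matrices) support benchmarking end to end.

## Worked example

```r
library(oculog)

# two minutes of synthetic EOG at a gaze-task event density
cfg <- sim_config(seed = 42, duration_s = 120, n_saccades = 180, n_blinks = 25)
sim <- generate_eog(cfg)

res <- detect_events(sim$recording, eog_config(filters.enabled = TRUE))
res$thresholds
#> <threshold_set> h_saccade = 627.1 uV/s, v_saccade = 516.3 uV/s, blink = 98.3 uV
res$events
#> <eog_events> 191 events @ 500 Hz
#>   HORIZONTAL_SACCADE   43
#>   VERTICAL_SACCADE     41
#>   OBLIQUE_SACCADE      85
#>   BLINK                22

match_events(res$events, sim$truth)
#> <match_result> tp = 191, fp = 0, fn = 14
#>   sensitivity = 0.932, fp_rate = 0.000
```

The thresholds were estimated purely from the signal: 627 µV/s for
horizontal and 516 µV/s for vertical saccade velocity, 98 µV for blink
amplitude — between the recording's noise floor and its smallest events.
191 of 205 injected events are recovered with no false positives; the
misses are small (2.5°) saccades whose vertical components sit near the
noise floor, the algorithm's known weak spot. Gain calibration from four
detected 10° saccades returns 12.45 µV/deg against a true 13 µV/deg:

```r
refs <- res$events[res$events$label == "HORIZONTAL_SACCADE" &
                   res$events$amplitude_uv > 110, ]
calibrate_gain(refs[1:4, ])
#> <calibration_gain> 12.45 uV/deg (from 4 reference saccades of 10 deg)
```

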