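---
title: "Auto-calibrating EOG event detection: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-calibrating EOG event detection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculog)
```

## The problem and the signal model

Electro-oculography measures the rotation of the corneo-retinal dipole
through periocular skin electrodes. In the bipolar derivation used here
(`EOG_h = right − left`, `EOG_v = up − down`), a saccade is a step in the
positional signal — roughly 10–20 µV per degree of gaze rotation — whose
time derivative is a ballistic velocity pulse; a blink is a large
(hundreds of µV) positive transient on the vertical channel produced by
eyelid movement. Superimposed on these are slow baseline drift from
electrode polarization and skin-impedance changes, broadband
instrumentation and muscle noise, powerline pickup, and occasional large
movement artifacts.

Velocity-threshold saccade detection is standard, but setting the
threshold in physical units (deg/s) requires a calibration linking voltage
to visual angle that long EEG-style recordings rarely provide. The
package's central idea is to estimate every threshold from the
distribution of peak amplitudes in the recording itself, exploiting the
fact that noise peaks are dense and small while event peaks are sparse and
large.

## Pipeline stages and their assumptions

### Baseline removal

Each channel is fit with a least-squares polynomial of degree 20 over time
normalized to [−1, 1] and the fit is subtracted. The normalization keeps
the Vandermonde system numerically sane at high degree (condition numbers
around 10^7, handled by QR); fitting raw time at degree 20 would be
numerically meaningless. A degree-20 polynomial over a one-minute trace
has an effective resolution of ~3 s: it tracks drift below ~0.05 Hz while
leaving 30–80 ms saccade steps and 100–600 ms blink pulses almost
untouched. The residual is the detrended signal; `r_squared` is reported
with the convention that a constant input (zero total variance) has
`r_squared = 0`.

The fit is global by design — event morphology must not be distorted — and
that has a visible cost: the polynomial partially absorbs the events
themselves, producing shoulder-shaped residuals of a few tens of µV around
large blinks and gaze plateaus. These shoulders merge monotonically into
their events and never form independent peaks, but they do raise the
apparent inter-event baseline. Piecewise fitting for multi-hour data is
deliberately left out of this version.

### Wavelet truncation

Haar wavelets match the step-like morphology of eye movements. The package
zeroes every detail level whose band lies entirely above the cutoff
(default 100 Hz): level *j* (1 = finest) covers approximately
[fs/2^(j+1), fs/2^j] Hz and is removed when its lower edge is at or above
the cutoff. At 500 Hz this removes level 1 (125–250 Hz) only. Because the
Haar filters are two taps long, no boundary padding is needed: truncation
is implemented as the exact block-average projection it mathematically is
(odd tail samples carried through per level), which makes it exactly
idempotent and linear — properties the test suite asserts bitwise.

### Differentiation

The truncated signal is pairwise-constant, and this forces a numerical
choice: a forward first difference of a pairwise-constant signal
degenerates into an alternating sequence of zeros and doubled slopes,
which shreds bounded-peak boundaries (2-sample events) and doubles
apparent peak velocities. The central difference recovers the underlying
slope of the pair staircase exactly at every interior sample, so velocity
is computed as `(x[i+1] − x[i−1])·fs/2` with one-sided differences at the
two ends (length is preserved). On a pure ramp both schemes agree; on the
post-Haar signal only the central difference is usable.

## Threshold auto-calibration

All local maxima of the absolute detection signal are collected (plateaus
count once, at their leftmost sample), sorted ascending and scaled to
[0, 1]. Outliers are trimmed from the top while the gap between successive
scaled peaks is at least 0.03 — isolated artifact peaks sit far above the
continuum of genuine peaks — and the curve is re-scaled afterwards
(configurable) so the pivot amplitude stays interpretable. For every split
index `n` in [10, N − 10] two straight lines are fit (rank as abscissa) to
the lower and upper segments; the split minimizing the summed squared
error is the knee separating the noise floor from the event tail, and the
threshold is 2 % above the knee amplitude, mapped back to signal units
through the recorded scale maximum. Ties are broken toward the smaller
index, i.e. the more conservative threshold. The scan is implemented with
prefix-sum closed forms (O(N) over all splits) and is verified in the
tests against an exhaustive `lm`-based oracle, exactly, on hundreds of
random curves.

Horizontal and vertical saccade thresholds are calibrated on the absolute
velocity signals; the blink threshold on the positive part of the
detrended vertical positional signal, since blinks deflect the up-minus-down
derivation upward (an option calibrates on |EOG_v| instead). Calibration
requires at least 30 peaks per channel and at least 20 points after
trimming; shorter recordings are rejected with an instruction to provide
more data.

**Operating assumption.** The knee exists only if events exist. On an
event-free channel the two-line fit settles somewhere inside the noise
distribution (empirically near its upper percentiles) and the threshold
fails open, passing hundreds of noise peaks. The method presumes
recordings that contain eye movements — the intended EEG-session material —
and a minimum event density: with very sparse events spanning a wide
amplitude range the knee can also slide above the smallest events (the
vertical channel is most vulnerable, since its event population mixes
modest saccade components with much larger blink velocities). Denser or
longer recordings stabilize it; this matches the task-paced recordings the
approach was designed around.

## Feature extraction and classification

A bounded peak starts from a local extremum above threshold and walks
outward to the first samples at or below 10 % of the peak amplitude
(`bound_frac`). The right-hand walk terminates on (1) reaching the bound,
(2) meeting a sample exceeding the current peak — in which case the peak is
*promoted* and the walk continues, absorbing double-peaked events — or
(3) exceeding the maximum span, in which case the peak is discarded. Two
caps govern the span: a single peak may last at most 0.80 s
(`max_peak_duration_s`), and only a peak that has absorbed a second one
may extend to the 1.2 s maximum blink duration. The distinction matters:
without it, a sustained upward-gaze plateau bracketed by an up-and-down
saccade pair inside 1.2 s is indistinguishable from a blink, and vertical
saccades silently disappear into false blinks. Bound crossings are stored
at integer sample indices (first at-or-below sample); overlapping accepted
peaks of the same polarity are merged keeping the larger, while
opposite-polarity neighbours may share boundary samples.

Blink extraction pairs each positive vertical-velocity candidate with the
nearest following negative one within the blink window and looks for the
intervening positional up-peak; if that peak exceeds the blink threshold,
a blink is emitted with the positional peak's bounds as onset/offset and
every velocity candidate peaking inside that span is consumed.
Classification then resolves the five classes, with blink coexistence
taking precedence over obliqueness for horizontal candidates, temporal
overlap of at least one sample defining simultaneity (configurable), and
an oblique saccade spanning the union of its component intervals.

The optional duration filters (inclusive 30–80 ms for saccade classes, an
optional minimum blink duration, both off by default in the library and on
in the command line's robust profile) encode the physiological range of
5–15° saccades; residual false positives are overwhelmingly short noise
peaks, so the filter removes most of them at a small cost among
jitter-tail events.

### Measures

Durations are `(offset − onset)/fs`; saccade peak velocity is the maximum
absolute velocity within the event on its axis (obliques report per-axis
maxima and their Euclidean combination); acceleration and deceleration are
the extremes of the differentiated velocity within the event — a
formulation chosen here, as the measure is otherwise underdetermined.
Event amplitude is the positional signal change between the two bounds
(saccades are steps); for blinks, whose positional profile is a pulse with
near-equal bound values, amplitude is the peak height above the mean bound
value. Blink closing and opening times are peak-relative; blink duration
is *defined* as their sum so the identity `closing + opening = duration`
holds exactly in floating point (it equals the offset−onset duration to
one ulp). The voltage-to-degree gain is the mean amplitude of
caller-supplied reference saccades divided by their nominal amplitude
(canonically a handful of 10° horizontal saccades), after which peak
velocities are also reported in deg/s; degree-domain values are invariant
to rescaling the recording, since the gain cancels.

## The synthetic generator

The generator emulates a 500 Hz DC-coupled laboratory recording of a gaze
task and is the package's test bed; its defaults are the study conditions
and are not tuned per test:

- **Saccades** are logistic position steps of height
  `amplitude_deg × gain` projected by direction; the steepness is set so
  the velocity pulse's 10 %-bound width equals the requested duration,
  with durations drawn from the normative amplitude–duration map
  (37 ms at 2.5° to 55 ms at 10°, linearly interpolated, jittered with the
  normative SDs by default). The logistic was chosen over minimum-jerk for
  its closed-form velocity (peak = amplitude × k/4); its peak-to-mean
  velocity ratio (≈1.8) is lower than that of real saccades, so simulated
  deg/s peak velocities sit below published main-sequence values at equal
  duration — a deliberate, documented simplification.
- **Blinks** are asymmetric half-cosine pulses (default 300 ± 30 µV,
  250 ± 50 ms, closing fraction 0.4, positive on `EOG_v`).
- **Gain** defaults to 13 µV/deg, inside the commonly cited 10–20 µV/deg
  range.
- **Drift** sums three to five random-phase sinusoids below 0.05 Hz with
  ~100 µV total amplitude — electrode polarization and sweating are slower
  than this, and a degree-20 polynomial over a minute can track it.
- **Noise** is 0.4 µV RMS broadband white noise (flat to Nyquist; the
  wavelet step removes its upper half-band) plus a 0.3 µV residual of
  50 Hz powerline. These values describe a shielded-laboratory floor and
  were fixed from the reported operating characteristics of the approach —
  near-perfect detection of 2.5° horizontal saccades (≈1600 µV/s at this
  gain) requires the post-denoise velocity noise floor to sit well below
  that, false-positive peaks are described as lasting under 25 ms, and a
  2 % pivot margin suffices — not from any test outcome. Larger in-band
  noise (µV-scale low-frequency noise) produces saccade-length noise bumps
  that no duration filter can remove; that regime contradicts those
  reported characteristics.
- **Artifacts** are 1–3-sample ragged spikes of 5–10× blink amplitude,
  exercising the outlier-trimming rule; ragged, because a perfectly
  rectangular spike yields two equal-amplitude velocity edges whose
  scaled gap defeats a sequential-gap trim.
- **Placement** draws non-overlapping onsets uniformly (≥150 ms apart),
  and each saccade's direction is reversed when the step would carry gaze
  further from centre — emulating the fixate-and-return structure of gaze
  tasks and keeping the positional signal bounded, as head-fixed task
  recordings are.

Generation is bit-deterministic for a fixed seed. What the generator does
*not* model: eyelid mechanics, smooth pursuit and fixational drift between
saccades, EMG bursts, heavy-tailed artifact families, inter-subject
electrode geometry. Passing tests therefore demonstrate correctness of the
algorithmic chain under controlled morphology, not clinical-grade
performance on arbitrary recordings.

## Evaluation protocol

Detected and reference events are matched one-to-one by nearest peak time
within 100 ms (ties toward the earlier reference event), class-agnostic;
sensitivity is tp/(tp+fn) and the false-positive rate fp/(tp+fp) — a
false-discovery fraction, the only reading under which a duration filter
can reduce it, and the denominator the reported numbers behave as.
Classification is scored second, on the matched pairs only, via the 5×5
confusion matrix. Greedy nearest-first matching is optimal whenever
candidate sets are disjoint (events three tolerance-widths apart); on
adversarially dense instances it can trail the optimal assignment by an
alternating chain, which the tests bound at one. The benchmark scores
saccade sensitivity against reference saccades of 30–80 ms true duration
when the 30–80 ms filter is applied to detections — the duration-restricted
protocol on both sides.

## Numerical choices and degenerate inputs

- Sample indices are 1-based with closed event intervals; all exported
  times are seconds (`(index − 1)/fs`), so the base never leaves the
  package.
- Pivot ties (all-collinear curves) resolve to the smallest admissible
  split, within a 10^-9 relative tolerance to absorb floating-point noise.
- Scale equivariance is exact: every stage is homogeneous of degree 1, and
  under power-of-two scaling the entire pipeline — preprocessing,
  thresholds, detection indices — reproduces bitwise.
- Degenerate inputs (constant signals, empty event lists, too-few peaks,
  infeasible simulation placements) raise typed, actionable errors rather
  than propagating nonsense.
- Test problem sizes (one-minute benchmark recordings at 50 seeds,
  150 s calibration recordings at 100 seeds, curves of ≤200 points) were
  chosen so the whole suite completes in a couple of minutes while keeping
  binomial noise on rate estimates near the percent level.

## Known limitations

- Auto-calibration fails open on event-free channels and can overshoot on
  very sparse recordings (see above); a minimum event density is an
  operating requirement, not an implementation detail.
- Small (≤5°) vertical saccades are intrinsically hard: their velocity
  peaks approach the noise knee, and up/down pairs around gaze plateaus
  compete with blink extraction. The duration-restricted benchmark scores
  ≈95 % saccade sensitivity; unrestricted sensitivity is lower, driven by
  these verticals.
- Measured durations inflate by a few samples under noise, because the
  10 %-bound walk terminates on the first sub-bound sample and the
  logistic tail hovers near the bound; events near the 80 ms filter edge
  can therefore be filtered despite a true duration inside the window.
- One threshold set per recording: slow nonstationarity (electrode gel
  drying, fatigue-induced amplitude changes over hours) is not tracked.
- The EDF reader covers continuous 16-bit EDF with uniform per-signal
  rates; EDF+ annotations and discontinuous files are out of scope.
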