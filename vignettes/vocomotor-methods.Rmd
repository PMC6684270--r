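---
title: "Methods: vocal-locomotor-arousal development analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal-locomotor-arousal development analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Infant marmosets produce two kinds of contact call: the *cry*, a short,
spectrally noisy immature call, and the *phee*, the long tonal contact call
of adults. Over the first two months of life cries give way to phees, while
posture and locomotion mature from righting reflexes and crawling to
hindlimb support and walking, and autonomic state (heart rate) becomes
increasingly coupled to both. `vocomotor` implements the full analysis
chain needed to study this co-development from repeated short observation
sessions: per-call acoustics, video-based locomotor activity, ECG-derived
arousal, maturity trajectories, event-aligned dynamics with resampling
inference, and a mixed-model suite — plus a synthetic-study generator with
known ground truth against which every stage is validated.

```{r, eval = FALSE}
library(vocomotor)
study <- simulate_study(study_config(rng_seed = 1))
results <- run_pipeline(study, n_rep = 200, seed = 1)
results$transition_days
```

## Per-call acoustics

Each call event contributes its duration and its **Wiener entropy**
(spectral flatness): the log of the ratio of the geometric to the
arithmetic mean of the power-spectrum values. The value is 0 for a
perfectly flat (white-noise-like) spectrum and strongly negative for tonal
sounds; it is invariant to overall amplitude. Choices the definition leaves
open, which we fix and record in the output metadata:

* **Spectrum estimator** — a single-taper periodogram with a Hann window
  over the whole call. The DC bin is excluded (offsets are acquisition
  artifacts).
* **Log base** — natural log. A different base only rescales the value.
* **Zero bins** — floored at machine epsilon times the maximum power before
  the geometric mean, so synthetic pure tones give a finite, very negative
  value rather than `-Inf` while the ordering of spectra is preserved
  (`floor_zeros = FALSE` restores the sentinel).

`segment_calls()` is a convenience amplitude-envelope detector for
exploratory use; the pipeline's canonical input is a provided, verified
call table.

## Locomotor activity from video

Movement is quantified as the average luminance difference per pixel per
second: the summed absolute RGB difference between the first and last frame
of each second divided by the pixel count (`frame_difference()`; dividing
by pixels x channels instead is available and recorded). Because absolute
pixel differences scale with body size, each session's raw values are
binarized at that session's own 90th percentile (strictly greater than;
`stats::quantile` type 7), then smoothed with a penalized cubic spline
(smoothing parameter 0.10) and clamped to [0, 1] — splines through binary
data can overshoot, and the index is defined on [0, 1] from immobile to
mobile. The percentile threshold makes the whole chain invariant to global
luminance rescaling.

## Heart rate and the arousal index

The ECG chain mirrors standard small-animal practice:

1. **Channel selection** — the channel with the larger ratio of
   95th-percentile to median absolute amplitude on the jointly valid
   extent (a spiky cardiac signal is heavy-tailed; pure noise is not).
   Ties go to the first channel. Artifact masks are supplied as intervals.
2. **Preprocessing** — anti-aliased resampling from the native 40 kHz to
   1500 Hz, zero-phase 4th-order Butterworth high-pass at 15 Hz, zero-phase
   60 Hz IIR notch (Q = 30). Masked regions propagate as `NaN`; each valid
   segment is filtered separately so artifacts cannot leak across gaps.
3. **Beat detection** — within every 1 s window, candidates exceed the
   window's 95th amplitude percentile. "Amplitude" is a 10 ms RMS envelope
   by default: an instantaneous-|x| threshold admits isolated noise maxima
   at low beat rates, while the envelope keeps precision and recall above
   99% when pulse peaks are 10x the noise sd. One spike is reported per
   supra-threshold region, at the maximum of |x|.
4. **Interval validation** — marmoset heart rate lies in 150-600
   beats/min, i.e. inter-beat intervals in 100-400 ms. Intervals below
   100 ms merge the two spikes at their midpoint (iterated left-to-right,
   re-checking after every merge, a deterministic version of pairwise
   substitution); intervals above 400 ms mark the span invalid. Leading and
   trailing beat-free spans longer than 400 ms are likewise invalid.
5. **Rate** — a binary beat series at 1500 Hz convolved with a unit-area
   Gaussian of 1 s nominal width. We take sigma = 1/6 s so +-3 sigma spans
   the 1 s window; the kernel is normalized to unit area on the discrete
   grid, making a constant train of period T read exactly 60/T beats/min.
   Sampled at the 1 Hz bin centers; `NaN` inside invalid spans.
6. **Coverage and percentiles** — sessions keep their heart rate only if it
   is defined at least 50% of the time (inclusive). Because baseline rate
   varies across pups and ages, the defined 1 Hz values are converted to
   within-session percentile ranks (mid-rank ties, 0 = session minimum,
   100 = maximum, a constant session maps to 50): the **arousal index**.
   The transform is invariant to any strictly monotone rescaling of rate.

## The smoothing-spline engine

Every smoothed curve in the package minimizes

$$p \sum_j (y_j - f(x_j))^2 + (1 - p) \int f''(t)^2 \, dt$$

over cubic splines, with unit weights on a per-second (or per-day)
abscissa. The printed smoothing parameters — 0.10 (activity), 0.03 / 0.01
(individual / population maturity trajectories), 0.1 / 0.3 (session /
population peri-event splines), 0.0001 (developmental curves) — are only
meaningful under this convention: `p = 1` interpolates, `p = 0` is the
least-squares line. The solver uses the banded Reinsch formulation (sparse
Cholesky, O(n)); duplicate abscissas are pooled into weighted means, which
leaves the minimizer unchanged. The test suite checks the solution against
an independent dense solve whose roughness matrix is built from
`stats::splinefun` natural interpolants with exact Simpson quadrature,
agreeing to 1e-8. Evaluation outside the data range extrapolates linearly
(the natural-spline boundary behavior).

## Maturity indices and transition days

Behaviors are classified *immature* or *mature* by the sign of the day
slope in `proportion ~ day + (day | subject)`, Holm-corrected within each
motor category at alpha 0.05; behaviors without a reliable trend stay
unclassified. The per-session **maturity index** is `m / (m + im)`, the
share of classified time spent in mature behavior; sessions with no
classified time contribute no point rather than an arbitrary 0 or 1.
Population trajectories are splines over postnatal day (p = 0.01 pooling
all subjects' sessions; p = 0.03 for individual fits).

The **transition day** is the earliest day at which the population
trajectory reaches 0.5 and stays at or above 0.5 for the next 3 days,
evaluated on a 0.1-day grid over days 1-61. The 3-day persistence guard is
our operationalization of "transitioned around day X": it prevents
noise-driven first crossings from defining the transition while changing
nothing for genuinely sigmoidal trajectories.

## Peri-event dynamics, bootstrap CI and scramble null

Locomotor activity is extracted from -20 to +5 s around call onsets and -5
to +20 s around offsets; heart-rate percentiles from -10/+5 and -5/+10 s.
For display and inference the two windows are stitched onto one
call-centered axis: times at or before the call from the onset-anchored
trace, times after it from the offset-anchored trace, with the call
interior excluded from band statistics (the merge rule is otherwise
underdetermined). Session splines (p = 0.1) are fit to all of a session's
pooled trace points; the population spline (p = 0.3) is fit to all session
splines evaluated on the common 1 Hz grid.

Uncertainty comes from two resampling schemes, both seeded and bit-exactly
reproducible:

* **Confidence band** — 10 traces per session drawn with replacement
  (session averages in developmental mode), population spline refit, 1000
  replicates by default; the band is the pointwise 2.5th/97.5th
  percentiles.
* **Scramble null** — within each session the sequence of event durations
  and the sequence of inter-event gaps (the lead-in before the first event
  counts as a gap) are permuted independently and a pseudo-timeline is
  reassembled from the session start. This preserves the number and
  lengths of events — and the total occupied time — while destroying their
  timing. Pseudo-event windows are extracted and splines refit; the 95%
  threshold is again the pointwise 2.5th/97.5th percentiles. Grid points
  where the observed spline leaves the null band are flagged, and
  contiguous runs reported. No multiple-comparison correction is applied
  across grid points: the bands are pointwise by design.

On synthetic studies with no event coupling the pointwise exceedance rate
is close to the nominal 5% (the calibration suite checks 5% +- 2% absolute
over 200 studies), and a heart-rate elevation during phees of the default
configured size (a realized arousal-index elevation of at least 10
percentile points) is flagged near the event in over 90% of studies.

**Developmental curves** (p = 0.0001 over postnatal day) use each event's
window-average value, averaged per session; the CI resamples per-event
values, the null scrambles timing before averaging.

## The mixed-model suite

Fourteen fits in twelve groups cover: per-behavior proportion trends
within each category (`proportion ~ day + (day | subject)`); a logistic
GLMM comparing maturation across categories (`index ~ category + day +
(category | subject) + (day | subject)`), fit as binomial with weights
equal to each session's observed mature+immature seconds — the natural
weighting for a time-share response the description leaves open; acoustic
parameters and call-type contrasts against locomotor activity and arousal
with subject nested in day (`(x | day/subject)`); early (day 1-10) vs late
(day 52-61) age-group contrasts; and arousal-locomotion coordination
during mature calls, rerun on the first (1-30) and second (31-61) months.

Gaussian models are fit by REML with `lme4`; on a singular or
non-convergent fit the random structure is simplified down a recorded
ladder (`(x | day/subject)` to `(1 | day/subject)` to `(1 | day) + (1 |
subject)`). p-values for gaussian terms use a normal approximation to the
t statistic by default — denominator-degrees-of-freedom methods differ
across software, and the package's validated surface is sign and
approximate magnitude recovery; `df_method = "satterthwaite"` switches to
`lmerTest` degrees of freedom. Holm correction (`stats::p.adjust`) is
applied within the stated families (per-category trends, the two acoustic
models, the coordination time-frames).

## The synthetic-study generator

`simulate_study()` emulates the reference design: 7 subjects, 29-34
sessions each (220 total) spread over postnatal days 1-61, 10-minute
sessions, audio in 192 and ECG in 149 sessions. Ground truth is known for
every generated quantity:

* **Calls** are a renewal process (exponential gaps at 5.7 calls/min, the
  rate implied by ~10,956 calls over 192 ten-minute sessions). Cries
  average 0.4 s with entropy near -1.5; phees 1.5 s with entropy near -4.
* **Maturation** is logistic with configurable midpoints (defaults: day 10
  vocal, 19 postural, 21 locomotor; slope 0.3/day). Because the maturity
  index is a *time* share and phees are several times longer than cries,
  the schedule governs the expected share of vocal time that is phee, and
  the per-call phee probability is derived from it through the mean
  durations. This makes the configured midpoint the true index-crossing
  day by construction; a schedule on call *counts* would shift the
  time-share crossing earlier by log(mean phee / mean cry duration) /
  slope (about 4 days at the defaults) and leave the configured "truth"
  unrecoverable. Postural and locomotor behaviors share one duration
  distribution, so for them the two formulations coincide.
* **Motion** is lognormal baseline activity multiplied by `1 + coupling`
  during calls (defaults +0.5 during cries, -0.5 during phees: infants
  move more while crying, stay still to phee).
* **Heart rate** is a slowly fluctuating baseline (400 beats/min, spline
  of 10 s Gaussian knots, sd 40) plus 30 beats/min around phees and 20
  around locomotor events, clipped to [180, 570] so every inter-beat
  interval respects the 100-400 ms validation bounds; beats are laid down
  as an inhomogeneous renewal process. The 30 beats/min phee effect
  realizes an arousal-index elevation of roughly 20 percentile points.
* **ECG waveforms** (synthesized on demand) place a ~20 ms biphasic pulse
  with a dominant positive lobe (an R-S-like complex, peak 1) at each beat
  over white noise; the second channel is attenuated to 0.3 with 1.5x
  noise so channel selection has a right answer.

What the generator deliberately does not emulate: parental interaction,
photorealistic video (a moving-blob frame generator exists for end-to-end
motion tests), biomechanical vocal synthesis, time-of-day effects, and
within-session non-stationarity of call rate. Passing tests therefore
demonstrate correctness of the analysis machinery under a faithful but
idealized data-generating process, not robustness to every artifact of
real recordings.

## Numerical choices and degenerate inputs

* Time is seconds from session start; intervals are half-open
  `[onset, offset)`; 1 Hz grids are anchored at bin centers 0.5, 1.5, ...
* A constant raw-activity series binarizes to all zeros (strict threshold).
* An all-zero spectrum has undefined entropy and errors.
* Sessions failing the 50% heart-rate coverage rule error out of the
  percentile transform, directing the caller to exclude them.
* A session with one call and one gap has a unique scramble layout; its
  null band collapses onto the observed curve, as does the bootstrap band
  for zero-variance data.
* Resampling seeds derive substreams by counter from a study-level seed
  and are recorded in the outputs.

## Problem sizes used in the validation suite

The suite validates at desk scale, chosen as the package's own fixture
sizes: ECG fixtures of 40-60 s at the native 40 kHz; null-calibration and
power studies of 3 subjects x 2 sessions (full 600 s sessions) with 199
null replicates; transition-day recovery on 20 studies at the full
220-session default design; sign recovery on 100 studies of 7 subjects x 6
sessions. `scripts/acceptance.R` recomputes the same quantities from
scratch at similar sizes.

## Known limitations

* Real-data coefficients from the original deposited dataset are out of
  scope; the validated surface is analytic identities, oracle equivalence,
  calibration, and parameter recovery on synthetic studies.
* The nested random-effect models can be singular at small scale; the
  fallback ladder is recorded per fit rather than hidden.
* Pointwise null bands do not control family-wise error across the grid.
* The call segmenter is a convenience tool, not a validated detector.
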