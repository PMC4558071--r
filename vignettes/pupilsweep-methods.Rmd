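---
title: "Analysing intrasaccadic perception with pupillometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing intrasaccadic perception with pupillometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilsweep)
```

## The scientific problem

Vision is strongly impaired while the eyes make a saccade, yet some stimuli
remain visible in flight. A polarity-reversing sinusoid grating — one that
exchanges its light and dark bars on every display frame — looks like a
uniform gray field during fixation, because the flicker rate (150 Hz, one
frame every 6.67 ms) is above the fusion threshold. But such a grating
contains two opposite ambiguous-motion signals of half a cycle per frame. If
a saccade is made *perpendicular* to the bars, and the grating's spatial
frequency is chosen so that the eye's peak velocity matches the grating's
motion speed, the grating is briefly stabilized on the retina near peak
velocity and becomes visible: an intrasaccadic percept. A saccade *parallel*
to the bars cannot stabilize the grating, so nothing is seen. Because
centrally viewed visual events reflexively constrict the pupil, the percept
can be detected without subjective report: as an extra pupillary
constriction, time-locked to the saccade, in the perpendicular
(intrasaccadic-percept) condition relative to the parallel (no-percept)
condition.

`pupilsweep` implements the full analysis chain for such experiments —
from raw 1000 Hz gaze/pupil samples to the sample-wise mixed-model
time-course statistic — together with a synthetic-experiment generator that
makes every stage testable end to end.

## Stimulus calibration

The half-cycle rule fixes the grating's spatial frequency per participant
and saccade direction. The eyes travel $v/f$ degrees between frames at peak
velocity $v$ (deg/s) and frame rate $f$ (Hz); equating that distance to half
a cycle gives

$$\mathrm{SF} = \frac{f}{2v} \quad \text{cycles/deg},$$

and conversely the grating's ambiguous-motion speed is $f/(2\,\mathrm{SF})$.
The two are exact inverses, which the test suite checks to $10^{-9}$ over a
grid of velocities and frame rates. At $v = 400$ deg/s and $f = 150$ Hz,
$\mathrm{SF} = 0.1875$ cycles/deg. Luminance is modelled on the linearized
(gamma-calibrated) axis: frames are sinusoids between 5.2 and 95.1 cd/m²,
consecutive frames sum pointwise to $L_{\min} + L_{\max}$, and the fused
mean is uniform at 50.15 cd/m² for any phase. Device transfer functions are
out of scope.

## Preprocessing

* **Coordinates.** Everything internal is in degrees from screen center, y
  positive upward; readers convert from pixel coordinates (and flip y).
  A pupil area of 0 is the tracker's blink sentinel and is held as missing,
  never as a value.
* **Position smoothing.** Gaze position is convolved with an 11 ms unit-sum
  Hanning window (reflection at the edges) before differentiation; the
  pupil channel is never smoothed.
* **Velocity.** Central finite differences scaled to deg/s, one-sided at the
  endpoints. Peak velocity is, per trial, the maximum over time of the
  larger per-axis absolute velocity — the maximum of the peaks of the two
  component profiles. A Euclidean-norm variant is available
  (`peak_velocity(mode = "norm")`) because "highest speed in any direction"
  could also be read that way; the componentwise reading is the default
  since it matches the operative description of the procedure.
* **Saccade landmarks.** The mid-saccade point is the first post-cue
  crossing of the meridian orthogonal to the saccade axis, located by
  linear interpolation between samples and rounded to the 1 ms grid.
  Saccade onset is the last upward crossing of the along-axis speed through
  a 30 deg/s threshold before the mid-saccade point (the onset detector is a
  package choice; standard velocity-threshold detection). Latency = onset −
  cue, and may be negative.
* **Blink reconstruction.** Missing runs are extended by a 50 ms margin on
  each side (eyelid distortion) and replaced by a cubic spline through four
  anchors at the raw run edges ∓1 and ∓2 margins. Runs longer than 500 ms,
  or too close to the trace edges to anchor, stay masked. Anchor offsets
  follow common pupillometry practice for spline blink reconstruction.
* **Epoching.** Pupil area is epoched from −300 to +1200 ms around the
  mid-saccade point (1,501 samples) and expressed relative to the mean area
  from −105 to −95 ms. "Relative to baseline" is implemented divisively
  (value / baseline, so 1.0 = baseline): ratios are unit-free under the
  tracker's arbitrary area units; a subtractive option exists. The baseline
  is computed on the blink-reconstructed series so a blink cannot
  contaminate it; if the whole baseline window is masked the epoch is
  rejected (with a classed condition, counted by the pipeline).

## Trial exclusion

Trials are dropped when (first matching rule recorded): latency < 0 ms
(anticipation); latency > 2,000 ms; peak velocity undeterminable; peak
velocity > 1,000 deg/s; gaze more than 3.3° (Euclidean) from the fixation
dot before the saccade; or more than 3.3° from the target after it — the
deviation checks skipping a 200 ms window around the mid-saccade point,
read as centered (±100 ms), the most common convention. Band edges are
read strictly ("above"/"below"), so 220, 664 and 3.3 themselves pass. For
the calibration phase, a separate validity band (220–664 deg/s) applies and
the per-direction peak-velocity estimate is the median of at least 40 valid
trials.

## The retinal-stabilization model

For a grating with motion speed $v_g$ and the eye-velocity component $e(t)$
along the grating's motion axis, each interpretation slips at
$|{\pm}v_g - e(t)|$; the stabilization index $s(t)$ is the smaller of the
two. In the percept geometry $e(t)$ is the along-saccade velocity, so
$\min_t s(t) = |v_{\text{peak}} - v_g|$; in the no-percept geometry $e(t)$
is the orthogonal (curvature) component, so straight saccades never
stabilize and strongly curved ones partially do. The percept window is the
maximal run with $s(t) < \theta$; $\theta$ defaults to 50 deg/s. The
threshold is this package's operationalization — the underlying account is
qualitative — so $\theta$ is exposed in the configuration and reported with
every profile, and the per-trial quantities used by the statistics
(peak-velocity error, orthogonal peak) do not depend on it.

## Sample-wise mixed-effects sweep

For every sample of the epoch grid an identical linear mixed-effects model
is fitted (REML, `lme4`): normalized pupil on the fixed effects — by default
Condition (reference: no-percept) × Saccade-axis (reference: horizontal) —
with a by-participant random intercept and by-participant random slopes for
all predictors. Random effects are uncorrelated by default, a robustness
choice at ten participants. No p-values are computed for the sweep; an
effect is *reliable* where $|t| > 2$ for at least 200 consecutive
milliseconds. The rule is applied two-sided because the percept effect is a
constriction (negative coefficient under these references); a one-sided
option exists. Samples whose full model fails are refit without random
slopes and flagged; flagged samples never count toward reliability. The
grid may be decimated (the run-length is counted in ms, so the criterion is
unchanged up to grid resolution); interval boundaries on smooth t-series
move by at most the decimation step.

The model source describes direction as a two-level *axis* factor
(horizontal/vertical) rather than four levels — the reference level
"horizontal" only parses as an axis contrast — with the four-level factor
available simply by passing `~ condition * direction`.

Post-hoc tools mirror the kinematic account of direction differences:
per-participant SD of peak velocity and mean orthogonal peak
(`dispersion_metrics()`), classical two-sided paired t-tests between axes
(`paired_t()`, df = n−1), and within participant × direction median splits
(`median_split_select()`, strictly below the group median) on peak-velocity
error and orthogonal peak to isolate trials where the percept should be
strongest.

## The synthetic experiment generator

`simulate_experiment()` produces complete experiments with the structure
the analysis assumes; it stands in for raw recordings, which are not
shipped.

* **Kinematics.** Saccades are 17° in four directions. The along-axis
  velocity profile is a raised-cosine pulse — smooth, unimodal, two
  parameters — whose duration is set by amplitude and peak velocity
  (85 ms at 400 deg/s, main-sequence-plausible); curvature is a
  zero-integral single-cycle sine in the orthogonal channel. Velocities are
  evaluated at sample midpoints so displacement integrates exactly. Peak
  velocities are drawn per trial around 400 deg/s with SD 100 (horizontal)
  vs 150 (vertical) deg/s: vertical saccades are more variable, and the
  horizontal SD leaves roughly 95% of horizontal calibration trials inside
  the 220–664 deg/s validity band. Orthogonal peaks average 25 (horizontal)
  vs 100 (vertical) deg/s, vertical curvature often approaching 150 deg/s.
  Invalid calibration trials are redrawn, emulating the session practice of
  repeating them.
* **Pupil.** Responses are impulses convolved with an Erlang kernel
  (shape 3, τ = 150 ms, peak at 300 ms) — a standard smooth unimodal
  pupil-response surrogate with few parameters: a +5% dilation at the cue
  (motor preparation), a −15% constriction from 220 ms after the
  mid-saccade point (the ordinary post-saccadic constriction), and a
  percept-driven extra constriction from 300 ms after the mid-saccade point
  with full-stabilization amplitude 4% of baseline. White (1%) and slow
  (1%, ~25 ms knots) noise, Poisson blinks (rate 0.3/trial), and a
  position-artifact term (2 and 4 a.u./° in x and y) are added. The true
  effect size in ratio units is not pinned down numerically by the source
  material; 4% is a configuration choice of this package, sized as a small
  fraction of the ordinary post-saccadic constriction.
* **Percept coupling.** The extra constriction scales per trial with the
  stabilization actually achieved: gain $\max(0, 1 - s_{\min}/v_g)$. In the
  percept geometry this is driven by the match between the trial's peak
  velocity and the grating speed; in the no-percept geometry by curvature
  (partial stabilization). This coupling — rather than a bare condition
  indicator — is what produces the observed direction differences: higher
  vertical velocity variability and curvature dilute the condition contrast
  for vertical saccades, and the two median splits restore it.
* **Calibration.** Each participant × direction gets its grating spatial
  frequency from the half-cycle rule applied to the median of its simulated
  calibration peaks, exactly as the pipeline would.

What the generator does **not** emulate: main-sequence amplitude–velocity
covariation (amplitude is fixed), oculomotor dynamics beyond the stylized
pulses, pupil foreshortening geometry, temporal contrast sensitivity, or
any masking by pre/post-saccadic stimulation. Passing end-to-end tests
therefore demonstrates that the pipeline recovers effects of the assumed
shape from data with realistic noise, blinks and artifacts — not that the
pipeline is robust to every property of real recordings.

## Problem sizes and numerical choices

Desk-scale runs use 10 participants × 4 directions × 2 conditions × 10
trials (800 trials, 2.1 s each at 1000 Hz) and a 10 ms-decimated sweep
grid; these sizes give stable mixed-model fits while keeping a full
replicate under ten seconds. Mixed models use the `bobyqa` optimizer with
derivative checks off; singular fits are accepted (variance components may
legitimately hit zero), convergence failures degrade to intercept-only
random effects and are flagged. Meridian crossings are interpolated to
sub-ms and rounded to the grid; ties in the percept-window rule take the
earliest run. Degenerate inputs error early and descriptively: non-uniform
grids, windows longer than traces, all-masked trials, baselines without a
single valid sample.

## Known limitations

Positional pupil artifacts are modelled and measurable but *not* corrected
by default — gaze angle has both a real and an artifactual effect on
measured pupil area, with opposite signs in this paradigm, so the linear
regression correction is unsafe; `position_artifact_regression()` is
provided for sensitivity analyses only. The sweep's reliability rule
controls no formal error rate; under the generator's null it produces
reliable intervals in well under 10% of replicates, but that is an
empirical property, not a guarantee. Binocular data, microsaccades and
torsion are out of scope.
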