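---
title: "Methods: countermovement-jump neuromechanics in simulated hypogravity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: countermovement-jump neuromechanics in simulated hypogravity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypojump)
```

## The problem this package addresses

When a person jumps and lands, their nervous system prepares the landing
before the foot touches the ground: the calf muscles (the triceps surae --
medial and lateral gastrocnemius and soleus) switch on roughly 100 ms before
touchdown. The timing and size of this *preactivation* depend on an internal
prediction of when and how hard the landing will be, which in turn depends
on an internal estimate of gravity. Exposure to simulated hypogravity --
body-weight support that reduces the net downward force -- changes that
prediction, and the change persists briefly after the support is removed
(an *aftereffect*): preactivation starts later (closer to touchdown) and is
weaker, and the push-off and landing force impulses shrink.

`hypojump` implements the complete measurement chain needed to quantify
these effects from synchronized force-plate, EMG, motion-capture, and
(optionally) ultrasound muscle-tendon-junction recordings of vertically
targeted countermovement jumps, together with a synthetic-trial generator
that produces recordings with known ground truth so every stage of the
chain can be validated by recovery tests.

## Pipeline stages

### Phase segmentation and jump kinetics

Jumps are segmented from the vertical ground reaction force (GRFz):

* **Aerial phase**: the longest contiguous run with total GRFz below 25 N;
  liftoff is its first sample and touchdown the first sample at or above
  25 N after it.
* **Lift phase**: begins at the last upward crossing of body weight before
  the push-off force peak. The countermovement unload dip therefore lies
  inside the search window, but the boundary chosen is the force *rising*
  through body weight toward push-off.
* **Land phase**: from touchdown to the first downward crossing of body
  weight after the landing force peak.

Lift and landing impulses are trapezoidal time integrals of the raw GRFz
over these windows. We integrate the gross force (area under the GRFz
curve); a net-impulse variant (GRFz minus body weight) is available via
`compute_impulses(net = TRUE)` and is the quantity used in the
impulse--momentum validation, where on noise-free synthetic trials the net
lift integral equals the takeoff momentum to within 0.5%.

Two conventions deserve note. First, for trials performed with body-weight
support, "body weight" means the standing force-plate plateau with the
support engaged (the effective weight), which is what the plates read and
what the crossing rules need. Second, GRFz and marker channels are low-pass
filtered at 25 Hz before segmentation, but the two 25 N aerial-threshold
crossings are then re-timed on the raw force within a ±60 ms neighborhood:
a zero-phase filter smears the near-instantaneous landing force onset
backwards in time by up to ~10 ms, which would otherwise bias touchdown --
and hence every onset-before-landing measurement -- early.

Jump height is the aerial-phase peak of the sternum marker minus the
standing reference height; target error is its difference from the target
(75% of the participant's best maximum jump). The effective gravity actually
experienced is estimated per jump as twice the quadratic coefficient of a
least-squares parabola fit to the aerial marker trajectory.

The ballistic analytics `fall_time()` (`sqrt(2 h / g)`),
`delay_prediction()`, and `delay_mitigation_percent()` quantify how much
later a jumper should expect to land if their motor system still assumes a
lower gravity: from 0.273 m, falling takes ~236 ms at 1 g and ~331 ms at
0.508 g, a predicted 95 ms delay; an observed aftereffect of ~26 ms
corresponds to ~73% mitigation of that prediction by online feedback.

### EMG preactivation analysis

Raw EMG is band-limited (5--450 Hz, zero-phase) and full-wave rectified.
Each muscle is normalized by the peak of a 100 ms centered sliding-window
average over the participant's three maximum jumps (the overall maximum
across all three trials; the window shortens at record edges).

Preactivation onset uses a cumulative-integration method: over the aerial
window, the cumulative integral C(t) of the rectified EMG is compared with
the chord joining its endpoints; the onset is the time of maximum downward
deviation of C(t) from the chord -- the elbow where electrical activity
most rapidly increases. Ties take the latest sample, and onset is reported
in ms before touchdown at EMG-clock resolution (kinetic landing time mapped
by nearest sample). An alternative elbow criterion (maximum second
difference of the smoothed cumulative integral) is available via
`detect_onset(method = "second-diff")` for sensitivity analysis.

Three exclusion gates handle the very low activation seen during and after
body-weight support:

1. **no-late-max** -- the aerial trace is smoothed at 1 Hz and local maxima
   extracted; if the latest maximum is not within 150 ms of touchdown there
   is no landing-directed burst.
2. **too-early** -- onsets more than 150 ms before touchdown (e.g. residual
   push-off activity during ascent) are outside the physiological
   preactivation range. Both 150 ms gates are inclusive.
3. **sub-1-percent** -- mean normalized activity between onset and
   touchdown below 0.01 indicates absent preactivation.

For gate 1, local maxima use plateau compression (a flat run counts once,
at its last sample, so a constant trace yields a single candidate at the
window end) and the smoothing is applied to the aerial segment itself so
the lift burst ending at liftoff cannot leak into the gate. The 1 Hz
smoother is a zero-phase Gaussian kernel with the equivalent -3 dB cutoff
(sigma = 0.1325/fc) rather than a Butterworth: a 4th-order IIR at a
1 Hz corner and 1000 Hz sampling is numerically degenerate in double
precision without second-order sections, and its transient exceeds the
aerial window length. Every other stated corner (25 Hz kinetics, 5--450 Hz
EMG, 6 Hz muscle length) is a 4th-order Butterworth applied
forward--backward with odd-reflection padding, so filtering is zero-phase
and record edges are not corrupted by filter transients.

Preactivation magnitude is the mean rectified normalized EMG from onset to
touchdown; iEMG is the trapezoidal integral over the same window. Triceps
Surae Preactivity is the mean iEMG over MG, LG, and SOL of one leg; when
any member muscle is excluded the leg-jump value is reported missing with
the reason propagated (the metric is defined as a three-muscle average and
partial averages would change its meaning; a two-muscle fallback exists
behind `allow_partial = TRUE` and is clearly non-default).

### Muscle-tendon geometry and spindle feedback

Ultrasound frames are acquired column by column (rolling shutter), so the
tracked muscle-tendon-junction (MTJ) pixel column sets its true sampling
time: frame time + (u / image width) x frame period. After this
per-frame correction the MTJ is interpolated (cubic) onto the kinematic
clock and projected orthogonally onto the muscle-tendon-unit line (knee
joint center to Achilles insertion). MG muscle length is knee-to-projection
distance, tendon length projection-to-insertion; for in-segment projections
they sum exactly to the MTU length. Out-of-segment projections are flagged
but not truncated, since truncation would bias lengths near extreme ankle
angles. Lengths are filtered at 6 Hz and differentiated by central
differences (lengthening positive).

Spindle group-Ia firing rate is estimated as

$$R_{Ia} = 65\,(V_{MG}/L_0)^{0.5} + 200\,\frac{L_{MG}-L_0}{L_0} + k_u^{max} u + R_{Ia0}$$

with the velocity term clamped at zero for shortening (the model encodes
lengthening velocity), the total rate floored at zero, the fusimotor term
using `k_u_max = 100` (percentage maximal recruitment) with `u` the
normalized activation envelope, and `R_Ia0 = 0` (participant-specific
resting rates are not observable here). The printed lineage of this model
is typographically ambiguous about whether the length term is normalized by
the resting length; the default is the normalized reading, which keeps both
dynamic terms dimensionless and matches the modelling tradition the
equation comes from, and a strict-literal variant (length term
`200 (L - L0)` in meters) is selectable with `variant = "literal"`. Both
variants are exercised in the tests; neither is asserted as uniquely
correct. `L0` defaults to the standing-calibration MG length. MG force is
ankle torque divided by the moment arm (orthogonal distance from the ankle
center to the MTU line), flagged unreliable below 1 mm.

### Wavelet-domain functional paired t-test

Waveform comparisons (PRE vs POST, paired by participant) are made in the
wavelet domain rather than point by point: each phase-normalized waveform
(64 points for lift and land, 34 for the aerial phase) is decomposed with a
full-depth orthogonal periodized discrete wavelet transform; each
coefficient gets a paired two-tailed t-test at alpha = .05 (per coefficient,
no multiplicity correction -- a Holm-corrected variant exists behind
`p_adjust = "holm"` and is clearly non-default); significant coefficients
carry their mean paired difference (PRE − POST) as a contrast, all others
are zeroed; and the inverse transform returns the contrast to the time
domain, where points with |contrast| at or above 10% of the peak contrast
are flagged significant.

Implementation choices:

* **Wavelet and depth.** Third-order coiflet at maximal decomposition
  depth, following the wavelet-functional-ANOVA tradition; `family` and
  `level` are arguments and recorded in the result. The transform is built
  as an explicit orthogonal matrix (signals here are at most 64 points), so
  synthesis is exactly the transpose: round-trip error is at machine
  precision and the coefficients of i.i.d. noise are themselves i.i.d.,
  which is what makes the per-coefficient t-test calibrated (the null
  false-positive rate is ~0.05; the acceptance script measures it over
  1000 seeded replicates).
* **The 34-point aerial phase** is internally resampled to 32 (the nearest
  power of two), decomposed, tested, and the reconstructed contrast
  resampled back to 34.
* **Time normalization / resampling** is cubic-spline interpolation on the
  index grid: it preserves endpoints exactly and reproduces linear trends
  without ringing, which Fourier or polyphase resampling does not on
  nonperiodic jump-phase segments.
* **Zero-variance coefficients** (all paired differences identical) are
  judged in the t-limit: significant if the common difference is nonzero,
  not significant if identically zero.

### Scalar comparisons

Every per-metric comparison against PRE (Early Adaptation, Late Adaptation,
POST, Washout) uses a gated paired test: Shapiro-Wilk on the paired
differences (the quantity whose normality the paired t-test actually
assumes; a per-group variant exists behind `shapiro_on = "groups"`) and
Levene's test on the two condition vectors (median-centered). If both pass
at .05, a two-tailed paired t-test (t, df = n − 1); otherwise a two-tailed
Wilcoxon signed-rank (z from the normal approximation with continuity and
tie corrections; exact p for n ≤ 25 without ties; zero differences
dropped). All differences exactly zero reports p = 1; zero-variance nonzero
differences are an exact effect, reported significant with p = 0 and
flagged degenerate. Effect sizes are Hedges
$g_{av} = J \cdot \bar d / \tfrac{1}{2}(s_x + s_y)$ with
$J = 1 - 3/(4(n-1)-1)$; tables print the magnitude, the signed value is
retained. No family-wise correction is applied across metrics, matching the
per-comparison convention of the summary tables this layout mirrors.

## The synthetic-trial generator

No raw recordings are distributed with the study this analysis chain
serves, so the generator is the package's test bed. It emulates, with known
ground truth:

* **Protocol**: 20 participants; 10 PRE / 50 ADAPT / 10 POST targeted jumps
  plus 3 maximum jumps for EMG normalization; target at 75% of the best
  maximum jump; ADAPT at 0.508 g effective gravity (body-weight support).
* **GRF / center of mass**: quiet stance, a countermovement unload dip, a
  push-off force peak, ballistic flight, and an underdamped spring-damper
  landing (force spike, one oscillation through body weight, settle). Two
  shape parameters are solved per trial -- the push peak so the flight apex
  hits the requested height, and the unload depth so the center of mass
  passes through standing height exactly at takeoff -- which makes the
  impulse--momentum and flight-time/height identities hold by construction.
  Phase durations scale with $\sqrt{9.81/g}$ (movement slows in
  hypogravity). The force steps from a 50 N residual to zero in one sample
  at liftoff so the 25 N threshold is pinned to the true boundary.
* **EMG**: a 20--450 Hz unit-RMS noise carrier multiplied by a normalized
  envelope -- tonic stance baseline, a lift burst ending exactly at
  liftoff, *exact silence* through the aerial phase, then a preactivation
  burst starting exactly `onset_truth_ms` before touchdown with a 10 ms
  half-cosine rise. The sharp rise reflects rapid initial recruitment and
  makes "onset" well-defined to a few ms; with slow (tens of ms) rises the
  elbow of the cumulative integral lags the envelope start for any
  detector, not just this one. Condition effects are injected as the
  configured onset shift (POST default: 26 ms closer to landing) and burst
  amplitude scaling (ADAPT 0.5, POST 0.6). Additive noise is stated in
  normalized units (fraction of the normalization peak).
* **Markers**: the sternum marker follows the center of mass, so the aerial
  trajectory is an exact parabola at the trial's effective gravity.
* **MTJ / torque** (optional): the MTJ moves along a fixed MTU line with a
  phase-locked shorten-then-stretch length profile kept inside the 6 Hz
  analysis passband, plus a fixed off-axis offset that the projection
  removes; pixel columns encode the rolling shutter by construction; ankle
  torque is proportional to GRFz over a 4 cm moment arm.

What the generator does *not* emulate -- and what passing recovery tests
therefore cannot certify about real data: electromechanical delay and
motion artifact in EMG, soft-tissue and marker-occlusion artifacts,
between-jump fatigue or learning curves within a block, probe motion
relative to the leg, and any horizontal mechanics. The generator's defaults
are the study conditions; they are not tuned per test.

Free parameters the source protocol does not pin down were fixed once at
physiologically conventional values: countermovement depth falls out of the
zero-takeoff-offset solution rather than being set; trial-to-trial jump
height jitter 1.5 cm with a −3 cm POST bias; onset jitter 5 ms SD;
landing leg stiffness ω = 22 rad/s with damping ratio 0.55; EMG scale
~0.4 mV.

## Problem sizes and reproducibility

The validation suites use sizes chosen to make each check statistically
meaningful while keeping a full run interactive: onset recovery over ~216
onset observations per noise level; null calibration of the wavelet test
over 1000 replicates of 20x64 matrices (the per-coefficient false-positive
rate has a binomial SE of ~0.0009 there); type-I calibration of the scalar
battery over 1000 replicates at n = 20; and the end-to-end demonstration on
20 participants with 3/2/2 jumps per block -- the comparison timepoints only
use the first and last jump of each block, so additional within-block jumps
add runtime without adding information. Every stochastic quantity derives
from a single seed; identical configurations reproduce identical cohorts
bit for bit.

## Known limitations

* The per-coefficient alpha with no multiplicity correction follows the
  method as specified; with 64 coefficients the family-wise error of "any
  coefficient significant" is high by construction, which is why the
  time-domain 10%-of-peak mask, not the coefficient count, is the unit of
  interpretation.
* The orthogonal periodized DWT fixes one filter-alignment convention;
  other implementations of the same wavelet family can distribute energy
  slightly differently between coarse bands on very short signals. The
  statistical properties used here (orthonormality, exact reconstruction)
  are convention-independent.
* Wilcoxon z-values use the normal approximation even when the p-value is
  exact, mirroring common reporting practice.
* The generator's landing spring is a one-degree-of-freedom model; landing
  impulse magnitudes are realistic but not subject-specific.
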