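---
title: "Screening carpal tunnel syndrome from spiral drawings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening carpal tunnel syndrome from spiral drawings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralscreen)
```

## The screening problem

Carpal tunnel syndrome (CTS) is a median-nerve entrapment at the wrist. Its
early symptoms (numbness, sensory disturbance) rarely send people to a
clinic, while severe CTS atrophies the thenar muscles and degrades thumb
control, and hence writing. A drawing task on a consumer tablet is an
attractive screening instrument: the subject traces a guide spiral with a
stylus, and the tablet records pen position and tip pressure at 120 Hz. This
package implements that pipeline end to end: the guide geometry, the
tracing-error and pen-pressure statistics, jerk-based spectral features, and
an SVM screening classifier evaluated by leave-one-out cross-validation
(LOOCV) with ROC analysis. Because no clinical recordings are distributed, a
synthetic cohort simulator stands in for real subjects; every stage is
exercised and tested against it.

## The guide spiral and the tracing error

The guide is the Archimedean spiral given in polar form by

$$ r = -\theta, \qquad 0 \le \theta \le 7\pi , $$

three and a half turns whose rendered Cartesian points are
$(x, y) = (-s\,\theta\cos\theta,\, -s\,\theta\sin\theta) + c$. The negative
sign simply rotates the familiar $r = \theta$ spiral by $\pi$; the start
direction is the negative $x$ axis. The screen scale $s$ is solved
numerically so that the maximum axis-aligned extent of the dense curve — the
on-screen "longitudinal diameter" — is exactly 4 cm, giving
$s \approx 0.0978781$ cm/rad. "Longitudinal" is not defined more precisely by
the app description, so the larger of the two axis-aligned extents is used;
the two extents differ by under 3% for this curve, and the choice is exposed
through `guide_spiral(diameter = )`.

A drawn trace is compared with the guide in polar coordinates. `to_polar()`
computes each sample's radius as its distance to the spiral centre and its
angle by *unwrapping*: successive angular increments are taken in
$(-\pi, \pi]$ and summed, so the angle accumulates turns rather than folding
at $2\pi$. A wrapped presentation (all angles in $[0, 2\pi]$) is convenient
for plotting but destroys the single-valued model radius the error metric
needs — with 3.5 turns there would be two or three guide radii per wrapped
angle — so the package computes on the unwrapped angle throughout and leaves
wrapping to plots. The angle origin is anchored at the guide's start
direction, and a sample at the exact centre (radius 0) adopts the angle of
the nearest following off-centre sample.

The tracing error (`spiral_rmse()`) is the root mean square of the *radial*
residuals $r_i - s\,\theta_i$ — each sample is compared with the guide radius
at the sample's own unwrapped angle, not with the nearest point on the curve.
This matches the $r$-versus-$\theta$ construction of the error, is cheap, and
is deterministic; an orthogonal-distance metric is deliberately out of scope.
Two windowing rules apply:

* samples with $\theta \le 2\pi$ are excluded (strict inequality at the
  boundary, an arbitrary but fixed tie rule). Subjects often start drawing
  slightly off the guide's start point, and that noise concentrates in the
  first turn; excluding the first turn removes it without per-subject
  thresholds. The bound is a parameter (`exclusion`, radians).
* samples with $\theta > 7\pi$ (overshoot past the guide's end) are clipped
  out, so a subject who keeps spiralling is not penalised for drawing more
  spiral than the template.

If no sample survives the window the drawing is "too short" and an error is
raised rather than a degenerate zero.

## Jerk and its chunked spectrum

Jerk — the third time derivative of a kinematic signal — indexes movement
smoothness; tremulous or poorly controlled strokes have elevated,
band-structured jerk. Two jerk series are computed per recording: the
Euclidean norm of the per-axis third finite difference of position
(`jerk_trajectory()`, cm/s³, non-negative by construction) and the signed
third difference of pressure (`jerk_pressure()`, device-units/s³). Both are
divided by $\mathrm{d}t^3$; this global constant is irrelevant to the
classifier (features are standardized) but keeps the outputs unit-honest and
directly testable against analytic derivatives ($x(t) = t^3$ must give
exactly 6 cm/s³). "Jerk of the trajectory" admits other readings (jerk of
speed, signed curvilinear jerk); the vector-norm convention is the standard
smoothness quantity and is what the package uses.

Featurization (`chunk_spectrum()`) takes the **first 512 frames** of each
jerk series (4.27 s at 120 Hz — every compliant drawing lasts over 5 s, so
the window always fits and no padding is implemented; shorter input is an
error), splits them into **16 consecutive non-overlapping chunks of 32
frames**, multiplies each chunk by a periodic (DFT-even) Hanning window and
applies a 32-point DFT. The magnitude spectrum is kept — magnitude being the
conventional reading of "frequency components"; power and complex parts are
the obvious alternatives and were rejected to keep features on the signal's
own scale. A 32-point real DFT has 17 non-redundant bins (DC through
Nyquist); **16** are retained: bins 1–16, i.e. 3.75 Hz to 60 Hz in 3.75 Hz
steps. DC is the bin dropped because the DC of a jerk series carries only
slow drift, while 60 Hz (the Nyquist frequency of 120 Hz sampling) is
explicitly part of the retained band. Flattened chunk-major this yields the
256-dimensional feature vector. All of the geometry is configurable through
`feature_config()`; the 256-dimension contract is asserted for the defaults
and the general $n_\text{chunks} \times n_\text{bins}$ contract for other
geometries.

## The four training-data sets

Per subject, `extract_bundle()` assembles:

| set | content | dimension |
|-----|---------|-----------|
| 1 | spectrum of the pressure jerk | 256 |
| 2 | spectrum of the trajectory jerk | 256 |
| 3 | spiral tracing RMSE (cm) | 1 |
| 4 | maximum pen pressure (device units, 0–4.166667) | 1 |

`bundle_to_matrix()` stacks any subset of the sets into a design matrix with
a fixed, documented column order (set order, chunk-major within a spectral
set), and `combination_grid()` evaluates all 15 non-empty subsets.

## Classifier and evaluation

The screen is a soft-margin SVM with polynomial kernel
$(\gamma u^\top v + c_0)^d$ — the kernel family implied by tuning a "kernel
degree" — with degree $d$ and cost $C$ as the tunable hyperparameters
(`model_config()`; defaults $d = 3$, $C = 1$, $c_0 = 1$,
$\gamma = 1/d_\text{features}$; an RBF kernel is available as an option).
Feature columns are z-scored **within each training fold** and the fold's
transform is applied to the held-out subject: the four sets live on wildly
different scales (spectral magnitudes vs cm vs device units), and fitting
the standardization on the training fold only avoids leakage.

`cts_screen()` is the package's central fit. For each subject it trains on
the other $n-1$ and records the held-out *decision value* (not the hard
prediction), oriented so larger means more CTS-like; the continuous LOOCV
scores feed the ROC. `roc_analysis()` sweeps thresholds over the unique
scores, integrates AUC by the trapezoid rule (provably equal to pairwise
concordance with ties counted ½ — the tests assert exact agreement with an
independent concordance computation), and picks the operating cutoff as the
threshold closest to the ideal top-left corner $(0, 1)$ of ROC space, ties
broken toward higher sensitivity — the screening-appropriate direction.
Degenerate all-tied scores yield a valid report with AUC 0.5 and a warning.
`tune_model()` evaluates a (degree, C) grid by the same LOOCV + ROC and
minimizes the chosen cutoff's corner distance, ties toward smaller degree
then smaller C.

Two honest caveats are reproduced as-designed rather than corrected: the
hyperparameters are tuned on the same LOOCV used for reporting (an
optimistic bias; nested CV is explicitly out of scope), and LOOCV itself has
a known *anti-learning* artifact — under label permutations at balanced class
sizes the held-out subject's class is always the fold minority, which biases
null AUCs below 0.5. The test suite documents this (and reproduces it with an
independent scikit-learn run) instead of pretending the permutation null sits
at exactly 0.5; the cohort-level null check (identical group parameters)
lands near 0.5 because the high-dimensional features carry no systematic
class signal.

## The synthetic cohort

`simulate_cohort()` generates the study conditions: 31 non-CTS and 33 CTS
subjects by default, one continuous stroke each at 120 Hz, duration drawn
per subject (normal, truncated above 5 s — every recording is long enough
for the 512-frame window). A subject advances along the guide with smoothly
modulated angular speed and radius

$$ r(t) = s\,\theta(t) + \text{ramp}(\theta)\,\bigl[b(t) + \tau(t)\bigr], $$

where $b$ is a slow random-walk shape bias (SD `radial_bias_sd`) and $\tau$
is band-limited tremor — white noise band-passed to 4–12 Hz (2nd-order
Butterworth, forward-backward filtered) and rescaled to SD
`tremor_amplitude`. The 4–12 Hz band is a physiological hand-tremor band
chosen so the group signal lives inside the retained 3.75–60 Hz feature
range; it is a simulator choice, not a claim about CTS physiology. The ramp
(linear in $\theta$ up to $\pi$, then 1) keeps the radius positive near the
centre so the trace cannot wind an extra turn around the origin; the damped
region lies entirely inside the excluded first turn. A start-position offset
(per-axis SD `start_offset_sd`) decays with a 0.08 s time constant —
effectively gone by 0.25 s, again inside the exclusion zone, mirroring why
the first turn is excluded at all. Pressure follows a smooth
rise–plateau–fall envelope (C¹ smoothstep shoulders over the first and last
15% of the drawing) whose plateau is a per-subject peak draw, plus
band-limited jitter, clipped to the device range [0, 4.166667].

Default group parameters (chosen once, as plausible magnitudes that realize
the reported group contrasts):

| parameter | non-CTS | CTS | units |
|---|---|---|---|
| tremor amplitude (4–12 Hz) | 0.02 | 0.06 | cm |
| radial bias SD | 0.05 | 0.12 | cm |
| pressure peak mean (SD) | 3.2 (0.3) | 2.4 (0.4) | device units |
| pressure jitter SD | 0.01 | 0.03 | device units |
| start offset SD | 0.1 | 0.2 | cm |
| duration mean (SD) | 8 (1.5) | 9 (2) | s |

These encode the three reported contrast directions — CTS traces less
accurately (higher RMSE), presses less hard (lower max pressure), and
carries more tremor energy in both jerk spectra — at roughly 2–3× contrast,
about what separates a patient group from controls on a motor task without
making the groups trivially disjoint subject-by-subject. Per-subject seeds
are derived from the master seed and subject index by a Lehmer-style mixing
step, so cohorts are byte-identical across runs and stable under reordering.

What the simulator does **not** emulate: pen lifts (a recording is one
continuous stroke; gaps are rejected at read time), severity grades,
altitude–azimuth stylus channels, device quantization, or any attempt to fit
parameters to real patients — no quantitative effect sizes for the jerk
spectra exist to fit. Consequently, passing tests demonstrate that the
pipeline recovers structure *of the kind reported* when it is present and
finds none when it is absent; they say nothing about clinical sensitivity or
specificity on real cohorts, whose headline numbers are not reproducible
without the original data.

## Numerical choices and problem sizes

* Guide scale: derivative sign changes of the unscaled extent are bracketed
  on a 20 000-point grid and polished with `uniroot` to `tol = 1e-14`; the
  rendered extent is exact to well below the 1e-6 cm contract.
* Angle unwrapping uses increments wrapped to $(-\pi, \pi]$; at 120 Hz the
  largest legitimate per-frame angular step is far below $\pi$.
* Writers emit full-precision (`%.17g`) ASCII and are byte-deterministic;
  round trips are lossless, and end-to-end reruns produce identical bytes.
* Degenerate inputs fail loudly: empty recordings for `max_pressure`,
  sub-4-sample recordings for jerk, windows shorter than 512 frames,
  single-class label vectors, empty tuning grids, non-finite features.
* Test problem sizes are kept at desk scale: the default 31/33 cohort for
  the recovery checks, 10 seeds for the null-cohort mean, 20 seeds for the
  direction and oracle sweeps, and an 8/8 cohort for the end-to-end
  determinism run. The full suite completes in well under a minute of
  simulation-heavy work.
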