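---
title: "Gait stability from wearable sensors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait stability from wearable sensors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitstab)
```

gaitstab implements a stride-level pipeline for quantifying how walkers
maintain balance in uncontrolled, outdoor-style conditions, from
synchronized wearable recordings (whole-body kinematics at 120 Hz,
per-foot insole forces at 100 Hz) to margins of stability, local
divergence exponents, balance-strategy regressions, spatiotemporal
measures and their statistical comparison across ground conditions. This
vignette explains the underlying models, the parameters that matter, the
synthetic data generator that the test suite is built on, and the design
decisions taken where the methodology left genuine freedom.

## The stability model

The pipeline treats the walker as an inverted pendulum of length $L$ in
gravity $g$. The extrapolated centre of mass
$$\mathrm{XCoM} = \mathrm{CoM} + \sqrt{L/g}\,\dot{\mathrm{CoM}}$$
summarizes position and velocity in a single point whose location
relative to the base of support determines whether ankle torque alone
can arrest a fall. $L$ is not a body measurement but is estimated per
stride as the mean distance from the stance-foot fifth-metatarsal marker
to the CoM over that foot's stance phase, which keeps the pendulum
constant consistent with the marker set actually recorded.

Margins of stability are evaluated at the heel strike that terminates
each stride (anterior–posterior) and over the contralateral
single-support window (mediolateral):

* **FW MoS** — AP distance from the anterior foot's heel marker to the
  XCoM. Larger values mean more resistance to a forward loss of
  stability. The anterior foot is resolved by comparing heel positions
  rather than assuming the striking foot is anterior, which is robust to
  atypical strides.
* **BW MoS** — AP distance from the XCoM to the posterior foot's
  fifth-metatarsal marker. By construction
  $\mathrm{FW} + \mathrm{BW}$ equals the AP base-of-support extent; the
  test suite asserts this identity per stride at machine precision,
  which guards the sign conventions.
* **ML MoS** — minimum signed distance from the XCoM to the stance
  foot's fifth-metatarsal marker over single stance, positive when the
  XCoM is medial to the marker. A signed (not absolute) distance is
  used, so lateral XCoM excursions beyond the foot show up as negative
  margins rather than being folded back.

## Stride segmentation and coordinate frames

Strides run from one right heel strike to the next. Kinematic heel
strikes are detected as the first sample of the heel's vertical ground
plateau, validated by a forward-velocity sign change of the heel within
±50 ms; toe-offs are the last forefoot ground-plateau sample followed by
sustained upward velocity. Heel velocity is projected onto the walking
heading (net sacrum displacement of the walking segment), so detection
is invariant to the world frame. Insole heel strikes are upward
crossings of a 30 N force threshold after at least 0.2 s below it; the
refractory interval rejects chatter around the threshold and is far
shorter than any plausible swing phase.

Each stride gets its own anatomical frame: origin at the right heel at
the initial contact, $z$ up, $x$ the horizontal unit vector along the
sacrum displacement over the stride, $y = z \times x$. The sacrum (not
the CoM) defines the heading because it is less perturbed by arm and
trunk motion; for straight walking the two are equivalent, and because
every stride carries its own frame, gradual heading changes are absorbed
without excluding turning strides. Percent-gait normalization resamples
each channel to 101 points (0–100%) by cubic spline for the smooth
kinematic channels and linear interpolation for the insole channels,
whose contact transients should not be rung by a spline. CoM velocity
and acceleration are central differences on the full 120 Hz recording
*before* any stride-level resampling — differentiating the percent-gait
arrays would conflate time warping with dynamics.

The two sensor clocks are aligned on the jumps performed at the start of
a trial: flight phases appear simultaneously as near-zero force and
free-fall vertical CoM acceleration, and the offset is the median
difference of the paired landing-onset times, with the insole onset
interpolated to sub-sample precision at the force-threshold crossing.
This recovers offsets to about a millisecond on synthetic trials; a
single constant offset is applied (linear clock drift is not modelled).
Decimation from higher kinematic rates to 120 Hz uses a zero-phase FIR
anti-alias filter so event times are not biased.

## The stepping and compensation regressions

The stepping strategy is quantified by a no-intercept OLS regression of
the foot-placement deviation on the nine mean-centred midstance CoM
state deviations (position, velocity, acceleration × AP/ML/VT), fitted
separately for the AP and ML placement coordinates. Foot placement is
the right heel-marker position at heel strike in the stride frame; the
midstance instant is the midpoint of the contralateral single-support
phase preceding the placement, operationalized as the 80% stride phase
(midpoint of the nominal 60–100% window) and exposed as
`midstance_frac`. Only right steps enter the regression — one
observation per right-heel-strike-delineated stride — which keeps the
estimates aligned with the generator's per-stride ground truth; pooling
mirrored left steps would double the sample at the cost of a second,
interleaved dependence structure.

The stepping error of stride $k$ is the predicted minus actual ML
placement deviation (the negative OLS residual). The compensation
regression relates it to two mean-centred predictors: the stance-mean ML
centre of pressure of the preceding stance foot (ankle strategy; CoP is
taken relative to the sole centreline, which is what insole hardware
reports) and the stride-mean ML trunk angular velocity in deg/s (trunk
strategy). Gains are tested against zero with t-tests; $\eta^2$ effect
sizes are always computed and the reporting layer applies the
significance gating.

All measures can be nondimensionalized before statistics (lengths by
$L$, velocities by $\sqrt{gL}$, accelerations by $g$, times by
$\sqrt{L/g}$); the regressions' $R^2$ is invariant under this scaling,
which the suite checks. Two conditions are compared with unpaired
pooled-variance t-tests (Welch available by flag); three or more with a
one-way ANOVA followed by pairwise t-tests under the Holm–Šidák
step-down correction $1-(1-p_{(k)})^{m-k+1}$ with monotonicity
enforcement.

## The synthetic gait generator

`simulate_walker()` is the package's test bed: it emulates the signals
the pipeline consumes while keeping every downstream target exactly
recoverable.

The CoM follows a constant-speed AP ramp with a small two-per-stride AP
oscillation, sinusoidal ML sway at step frequency, and a double-bump
vertical oscillation; the CoM height is calibrated numerically (by root
finding on the sampled baseline) so that the *measured* leg length
equals the configured $L$, and the AP offset so that the *measured* mean
FW MoS equals its target, using exactly the sampled-signal operations
the analysis applies. Per-stride CoM-state perturbations are injected as
compactly supported $C^1$ window functions centred on the midstance
instant, carrying a prescribed position, velocity and acceleration
there; their covariance (`com_state_cov`) is a free modelling choice —
defaults of roughly 1 cm / 3 cm s⁻¹ / 0.1 m s⁻² SD per axis give
stepping $R^2$ values in the low-to-mid 0.9s, the range typical of
steady overground walking.

Foot placements follow the recursion
$$\mathrm{fp}_k = B\,s_k + \varepsilon_k, \qquad
  s_k = c_k - o_{k-1},$$
where $c_k$ is the injected midstance state *as the analysis measures
it* (same central differences, same interpolation, on the generator's
own sampled CoM) and $o_{k-1}$ is the accumulated placement deviation of
the stride origin. Because the stride frame originates at the previous
right footfall, the horizontal position components of the measured state
inherit the origin's deviation; building the recursion in exactly that
frame makes the noiseless stepping regression recover $B$ and $R^2 = 1$
to machine precision end-to-end, which the suite asserts. The same
recursion implies that the measured state covariance exceeds
`com_state_cov` in the horizontal position components by the stationary
variance of $o$ (an AR process with matrix $I - G$, $G$ the 2×2 position
gain block); `analytic_stepping_r2()` accounts for this via the discrete
Lyapunov equation, and the 50-replicate acceptance run reproduces its
value to well under 0.01.

The ML placement noise $\varepsilon^{ML}$ is i.i.d. Gaussian with SD
`fp_noise_sd`. After the footfalls are fixed, the generator decomposes
the stepping residual the downstream OLS will leave — which it can
compute exactly, since it knows the realized design matrix — into the
two compensation channels plus a residual of SD
`compensation_noise_sd`: the trunk deviations are drawn freely and the
CoP deviations solved from the identity
$\mathrm{Error} = \beta_{ankle}\,\Delta\overline{\mathrm{CoP}} +
\beta_{trunk}\,\Delta\overline{\omega}_{trunk} + \eta$. With
$\eta = 0$ the compensation fit is exact ($R^2 = 1$, gains to machine
precision). With $\eta \neq 0$ the constructed CoP channel necessarily
correlates with $\eta$, so the noisy-case OLS gains are attenuated
relative to the generative constants — the generator guarantees the
decomposition identity and the residual's scale, not predictor
exogeneity. The acceptance checks therefore use the noiseless case for
exactness and a zero-ankle-gain generator for null calibration (the
ankle estimate is non-significant at $\alpha = 0.05$ in ~95% of
replicates), which is what the statistical claims downstream rely on.

Vertical GRFs are two-peaked stance profiles
$0.8\sin(\pi s) + 0.2\sin(3\pi s)$, scaled so the stance-average force
equals body weight; the profile crosses 30 N within a few milliseconds
of the true contact, so force-detected heel strikes land within one
insole sample of truth. Three jumps (0.3 s flights with landing
transients, plus a 50 ms load ramp so the threshold crossing is
continuous) are prepended for synchronization, and a configurable
constant offset shifts the insole clock.

What the generator deliberately does **not** emulate: stride-*time*
variability (all strides share the configured duration, so temporal
variability measures are trivially zero on synthetic data), feedback
from foot placement back into the CoM trajectory, ground-slope and
surface effects, soft-tissue artefacts, and marker noise. Passing tests
therefore demonstrate that the estimators recover the constructs they
claim to measure under the stated noise model — not that real
winter-walking data are free of the additional error sources above.

## Local divergence exponents

The LDE input is the stride-normalized CoM velocity: each stride's
velocity component resampled to 100 points and concatenated (the
half-open grid avoids duplicated boundary samples). The series is
delay-embedded with dimension 5 and delay 10; each point's nearest
neighbour is searched outside a Theiler window of one stride, ties going
to the first index; the mean log Euclidean distance is tracked over one
stride of forward offsets; and the exponent is the least-squares slope
over the first half stride (`fit_range = c(0, 0.5)`), expressed per
stride-normalized time. The fit interval and per-stride sample count are
conventions, exposed as arguments. Exact zero distances (perfectly
periodic series) are floored at $10^{-12}$ before the log, giving a flat
curve and a zero exponent in the noise-free limit. The implementation is
verified elementwise against an independent brute-force all-pairs
oracle on small instances, and is exactly invariant to affine scaling of
the input. Desk-scale analyses here use tens to a few hundred strides;
with very long series the $O(n^2)$ neighbour search (blocked through
BLAS) dominates the pipeline's run time.

## Numerical choices and degenerate inputs

* Central differences (second-order interior, first-order ends) for all
  derivatives; linear interpolation for sub-sample state evaluation.
  Both are linear operators, which is what makes generator/analysis
  self-consistency exact rather than approximate.
* Cubic "fmm" splines for percent-gait resampling of smooth channels;
  boundary samples are copied verbatim so 0% and 100% are the original
  heel-strike samples.
* Strides missing a contralateral event keep `NA` in the affected
  columns (ML MoS, stance time, step width, CoP mean) with a warning;
  regressions drop incomplete strides listwise and refuse to fit below
  30 complete strides.
* Rank-deficient stepping designs abort with the names of the collinear
  columns; constant compensation predictors abort likewise.
* Two all-constant groups with equal means compare at $p = 1$ by
  convention (with a warning); standing recordings and zero-length
  strides abort with explanatory errors.

## Known limitations

The kinematic event detector is a marker-geometry replacement for
proprietary sensor-fusion contact detection and is validated against the
synthetic ground truth, not against commercial systems. Clock alignment
assumes a constant offset. The compensation regression inherits the
attenuation caveat above whenever a nonzero residual is present, which
is worth remembering when interpreting its absolute gain values on real
data; its $R^2$ and significance structure are unaffected. Finally, all
calibration statements in this vignette are statements about the
generator's noise model at the problem sizes used by the test suite
(typically 40–60 strides for exactness checks, 500 strides × 50 seeds
for recovery statistics).
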