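---
title: "Methods: an EEG-triggered assistive reach pipeline in software"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EEG-triggered assistive reach pipeline in software}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachbci)
```

This vignette documents the models implemented in `reachbci`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## The system being simulated

A user wearing a 32-channel EEG headset hears a dictated list of objects
detected on a tabletop and selects one by clenching their jaw while its name
is being read. The clench produces a large muscle artifact in the EEG
band-power stream; a binary classifier ("relaxed" vs "clench") turns it into
a selection trigger. Four square fiducial markers bound a 600 × 300 mm work
area; a planar homography maps the detection's pixel centroid to table
coordinates, and a 3-DoF serial arm reaches the target under a
gradient-descent planner. The package implements each stage as a pure,
seeded software component so the whole loop can be simulated and tested.

## Arm kinematics

The arm is described by Denavit–Hartenberg rows
$(\theta_1, \pi/2, a_1, a_0)$, $(\theta_2, 0, a_2, 0)$,
$(\theta_3, 0, a_3, 0)$: a vertical base revolute joint, then a shoulder and
elbow acting in the vertical plane selected by the base azimuth. The default
link constants are $a_0 = 22$, $a_1 = 15$, $a_2 = 13$, $a_3 = 15$ cm. All
world lengths in the package are centimetres, so the planner's squared-error
threshold of 0.1 cm² is dimensionally direct; configuration keys suffixed
`_mm` are converted at the boundary. The hardware being modelled quotes its
link lengths only per physical segment, and the exact assignment of segment
lengths to DH constants is a modelling choice; all four constants are
configurable in `arm_geometry()`.

Joint limits default to a 270° span per joint — the travel of the modelled
servos — centred on the home pose $(\pi/2, 0, 0)$.

Inverse kinematics is solved in closed form: the base azimuth is
$\mathrm{atan2}(y, x)$ and the remaining two joints solve the planar
two-link problem in the radial–vertical plane, giving an elbow-up
($\theta_3 \le 0$) and an elbow-down branch. A published analytic solution
for this arm family exists but mixes axis conventions and, in one step,
equates an angle to a length; rather than guess its intent the solver here
is re-derived from the forward kinematics and accepted purely through the
round-trip property $FK(IK(p)) = p$, which the test suite enforces to
1 nm-scale tolerance (1e-9 cm) over a thousand random targets on both
branches. Elbow-up is the default branch so the end effector approaches the
table from above. Because joint limits can exclude the principal-azimuth
solution while admitting the wrapped one (base rotated by $\pi$ with a
negative radial extension), reachability enumerates both azimuth families
and both elbow branches; `is_reachable()` reports `"outside reach"` when the
two-link annulus condition fails and `"joint limits"` when solutions exist
but all violate the limits.

## The gradient-descent planner

The planner minimises the summed squared coordinate error
$\epsilon(\theta) = \lVert p_\mathrm{target} - FK(\theta)\rVert^2$ by plain
gradient descent from the home pose. The gradient is analytic
($\nabla\epsilon = -2 J^\top r$ with $J$ the forward-kinematics Jacobian and
$r$ the residual); the test suite pins it to central finite differences at
1e-6 relative error. One published form of these gradient expressions
carries a sign/factor inconsistency relative to its own update equations;
the update equations — which add $2\eta\, r^\top \partial P/\partial\theta_i$
to each angle — are the internally consistent pair, and the implementation
reproduces them literally (a unit test checks the symbolic form
term-by-term).

Parameters (`gd_config()`): learning rate $\eta = 0.001$ per iteration,
shared by all joints; convergence threshold 0.1 cm²; iteration cap 100 000
(the reference procedure states no cap, so non-convergence is an explicit
status, never silent); servo quantum 0.063 rad; approach clearance 5 cm.
The quantum is kept at the printed 0.063 rad even though the quoted "50
pulses per revolution" resolution would imply $2\pi/50 \approx 0.126$ rad;
it is configurable. Angles are clamped to the joint limits during descent,
with a warning — the underlying controller is silent on this case, and
clamping (projected descent) is the conservative choice.

Convergence behaviour depends on the target set. Descent at $\eta = 0.001$
is provably stable only while the local curvature $2\lVert J\rVert^2$ stays
below $2/\eta$; near the stretched-arm rim of the tabletop annulus (radius
$\approx 32.3$ cm at table height for the default geometry) the problem
becomes singular and the iteration can oscillate. The utilized work region
therefore matters: `sample_reach_targets()` draws targets with radius in
[8, 30] cm, a margin inside the rim chosen because no object of practical
footprint can have its centroid at full stretch and the safe approach needs
headroom above the target. Inside that region the suite verifies, for 100
sampled targets, monotone non-increasing SSE and convergence below
0.1 cm², with 26–60 iterations typical.

The servo-readout model is a per-joint latch: the read angle jumps to the
written angle only when they differ by at least one quantum, which yields
the stepped read-vs-written traces characteristic of coarse servo
potentiometers and bounds the final written/read gap by one quantum. The
total positional error of a completed plan is reported as
`sse_threshold + ||FK(written) - FK(read)||²`; the reference formulation of
this bound mixes a squared threshold with a positional term, and the
squared-distance reading (both terms cm²) is the interpretation implemented
here. A mismatch beyond 0.1 rad on any joint raises the `"servo fault"`
state, strict inequality at the boundary.

The safe approach plans in two phases — to a hover point one clearance
above the target, then down onto it — and emits the descent commands with
the elbow (J3) ahead of the shoulder (J2), so the end effector comes down
from above instead of sweeping across the table.

## Perception

All targets lie in one plane, so the pixel-to-world map is a planar
homography rather than a full pose estimate: a normalized DLT (Hartley
normalization of both point sets, SVD null vector, residual reported as RMS
reprojection in pixels) from at least four non-collinear marker-corner
correspondences. Pixels are 0-based with the origin at the top-left, x
right and y down. Marker validity follows the device rule — at least three
of the four markers visible and the base marker among them — and failures
carry the device's user-facing message verbatim, since the pipeline treats
that string as an abort signal. Detections enter as plain
class/bounding-box records; the z of a reach target is the configured
object height (default 0, the tabletop), as the detector itself provides no
height information.

## Trigger classification

Band-power features behave like threshold detectors, so the weak-learner
baseline is an exhaustive single-feature threshold sweep over a quantile
grid (resolution 1/200 by default; the grid is a package choice) covering
`above`, `below` and closed-interval `band` rules, with deterministic
tie-breaks (smallest lower threshold, then narrowest band). The boosted
model is two-class discrete adaptive boosting with stagewise weights
(SAMME) over depth-limited CART trees, the variant implemented in-package
because the exact boosting flavour of the reference classifier is unstated
and no adaptive-boosting implementation ships with the environment's R
stack; `rpart` supplies the weighted trees. Defaults follow the tuned
reference model: 300 estimators, learning rate 1, depth 7. Per-round stage
errors hover near 0.5 by construction (reweighting), so the monotone
quantity tracked is the classical exponential training bound
$\prod_m 2\sqrt{e_m(1-e_m)}$, non-increasing whenever every stage beats
chance — which the trainer enforces by stopping early otherwise.

The comparison network is a fully connected 160–80–40–1 net with
rectified-linear hidden layers and a sigmoid output, trained for 100 epochs
with batch size 32 on standardized features. Its optimizer and loss are
unstated in the reference description, so the implementation uses binary
cross-entropy with Adam ($10^{-3}$, $\beta = 0.9/0.999$) under a fixed
seed; the suite asserts qualitative properties only (separable data is
separated, outputs lie in [0, 1], identical seeds give identical weights),
never real-data accuracies, which are not reproducible without the original
recordings.

Metrics: accuracy, precision, recall and specificity in percent, F1 as a
fraction computed both as the harmonic mean of precision and recall and
directly from counts, `tp / (tp + (fp + fn)/2)`; the two agree to machine
precision and the suite property-tests that identity over thousands of
random count tuples. Ratios with zero denominators are `NA`, an explicit
undefined marker — returning 0 would silently deflate or inflate scores.
Five-fold cross-validation shuffles once under a seed, partitions the data
so every sample is tested exactly once, and reports per-fold metrics with
mean, standard deviation and coefficient of variation. The 95% bound is
the normal-approximation interval $\mu + 1.96\,\sigma/\sqrt{n}$.

Stream decoding emits a selection at the k-th consecutive positive
prediction and resets after each emission; `k = 3` reproduces the
three-consecutive-labels debounce that trades latency for a lower
false-positive rate, and `k = 1` is the undebounced trigger.

## Synthetic data: what it emulates, and what it does not

`generate_fbp_stream()` emulates the 8-samples-per-second, 160-feature
band-power stream with three empirically motivated feature behaviours:

* **Pattern 1** (16 features): an extreme upper tail that appears almost
  exclusively during clench samples, but with partial penetrance — a
  single-feature rule on such a feature produces near-zero false positives
  yet misses roughly half the clenches. Default penetrance 0.38, which
  places the best single-feature accuracy near 70%, the top of the observed
  weak-learner range.
* **Pattern 2** (132 features): overlapping state-conditional distributions
  with a weak multiplicative shift under clench.
* **Pattern 3** (12 features): clench values concentrated in a narrow,
  low-density band.

Band powers are log-normal (non-negative and right-skewed, the standard
shape for spectral power). Crucially, features are *not* conditionally
independent: a per-sample clench intensity scales all responses, pattern-1
and pattern-3 events co-occur across features through a shared latent (its
weight exactly preserves each feature's marginal event rate via the
trapezoidal CDF of the latent mixture), and pattern-2 features share a
common log-noise component. Concurrent band powers of a single muscle
artifact are strongly correlated in reality, and without this redundancy a
boosted ensemble over 160 conditionally independent weak features would be
nearly perfect — an artefact, not a property of the method. With the
defaults the best single feature lands in the low/high-60s to 70% and the
default ensemble reaches the low 80s under five-fold CV, a gain comfortably
above the eight-point margin the acceptance suite requires and of the same
shape as the reference system's weak-learner-to-ensemble improvement.

What the generator does **not** emulate: raw EEG time series, real spectral
estimation, volume conduction, electrode drift, inter-session and
inter-subject variability, or the true (unpublished) joint distribution of
the 160 features. Passing tests on this data demonstrate that the
algorithms are implemented correctly and behave as designed under the
stated statistical structure — not that the reported real-data accuracies
would be reproduced on new recordings.

Scenes project marker corners and object footprints through a known
world-to-pixel map with optional i.i.d. pixel noise. The default map is
affine (10 px/cm with mild shear): under an affine map the centroid of a
projected square footprint coincides with the projection of the object's
centre, which makes the zero-noise recovery oracle exact (< 1e-6 cm);
projective maps are supported and are what the homography-recovery tests
use. Session timelines dictate one summary statement plus one numbered
statement per object at 200 words per minute with 1500 ms gaps; the user's
reaction time is normal with mean 0.756 s and SD 0.14 s, truncated at zero
(resampled, not clipped, so the density at zero is not inflated); the
1.5 s selection window is evaluated as a flag, never imposed on the
sampler. Object counts are drawn uniformly from five to eight.

## The simulated trial and its accounting

`run_trial()` validates markers (aborting with the recalibration message if
the rule fails), fits the homography from the visible marker corners,
prompts the detected objects, lays a labeled clench burst (default 0.75 s)
at the session's reaction-time offset, decodes the stream, and classifies
the trial: a decoded event inside the target statement's window (statement
onset to next statement onset) is a true positive; with no true clench, any
decode is a false positive and silence a true negative; a clench with no
in-window decode is a false negative. The reference validation reports
trial-level counts only, so this event-alignment rule is the package's own
(documented) choice. Selected targets are mapped to world coordinates,
assigned a work zone, and planned; the final written/read mismatch is run
through the servo-fault check.

The latency ledger is exact left-to-right summation of named per-activity
latencies; prompting and actuation latencies are injected parameters, not
wall-clock measurements, so reproducing a published latency table is an
arithmetic exercise by design. Usability scoring implements the standard
System Usability Scale arithmetic (odd items `response - 1`, even items
`5 - response`, total × 2.5) and the NASA-TLX scaled average. The TLX
scorer consumes already-scaled 0–100 subscale values rather than raw
21-point responses, because the reference scaling of raw scores is not a
consistent multiple.

The emergency override is a latched halt flag checked at every simulated
actuation step: any override signal stops execution within one step and
stays latched until an explicit reset, mirroring a panic key.

## Problem sizes and determinism

The test and acceptance runs use: 1000 random angle triples for the
forward-kinematics/transform-chain and IK round-trip identities, 500 random
states for the gradient check, 100 sampled reach targets for the
convergence study, a 1500-sample stream for the classifier study (all 160
features swept, then the default 300-tree ensemble under five-fold CV), and
1000 sessions for the reaction-time law. These sizes keep the full suite
and the acceptance script within a few minutes on one CPU while leaving the
statistical assertions comfortably powered. Every stochastic component is a
pure function of its configuration and seed; the acceptance script derives
all its seeds from a single `--seed` argument.

## Known limitations

* No dynamics: the arm model is kinematic; torque, payload, backlash and
  actuation timing are out of scope, so "actuation time" exists only as an
  injected ledger entry.
* The planner is first-order: no line search or momentum. That is faithful
  to the method being modelled, but it also means behaviour near the
  workspace rim is genuinely oscillatory rather than an implementation
  artefact; the utilized-region margin is the honest fix.
* Lens distortion and full camera pose are not modelled; the homography
  path assumes an undistorted planar view.
* The synthetic stream is stationary; real use would face drift and
  artifact confounds that the classifier stack has not been evaluated
  against.
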