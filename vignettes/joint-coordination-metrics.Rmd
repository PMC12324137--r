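---
title: "Quantifying changes in inter-joint coordination with JcvPCA and JsvCRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying changes in inter-joint coordination with JcvPCA and JsvCRP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointcoord)
```

## The problem

Inter-joint coordination — how several joints share and time their rotations
during a movement — changes with motor learning, pathology, and the use of
assistive devices such as exoskeletons. Comparing two sets of repeated
movements ("did the coordination strategy change, and how?") is hard because
the change has both a *spatial* side (which joints contribute how much) and a
*temporal* side (how joint rotations are synchronized), and because the
standard tools (PCA on joint trajectories, continuous relative phase) do not
by themselves produce a comparable, physiologically readable number.

`jointcoord` implements two complementary change metrics:

* **JcvPCA** (joint contribution variation): how much each joint's
  contribution to each principal component changed between a reference and a
  comparison dataset;
* **JsvCRP** (joint synchronization variation): the area between the two
  datasets' mean continuous-relative-phase curves for a joint pair.

Both reduce a change in coordination to a small set of signed (JcvPCA) or
non-negative (JsvCRP) numbers that can be compared against a
natural-variability threshold estimated from the reference condition itself.

## JcvPCA

Let dataset A (reference) and dataset B (comparison) each hold repetitions
of the same task over the same `n` joints; repetitions may differ in length
and count, and timing is ignored. The pipeline, for `m` retained components:

1. center each dataset to zero per joint (grand mean over all samples of all
   repetitions pooled — the same mean the PCA sees; this removes small
   starting-posture offsets). No amplitude scaling is applied, so strongly
   moving joints keep their weight and noise on quiet joints is not
   amplified;
2. PCA of A's concatenated samples: an orthonormal frame `R_A` whose rows
   `a_u` are components over joints;
3. project B's samples into `R_A` and run PCA again, giving rows `c_u` over
   the PC coordinates;
4. compose back to joint space, `b_u = c_u R_A` (the **joint reprojection
   weights**, JRW), and subtract absolute weights:
   `delta[u, i] = |b[u, i]| - |a[u, i]|`;
5. optionally scale each row by A's explained-variance ratio.

Positive entries mean joint `i` does more of the work of component `u` in
the comparison dataset. All entries lie in `[-1, 1]`; identical datasets
give the zero matrix. The first `p` components (task degrees of freedom)
describe functional joint use; trailing components describe redundant
(null-space) coordination, hence the `m = p + 1` default via `task_dof`.

Two properties worth knowing:

* the printed subtraction order in some descriptions of the method is
  `|a| - |b|`; the interpretation "positive = more used in the comparison
  dataset" is the one all reported results follow, and is what this package
  computes;
* with all `m = n` components retained, `c = R_B R_A'` and therefore
  `b = R_B`: the metric reduces to `|R_B| - |R_A|` and is exactly
  antisymmetric in the dataset order. The choice of reference genuinely
  matters only when `m < n`, i.e. when the comparison happens inside a
  retained subspace of the reference frame — the recommended usage.

Numerical choices: the PCA is computed by SVD of the centered sample matrix
(no explicit covariance), variances use `1/(N - 1)`, and each eigenvector
row is sign-flipped so its largest-magnitude coefficient is positive. The
sign convention is irrelevant after the absolute values but makes JRW
tables and the self-projection identity deterministic. A warning (not an
error) is raised when a dataset has fewer than 5 samples per joint, the low
end of the usual variable-to-factor guidance; `pca_stability()` offers a
repetition-level bootstrap check of frame stability.

## CRP and JsvCRP

For each repetition and joint, the angular velocity is estimated by central
differences (second-order one-sided formulas at the endpoints; optional
zero-phase Butterworth low-pass of the angle signal first — see below), and
position and velocity are independently range-normalized onto `[-1, 1]`
(`range_normalize()`: min to -1, max to +1 exactly, per repetition, matching
the per-movement phase-portrait construction). The phase angle is the
quadrant-aware arctangent `atan2(velocity, position)` in `(-pi, pi]`, and
the CRP of a pair is `phi_j - phi_i`.

Sign convention: for oscillatory motion the phase portrait rotates
clockwise, so a joint that is *ahead in time* sits at a *lower* phase
angle; a second joint leading by a constant lag `d` yields a constant CRP
of `-d`. The magnitude, not the sign, enters JsvCRP.

Wrap policy: phases are subtracted wrapped and the difference is re-wrapped
into `(-pi, pi]` (default). `unwrap = TRUE` unwraps each phase over time
first (via `pracma::unwrap`) and skips the re-wrap, preserving accumulated
lead at the cost of sensitivity to wrap detection. The default is used
throughout the package's own analyses.

Each repetition's CRP curve is linearly interpolated onto a fixed grid of
`G = 101` points spanning 0–100% of movement duration, curves are averaged
pointwise over all repetitions (pooling targets), and

```
JsvCRP(A, B) = integral of | meanCRP_B - meanCRP_A |
```

by the trapezoidal rule. The result is 0 exactly when the mean curves
coincide, symmetric in the dataset order, and non-negative. The abscissa is
the percent axis by default (units: angle × percent); `axis = "seconds"`
rescales the progression by the mean repetition duration (units: angle ×
s, the natural choice when both datasets share one duration, as in the
two-sine validation). CRP values are radians internally and are reported in
the dataset's declared angle unit.

Degenerate inputs: a joint whose recorded range of motion is smaller than
the caller-supplied noise band (`noise_ratio_guard()`, ratio of noise range
to range of motion above 1) is replaced by the constant 0 — position,
velocity and phase — and flagged non-contributing, encoding the hypothesis
that it neither synchronizes with nor contributes to the movement. Constant
signals are otherwise rejected rather than silently normalized.

Velocity smoothing: raw finite differences amplify encoder noise
(0.2 deg of white noise at 100 Hz becomes ~14 deg/s of velocity noise,
comparable to the peak velocities of a 2 s reach), which floods the
range-normalized velocity and hence the phase. All of the package's own
reaching analyses therefore pass `smooth = TRUE, cutoff_hz = 5` (zero-phase
2nd-order Butterworth; a 2 s minimum-jerk reach has essentially no content
above ~2 Hz) together with `noise_range = 2` deg (about the 6-sigma
peak-to-peak band of the simulated encoder noise). Smoothing is off by
default at the function level so that clean or pre-filtered data are not
touched twice.

## Natural-variability thresholds

Human repetitions of the same movement differ ("repetition without
repetition"), so a nonzero metric value does not by itself demonstrate a
change of strategy. `natural_variability()` shuffles the baseline
condition's repetitions and splits them in two (reference half
`ceiling(k/2)`, without replacement, independently per iteration), computes
the metric between the halves, and aggregates per-entry mean, SD and
standard error (`SD / sqrt(n_splits)`) over `n_splits = 15` iterations by
default. `exceeds_threshold()` then flags metric entries outside
`mean ± SE` (or `± SD`). The split-half procedure is fully reproducible
from its seed. Whether a published dispersion is an SD or an SE is often
ambiguous; both are reported so the caller can pick the rule.

## The synthetic generators

Two generators reproduce the package's validation conditions without any
recorded data.

**Two-sine pair** (`make_sine_datasets()`): `theta1 = sin(2 pi t)` in both
datasets; `theta2` has twice the amplitude and a phase shift of 1 rad
(dataset A) vs `pi/2` rad (dataset B). Defaults: 1 Hz, 5 s (whole periods),
100 Hz sampling, no noise. Analytically, A's covariance is
`[[0.5, cos 1], [cos 1, 2]]` (eigenvalues 2.1743 / 0.3257) and B's joints
are uncorrelated, so B's leading component is `theta2` alone: the PC1
contribution of `theta1` drops sharply (about -0.31 for whole-period
sampling) while `theta2` rises slightly (about +0.05). The CRP of each
dataset is the constant wrapped lag, so the JsvCRP area on the seconds axis
is `|pi/2 - 1| x duration`. The exact sampling grid of the movement (how
many periods, whether partial) changes the decimal values — only the sign
pattern is sampling-invariant, and that is what the tests pin down.

**Two-link reaching simulator** (`make_reaching_dataset()`,
`simulate_experiment()`): a planar shoulder–elbow arm (segment lengths
0.30 / 0.28 m) reaching three target heights (-0.15, 0, +0.15 m relative to
the shoulder, chosen to demand distinct joint excursions), 5 repetitions
per target, starting with the arm hanging and the elbow flexed at 140 deg.
Each repetition follows a minimum-jerk progression (any smooth sigmoid
would do; this is a documented knob, not a claim about motor control) from
a jittered start posture (SD 1 deg) to a posture that reaches the target
exactly under the strategy's joint allocation, plus 0.2 deg of white
measurement noise and ~0.1 s of duration jitter; sampling at 100 Hz keeps
the test suite fast while oversampling the movement content by an order of
magnitude. Four strategies:

* *physiological* — simultaneous proximal-weighted sharing: elbow excursion
  = 0.54 × shoulder excursion (set so that the baseline's PC1 joint weights
  reproduce the proximal-to-distal pattern reported for unconstrained
  reaching, ≈ (0.88, 0.47)), with a 10% elbow onset lag;
* *desync* — identical amplitudes but sequential timing: the shoulder
  completes by 45% of the movement, the elbow starts at 55%;
* *shoulder_only* — the elbow holds its start angle (noise only) and the
  shoulder alone solves the target height;
* *elbow_overuse* — the shoulder keeps its physiological profile while the
  elbow first flexes by an extra 15 deg (peak at 40% of the movement) and
  then extends to the target angle.

What the simulator emulates: the geometry, the task, the strategy
definitions, encoder-like noise, and trial-to-trial jitter. What it does
not: human neuromotor variability structure (signal-dependent noise,
corrective submovements, fatigue), real exoskeleton dynamics, or the
idiosyncrasies of one participant's execution. Passing tests therefore show
that the metrics *separate and sign the strategy differences as designed*
on data with known ground truth — not that any particular decimal value
from a human recording will be reproduced.

## What the checks compute

The test suite validates every operation against independent oracles
(closed-form 2×2 eigendecompositions, analytic sinusoid covariances, a
generic planar-chain forward-kinematics oracle, high-resolution Riemann
sums) and asserts the qualitative validation picture on simulator output:
the contribution signs per strategy, threshold exceedance of all three
altered strategies, and the separation ordering

```
shoulder_only > desync > elbow_overuse >> within-condition baseline
```

for JsvCRP, with `shoulder_only` showing the largest absolute elbow
contribution change for JcvPCA. `scripts/acceptance.R` recomputes the
headline numbers (sine deltas and area, per-strategy JcvPCA percentages and
JsvCRP areas, natural-variability thresholds) from scratch at a given seed.
Problem sizes used there: 501 samples per sine dataset, 15 repetitions per
reaching condition, 15 split-halves for the thresholds.

## Worked example

```{r example, eval = FALSE}
library(jointcoord)

sims <- simulate_experiment(arm_spec(), seed = 1)
phys <- sims$physiological

# spatial change: which joint contributes more/less?
jcvpca(phys, sims$shoulder_only, task_dof = 1)

# temporal change: how different is the lead-lag pattern?
jsvcrp(phys, sims$desync, noise_range = 2, smooth = TRUE, cutoff_hz = 5)

# is it beyond natural variability?
nv <- natural_variability(phys, "jcvpca", n_splits = 15, seed = 2)
exceeds_threshold(jcvpca(phys, sims$shoulder_only)$delta, nv)
```

## Known limitations

* JcvPCA monitors *evolutions* of a strategy; if two strategies are
  entirely unrelated, the reprojection step can hide information that a
  direct PCA-to-PCA comparison would show. Such direct comparison is out of
  scope here.
* CRP assumes roughly oscillatory, noise-resolvable joint excursions;
  Hilbert-transform phase extraction and curve-registration alignment are
  deliberate non-goals, as is DTW-based time alignment beyond the linear
  0–100% normalization.
* Areas on the percent axis are only comparable between analyses using the
  same grid and wrap policy; both are therefore fixed defaults (`G = 101`,
  wrapped subtraction).
* Thresholds from 15 split-halves of 15 repetitions are coarse; they bound
  single-subject natural variability, not population variability.
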