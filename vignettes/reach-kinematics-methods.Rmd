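---
title: "Methods: from mirror-view keypoint tracks to reach kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mirror-view keypoint tracks to reach kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

## The measurement problem

In the single-pellet reach-to-grasp task a food-restricted mouse reaches
through a narrow slit with one forepaw to retrieve a ~2 mm sugar pellet
resting 7 mm beyond the slit. A single high-speed camera (100 Hz) films the
scene frontally; two tilted mirrors flanking the box add side views within
the same video frame, so a single unsynchronized camera yields the three
projections needed for 3D reconstruction. A markerless pose tracker supplies,
per view and per frame, image coordinates and a confidence (likelihood) for
each keypoint (palm, fingers, snout, pellet). `reachkin` turns those 2D
tracks into calibrated 3D trajectories in millimetres, segments them into
individual reaches, scores each reach kinematically and behaviorally, and
aggregates session-level learning metrics.

## Camera model and mirror geometry

Each view is a pinhole camera: a `3x4` projection matrix $P$ mapping world
millimetres to pixels. The key modeling decision is that a **mirror view is a
reflected virtual camera**: if $H$ is the `4x4` reflection about the mirror
plane, the virtual camera is $P H$. Decomposed as $K[R\,|\,t]$, such a camera
has $\det R = -1$, which the `mirrored` flag records. The payoff is that
triangulation needs no special casing — the reflection lives inside $P$.

Calibration uses the direct linear transform (DLT): each 3D–2D
correspondence contributes two rows to a homogeneous linear system whose
least-squares solution (smallest right singular vector) is $P$. Both point
sets are Hartley-normalized first (centroid at the origin, mean distance
$\sqrt{d}$) — a conditioning step that is standard practice for DLT. The sign
of $P$ is fixed by requiring positive depth for the calibration points, after
which the mirrored flag is read off $\det R$. At least 6 correspondences are
required, and the 3D set must span three dimensions: a single checkerboard
pose is coplanar and therefore degenerate, so the synthetic calibration
fixture places the 4x4-square, 1 mm-pitch board in three orientations. (The
field's usual calibration tools get away with a single waved board because
they bundle-adjust over many frames; that is out of scope here, and the
multi-pose DLT is the transparent, testable equivalent.)

Triangulation is per-frame linear DLT: stack the two rays' constraint rows
from every view where the point is finite, solve by SVD. Frames seen by
fewer than two views become `NA`. A nonlinear per-point refinement
(`triangulate_refine()`, direct minimization of squared pixel reprojection
error) serves as an independent accuracy reference under pixel noise; the
tests require the linear solution's RMSE to agree with it within 10%.

The calibration frame is arbitrary (gauge freedom), so triangulated
trajectories are mapped into the *behavioral frame* — origin at the pellet
rest position, $+x$ forward (slit toward pellet), $+y$ sideward, $+z$ upward
— by a least-squares similarity transform (Umeyama closed form: rotation,
translation, isotropic scale) fitted on at least three non-collinear static
reference points (the slit edges and the pellet rest position; the residual
scale absorbs the calibration gauge). The tests verify that two pipelines
run in different world frames produce identical aligned trajectories, and
that the slit-to-pellet distance comes out at the configured 7 mm.

## Cleaning and segmentation

Cleaning happens in three fixed steps: (1) 2D samples below the likelihood
threshold (default 0.6) are discarded; (2) interior gaps up to 5 frames
(50 ms) are filled by linear interpolation, longer gaps stay missing;
(3) each finite run is smoothed with a Savitzky–Golay filter (window 7
frames, polynomial order 3). The window/order pair is scaled to 100 Hz
sampling: it preserves the ~300 ms reach shape essentially unbiased
(constants and cubics are reproduced exactly) while attenuating tracking
noise enough that third derivatives remain usable. All five parameters are
exposed; the defaults are the package's convention.

The original workflow selects reach windows by hand in a GUI. For
reproducibility `reachkin` replaces this with a deterministic detector on
the forward coordinate $x(t)$ of the palm: local maxima with topographic
prominence of at least 3 mm whose height clears the resting baseline (median
forward position, i.e. the slit plane) by at least 2 mm are accepted as
apices; each window grows outward to the crossings of a hysteresis level at
baseline + 25% of the peak's prominence; windows shorter than 10 frames
(0.1 s) or longer than 200 frames are rejected; overlapping windows merge,
keeping the higher apex (the earlier one on ties). Manually chosen spans can
be supplied as a CSV and flow through the identical downstream path — given
the same windows, the scalar tables are identical. A plateau at the apex
reports its first frame, matching `which.max` on the same window, so
automatic and manual apices coincide.

The paper gives no quantitative criterion for what counts as a full reach
during manual selection; the detector's thresholds above are this package's
operationalization, chosen once for the 100 Hz / millimetre geometry.

## Per-reach kinematics

Derivatives are central differences (one-sided at run edges) of the
*smoothed* trajectory, applied once, twice or three times for velocity,
acceleration and jerk; at 100 Hz raw third differences would be noise-
dominated, which is why differentiation is defined only downstream of the
Savitzky–Golay stage. Per reach, the package reports: duration
(frames/`fs`), the endpoint — the 3D position at the **apex**, the frame of
maximal forward extension, expressed as distance to the pellet per axis
since the origin is the pellet — path length, mean and peak speed, the
relative timing of the speed peak within the window, and peak acceleration
and jerk magnitudes. The endpoint is taken at the apex rather than the
window end because windows deliberately include the retraction. "Peak
position" quantities are reported as maxima of vector magnitudes; full
profiles remain available programmatically via `differentiate()`. Windows
with under 50% finite frames are flagged (`ok = FALSE`) instead of scored.

Time-normalized averages (`average_trajectory()`) resample each reach to a
common length and return per-axis mean ± SD bands — the standard
forward/sideward/upward decomposition of the movement, whose axis-wise
velocity components recompose exactly (in quadrature) into 3D speed.

## Outcome classification

Six outcome categories describe a trial: grasped, missed, flicked, lost,
in-vain, artifact. The original assignment is a human watching video;
`reachkin` provides a deterministic cascade over the paw and pellet
trajectories inside the reach window, with manual labels taking precedence
when supplied:

1. under 50% finite paw frames, or duration outside bounds → **artifact**;
2. pellet missing throughout → **in-vain**;
3. minimum paw–pellet distance above the contact radius (default 2 mm, the
   pellet diameter) → **missed**;
4. contact without co-movement: pellet net displacement ≥ 1 mm → **flicked**,
   otherwise **missed**;
5. co-movement ending outside the mouth zone (5 mm sphere at the slit) →
   **lost**; inside → **grasped**.

*Co-movement* requires a run of ≥ 3 consecutive frames with paw–pellet
distance below the contact radius **during which the pellet itself is
displaced** by at least 1 mm. The displacement clause matters: any touching
reach leaves the decelerating paw hovering within the contact radius of a
still-static pellet for several frames, which a distance-only test would
misread as transport. The flicked/lost boundary (a pellet briefly carried
then dropped) is not precisely defined by human scoring either; this
cascade is the package's convention and the generator encodes the same
semantics, so the two are validated against each other.

Rule (4)'s fall-through (contact, negligible displacement, no transport) is
deliberately scored *missed*: a grazing touch without consequence.

Clustering of reaches (`cluster_reaches()`) standardizes the scalar features
and offers k-means, Ward agglomerative and Gaussian-mixture methods, with
silhouette-based selection of $k \in [2, 6]$ when none is given; results are
deterministic under a seed and invariant to feature scaling.

## Session metrics

From per-paw success/failure counts: total reaches is the sum of the four
counts; the percentage of right-paw reaches is right/total × 100; the
dominant paw is the paw used for **more than** 70% of all reaches (strict
inequality — exactly 70% yields no dominance, and left dominance is the
mirror reading at under 30%); success rate is successful/(successful +
failed); the shaping criterion is ≥ 20 reaches with a determined dominance;
a *learner* is an animal at or above the 30% success threshold (boundary
inclusion is not stated anywhere authoritative; inclusive is this package's
choice). Zero-total sessions report undefined rates and false flags rather
than NaN arithmetic. Learning curves aggregate any session metric across
animals per training day as mean ± SEM (SD/√n), reporting SEM = 0 with a
flag for n = 1 so single-animal cohorts still plot.

These rules are simple enough to check exhaustively: the test suite
enumerates every count vector with total ≤ 30 against an independent
transcription of the quoted definitions.

## The synthetic scene

Real sessions require an animal, a box and a tracker; every stage here is
instead validated against a generator whose defaults encode the physical
task: 100 Hz sampling, pellet at the origin 7 mm from the slit, paw resting
1 mm behind the slit, two 45° mirror planes, a front camera 200 mm away with
a 2000 px focal length, and a world frame deliberately offset from the
behavioral frame (15° rotation, (10, −5, 3) mm translation) so that every
simulated pipeline run must perform the alignment step.

Reaches are **minimum-jerk** trajectories — the quintic
$s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$ — the standard smooth point-to-
point limb-movement model, chosen because it has closed-form derivatives
(peak speed $1.875\,D/T$) against which recovery can be checked exactly.
Out and return phases draw durations from 0.25–0.35 s with a 2-frame dwell
at the target; idle epochs of 0.5–1.2 s with 0.02 mm positional jitter
separate reaches. Pellet dynamics implement the six outcome semantics
(transport to the mouth, mid-retraction drop at a spot far from the mouth,
a 2-frame knock-off, a 3 mm sideways miss offset, an absent pellet, a
60%-missing paw track). The default outcome mix (grasped .35, missed .25,
flicked .15, lost .15, in-vain .10) puts the success rate inside the 30–40%
band reported for trained animals; artifacts are generated only on request
since they emulate tracking failure rather than behavior. Tracking
likelihoods are bimodal (high > 0.9, dropped < 0.5) rather than calibrated
to any particular tracker — only the thresholding behavior matters
downstream.

What the generator does *not* emulate: lens distortion, correlated tracker
errors (noise is i.i.d. Gaussian in pixels or millimetres), paw-shape
deformation during grasping, finger articulation, and reach-to-reach
kinematic variability beyond duration/amplitude jitter. Passing tests
therefore demonstrate the correctness of the geometry, segmentation, scoring
and counting machinery under realistic magnitudes — not robustness to every
failure mode of a real tracker.

## Numerical choices and problem sizes

Homogeneous systems are solved by SVD throughout; RQ decomposition fixes
intrinsic signs so the mirrored flag is well defined; cheirality (median
positive depth) resolves the DLT sign ambiguity. Equality of cameras is
always up to projective scale (matrices compared after Frobenius
normalization). Calibration files round-trip at 17 significant digits.
Degenerate inputs fail loudly: coplanar calibration sets, collinear
reference points, overlapping manual spans, unknown outcome labels,
decreasing sensor-log frame numbers.

The test-suite problem sizes — sessions of up to a dozen reaches, 50-seed
recovery ensembles, 20-seed session sweeps, 100-seed calibration noise
sweeps, exhaustive count enumeration to total 30 — were chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error
comfortably below the tolerances being asserted.

## Known limitations

- On-disk dialects are CSV and the restricted calibration TOML; the HDF5
  dialect named in the track-table interface is recognised but not
  implemented in this build.
- No lens-distortion model; the pinhole assumption is exact only for the
  synthetic scene.
- Movement phases (reaching, pronation, grasp, retraction) and per-digit
  aperture are not parsed; the palm keypoint drives segmentation and
  scoring.
- The learner flag is per-session; whether an animal "is" a learner on its
  final day or on any day is left to the caller aggregating sessions.
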