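---
title: "Floating-center glenohumeral kinematics: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating-center glenohumeral kinematics: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghfloat)
```

## The problem

The glenohumeral (GH) joint is well approximated by a ball-and-socket
joint, but its centre is not fixed relative to the trunk: as the humerus
elevates, the shoulder girdle (clavicle and scapula) carries the joint
centre through a path of several centimetres. An upper-limb model that
treats the GH joint as a fixed spherical joint therefore misplaces the
elbow progressively with elevation — a practical problem for
rehabilitation-robot and exoskeleton design, where residual interface
loads scale with such model error.

`ghfloat` models the shoulder complex as a *generalized GH joint with
floating centre*: a spherical joint whose centre translates in the
thorax frame as a deterministic function of the humeral elevation angle
θ. The package provides the full chain needed to estimate that coupling
from optical motion-capture data and to use it in a forward model:

1. thorax anatomical frame from the C7, T8, IJ, PX markers;
2. GH-centre estimation from dual rigid marker clusters (scapula and
   humerus) by an invariance regression;
3. elevation kinematics (θ, elevation plane η, axial rotation ψ) and
   ISB-to-anatomical Euler conversion;
4. phase segmentation, cross-trial averaging and coupling-model fitting;
5. a Klopčar-style shoulder-girdle reference model for comparison;
6. a synthetic motion-capture generator with full ground truth.

## The invariance regression

The scapula and humerus each carry a rigid 4-marker block; three visible
noncollinear markers \(P_1, P_2, P_3\) per block define an affine basis

\[
q_1 = P_1 - P_2,\quad q_2 = P_1 - P_3,\quad q_3 = q_1 \times q_2,
\quad q_4 = P_1 .
\]

Because the GH centre is (to the rigid-body approximation) fixed in both
cluster frames, there are constant local coordinates \((a,b,c)\) and
\((d,e,f)\) with, at every time \(K\),

\[
J^K = q_4^K + a\,q_1^K + b\,q_2^K + c\,q_3^K
    = q_8^K + d\,q_5^K + e\,q_6^K + f\,q_7^K ,
\]

where \(q_5,\dots,q_8\) are the humerus-block analogues. Equating the
two expressions gives three linear equations per frame in the six
unknowns,

\[
[\,q_1\;q_2\;q_3\;-q_5\;-q_6\;-q_7\,]\,(a,b,c,d,e,f)^\top = q_8 - q_4 ,
\]

stacked over frames into \(AX = B\). Note the negated humerus columns:
without them the recovered \((d,e,f)\) would be sign-flipped local
coordinates. `solve_center_regression()` solves the stack by SVD-based
least squares; on well-conditioned systems this matches the textbook
normal-equations solution \((A^\top A)^{-1}A^\top B\) to better than
1e-8 relative (tested), while degrading gracefully near rank
deficiency, where it reports the offending singular value instead of
amplifying it.

The final centre is the midpoint of the scapula-side and humerus-side
reconstructions; their per-frame disagreement is kept as a quality
metric (it is identically zero on noise-free rigid data).

### Identifiability

The regression is identified only by *relative rotation* between the two
clusters. Two practically important degeneracies:

* **Common rotation axis.** If both segments rotate about the same
  spatial axis throughout a trial, the centre is unidentifiable along
  that axis. With the generator's default scapular program (rotation
  about the thorax x axis), a single trial in the 90° elevation plane is
  exactly singular, because the humeral elevation axis
  \(R_z(90°)\,y = -x\) then coincides with the scapular axis. This is
  why the analysis pools all of a subject's trials (all elevation
  planes) into one regression — mirroring the study protocol — rather
  than fitting per trial. A per-trial mode exists but inherits the
  degeneracy.
* **Consistent triples.** Pooled frames share one parameter vector, so
  every pooled trial must use the *same* marker triples. With square
  marker blocks all four triples tie in area and measurement noise
  would otherwise flip the per-trial max-area choice (silently changing
  the meaning of \((a,b,c)\)); `analyze_cohort()` therefore fixes the
  triples on each subject's first trial.

## Thorax frame and angles

The thorax frame follows the ISB convention: x lateral from the cross
product of IJ−PX and C7−PX, z cranial along the mid-sternum line, y
anterior completing the triad, origin at IJ. As printed, that
construction is not exactly orthonormal on noisy markers; we keep z as
the primary axis, set \(y = z \times x_{raw}\), then
\(x = y \times z\), and record the tilt applied to x as a `skew_deg`
diagnostic. The frame is rebuilt every frame, so trunk sway does not
leak into the GH-centre path.

Elevation is measured from the hanging posture:
\(\theta = \arccos\big(D\cdot(-z_t)/\lVert D\rVert\big)\), where
\(D = \tfrac12(EL + EM) - J\) is the GH-centre-to-elbow-midpoint axis
(0° hanging, 90° horizontal, 180° overhead). The elevation plane is
\(\eta = \operatorname{atan2}(D\cdot y_t,\, D\cdot x_t)\): 0° is
frontal-plane abduction, 90° forward flexion; it is flagged undefined
below 5° of elevation, where the projection degenerates. The humeral
orientation composes as \(R_z(\eta)R_y(-\theta)R_z(\psi)\) and converts
to anatomical abduction/flexion/rotation angles by decomposing the same
matrix as \(R_y(\alpha)R_x(\beta)R_z(\gamma)\); near gimbal lock
(\(|\beta| \to 90°\)) the canonical γ = 0 solution is returned with a
flag.

## Coupling models and normalization

Per trial, the centre displacement
\(\Delta J^K = J^K - J^{1}\) (reference = first usable frame, the
natural hanging posture in raising trials) is divided by
\(d_0 = \lVert J^{1} \rVert\), the IJ-to-centre distance at rest — the
thorax origin is IJ, so this is a pure per-subject scale normalization.
The resulting dimensionless *magnification ratios* \((x, y, z)\) are
expressed as functions of θ, split into raising and lowering phases at
the global elevation maximum (lowering re-indexed over increasing θ),
interpolated onto a common grid, averaged across subjects, planes and
repetitions without weighting, and fitted per axis.

**Intercept identifiability.** Any constant offset of the GH path
cancels in \(\Delta J\), so a displacement pipeline referenced to the
hanging posture cannot identify a coupling curve's intercept — only its
shape. Recovery checks therefore compare the degree ≥ 1 coefficients
(and require the fitted constant-removed curve to vanish at the
reference); the packaged models carry the intercepts printed with them,
which reflect the original cohort's averaging, not a quantity this
pipeline can re-estimate.

**Model selection.** Candidate polynomial degrees (default 2–5) are
scored by SSE, RMSE (n−p degrees of freedom, curve-fitting-toolbox
convention; plain √(SSE/n) by flag), R² and adjusted R², with
acceptance thresholds 0.995 / 0.005. The lowest degree meeting all four
is selected; if none passes, the RMSE minimizer is used, since real
mean curves routinely miss the thresholds narrowly. A caveat worth
stating: on *exact* samples of the packaged cubics, a quadratic already
meets these thresholds (the cubic term contributes only a few times
1e-3 RMS over 0–150°), so threshold-based selection and coefficient
recovery are distinct questions — the test-suite checks selection on
data where the rule discriminates and checks recovery at the known
generator order.

**Rational fits.** The comparative four-plane ("CAK") model's y axis is
a quadratic-over-quadratic rational curve. `fit_rational_model()` fits
\((n_2\theta^2+n_1\theta+n_0)/(\theta^2+d_1\theta+d_0)\) (monic
denominator for identifiability) by damped Levenberg–Marquardt from a
linearized initialization, with a flat-denominator fallback start
(the monic form only reaches polynomials in the limit
\(d_0 \to \infty\), where the linearized system is ill-posed). Fits
whose denominator has a real root inside the data range are rejected.

## The Klopčar reference model

For external comparison the package ships the piecewise-linear girdle
model: elevation/depression \(\phi_{ed}\) (0 up to 30°, then
\(0.36\phi - 10.8°\)), protraction/retraction \(\phi_{pr}\) (0 up to
70°, then \(-0.22\phi + 15.4°\)), and a girdle-length scale
\(1 + 3{\times}10^{-4}\phi - 1.6{\times}10^{-5}\phi^k\). The printed
source is ambiguous about the exponent \(k\); both the literal linear
reading (default) and a quadratic reading are implemented behind
`exponent_reading`, and the discrepancy is surfaced rather than
silently resolved. Displacements are scaled by the 0.75
sternum-to-girdle factor and compared on the dimensionless ratio scale
after constant removal, where all curves vanish at zero elevation.

```{r klopcar}
cmp <- compare_models(builtin_coupling_model("raising"), klopcar_model(),
                      grid = seq(0, 150, by = 1))
round(cmp$max_abs_gap, 3)
```

## The synthetic generator

Real recordings for this protocol are not publicly available, so the
generator is a first-class module that emulates the study conditions:
12 subjects, 16 guided elevation planes (0°–135°), 3 repetitions,
raising / lowering / raising-and-lowering phases, 50 Hz sampling,
elevation 0°–150°, and additive marker noise up to the ~4.2 mm scale of
reported acromion skin slippage. Its defaults are the study conditions;
quantities the protocol does not state were chosen once on anatomical
grounds:

* rest GH centre (165, −25, −35) mm in the thorax frame
  (d0 ≈ 170 mm, within the plausible 120–220 mm IJ-to-GH range for the
  cohort's stature);
* arm length 551.5 mm (the cohort mean), humerus share 0.53;
* 40 mm square marker blocks, epicondyle markers ±30 mm about the elbow
  midpoint;
* scapular rotation ramping 0→30° over the elevation range — the order
  of magnitude implied by the ≈1.7:1 glenohumeral-to-scapulothoracic
  rhythm — about the thorax x axis (configurable; it exists to make the
  regression well-posed, since the protocol records rather than models
  scapular motion);
* smooth cosine elevation ramps, so endpoint rates vanish;
* i.i.d. isotropic Gaussian marker noise by default, with an AR(1) mode
  (coefficient 0.98) to emulate slow soft-tissue drift;
* per-subject geometry jitter of ~3% on the rest centre and arm length.

The generator animates the GH centre by the built-in raising/lowering
coupling models (constant-removed, so the path starts at the rest
centre) and keeps the centre rigidly attached to both marker blocks by
construction; on raising-and-lowering trials each leg uses its own
phase's coupling, joined continuously at the 150° peak. What it does
*not* emulate: genuinely deforming soft tissue (markers stay exactly
rigid up to additive noise), subject-specific scapulohumeral rhythm
nonlinearity, trunk sway, and elevation-dependent marker occlusion
patterns (dropouts are Bernoulli). Passing recovery tests therefore
demonstrate correctness of the estimator chain under the stated noise
model, not robustness to every artifact of real skin-marker data.

## Numerical choices

* Collinearity: marker triples with triangle area below 1 mm² are
  rejected; triple selection maximizes area with a lexicographic
  tie-break, so bases are reproducible.
* Rank: singular values below 1e-8 of the largest declare the
  regression unidentifiable, with the offending value reported.
* d0 below 50 mm is rejected as implausible geometry.
* Elevation angles within 1e-6° of the 0–150° bounds are clamped, not
  dropped (the arccos round-trip can overshoot by ~1e-12°); curve
  resampling allows constant extrapolation only within the 1e-9°
  coverage slack.
* Polynomial fits are computed on θ/150 for conditioning and rescaled
  exactly; zero-variance responses define R² = 0.
* Degenerate phase segments (fewer than two in-range points after
  clipping, as happens when noisy θ estimates spike past 150°) are
  dropped rather than fatal.

## Problem sizes used by the test-suite

The shipped tests exercise the full protocol shape — 12 subjects × 16
planes × 3 repetitions — with 75-frame (1.5 s at 50 Hz) trials, and
five replicate cohorts at σ = 2 mm for the Monte-Carlo bounds; these
sizes were chosen so the whole suite runs in about a minute while
keeping every per-subject regression far above its identifiability
threshold (3600 pooled frames per subject against 6 unknowns).

## Known limitations

* The C3D container is recognised but not parsed; trials are exchanged
  through a lossless CSV dialect documented in
  `read_marker_trajectories()`.
* Left-arm (mirrored) data is not validated; all conventions are
  right-arm.
* The pipeline estimates coupling against elevation only; dependence of
  the GH path on the elevation *plane* is averaged over, as in the
  source protocol.
* Coupling intercepts are not identifiable from displacement data (see
  above); consumers of fitted models should use them constant-removed,
  as `forward_elbow_position()` does.
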