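---
title: "Greedy LDDMM registration and multi-atlas segmentation: methods and design"
author: "lddmmseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy LDDMM registration and multi-atlas segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lddmmseg)
```

## The model

Given an atlas intensity image $I_0$ and a target $I_1$, both functions on
the unit cube $\Omega = [0,1]^d$ ($d = 2$ or $3$), large deformation
diffeomorphic metric mapping (LDDMM) estimates a time-dependent velocity
field $v_t$, $t \in [0,1]$, whose flow
$\dot\phi_t = v_t(\phi_t)$, $\phi_0 = \mathrm{Id}$, deforms the atlas onto
the target. The velocity is found by minimizing

$$E(v) = \int_0^1 \lVert L v_t \rVert_{L^2}^2 \, dt
       + \frac{1}{\sigma^2} \lVert I_0 \circ \phi_1^{-1} - I_1
         \rVert_{L^2}^2 ,$$

with the differential operator $L = -\alpha \nabla^2 + \gamma\,
\mathrm{Id}$. Because the minimizing velocity lives in the smooth
reproducing-kernel space induced by $L$, the resulting map is a
diffeomorphism: smooth, invertible, topology-preserving. We certify this
numerically by requiring a strictly positive Jacobian determinant of
$\phi^{-1}$ at every voxel, and the test suite asserts it after every
registration.

The greedy optimizer updates each timestep's velocity by steepest descent,

$$v_t \leftarrow v_t - \varepsilon \nabla_{v_t} E, \qquad
\nabla_{v_t} E = 2 v_t - K\!\left(\frac{2}{\sigma^2}
  \lvert D\phi_{t,1} \rvert \, (J_t^0 - J_t^1)\, \nabla J_t^0\right),$$

where $\phi_{s,t} = \phi_t \circ \phi_s^{-1}$,
$J_t^0 = I_0 \circ \phi_{t,0}$, $J_t^1 = I_1 \circ \phi_{t,1}$ and
$K = (L^\dagger L)^{-1}$ is the smoothing kernel, applied in the Fourier
domain. The mismatch factor is $2/\sigma^2$, consistent with
differentiating the $1/\sigma^2$-weighted image term. This is the greedy
per-timestep scheme, not geodesic shooting: no initial-momentum encoding
or metric distance is computed, which is out of scope here.

## Discretization choices

**Grid and coordinates.** Voxel $i$ (0-based) along an axis with $N$
voxels sits at $(i + 0.5)/N$, so the domain is exactly the unit cube at
any resolution and all maps are stored as displacements in domain units.
Intensity images deform by multilinear interpolation, integer label
charts by nearest-neighbor lookup (labels are never interpolated, so the
label alphabet is preserved). Out-of-domain samples clamp to the
boundary: the phantoms carry a uniform background, so clamping is benign
and avoids the wrap-around the periodic kernel would otherwise imply.

**The kernel.** The Laplacian in $L$ is the periodic second-difference
stencil, whose DFT symbol along one axis is
$2(1 - \cos(2\pi k/N))/h^2$. With that choice $L$ is real, diagonal in
frequency and self-adjoint, so $L^\dagger L = L^2$ and the kernel
multiplier is $A(\omega)^{-2}$ with
$A(\omega) = \gamma + \alpha \sum_d 2(1 - \cos(2\pi k_d/N_d))/h_d^2$.
The stencil form and the Fourier form agree to round-off (tested), and
the Fourier kernel equals a dense-matrix $(L^\dagger L)^{-1}$ built
independently from the stencil to better than $10^{-8}$ relative
Frobenius error on 1-D and 2-D grids up to 32 nodes per axis. $K$ is a
low-pass filter; decreasing $\alpha$ raises every nonzero-frequency
multiplier, which is what makes small-$\alpha$ deformations "more local
and elastic".

**Flow integration.** Time is discretized into $T$ uniform steps
(default $T = 10$). The maps are advanced semi-Lagrangianly:
$\phi_{t+\Delta t,0} = \phi_{t,0} \circ (\mathrm{Id} - \Delta t\, v_t)$
forward, and $\phi_{t,1} = \phi_{t+\Delta t,1} \circ (\mathrm{Id} +
\Delta t\, v_t)$ backward, so the backward maps used by the gradient
never require numerical map inversion. The scheme is first order in
$\Delta t$ (verified against the exact rotation flow, whose affine
displacement interpolates exactly). With $T = 1$ the backward map
degenerates to $\mathrm{Id} - v_0$ after a single exact composition —
the small-deformation (elastic) setting used for comparison with
$T = 10$.

**Step size and stopping.** $\varepsilon$ starts at `epsilon0` (default
1) and is halved by a backtracking line search until the trial step
both leaves the total energy non-increasing *and* keeps the backward
map's Jacobian determinant strictly positive, then restored at the next
iteration. The energy condition guarantees a monotone trace on
arbitrary inputs; the Jacobian condition is what upholds the
diffeomorphy contract in the $T = 1$ small-deformation mode, where the
map is a single displacement field with no compositional protection
against folding. Setting `lineSearch = FALSE` recovers the plain
fixed-step update, which carries neither guarantee. Descent stops when
the relative total-energy change stays below `tol` (default $10^{-6}$)
for 5 consecutive iterations, or at `maxIter` (default 100). A
non-finite energy aborts with the offending iteration named. The
velocity starts at $v \equiv 0$; pose normalization is the job of the
preprocessing stage, not the flow.

**Gradient verification.** The analytic gradient is checked against
symmetric finite differences of the fully discrete energy. At the
$v \equiv 0$ state — the starting point of every registration — the two
agree to better than $10^{-3}$ relative error along random smooth
directions, because there the symmetric difference quotient of the
multilinear interpolant reproduces exactly the central differences the
analytic formula uses (the check uses interior-supported images so
boundary clamping contributes nothing). At generic nonzero velocities
the analytic formula is a discretization of the continuum gradient and
differs from the exact derivative of the interpolated energy at
$O(h)$ — an intrinsic property of multilinear interpolation, not a bug —
so there the suite asserts the weaker, practically relevant property:
the analytic gradient is a descent direction of magnitude comparable to
$\langle g, g \rangle_V$. The backtracking line search makes the
optimizer robust to this discrepancy.

## Cascading

Very small $\alpha$ registers fine detail but, started cold, can settle
into poor local minima on large deformations. The cascade runs stages
with decreasing $\alpha$ (default $0.01 \to 0.005 \to 0.002$, $\gamma$
fixed at 1), each stage registering the running deformed atlas
$I_0 \circ \phi_1^{-1} \cdots \phi_{i-1}^{-1}$ to the target, and
composes the backward maps as $\phi^{-1} = \phi_1^{-1} \circ \cdots
\circ \phi_n^{-1}$. The composed map is still diffeomorphic (positive
Jacobian, asserted), but it is no longer the endpoint of one geodesic
flow, so the result is flagged `metricRetained = FALSE`. To limit
compounding interpolation blur, each stage resamples the original atlas
through the composed map rather than re-warping the previous stage's
output.

## Preprocessing

The full-scale pipeline precedes registration with histogram matching
and a linear alignment. Histogram matching is a monotone remap taking
the source's quantiles onto the reference's, piecewise linear between
256 anchors (8-bit-style granularity); it is idempotent and inverts any
monotone affine intensity distortion. Note one intrinsic caveat the
tests document: at a density gap (e.g. between modes of a bimodal
histogram) a vanishing probability error can move a quantile across the
gap, so quantile agreement is exact in probability but not pointwise in
value there. The linear step is a moment matcher — intensity centroid
plus per-axis second central moments, i.e. translation and diagonal
scaling — rather than a full 12-parameter intensity-driven affine
optimizer: the linear transform only initializes the diffeomorphic
solver, the phantom populations are generated near-aligned (so it
defaults to off in the segmentation pipeline), and a full affine
optimizer would duplicate the LDDMM machinery without adding method
content. Mass is taken as intensity above the per-image minimum so a
uniform background does not bias the centroid.

## Segmentation and fusion

Single-atlas segmentation is the standard chain: histogram-match the
atlas to the subject, (optionally) pre-align, register (cascaded by
default), then pull the atlas ROI charts through the composed backward
map by nearest neighbor.

Multi-atlas segmentation registers every atlas to the subject
independently — complexity linear in the number of atlases — and fuses
the deformed atlases by an EM mixture model: the subject intensity at
voxel $x$ is modeled as Gaussian with mean $M_j(x)$ (the $j$-th deformed
atlas) and shared variance $\sigma_f^2$, with global mixing priors
$\pi_j$. The E-step yields per-voxel convex responsibilities
$w_j(x) \propto \pi_j \exp(-(I(x) - M_j(x))^2 / 2\sigma_f^2)$; the
M-step re-estimates $\pi_j$ and $\sigma_f^2$; the fused label is the
responsibility-weighted vote $\arg\max_l \sum_j w_j(x)\,
\mathbf{1}[L_j(x) = l]$, ties to the smallest label id (deterministic).
The observed-data log-likelihood is non-decreasing (asserted); the
variance update is floored at $10^{-12}$ — a constrained M-step, which
preserves the ascent property — so that an atlas fitting the target
essentially exactly does not degenerate the E-step. Whether fusion
weights should be global per atlas or voxelwise fields is genuinely
open; both are available: the default is voxelwise responsibilities
with pointwise residuals, and `neighborhoodRadius > 0` averages squared
residuals over a box neighborhood for patch-style locality (the
monotone-likelihood guarantee is stated for the pointwise model). A
majority-vote fuser is included as the natural baseline.

## Accuracy metrics

Three per-ROI measures compare an automated mask $A$ against a manual
mask $M$:

* kappa: $(p_\mathrm{agree} - p_\mathrm{random}) / (1 -
  p_\mathrm{random})$, with chance agreement computed from the
  foreground fractions only, over the full grid by default (a cropped
  domain is available as an option). Kappa is biased upward for large
  structures; 0.8 is the conventional "quite good" threshold for brain
  structures.
* volume difference: $100\,\lvert V(A) - V(M) \rvert / V(M)$ on integer
  voxel counts.
* $L_1$ misclassification error: implemented as
  $(\lvert A \cup M \rvert - \lvert A \cap M \rvert) /
  (\lvert A \cup M \rvert / 2)$ — twice the Jaccard distance, the only
  grouping of the conventional one-line rendering that is dimensionless
  and zero at perfect overlap. The alternative normalization by the mean
  mask size (twice the Dice distance) sits behind
  `denominator = "mean_size"`. Both relations to Jaccard/Dice are
  regression-tested, and all three metrics are tested for exact equality
  against brute-force set-operation implementations on hundreds of
  random mask pairs.

Per-subject summaries are unweighted means across ROIs, written as a
tab-delimited table (`subject, roi, name, kappa, vd, l1, v_auto,
v_manual`).

## The phantom generator

Every stage is testable without external data via synthetic phantoms:
smooth-edged ellipsoidal structures (intensity ramps over about one
voxel at the surface) on a uniform background, with labels defined by
the noise-free ellipsoid membership. The default layout mimics a
subcortical slice: 14 structures — left/right pairs of ventricle,
caudate, putamen, globus pallidus, thalamus, hippocampus, amygdala —
mirrored about the midline, with adjacent intensities separated by at
least 20% of the dynamic range (structure proximity is precisely what
makes subcortical segmentation hard). Noise is additive Gaussian with
sd 2% of the dynamic range by default, enough to exercise robustness
while keeping the Gaussian fusion likelihood well specified.

Ground-truth deformations come from kernel-smoothed white-noise fields,
rescaled so each of several composition steps moves well under half a
voxel, composed, and verified to have positive Jacobian (halving the
amplitude and retrying, at most five times, otherwise failing). Because
the smoother is the registration kernel itself, the ground truth lies in
the deformation class the solver searches. A population is the base
phantom pulled through independent such maps with independent noise;
subject labels are the base labels transported through the same map, so
kappa/VD/L1 against "manual" labels are well defined. Everything is
bit-reproducible from the seed.

What the phantoms do *not* emulate: bias fields, partial-volume
fractions, Rician noise, cortical folding, or true inter-subject
anatomical variability (every subject is a diffeomorphic copy of one
template). Passing the suite therefore demonstrates correctness of the
machinery and the expected qualitative parameter behavior, not clinical
segmentation accuracy on real MRI.

## Problem sizes and study conditions

The verification study runs at sizes a laptop handles in minutes, chosen
so every effect is still resolvable: kernel oracles on grids up to 32
nodes per axis; the gradient oracle on a $16^2$ problem; the
registration parameter grid $\alpha \in \{0.01, 0.005, 0.002\}$ (plus
the cascade) crossed with $T \in \{1, 10\}$ on $32^2$ two-structure and
$32^3$ fourteen-structure phantoms; deformation recovery and the
segmentation study on $64^2$ fourteen-structure phantoms with 2-voxel
("moderate") population deformations, 3-voxel recovery targets, and
five atlases. Solver caps in the study are 20-25 iterations per stage,
which the energy traces show is past the knee of convergence at these
sizes. The acceptance script reruns the same conditions from scratch.

## Known limitations

* The greedy scheme offers no metric distance or momentum encoding;
  cascaded results additionally give up the geodesic property.
* First-order flow integration: endpoint error is $O(1/T)$; $T = 1$ is
  deliberately only the small-deformation approximation.
* The analytic gradient's $O(h)$ inconsistency with the interpolated
  discrete energy at generic states (above) is handled, not removed, by
  the line search.
* Boundary clamping makes the operators slightly non-adjoint within one
  voxel of the boundary; all shipped phantoms keep structure away from
  the boundary.
* `sigma`, `epsilon0` and the iteration caps are engineering defaults
  surfaced in the configuration, not method constants.
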