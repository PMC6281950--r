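---
title: "Methods: transfer matrices, regularization and parameter selection for ECGI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer matrices, regularization and parameter selection for ECGI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electrocardiographic imaging (ECGI) reconstructs the extracellular electrical
potential on the outer heart surface (the epicardium, $\Gamma_H$) from
potentials measured on the body surface ($\Gamma_{ext}$). The torso volume
$\Omega_T$ between the two surfaces is modeled as a passive, homogeneous,
isotropic volume conductor, so the torso potential $u_T$ satisfies a Laplace
equation with Dirichlet data $u_H$ on the heart, and zero normal flux (an
insulated boundary) on the body surface. Discretization reduces the problem to
a linear system $A x = b$ where $b$ carries the body-surface potentials (BSPs)
and $x$ is either the epicardial potential vector itself (finite elements) or
a vector of source coefficients (fundamental solutions). The map is severely
ill-posed: smooth epicardial patterns are attenuated through the torso roughly
geometrically in spherical-harmonic degree, so inversion requires
regularization.

This package implements the full comparison design of three numerical methods
— MFS with zero-order Tikhonov, FEM with zero-order Tikhonov, and FEM with
L1-norm current-density regularization — crossed with five
regularization-parameter selection criteria (GCV, robust GCV, CRESO, U-curve,
ADPC), together with a synthetic heart–torso phantom so the entire pipeline is
testable without any external data.

## Forward models

**FEM.** The annular domain between two topologically matching triangulated
surfaces is discretized by radial extrusion: `refinement` layers of prisms
(default 12), each prism split into three conforming tetrahedra by the
minimum-vertex-index diagonal rule, with linear (P1) elements. Partitioning
the stiffness matrix into heart-boundary (H) and remaining (I) blocks gives
the transfer matrix $A = -R\,K_{II}^{-1} K_{IH}$, with $R$ restricting to
torso-surface vertices. Before extrusion, both surfaces are subdivided once in
place (midpoints, no reprojection) and the Dirichlet data prolongated
linearly (`surface_refine = 1`). This internal refinement was a decisive
numerical choice: at the phantom's 162-vertex surfaces the un-refined P1
forward map errs by tens of percent on degree-4 spherical harmonics, while
the refined composite map is accurate to about 1–2 % (the interpolation error
of the prolongated data partially cancels the chord-geometry error; a second
subdivision does *not* improve further because the data-interpolation limit
of the original 162-vertex grid is reached). The interior solve uses a sparse
Cholesky factorization with fill-reducing permutation. Conductivity is
homogeneous and cancels from the Dirichlet-data transfer.

**MFS.** The torso potential is expanded in Laplace fundamental solutions
$1/(4\pi r)$ anchored at fictitious sources: torso vertices inflated and heart
vertices deflated about the heart centroid, plus a constant term. Rows of $A$
are kernel values at the electrodes (Dirichlet block) followed by kernel
normal derivatives at all torso vertices (the insulated-boundary block), and
the right-hand side is $[\mathrm{BSP}; 0]$. Source placement matters: with
inflation 1.2 the sources sit within one collocation spacing of the surface
and the expansion ripples (forward errors of several percent); the defaults
are therefore inflation 2.0 and deflation 0.5, which keep the fictitious
boundaries well separated and validate below 1 % against the analytic
solution. On phantoms whose two surfaces have equal vertex counts, using
every vertex of both surfaces as a source would leave more unknowns than
constraint rows; `source_stride = 2` (the experiment default) halves the
source sets, mirroring the usual MFS practice of fewer sources than
measurements.

**Dirichlet-to-Neumann operator.** For the current-density penalty the
package builds the matrix $D$ mapping epicardial potentials to their outward
normal derivative at the heart vertices: the weak boundary flux of the FEM
solution (a Schur complement), converted to pointwise values through a lumped
boundary mass matrix. $D$ annihilates constants — the insulated domain with
constant Dirichlet data has a constant solution — and this null direction is
central to how the generalized decomposition below treats the operator. $D$
is the *normal* component of the potential gradient, not the tangential
surface gradient of total-variation schemes.

**The analytic oracle.** On concentric spheres the Laplace problem has the
closed-form solution $u = (A_l r^l + B_l r^{-(l+1)}) Y_{lm}$ with
$B_l = A_l\,l\,b^{2l+1}/(l+1)$ (zero flux at the outer radius $b$) and unit
Dirichlet data at the inner radius $a$. Every forward model is validated
against it, and the phantom generator uses it — not the FEM or MFS matrices —
as the forward map, so the inverse solvers are never tested on data produced
by their own discretization (the "inverse crime" guard). The guard has a
visible cost discussed under Limitations.

## Spectral machinery

All solvers and criteria are driven by two decompositions with precomputed
per-frame data coefficients:

* the SVD of $A$ ($\sigma_i$ decreasing, coefficients $\mu_i = u_i^\top b$,
  and the least-squares residual floor $\|r_\perp\|^2$), used for zero-order
  Tikhonov; and
* the GSVD of the pair $\{A, L\}$, computed by QR of the stacked matrix
  followed by a cosine–sine split, with $\sigma_i$ increasing, $\nu_i$
  decreasing, $C^\top C + S^\top S = I$, generalized singular values
  $\bar\lambda_i = \sigma_i/\nu_i$, and filter factors
  $\bar\lambda_i^2/(\bar\lambda_i^2+\lambda^2)$.

Directions with $\nu_i$ below $10^{-8}$ are flagged as infinite generalized
singular values and pass unfiltered at every $\lambda$. The threshold is
deliberately far above machine precision: the numerically assembled
Dirichlet-to-Neumann operator leaves the constant direction at
$\nu \sim 10^{-11}$, and classifying it as a huge *finite* generalized
singular value would corrupt the shared $\lambda$ grid by eight orders of
magnitude. All closed-form curves — residual $\rho(\lambda)$, (semi)norm
$\eta(\lambda)$, influence trace $\xi(\lambda)$, GCV, CRESO — are evaluated
through $\sigma$ and $\nu$ rather than $\bar\lambda$ so the infinite entries
contribute their exact limits.

The out-of-range residual term $\sum_{i>n}(p_i^\top b)^2$ is computed as
$\|b\|^2 - \sum_{i\le n}(p_i^\top b)^2$, i.e. the squared least-squares
residual, which equals the missing-direction sum whenever the retained
columns are orthonormal.

## Regularizers

Zero-order Tikhonov and first-order (generalized) Tikhonov are direct
spectral sums. The L1-norm current-density scheme smooths the absolute value
as $|t| \approx \sqrt{t^2+\beta}$ ($\beta = 10^{-5}$, fixed), which turns the
problem into a weighted first-order solve with diagonal weights
$W_{ii} = 1/(2\sqrt{|[Dx_0]_i|^2+\beta})$ evaluated at a zero-order Tikhonov
seed $x_0$ — a single half-quadratic linearization, no further iteration by
default (an iterate-to-convergence mode exists for study and consistently
performs slightly worse on the phantoms). The printed forms of this scheme
are ambiguous between a penalty $\lambda^2 D^\top W D$ and
$\lambda^2 D^\top W^\top W D$; the package follows the standard
half-quadratic form, i.e. effective operator $\tilde D = W^{1/2} D$, with the
squared-weight variant selectable (`weight_form = "squared"`). The seed's
$\lambda$ defaults to the value chosen by whatever criterion is being
evaluated.

## Parameter-selection criteria

All criteria scan one shared geometric grid (300 points spanning
$[10^{-8}, 10] \times$ the largest finite spectral value) so comparisons
across methods are fair. Three design decisions deserve explanation because
the naive textbook rules misbehave on realistic spectra:

* **Scan window.** Peak and valley detection for CRESO and robust GCV is
  restricted to $[\delta_n^{2/3}, \delta_1^{2/3}]$ (smallest/largest nonzero
  finite spectral value) — the interval on which the regularized solution
  actually transitions, and the same interval in which the U-curve minimum
  provably lies. Outside it the curves are flat up to noise-driven
  micro-bumps, and a literal "first local maximum" latches onto meaningless
  wiggles at $\lambda \sim 10^{-7}$ with catastrophic results.
* **Robust GCV.** $R(\lambda) = [\gamma + (1-\gamma)\xi(\lambda)]G(\lambda)$
  decays artificially to zero at the top of any finite grid for $\gamma < 1$
  (because $\xi \to 0$ while $G$ saturates), so a global argmin is
  degenerate; the package returns the deepest *interior* local minimum in
  the scan window, the quantity one reads off a plot of the criterion.
  At $\gamma = 1$ the rule reduces exactly to GCV.
* **CRESO fallback.** Frames whose signal lives entirely in unpenalized
  directions leave a monotone, noise-driven composite curve with no interior
  peak. Falling back to the global argmax would select the most
  under-regularized grid point; instead the package returns the largest
  $\lambda$ with $C > 0$ in the window (the corner at which the constraint
  term stops growing faster than the residual) and flags the choice.

GCV carries an ill-determined-minimum diagnostic: when the set of grid
points within 0.1 % of the minimum spans more than a decade of $\lambda$, the
choice is flagged `"flat"` — the behavior GCV is known for on severely
ill-conditioned FEM transfer matrices with clean data, where its minimum
provides almost no localization. Ties always break toward larger $\lambda$
(more regularization). ADPC fits a degree-5 polynomial (degrees 5–7
supported) to the log spectral data coefficients in decreasing-spectral-value
order, takes per frame the spectral value at the last index where the
spectrum stays above the fit (the discrete Picard condition), and returns the
median over frames; on the GSVD branch the infinite generalized singular
values are excluded before the relabeling.

## The synthetic phantom

`phantom_dataset()` generates the study conditions every end-to-end test
runs on: concentric icosphere surfaces (heart radius 1, torso radius 2,
subdivision 2 = 162 vertices each — desk scale), a paced wavefront of 60
frames, measurement noise at 20 dB SNR, and the analytic-oracle forward map.
Design choices:

* **Extracellular convention.** The wave steps from a 0 mV baseline to a
  −40 mV activated plateau. ECGI reconstructs *extracellular* potentials;
  a −80 mV resting baseline is a transmembrane convention that real
  (Wilson-terminal-referenced) recordings do not show, and the negative-going
  plateau makes the earliest-activated region the spatial minimum, matching
  the unipolar-electrogram detection rule.
* **Kinematics.** Conduction speed 0.06 length units per frame and a
  logistic upstroke of width 2 frames (midpoint delayed two widths after the
  nominal activation time, so at frame 0 only the paced vertex has begun its
  transition). The wave crosses the sphere in roughly 55 frames; the moving
  front is 1–2 edge lengths wide — the sharp spatial leap the L1 scheme
  targets.
* **Band-limited truth.** The stored ground truth is the projection of the
  logistic wave onto spherical harmonics of degree ≤ 10. A 162-vertex sphere
  cannot represent higher degrees anyway, and band-limiting makes the
  analytic forward exact for the stored truth while remaining independent of
  the operators under test; without it, up to ~11 % of per-frame energy sits
  in components no inverse method could ever recover and every comparison is
  biased by the same irrelevant floor.
* **Noise.** Gaussian, scaled so the realized whole-recording SNR equals the
  request exactly, reproducible under a seed that does not disturb the
  caller's RNG stream.

What the phantom does **not** emulate: realistic torso and cardiac geometry,
inhomogeneous conductivities (lungs, bones), reaction–diffusion
electrophysiology, moving hearts, electrode dropout beyond simple subsets.
Passing tests on the phantom therefore demonstrate correctness and the
relative behavior of algorithms under controlled conditions, not clinical
performance.

## Evaluation

Spatial relative error and correlation are computed per frame, temporal ones
per node; summaries are means ± standard deviations. Frames whose reference
norm is below 5 % of the largest frame norm are marked inactive and excluded
from summary means: a relative error against a near-zero reference is
unbounded noise, not a reconstruction score (per-frame values are always
retained). Pacing sites are detected as the potential minimum at the
detection frame (unipolar convention; `polarity` switches the rule for
positive-going data, and a temporal-derivative rule is available), with ties
to the lowest index, and an indeterminate result — potential spread below
5 % of the frame's scale — reported as `NA`, the analogue of
non-applicable table entries. The default detection frame is the earliest in
which at least 5 % of vertices have crossed half-activation; localization
error is the edge-graph geodesic distance (Dijkstra with Euclidean weights),
which overestimates continuum geodesics on spheres by roughly 5–8 % and is
reported in units of mean edge length.

## Problem sizes and runtime

The test suite runs the full 15-cell comparison once on the default phantom
(162 + 162 vertices, 60 frames, 300-point grids), the forward validation at
the same resolution, the L1-versus-ZOT comparison over 10 noise seeds on a
subsample of active frames, and 10-seed pacing localization; the whole suite
completes in a few minutes on one CPU. These sizes were chosen as the
smallest at which the spectra, criteria interplay and localization are
non-trivial.

## Known limitations

* Under the inverse-crime guard, noise-free reconstruction errors floor at
  the level of FEM/MFS-versus-oracle operator mismatch amplified through the
  inverse (about 4–6 % at this resolution). The weighted L1 filter shapes
  that mismatch slightly worse than zero-order Tikhonov on smooth low-degree
  truth, so its noise-free floor is the highest of the three.
* The U-curve criterion over-regularizes on these phantoms by roughly a
  factor 5 in $\lambda$, costing more than a factor 2 in RE against the
  oracle-best choice — consistent with it being the weakest of the workable
  FEM criteria in comparative studies, but worth knowing before trusting it.
* The L1 advantage over zero-order Tikhonov materializes on *moving*
  two-level wavefront sequences (where the test suite verifies it across 10
  seeds with a sign test); on a static spherical-cap step at this resolution
  the one-shot linearization does not beat zero-order Tikhonov at any SNR we
  examined.
* ADPC and (for FEM) GCV frequently choose $\lambda$ at the unusable end of
  the grid; these failures are flagged, not repaired, since reporting them is
  part of the comparison design.
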