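---
title: "Motion-corrected 4D cine reconstruction of the fetal heart"
author: "fetalcine4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected 4D cine reconstruction of the fetal heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalcine4d)
```

# The problem

Fetal cardiac MRI acquires stacks of 2D real-time frames (balanced SSFP,
about 72 ms per frame, 2 mm in-plane resolution, 6 mm slices) in several
roughly orthogonal orientations. Neither the cardiac phase nor the spatial
position of each frame is known: the fetal heart beats at 115–180 bpm
without a usable ECG, and the fetus moves freely between and during slices.
`fetalcine4d` reconstructs a single motion-corrected 4D cine — three
isotropic spatial dimensions plus a cyclic cardiac phase — from such
multi-planar frame stacks, and ships a numerical beating-heart phantom and
acquisition simulator so the whole method can be validated end-to-end with
known ground truth and no scanner data.

# The acquisition model

Each acquired frame $Y_k$ (pixels $y_{jk}$, acquisition time $t_k$) is
modelled as a linear sampling of the unknown 4D cine
$X = \{X_h\}_{h=1,\dots,N_h}$ with voxels $x_{ih}$ at cardiac phases
$\vartheta_h$ on $[0, 2\pi)$:

$$ y_{jk} \;=\; \sum_i \sum_h w_{ijhk}\, x_{ih}, \qquad
   w_{ijhk} = d_{hk}\, m_{ijk}. $$

The spatial factor $m_{ijk}$ is a 3D Gaussian point-spread function: the
in-plane full width at half maximum equals the pixel spacing and the
through-plane FWHM equals the slice thickness, with the footprint mapped
through the frame's rigid-body transform $A_k$ (six parameters: three
fixed-axis rotations composed as $R_z R_y R_x$ about the heart-mask
centroid, plus translation). Footprints are truncated below 1% of peak and
normalised per pixel. The temporal factor $d_{hk}$ is a sinc in cyclic
phase distance whose width is the acquisition temporal resolution expressed
as phase, $2\pi \cdot 0.072 / t_{RR}$, truncated after two side lobes and
wrapped on the cycle — the temporal response of a band-limited real-time
reconstruction. For scattered-data interpolation (initialization and the
per-slice volume weights $V_l$) the non-negative main lobe of the sinc is
used instead, so the interpolation weights form a positive partition; the
full signed sinc is retained in the super-resolution data term: a
positive kernel is required for a ratio-of-sums interpolant to be stable,
while the signed kernel preserves the band-limited temporal response in
the inverse problem.

Residuals $e_{jk} = y^*_{jk} - \hat y_{jk}$ compare intensity-matched data
$y^*$ with the model prediction. Intensity matching estimates one
multiplicative scale per frame (ratio of predicted to acquired in-mask
medians) and one smooth multiplicative bias field per slice — the mean
log-ratio of predicted to scaled acquired intensities, smoothed with a
Gaussian-weighted *local linear* fit of width 8 mm (exact for log-linear
shading, including at mask boundaries) and clamped to a factor of 2.

# Reconstruction

Reconstruction minimises the robust super-resolution objective

$$ \sum_{jk} p_{jk}\, e_{jk}^2 \;+\; \lambda R(X), $$

by preconditioned gradient descent: the data gradient back-projects
probability-weighted residuals through the adjoint of the acquisition
model, and the update is divided by the accumulated PSF weight per voxel
plus the curvature bound of the regulariser ($24\lambda$; the potential
$\varphi(t) = 2\sqrt{1+t^2}-2$ has $|\varphi''| \le 2$ over 12 neighbour
terms). $R$ applies $\varphi$ to the six spatial neighbour differences
scaled by $\delta$ times the mean in-mask intensity — spatial only, never
across the phase axis. A step that raises the objective is halved and
retried, so the objective trace is non-increasing. Twenty iterations are
used by default. The defaults $\lambda = 0.05$, $\delta = 0.25$ come from
an NRMSE grid search on the packaged phantom (`scripts/param_grid.R`
reproduces it): the surface is almost flat in $\delta$ and shallow in
$\lambda$, with the measured minimum at the upper grid edge
($\lambda = 0.1$); the chosen interior value is within 6% of that minimum
and avoids pushing towards over-smoothing of fine structure.

Outlier rejection follows the two-level robust-statistics scheme. Voxel
level: pooled in-mask residuals are modelled as a zero-mean Gaussian inlier
class plus a uniform outlier class over the observed residual range, fitted
by EM (the posterior inlier probability is $p^{voxel}_{jk}$). Frame level:
each frame's potential $q_k$ is the RMS of its voxel probabilities over the
heart mask; a two-class Gaussian mixture over $\{q_k\}$ gives
$p^{frame}_k$ as the posterior of the higher-mean class. Frames
contributing fewer than $\mathrm{median}(N_j)/10$ in-mask pixels are
excluded from the mixture fit and scored from the fitted model. Because the
potentials live on $[0,1]$, mixtures whose class means differ by less than
0.02 are treated as degenerate and all frames accepted — spreads that small
carry no class structure. Both EM fits have non-decreasing log-likelihood
and are re-estimated, together with intensity matching, at every
super-resolution iteration.

# Cardiac synchronization

A constant heart rate per slice is estimated from the temporal frequency
spectrum: the magnitude of the per-pixel temporal DFT, averaged over the
heart ROI, with the largest strict local maximum in the 115–180 bpm band
refined by quadratic sub-bin interpolation and then by a bounded continuous
maximisation of the band-limited spectrum within one bin of the discrete
peak. The continuous refinement matters: a cyclic phase assignment
accumulates $2\pi \cdot \epsilon$ of drift over the slice for a relative
rate error of $\epsilon$ per beat, so sub-bin accuracy of a few hundredths
of a bin is needed to keep the drift below a few percent of the cycle.
Peak height and FWHM feed the reliability screen: estimates more than three
scaled median absolute deviations (3 × 1.4826 MAD) below the median height
or above the median width are replaced by linear interpolation in
acquisition time between reliable slices of the same stack.

Phases are assigned as $\theta_k = 2\pi\,((t_k - t_{first})/t_{RR} \bmod
1)$ with the slice's first frame as phase origin; all absolute timing is
absorbed into per-slice offsets. For slice-slice alignment a per-slice cine
$X_l$ and volume weights $V_l$ are interpolated into a common heart-region
grid; the offset of each slice is found greedily, starting from the slice
with greatest total overlap, by bounded 1-D minimisation (16 starts spread
over the cycle, golden-section refinement) of the negative overlap-weighted
Pearson correlation against all already-fixed slices, with cines shifted by
a cyclic Fourier time shift (Hermitian-symmetric, so real cines stay
real). Only relative alignment is identifiable: evaluation against ground
truth always removes the global cyclic gauge first.

The estimated offsets are then screened for consistency: with a
near-constant heart rate the offsets of consecutive slices in a stack
advance deterministically by the elapsed acquisition time expressed as
phase. A consensus progression frequency is found per stack (RANSAC-style
inlier counting over a narrow band around the estimated rate, since the
progression aliases over long stacks), and offsets deviating from it by
more than three scaled median absolute deviations (floored at 0.35 rad)
are replaced by the progression prediction. The screen exists because a
motion-corrupted slice's cine carries little pulsation, and its
overlap-weighted correlation can lock onto an anti-phase optimum (its
atria matched against another slice's ventricles); a single such flip
dominates the cohort phase RMSE. The screen presumes slice-to-slice rate
stability — exactly true for the phantom, approximate in vivo — and is
applied in the pipeline, not inside `synchronizeSlices()`.

# Motion correction

Rigid motion is estimated in three stages, interleaved with
reconstruction, using normalized cross-correlation and Nelder–Mead over
the six rigid parameters (slice-to-volume pipelines often delegate this
step to an external registration toolkit; here it is implemented natively
so every choice is inspectable). Frames are compared to volumes by
sampling along
the slice PSF: pixel centres replicated over a 5-point Gaussian quadrature
across the slice profile.

1. *Stack–stack*: each stack's temporal-mean slices are registered to a
   static volume interpolated from a user-chosen target stack, with a
   4×/2×/1× multi-resolution pyramid.
2. *Slice–volume*: each slice's temporal-mean image is registered to the
   static volume interpolated from the *other stacks* at their current
   transforms, and the consensus is rebuilt after every sweep.
3. *Frame–volume*: after synchronization, every frame is registered to the
   cine phase-volume nearest its cardiac phase, interpolated from all
   frames *outside its own slice*; reconstruction and registration are
   interleaved (3 iterations by default, which simulation shows to be
   sufficient).

Two design points deserve emphasis, both adopted after the naive
implementation provably stalled. First, the *leave-out structure*: fetal
motion is temporally correlated, so the frames of one slice (and the slices
of one stack) share their pose error. If a slice is registered to a
consensus containing its own imprint — or its siblings' — the metric is
maximised exactly at the current wrong pose and the cascade freezes.
Excluding the slice's own stack (stage 2) and the frame's own slice
(stage 3) removes the self-anchoring while keeping the independent,
roughly zero-mean information of the other orientations. Second, the
*gauge*: the pose of the consensus volume is a free gauge of the
interleaved problem and drifts as transforms update. After every sweep the
transform set is rigidly re-anchored so that its Fréchet mean (iterative
geodesic averaging in the matrix-logarithm parameterisation, tolerance
1e-6) is the identity — the reconstruction is placed at the average pose
of the data, which is also the phantom's reference-pose convention, so
simulated registration errors are not inflated by an unobservable global
offset. A per-frame or per-slice registration whose final metric is worse
than its initial value falls back to its previous transform, and an
optional screen flags slices whose deviation from the slice-mean transform
exceeds 3 mm.

# The phantom and simulator

The phantom is analytic: four ellipsoidal chambers (blood pool plus
myocardial shell; ventricular walls 2.8 mm, atrial walls 55% of that), a
great-vessel tube, fluid-filled lungs, a low-signal spine analogue and an
ellipsoidal fetal body, immersed in amniotic fluid, with bSSFP-like signal
levels (blood 1.0, amniotic fluid 0.9, lung 0.7, tissue 0.5, myocardium
0.35, spine 0.15, arbitrary units). Ventricular blood-pool radii shrink by
25% at end-systole following the smooth cyclic fraction
$(1-\cos\theta)/2$; atria move in anti-phase at 60% of that amplitude. The
default grid is 0.44 mm isotropic with 25 cardiac phases at 150 bpm.

Frames are simulated by evaluating the acquisition model directly: the
phantom (linearly interpolated in phase at the frame's true phase
$2\pi\,\mathrm{frac}(t_k/t_{RR})$) is sampled on a 0.5 mm in-plane grid
sharing the acquisition-grid origin, with a 7-point Gaussian quadrature
across the 6 mm slice profile, down-sampled to 2 mm in-plane by central
k-space truncation (which preserves the DC term, and lands the
sub-sampled points exactly on the acquired pixel centres), and corrupted
with additive complex Gaussian noise (default SD 5% of the blood signal)
before the magnitude is taken. Slices are acquired sequentially within a
stack with contiguous frames, 96 frames per 72 ms slice by default.

Fetal motion is simulated in the rigid-motion Lie algebra as a
mean-reverting Ornstein–Uhlenbeck process (correlation time 6 s, about
1.5 mm / 1.5° per axis) plus sparse jump events (rate 0.05 per second,
about 5 mm / 5°) that persist and decay — the quiescent-drift-plus-episode
pattern seen in fetal transform traces. The trajectory is centred so the
phantom's reference pose is the mean pose over the acquisition, and the
whole 6-vector state is scaled by a single factor to reach a requested
global displacement (`calibrateMotionScale`), exactly linear for
translations and to first order for rotations.

What the simulator does *not* emulate: beat-to-beat heart-rate
variability (a stated limitation of the constant-rate model), coil
sensitivities, undersampling artefacts and the k-t reconstruction itself
(the framework starts from reconstructed frames), trabeculation, valves,
flow signal, and non-rigid deformation. Passing the packaged simulations
therefore demonstrates the geometry, timing and robustness machinery — not
the artefact behaviour of real scanner data.

# Velocity-sensitive path

As a proof of principle the framework reconstructs complex-valued cines:
the smoothly varying background phase of each stack is removed by fitting
a third-order 3D polynomial (20 monomials, QR least squares on coordinates
scaled to the static-region extent) to the quality-guided-unwrapped phase
of static amniotic fluid and tissue pooled across the stack's frames; a
global ±1 phase-sign factor per stack is chosen to match the target stack
over their spatial overlap; and the real and imaginary channels are then
reconstructed separately (robust weights from the magnitude pass reused,
no intensity matching, signed data) and recombined. The mapping from phase
to velocity, $\phi = \gamma\, v \cdot M_1$, is exposed as a configurable
linear relation for the through-slice component only — gradient first
moments are sequence-dependent inputs, not computable here.

# Numerical choices and degenerate inputs

* Identical residuals (e.g. an exactly consistent model) make the outlier
  mixture unidentifiable; all weights are set to 1.
* Voxels never touched by any frame are filled by nearest-neighbour
  diffusion (then across phases) and flagged in a provenance mask.
* Empty frame sets, all-zero weights, degenerate grids, zero R-R
  intervals and sub-40-voxel static masks raise errors rather than
  propagate silently.
* The cyclic Fourier shift treats the Nyquist coefficient specially
  (cosine modulation) so real cines remain exactly real.
* Registration accepts a move only if the NCC does not decrease, restarts
  the simplex once at its optimum, and treats out-of-volume samples as
  missing rather than zero.
* Seeds: the simulator consumes an explicit seed; reconstruction consumes
  `ReconConfig@seed` (default 2019). All pipeline stages are deterministic
  given the configuration.
* The per-frame intensity scales are normalised to geometric median 1:
  the absolute intensity of the reconstruction is a gauge, and leaving it
  free lets the volume's scale drift over the iterations.
* The heart-rate reliability flag additionally requires the spectral peak
  to fall to half height within the search band (when the band spans
  enough bins for a width to be measurable): under episodic motion the
  in-band maximum is often just the top of broadband motion power, and
  with nearly half the slices corrupted the MAD screen alone loses its
  breakdown protection.

# Problem sizes used in the packaged studies

The packaged validation study runs the pipeline on a 1 mm phantom with 12
phases, 3 orthogonal stacks of 8 slices with 64 frames per slice,
reconstructing at 2 mm with 16 phases — sizes chosen so the full
simulation study completes on a single CPU in well under half an hour
while preserving the acquisition geometry (2 mm in-plane, 6 mm slices,
72 ms frames, 150 bpm, displacement 5.6 mm) of the study conditions. The
phantom default (0.44 mm, 25 phases) is used where only the phantom
itself is exercised. On this study the cascade reduces the target
registration error from about 6.4 mm after stack alignment to about
2.8 mm after three frame-volume iterations, and cardiac synchronization
recovers phases to about 4% of the cycle; both numbers are recomputed
from scratch by `scripts/acceptance.R`.

# Known limitations

* Synchronization runs once, before frame-level motion correction;
  interleaving it with reconstruction would likely reduce phase error
  further and is deliberately left out of scope.
* The slice-to-volume registration is accurate to roughly half an acquired
  pixel against interpolated consensus targets, and the frame-level
  cascade converges to a collective error of roughly 2-3 mm at fetal-scale
  motion: although a single frame registers to about 1.2 mm against a
  perfect target, the consensus targets are blurred by the other frames'
  errors, and the coupled iteration settles well above the single-frame
  floor. A sharper (deconvolved) target model or a gradient-based,
  mutual-information registration engine would be needed to approach the
  single-frame floor.
* Synchronization quality degrades steeply once slice-stage alignment is
  worse than about 4 mm: misaligned slice cines can overlap anti-phase
  anatomy (atria against ventricles), flipping the apparent cycle.
* A constant heart rate per slice cannot express beat-to-beat variability;
  residual phase error grows with the length of each slice acquisition.
* The multi-component velocity decoding of the phase map is deliberately
  unsupported; only the through-slice first moment is inverted.
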