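---
title: "Tracking left-ventricular motion and regional strain from gated cardiac CT"
author: "cctMotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking left-ventricular motion and regional strain from gated cardiac CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

Retrospectively gated cardiac CT reconstructs 10-20 three-dimensional
volumes across one heart beat. `cctMotion` estimates the motion of the
left-ventricular (LV) endocardium across such a sequence and converts it
into regional deformation measures:

1. the blood pool of the end-diastolic reference frame (frame 0, the
   R-wave) is segmented by grey-value region growing and triangulated into
   an endocardial surface mesh;
2. every later frame is registered to the reference with one of two
   intensity-based engines, giving a displacement field over the whole
   image;
3. the single reference mesh is carried through the cycle by interpolating
   the field at its vertices;
4. per-element deformation gradients yield Green-Lagrange circumferential
   and longitudinal strains and the local endocardial area change
   (SQUEEZ), averaged over the 16 AHA segments;
5. curve metrics (time to peak, time to 50% amplitude, magnitude), the
   systolic dyssynchrony index (SDI), and group comparisons summarise the
   regional curves.

Radial (transmural) strain is deliberately out of scope: it would require
a myocardial segmentation, and the surface deformation gradient used here
carries no through-wall information by construction.

## The strain model

For each reference triangle with counter-clockwise vertices, an element
frame is built once (Eqs. in `?elementBasis`): `e_r` is the outward unit
normal, `e_z` the unit projection of the LV long axis (apex to
mitral-centroid) orthogonal to `e_r`, and `e_theta = e_z x e_r`. The
deformation gradient maps reference edges to deformed edges and unit
normal to unit normal,

    F = [e21' e31' n'] [e21 e31 n]^-1 ,

and `E = (F'F - I)/2`. Rotating `E` into the element frame with `Q = [e_r;
e_theta; e_z]` zeroes the radial row and column *identically* -- that is a
consequence of the unit-normal convention for `F`, which we chose over an
area-preserving normal precisely because it makes the radial components
vanish rather than absorbing spurious through-wall stretch. The
circumferential and longitudinal strains are the remaining diagonal
entries; the area ratio and its square root (SQUEEZ) come from triangle
areas directly. The element frame is computed on the reference mesh only
and reused for every frame, so strains are always relative to
end-diastole.

Regional curves are unweighted means over the elements of each AHA
segment, matching the convention that each element is one observation; an
area-weighted variant would down-weight the apex where elements are
small, and is intentionally not the default.

### AHA labelling

The long axis runs from the apex landmark to the centroid of the three
mitral-valve landmarks. Each triangle centroid receives a longitudinal
coordinate `s` in [0, 1] and an angle about the axis measured from the
mean septal-landmark direction, counted counter-clockwise viewed from the
base. Thirds of `s` give the apical/mid/basal rings; basal and mid rings
split into six 60-degree sectors (segments 1-6, 7-12), the apical ring
into four 90-degree sectors (13-16). The 17th apex-cap segment is not
used. The septal anchor fixes the sector origin deterministically; the
convention is arbitrary up to a cyclic relabelling, which the test suite
checks explicitly.

## The phantom

Clinical CCT data cannot be redistributed, so every stage is validated
against a synthetic ventricle: a prolate-spheroid blood cavity
(`blood_hu` = 400 HU) inside a myocardial shell (50 HU) on an air
background (-1000 HU), with additive i.i.d. Gaussian noise (sd 20 HU).
The cavity contracts by an axis-aligned stretch
`lambda(t) = 1 + (lambda* - 1) sin^2(pi t / n)` about its centre --
cyclic, C1 in time, identity at the R-wave. Defaults: 64^3 voxels at 1 mm,
10 frames, `lambda_c* = 0.8`, `lambda_l* = 0.88`, giving a peak
circumferential Green-Lagrange strain of -0.18, in the healthy range.

The deformation is deliberately *not* physiological: an axis-aligned
stretch admits closed-form strains everywhere
(`E_cc = (lambda_c^2-1)/2`, `E_zz = (lambda_l^2-1)/2`, area ratio
`lambda_c lambda_l`), so the strain pipeline can be verified to 1e-6
rather than against another numerical code. Two surfaces play different
roles:

* the **cylindrical verification tube** (`phantomTubeMesh`) has every
  element basis aligned with the stretch axes, so the closed forms hold
  for *every* element -- this is the idealised configuration used for the
  exact strain checks;
* the **cavity mesh** extracted from the segmented phantom image is what
  the full pipeline deforms; on the ellipsoid, `E_cc` is exact for every
  element (the circumferential direction is always orthogonal to the long
  axis) while per-element `E_zz` varies with the surface inclination, so
  end-to-end accuracy is asserted on the LV-mean peak circumferential
  strain.

What the phantom does **not** emulate: papillary muscles and trabeculae
(the clinical protocol includes papillaries in the blood pool), contrast
gradients inside the cavity, beam hardening, gating artefacts, and
through-plane anisotropy. Passing the phantom tests therefore demonstrates
correctness of the machinery under known smooth motion, not clinical
accuracy; the original clinical error statistics cannot be reproduced
without the cohort.

## Registration engines

### Temporal sparse free-form deformation (TSFFD)

A cubic B-spline transform per frame, four resolution levels, coarsest
control spacing a quarter of the domain extent and halving per level.
The objective per level is

    sum_t SSD_t + Theta0 * (bending + temporal) + Theta1 * sparsity

minimised by gradient descent with a backtracking line search (only
decreasing steps are accepted). Defaults `Theta0 = 5e-6`,
`Theta1 = 0.43` are the values found optimal by exhaustive grid search on
annotated clinical training data; the sparsity weight has little effect
around its default, while the bending weight trades tracking of noise
against stiffness -- setting `Theta0 = 1` visibly biases recovered strain
toward zero, a property the tests assert.

Scaling conventions that make these dimensionless weights meaningful:
intensities are rescaled to [0, 1] by the reference range before the SSD
(a mean over voxels); control displacements enter the penalties in units
of the control spacing; and the L1 sum over control coefficients is
divided by the voxel count, i.e. both terms are the sum formulation
divided by the same N. Without this normalisation a weight tuned on one
image scale would be meaningless on another.

Implementation choices worth knowing:

* **Additive multi-level transform.** Each level optimises an increment on
  top of the frozen coarser levels, and the sparsity penalty applies to
  the concatenated multi-level coefficients. Re-fitting the whole field at
  the finest grid instead would make the L1 term shrink the entire
  displacement, not just the fine corrections.
* **Temporal model.** Control points are replicated per frame and coupled
  by a cyclic first-difference penalty in time sharing the bending weight;
  the reference frame closes the cycle as the identity. A full 4D B-spline
  basis in time is a possible extension, not implemented.
* **Image pyramid with blur continuation.** Levels run on block-mean
  downsampled images (at least four voxels per control spacing), each
  optimised against a decreasing sequence of Gaussian blurs (2, 1, and
  finally 0.5 voxels). The wide blur gives tissue edges a broad basin of
  attraction -- without it, boundary samples that temporarily land in
  flat-intensity regions (blood pool, air) lose their SSD gradient and
  descent stalls; re-optimising at smaller blur removes the localisation
  bias wide blurs introduce under contraction. Blurring both images
  symmetrically keeps the true alignment optimal.
* **Line search and convergence.** Steps are along the infinity-norm-
  normalised gradient with a length in mm (initial 2 voxels, halved on
  failure, regrown on success, capped at 4 voxels); a stage stops when
  the relative decrease over a 20-iteration window falls below `tol` per
  iteration, after `maxIter` accepted steps (default 200), or when the
  step underflows. A single small step is not treated as convergence:
  descent routinely stalls briefly while boundary samples cross
  flat-intensity plateaus. The trilinear interpolant's gradient is exact
  except on lattice planes, where the average of the two adjacent cells'
  derivatives is used -- the one-sided value would systematically bias the
  very first step of a zero-initialised transform.

### Dense displacement sampling (DEEDS-style)

Discrete registration on the full-resolution image: per-voxel 12-bit
binarised self-similarity-context descriptors (Gaussian-weighted patch
SSDs between the 12 orthogonal pairs of 6-neighbour offsets, exponentiated
with the per-voxel mean SSD as scale -- hence invariant to affine
intensity rescaling -- and binarised against the per-voxel mean channel,
ties to zero). Control grids of spacing 8, 7, 6, 5, 4 voxels are solved in
sequence; each node chooses among displacement labels (radius = spacing,
quantisation `ceiling(spacing/2)`) by exact min-sum inference on a
minimum spanning tree built from local mean-intensity differences (so the
tree prefers not to cross tissue boundaries), with pairwise potential
`Theta ||u_p - u_q||^2` and the optimised default `Theta = 0.5`. The
final level refines at unit-step labels: with the coarse quantisation
alone, odd integer displacements are unrepresentable (a 3-voxel
translation would oscillate between 2 and 4). Chosen labels are
interpolated to a dense field with a cubic B-spline (edge-replicated
control padding) and refined by the next level around the current
estimate. Every frame is registered directly to the reference frame;
frame-to-frame accumulation is deliberately avoided.

## Validation machinery

The ten anatomical measurements (trigone-to-trigone, posterior perimeter,
mitral annulus area, intercommissural and horn diameters, and five
distances from the automatically computed annulus midpoint) are plain
geometry on named landmark points; the annulus area projects the ring
onto its least-squares plane before the shoelace formula. The tracking
cost is the mean of squared *relative* differences between estimated and
observed measurements over measurements and frames -- the relative form is
the only reading consistent with errors reported in percent -- and the
companion report is the mean absolute relative error in percent. The grid
search enumerates every permutation (first axis fastest, ties to the
first point); engine failures score NA and do not abort. Agreement
statistics use Pearson r, the R^2 of the auto-on-manual regression, and a
Welch two-sample t-test (the unequal-variance form; the plain form was
not specified).

For the dyssynchrony analysis the reading of "16-segment SDI" is: per
subject, compute T2P/TOS/MAG per segment, take the standard deviation
across the 16 segments, then compare those per-subject SDI values between
groups with a Welch t-test, giving the 9-row (3 strains x 3 measures)
table. The alternative composition (metric of SDI) is not meaningful for
MAG and was rejected. Onset is frame 0; the peak is the sample of largest
absolute deviation from the frame-0 value, which treats negative-going
strain and positive-going area curves alike; TOS is linearly
interpolated.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based in R with `world = origin + (index-1) *
  spacing`; no direction cosines beyond identity.
* Region growing is 6-connected; the margin default of 30 HU is the
  clinical protocol value; the window is min/max over seeds +- margin.
* Sparse slice annotations interpolate via 2D signed Euclidean distance
  maps, thresholded at zero; annotated slices are reproduced exactly.
* Surface extraction tetrahedralises each lattice cell about its body
  diagonal (consistent across cells, hence watertight) after a 1-voxel
  Gaussian smoothing of the binary field; triangles are oriented outward
  by the local field gradient. Mesh smoothing is Taubin lambda/mu with an
  isotropic volume-restoring rescale, keeping enclosed volume changes
  far below 0.5%.
* Degenerate geometry is an error, not a silent fix: degenerate triangles
  reject basis/gradient computation, deformed-to-degenerate triangles are
  flagged with a warning, out-of-domain interpolation points name the
  offending point.
* Empty AHA segments yield NA, never zero. The frame-0 row of a strain
  curve set is exactly (0, 0, 1, 1).

## Problem sizes

The test-suite and acceptance runs use the phantom at its default study
conditions (64^3 voxels, 10 frames, peak stretches 0.8/0.88, noise sd
20 HU). Registration sub-checks that only need a pair of frames use a
two-frame phantom or a 48^3 variant; the tiny end-to-end determinism
check uses 32^3 with 3 frames. For the full-sequence TSFFD run the
optimiser uses 60 accepted iterations per level and blur stage, which on
the phantom's smooth motion is well past the window-convergence point of
every level but the last.

## Known limitations

* SSD is the only similarity for TSFFD (no mutual information), so both
  engines assume a fixed intensity mapping across the cycle -- true for
  the phantom and approximately true for contrast CCT.
* The discrete engine's accuracy is bounded by its final one-voxel label
  quantisation, smoothed only by the B-spline interpolation of labels.
* Inside homogeneous regions (blood pool interior) motion is recovered by
  regularisation, not data; strains are therefore only meaningful on the
  endocardial surface where the registration is driven by the boundary.
* The group-comparison and frame-rate analyses operate on simulated curve
  sets with prescribed timing offsets; they exercise the statistics, not
  the registration.
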