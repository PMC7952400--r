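# cctMotion

Regional left-ventricular (LV) deformation from retrospectively gated
cardiac CT (CCT). A gated acquisition reconstructs 10–20 3D volumes over
one cardiac cycle; `cctMotion` tracks the endocardial wall across those
frames with two hyperparameter-optimised intensity-based registration
engines, deforms a single end-diastolic endocardial mesh through the
cycle, and reports regional strain and dyssynchrony measures on the AHA
16-segment division. It is aimed at researchers quantifying cardiac
mechanics from CT — e.g. comparing healthy controls with dyssynchronous
heart-failure patients receiving cardiac resynchronisation therapy — and
at method developers who need a fully testable motion-analysis stack
without clinical data.

## What it computes

For each reference-mesh triangle (counter-clockwise vertices, element
frame `e_r` = unit normal, `e_z` = unit long-axis projection,
`e_theta = e_z × e_r`), the surface deformation gradient

    F = [e'21  e'31  n'] [e21  e31  n]⁻¹

maps reference edges to deformed edges and unit normal to unit normal.
The Green–Lagrange tensor `E = (FᵀF − I)/2` rotated into the element
frame, `E_e = Q E Qᵀ`, has identically vanishing radial components; its
diagonal gives the circumferential strain `E_cc` and longitudinal strain
`E_zz`. Local area change `A/A₀` and its square root (SQUEEZ) complete
the per-element measures; regional curves are unweighted means per AHA
segment. Curve metrics (T2P, TOS, MAG), the systolic dyssynchrony index
(standard deviation of a timing measure over the 16 segments), and Welch
t-tests between subject groups summarise the curves.

Motion comes from one of two engines, both registering every frame to the
end-diastolic reference:

* **TSFFD** — multi-level cubic B-spline free-form deformation with
  sum-of-squared-differences similarity, bending-energy weight
  `Θ0 = 5e-6`, L1 sparsity weight `Θ1 = 0.43`, and a cyclic temporal
  coupling, minimised by gradient descent;
* **DEEDS-style dense displacement sampling** — binarised self-similarity
  context descriptors, per-control-point discrete displacement labels on
  grids of spacing 8, 7, 6, 5, 4 voxels, exact min-sum inference on a
  minimum spanning tree, smoothness weight `Θ = 0.5`.

A deforming-ventricle phantom (prolate-spheroid blood pool, cyclic
axis-aligned stretch with closed-form strains) makes every stage testable
to machine precision; see the methods vignette
(`vignettes/cctMotion-methods.Rmd`).

## Worked example

```r
library(cctMotion)

## a synthetic gated sequence: 64^3 voxels, 10 frames, peak stretches
## lambda_c* = 0.8 / lambda_l* = 0.88 (peak E_cc = -0.18), noise 20 HU
man <- runPipeline(list(method = "tsffd", output = "out", seed = 1))
man$peak_mean_Ecc
#> [1] -0.1847018
man$tracking_error_pct
#> [1] 1.826623
```

`out/` then contains the blood-pool mask (`bloodpool_mask.nii.gz`), the
AHA-labelled reference mesh (`reference_mesh.ply`), per-frame deformed
meshes (`mesh_frame??.vtk`), tidy strain curves (`strain_curves.csv`:
frame, time, segment, metric, value), 16-segment bullseye tables per
metric, the propagated-landmark measurement report, and a manifest with
the configuration hash. `peak_mean_Ecc` is the LV-mean peak
circumferential Green–Lagrange strain recovered by registration — within
0.005 of the phantom's closed-form −0.18 — and `tracking_error_pct` is the
mean absolute relative error of the ten anatomical measurements tracked
through the cycle against the phantom's ground-truth trajectories.

The same configuration with `method = "dds"` runs the discrete engine.
Lower-level entry points (`regionGrow`, `extractSurface`,
`registerTSFFD`, `registerDEEDS`, `deformMesh`, `meshStrain`,
`regionalCurves`, `curveMetrics`, `sdi`, `groupComparison`, …) expose
each stage separately; `inst/exec/cctmotion` is a shell wrapper over the
pipeline.

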