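---
title: "Dynamic-elastic modeling of meniscal kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-elastic modeling of meniscal kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The menisci are crescent-shaped fibrocartilage pads between the femoral
condyles and the tibial plateau. Their motion during knee flexion matters
clinically, but measuring it is hard: each loaded flexion pose requires a
separate static MRI acquisition, goniometer-set flexion angles are only
approximate, and manually segmented menisci from different scans share no
point-to-point correspondence, so "how far did this part of the meniscus
move" is ill-posed with classical single-plane measurements.

`meniscusdyn` implements a computational alternative. The menisci are not
segmented per pose; they are *modeled* as elastic, volume-preserving
triangulated meshes that conform to the underlying bony anatomy in every
pose. Because every pose of a meniscus is a deformation of one template
mesh, vertex index `k` denotes the same anatomical location in every pose
and subject (anatomical correspondence by construction), and point-wise
three-dimensional displacement is simply the distance between corresponded
vertices. A non-linear shape model over the four acquired poses (Principal
Polynomial Shape Analysis, PPSA) then interpolates the articulated knee
continuously in flexion, so poses can be extracted at *exact* flexion
angles rather than at the goniometer-approximate ones.

## Pipeline overview

For each subject the workflow is:

1. **Bone placement.** Full bone meshes (from an overview acquisition) are
   rigidly placed into each loaded pose by least-squares Procrustes
   alignment of ~300 paired cortical surface points (`rigid_procrustes()`;
   cross-covariance SVD with determinant correction, no scaling -- the
   bone's shape is preserved, only its pose changes).
2. **Cartilage.** A population mean cartilage thickness map, scaled
   linearly by the subject's femoral length, is applied to the articular
   bone vertices along their vertex normals (`scale_thickness_map()`,
   `build_cartilage_surface()`).
3. **Menisci.** A meniscus dimension template (anterior-to-posterior horn
   centerline with height/width profiles, also scaled by femoral length)
   is swept into a closed wedge-section tube (`build_template_tube()`) and
   fitted elastically against the posed femoral and tibial cartilage under
   volume preservation (`fit_meniscus()`).
4. **PPSA.** The four corresponded poses (bones + menisci, flattened into
   shape vectors) train a subject-specific non-linear model indexed by
   flexion angle (`fit_ppsa()`, `sample_pose()`).
5. **Analysis.** Poses are extracted at exact angles, averaged across the
   cohort in each subject's tibial frame (`mean_corresponded_mesh()`), and
   point-dependent displacement relative to the extended pose is reported
   (`displacement_field()`, `max_point_displacement()`), alongside the
   classical anteroposterior projection (`ap_projection()`) it improves
   upon.
6. **Validation.** Leave-one-out experiments (`leave_one_out()`) predict
   each subject's menisci from the remaining subjects' statistics and
   compare them to that subject's reference menisci with RMSE, average
   surface distance (ASD) and Hausdorff distance (HD), summarized as
   median (range) per structure and angle; predictions count as accurate
   when the ASD lies within the MRI voxel size.

`run_pipeline()` executes all stages and writes tables, annotated meshes
and a manifest sufficient to reproduce the run bit-identically.

## The elastic, volume-preserving meniscus fit

The literature states the constraints such a model must satisfy -- conform
to the condyle, do not penetrate cartilage or bone, preserve volume, keep
the horn attachments fixed, preserve correspondence -- but not a solver.
The solver here is a deterministic block-iterative scheme on the vertex
positions $X$:

* **Energy.** $E(X) = w_p \sum \max(0, -d)^2 + w_c \sum \tilde d^2 +
  w_e \sum (\|e\| - \|e_0\|)^2 + w_s \sum \|\delta(X) - \delta(X_0)\|^2$,
  where $d$ are signed distances to the two cartilage surfaces, $\tilde d$
  is the distance of near-contact vertices (within `contact_range`, 1.5 mm
  by default) to the femoral cartilage, $e_0$ are rest edge vectors and
  $\delta$ are uniform-Laplacian delta coordinates. The fairness term
  penalizes deviation *from the rest shape's* delta coordinates rather
  than smoothness per se, so the undeformed template is exactly
  energy-free and a constraint-free fit is an exact fixed point.
* **Iteration.** A damped gradient step (`step_size`, default 0.8, halved
  on energy increase and cautiously regrown) is followed by a hard
  projection of penetrating vertices onto the cartilage surfaces and a
  volume-restoring uniform offset along vertex normals, applied only to
  free vertices clear of both surfaces (so the restoration cannot
  reintroduce penetration). The offset solves the scalar equation
  $V(c) = V_0$ by safeguarded Newton.
* **Attachments.** Horn attachment vertices are reset to their input
  positions every step: their displacement is exactly zero, not merely
  small.
* **Convergence.** The fit stops when the largest vertex move falls below
  `step_tolerance` (1 µm–1 mm scale; default $10^{-3}$ mm) or, after a
  30-iteration burn-in, when an accepted step lowers the energy by less
  than `energy_tolerance` (default $10^{-6}$ relative); a final polish
  phase alternates projection and volume restoration until the
  penetration bound (`penetration_tolerance`, default 0.05 mm) and volume
  bound (`volume_tolerance`, default $10^{-3}$ relative) hold
  simultaneously. These defaults sit an order of magnitude below the
  voxel-scale accuracy bar the predictions are judged against, so solver
  error is negligible in the validation.
* **Pose sequences.** Successive poses are fitted with the previous pose
  as a warm start but with the *template tube* as the elastic rest shape
  (`rest_mesh`). Referencing the previous pose instead would accumulate
  deformation across poses and contaminate the displacement analysis with
  solver creep.
* **Determinism.** There is no randomness anywhere in the fit; identical
  inputs and configuration give bit-identical meshes.

Signed distances use exact point-to-triangle queries (lowest triangle
index on ties) with inside/outside decided by the generalized winding
number, which stays robust for queries near the surface. Inside the fit
loop the winding evaluation is skipped for vertices farther than 6 mm from
a surface (they are reported outside); this is safe because fit scenes
never bury vertices deeper than the initial press depth of 2–3 mm.

## PPSA: the continuous flexion model

Given $n \ge 3$ corresponded poses flattened to shape vectors, the data
are mean-centered and decomposed by SVD. The first principal direction
carries the latent flexion parameter $t$ (sign-fixed to correlate
positively with flexion angle); every orthogonal-complement coordinate is
fitted as a polynomial of degree $\le n-1$ in $t$ (default $n-1$, so all
training poses are reproduced to machine precision); and a monotone
polynomial of degree $n-1$ through $(t_i, \theta_i)$ calibrates the latent
score against the flexion angle, with $\theta_i$ *recomputed* from the
bone meshes (shaft principal axis projected onto the sagittal plane)
rather than taken from the goniometer nominals. Sampling at an exact angle
inverts the calibration by bisection (score tolerance $10^{-10}$) and
evaluates the principal polynomial. A non-monotone calibration is refused:
it would mean flexion is not the dominant mode and angle-indexing is
meaningless. No Procrustes pre-alignment is applied across poses -- the
relative bone motion *is* the signal.

Two design points that were genuinely open: the original method
description does not state whether polynomials attach to coordinates or
principal directions, nor the degree; this implementation fixes
per-complement-direction polynomials of default degree $n-1$ and documents
the choice. And with coordinates (not residuals) as features, the model is
exactly equivariant under a common rigid transform of all training poses.

## Coordinate frames and displacement reporting

The tibial frame is anatomical: ML axis = leading principal axis of the
plateau vertices, SI = plateau best-fit-plane normal (superior positive,
away from the shaft), AP = ML × SI, with the AP sign fixed by the
tuberosity-side centroid offset. Anterior/superior are positive; for a
right knee +ML is medial; `ap × ml = si` (right-handed). Cohort averaging
re-expresses every mesh in its subject's tibial frame with *no* size
normalization, preserving millimeter displacement semantics.
Displacements are reported relative to each subject's extended (0°) pose.
The per-vertex 3D point-dependent distance is always at least as large as
its anteroposterior projection; the package reports both, plus per-region
maxima over the anatomical thirds (anterior horn, body, posterior horn).

## The synthetic cohort

The study design this package targets uses an access-restricted in-vivo
dataset, so the generator (`generate_subject()`, `generate_population()`)
emulates its structure with parametric geometry chosen so that every
pipeline stage has a closed-form oracle:

* **Femur:** two condylar *spheres* (medial 22 mm, lateral 21 mm radius at
  the 432 mm reference femoral length) plus a shaft cylinder. Spheres make
  contact geometry analytic and make pure flexion rotation a symmetry, so
  meniscal deformation is driven only by condylar translation.
  Extension-facet/flexion-facet subtleties of real condyles are
  deliberately out of scope.
* **Tibia:** a grid-topped plateau slab (so cartilage offsets stay flat),
  shaft, tuberosity block (which fixes the anterior direction) and a
  fibula cylinder.
* **Kinematics:** at flexion $\theta$, the femur rotates about the
  transcondylar axis and each condyle translates posteriorly at its own
  rate -- 0.02 mm/deg medially, 0.12 mm/deg laterally by default, i.e.
  about 2 mm vs 11 mm over 0–90°, the medial-pivot/rollback pattern and
  magnitude scale reported for loaded deep flexion in vivo. The exact
  rigid transform is stored per pose as ground truth.
* **Poses:** four loaded poses at nominal 0/30/60/90°, achieved angles
  jittered by a uniform goniometer error (half-width 5°; the 0° pose only
  errs into flexion, as a loaded knee does not hyperextend).
* **Menisci:** C-shaped templates around each condyle (medial C spans
  250°, lateral 290°), wedge cross-sections with sinusoidal height/width
  profiles (peaks 4.5/9.0 mm, horns 2.2/4.5 mm at reference length), horn
  anchors on the plateau. Ground-truth menisci are the converged elastic
  fits per pose.
* **Cohort:** femoral lengths ~ N(432 mm, 18 mm) (matching a 1.65 ± 0.07 m
  cohort); all geometric parameters scale linearly with length; meniscal
  profile parameters additionally receive Gaussian perturbations of SD
  `variability` (default 0.5 mm). Per-subject seeds derive
  deterministically from the cohort seed.
* **Noise:** "observed" meshes carry i.i.d. vertex jitter of SD 0.3571 mm,
  the in-plane voxel size of the target MRI protocol; ground truth is
  never perturbed.

What passing tests on this cohort do **not** show: recovery of real
meniscal shape detail (no roots/ligaments, no tears, spherical condyles),
realism of absolute displacement magnitudes (the pivot rates are
literature-scale but not calibrated), or robustness to segmentation
artifacts beyond i.i.d. vertex noise. What they do show: the machinery --
correspondence bookkeeping, constraint satisfaction, angle indexing,
error metrics, leave-one-out logic -- is correct on data whose ground
truth is known exactly.

## Validation harness

Surface errors are vertex-to-surface (never index-to-index: reference
segmentations share no correspondence with predictions): RMSE is the root
mean square of the absolute distances, ASD their mean, HD their maximum,
so ASD ≤ RMSE ≤ HD always. The default direction is symmetric (the union
of predicted→reference and reference→predicted distance sets), the
standard in segmentation evaluation; a one-sided mode exists, and the
parallel-plane oracle case is direction-invariant, which keeps tests
meaningful under either reading. The voxel criterion compares the ASD to
the *largest* voxel dimension (1.5 mm slice thickness for the reference
protocol). Error distributions are tested for normality per cell with
Shapiro–Wilk at α = 0.05 (no multiple-testing correction, by design), and
because normality is typically rejected somewhere, summaries are median
(range) throughout. Leave-one-out predictions rebuild the mean profiles
and cartilage maps from the other subjects after normalizing to a common
reference femoral length, rescale them to the held-out subject, and fit on
that subject's own bony anatomy -- bones are observed inputs, menisci are
predictions.

## Problem sizes and numerical choices

Mesh resolutions are chosen so a full 11-subject workflow (generation,
88 elastic fits, 11 PPSA models, displacement analysis and the 88-fit
leave-one-out) runs in minutes on one core: condylar spheres at 9×12
UV resolution, 16 meniscus sections with 8-point wedge rings (130 vertices
per meniscus), plateau grids of 9×11. The wedge ring is sampled on the
triangle perimeter so its polygon area is exactly $hw/2$, and ring offsets
are centered on the cross-section centroid, which removes the first-order
coupling between profile scaling and centerline curvature (the
$\lambda^2$ volume-scaling law is exact for straight centerlines and holds
to discretization accuracy for curved ones). Degenerate inputs error
loudly: open meshes in volume/signed-distance queries (with boundary-edge
counts), collinear point sets in Procrustes, collinear plateaus, empty
shaft masks, non-monotone PPSA calibrations, out-of-range sampling
angles, self-intersecting sweep curvature (reported with its arclength
location).

## Known limitations

* The elastic model is geometric, not biomechanical: weights are not
  material constants and no stresses are meaningful.
* One latent dimension only; PPSA here models flexion, not inter-subject
  shape variation.
* The winding-number sign shortcut inside the fit assumes penetrations
  shallower than 6 mm; pathological scenes violating this must query
  signed distances through the exported, exact interface.
* Real menisci attach through root ligaments with some compliance; hard
  zero-displacement attachments are a simplification.
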