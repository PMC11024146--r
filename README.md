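# meniscusdyn

Dynamic-elastic modeling of knee meniscal kinematics in R.

## What this package does

Meniscal motion during knee flexion is usually measured from static MRI
scans at a few goniometer-approximated flexion angles, with manually
segmented menisci that share no point-to-point correspondence between
poses. `meniscusdyn` implements a computational workflow that replaces
per-pose segmentation with *modeling*: the menisci are elastic,
volume-preserving triangulated meshes that conform to the femoral
condyles in every pose, so the same vertex index denotes the same
anatomical location in every pose and subject, and three-dimensional
point-dependent displacement is well defined everywhere on the meniscus.

The core pieces:

* **Rigid bone placement** — least-squares Procrustes alignment (SVD with
  reflection correction, no scaling) of sparse paired cortical points
  places full bone meshes into each loaded pose.
* **Cartilage construction** — population mean thickness maps, scaled
  linearly by femoral length, applied along vertex normals.
* **Elastic meniscus fit** — a template tube (horn-to-horn centerline with
  height/width profiles) deforms under contact attraction and penetration
  penalties against the cartilage, with the enclosed volume preserved to
  10⁻³ relative, horn attachments fixed exactly, and mesh topology
  untouched (correspondence by construction).
* **PPSA** (Principal Polynomial Shape Analysis) — a subject-specific
  non-linear shape model of the articulated knee over flexion: the first
  principal direction carries the latent flexion score, all orthogonal
  coordinates are polynomials in that score, and a monotone calibration
  maps score to flexion angle so poses can be extracted at *exact* angles
  (e.g. precisely 0/30/60/90°) instead of goniometer approximations.
* **Displacement analysis** — per-vertex displacement fields between
  corresponded poses, their anteroposterior projections (always ≤ the 3D
  point-dependent distance), maximal displacement per structure, angle and
  anatomical region, and cohort mean shapes in anatomical tibial frames.
* **Validation harness** — RMSE / average surface distance (ASD) /
  Hausdorff distance (HD) between predicted and reference meshes
  (vertex-to-surface, symmetric by default), an MRI voxel-size accuracy
  criterion, Shapiro–Wilk normality testing, median (range) cohort tables,
  and a leave-one-out experiment harness.
* **Synthetic cohort generator** — a parametric knee (spherical condyles,
  grid plateau, medial-pivot/rollback kinematics, goniometer error,
  voxel-scale segmentation noise) standing in for the restricted MRI
  cohort such a study uses, with exact ground truth for every stage.

Mesh IO (PLY binary/ASCII, STL, OBJ) preserves vertex order exactly,
because vertex order *is* the anatomical correspondence.

## Worked example

```r
library(meniscusdyn)

# one synthetic subject: bones, cartilage, four loaded poses with
# elastically fitted, volume-preserving menisci
s <- generate_subject(subject_params(seed = 42))
#> synthetic_subject (seed 42): femoral length 432.0 mm,
#>   achieved angles 4.6/34.4/57.9/93.3 deg

# point-dependent displacement of the lateral meniscus, extension -> 90 deg
f  <- ground_truth_displacement(s, "0", "90", "meniscus_lateral")
mx <- max_point_displacement(f)
sprintf("max displacement %.2f mm at vertex %d", mx$mm, mx$vertex)
#> "max displacement 4.10 mm at vertex 69"
ap_projection(f, s$tibial_frame)[mx$vertex]
#> 0.74   # the classical anteroposterior measure sees only a fraction

# surface error of a noisy observation against the ground truth
rep <- surface_error_report(s$observed_poses[[1]]$meniscus_medial,
                            s$poses[[1]]$meniscus_medial)
#> surface_error_report (symmetric): RMSE 0.316, ASD 0.250, HD 0.905 mm
voxel_accuracy_check(rep, c(0.3571, 0.3571, 1.5))$margin
#> 1.25   # ASD is well within the 1.5 mm slice thickness
```

The numbers read as follows: at 90° of flexion the most mobile point of
the lateral meniscus has moved 4.10 mm in 3D from its extended-knee
position, while its anteroposterior component alone is 0.74 mm — the
single-direction classical measurement misses most of this point's
motion. The observation noise study shows a mean surface error of 0.25 mm,
far inside the 1.5 mm voxel criterion.

The full workflow — cohort generation, Procrustes placement checks, PPSA
fitting, exact-angle extraction, cohort-mean displacement tables and
leave-one-out validation — is one call:

```r
res <- run_pipeline(pipeline_config(n_subjects = 11, cohort_seed = 1,
                                    output_dir = "run"))
res$displacement_table      # maximal point-dependent displacement per
                            # structure, angle and anatomical region
print(res$loo)              # median (range) RMSE/ASD/HD tables
```

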