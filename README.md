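# radcs

Automatic placement of an anatomical coordinate system on full or **partial**
radius bone meshes, and the tooling to quantify what partial scans cost you.

## Why

3D surgical planning for radius malunion and 4D wrist-kinematics studies both
report their parameters in a radial coordinate system (RCS): origin on the
distal articular surface, z distal along the bone axis (pro-supination),
x toward the radial styloid (flexion-extension), y = z × x (radioulnar
deviation). Scan protocols image very different amounts of the radial shaft,
and an RCS derived from a partial radius is *not* the RCS of the full bone.
This package is for researchers who need (a) a deterministic, automatic RCS
placement for radius surface meshes, and (b) a quantitative answer to "how
wrong does the frame get when x% of the bone is missing, and when should a
human place it instead?"

## What it implements

* **Placement** (`place_rcs`): inertia tensor of the mesh vertices
  (T = Σᵢ(‖rᵢ‖²I − rᵢrᵢᵀ)); the smallest-eigenvalue eigenvector is the bone
  axis, sign-resolved against the scan convention; z-axis line translated to
  the centroid of the distal 15% (≥ 20 mm) of the bone; origin ray-cast onto
  the distal articular surface; x toward the styloid (highest vertex).
* **Mesh core**: STL/PLY I/O (ASCII + binary), rigid transforms, mirroring of
  left radii, and exact plane-clipping for systematic shortening.
* **Pose errors** (`pose_error`): the CS100→CSx transform decomposed in the
  reference frame; rotations as intrinsic y-x-z Euler angles; totals
  d_err = √(Δx²+Δy²+Δz²) (mm) and φ_err = √(Δφx²+Δφy²+Δφz²) (degrees).
* **Synthetic cohort** (`generate_cohort`): parametric radius-like meshes
  (curved tapered shaft, distal flare, styloid bump) with known ground-truth
  frames, segmentation jitter, and a calibrated simulator of manual
  (observer) placement.
* **Statistics** (`fit_lmm_length`, `mann_whitney`, `ansari_bradley`,
  `icc_two_way_absolute`, `run_experiment`): mixed-model length association
  with a nested LRT, exact small-sample rank tests, and two-way
  absolute-agreement ICC with Landis-Koch bands.

## Worked example

```r
library(radcs)

g   <- generate_radius(radius_shape_params(seed = 42))  # 240 mm synthetic radius
res <- place_rcs(g$mesh)
res$cs
#> <coordinate_system>
#>   origin:    -0.642     0.049   240.034
#>   x_axis:  0.999988 -0.004964  0.000237
#>   y_axis:  0.004964  0.999987 -0.000769
#>   z_axis: -0.000233  0.000770  1.000000
```

The frame lands on the distal surface (origin z ≈ 240 mm = bone length) with
z within 0.05° of the generator's ground-truth axis and x pointing at the
styloid. Now keep only the distal 30% and re-place:

```r
short <- clip_fraction(g$mesh, res$cs$z_axis, 0.3)
pose_error(res$cs, place_rcs(short)$cs)
#> <pose_error> d_err 0.951 mm (dx 0.916 dy -0.045 dz 0.252),
#>              phi_err 2.838 deg (phix 0.157 phiy 2.800 phiz 0.437)
```

Losing 70% of the shaft tilts the frame by ~2.8° (mostly φy: the bowed shaft
no longer pulls the inertia axis) and shifts the origin by ~1 mm. The full
experiment over a cohort, including simulated manual observers:

```r
coh <- generate_cohort(10, seed = 1)
rec <- run_experiment(coh, lengths = c(10L, 50L, 90L), manual_bones = 3)
summarize_experiment(rec, "phi_err")
#>   length_pct     method  n  median     q1      q3     min    max
#> 1         10       auto 10 187.047 182.20 192.257 177.968 195.59
#> 2         50       auto 10   1.259   1.14   1.939   0.606   3.21
#> 3         90       auto 10   0.247   0.18   0.306   0.112   0.56
#> 4         10 manual_sim 90   7.203   3.26  11.673   0.468  26.33
#> 5         50 manual_sim 90   5.467   2.10  11.235   0.288  21.18
#> 6         90 manual_sim 90   5.208   2.73   8.570   0.186  18.60

fit_lmm_length(rec[rec$method == "auto", ], "phi_err")
#> <lmm_result> LRT chi2(1) = 42.085, p = 8.74e-11
```

Read the table as the method-comparison result it is: automatic placement is
near-perfect down to mid-shaft lengths (φ_err well under the ~5–7° of a
simulated observer), but at 10% retained length the inertia axis flips and
the automatic error explodes to ~187° — the crossover where manual placement
becomes the better option. The mixed model confirms the length association
(p ≪ 0.001).

## Command line

```sh
Rscript -e 'radcs::rcs_cli()' simulate --n-bones 5 --seed 1 --out cohort/
Rscript -e 'radcs::rcs_cli()' place cohort/bone001.stl --out results/
Rscript -e 'radcs::rcs_cli()' experiment --cohort-dir cohort/ --out results/
```

`place` prints the frame as 12 numbers (origin + three axes); `experiment`
writes `records.csv` and `report.json` with per-length summaries, LMM/LRT
results, rank-test comparisons and a provenance block.

## Documentation

`vignettes/rcs-placement-methods.Rmd` describes the algorithm, the pose-error
conventions, the synthetic-data model and its limits, the manual-observer
calibration, and all numerical edge-case choices.
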