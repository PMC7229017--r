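---
title: "Methods: automatic radial coordinate-system placement and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic radial coordinate-system placement and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantitative wrist research — corrective osteotomy planning for radius
malunion, carpal kinematics from 4D CT — reports its numbers in an anatomical
radial coordinate system (RCS): origin on the distal articular surface,
z along the bone axis (pro-supination), x toward the radial styloid
(flexion-extension), y = z × x (radioulnar deviation). Scanning protocols
differ in how much of the radial shaft they image, and an RCS placed on a
partial radius will not coincide with the RCS of the full bone. `radcs`
implements an automatic, deterministic placement algorithm for full or
partial radius surface meshes, a systematic-shortening experiment that
measures the induced pose error, and the statistical machinery to evaluate
automatic against (simulated) manual placement.

## The placement algorithm

Given a triangulated surface mesh with vertices $p_i$ (mm):

1. **Inertia tensor.** $T=\sum_i(\lVert r_i\rVert^2 I_3-r_ir_i^\top)$ with
   $r_i = p_i-\bar p$, unit mass per vertex. The eigenvector of the smallest
   eigenvalue is the elongation (bone) axis. The decomposition fixes only the
   axis orientation; its sign is resolved against a scan-convention hint
   `global_up` (default $(0,0,1)$: the scanner axis points distal for prone,
   arm-overhead acquisition; configurable for other set-ups).
2. **Alignment.** The mesh is rotated so the bone axis is vertical. The
   in-plane axes of this temporary frame come from the remaining
   eigenvectors, but their choice is immaterial: every later step is a
   rotation about z or a projection along z, so any in-plane basis gives the
   identical final frame. This matters numerically because the two larger
   eigenvalues of a near-tubular bone are nearly degenerate and their
   eigenvectors are individually unstable.
3. **Distal window and centroid.** The bone length is the z-extent of the
   aligned vertices. The window holds the distal 15% of the length, at least
   20 mm, clamped to whatever is available for very short segments (both
   parameters are exposed: `distal_frac`, `distal_min_len`). The z-axis line
   is translated to pass through the centroid of the window's vertices.
4. **Origin.** The origin is the most distal intersection of that line with
   the mesh, found by a vertical ray cast from the centroid (a hollow
   cortical shell can be crossed more than once; the most distal crossing is
   the outer articular surface). If the line misses every triangle — possible
   on open or clipped synthetic meshes — the fallback takes the vertex within
   2 mm of the line with maximal projection and puts the origin on the line
   at that height, keeping the origin exactly on the z-axis line.
5. **Styloid and in-plane axes.** The styloid is the vertex with the largest
   projection on z (exact ties resolve to the lowest vertex index, for
   determinism). x is the origin-to-styloid direction orthogonalized against
   z; y completes the right-handed triad. Everything is transformed back to
   the original frame.

There is no randomness anywhere in placement; identical meshes give
bit-identical frames. Failure modes are signalled as typed conditions naming
the stage: non-elongated objects (relative eigen-gap below $10^{-6}$ between
the two smallest eigenvalues), a bone axis exactly perpendicular to
`global_up`, or an origin ray with neither intersection nor fallback vertex.

The inertia tensor is computed from **surface vertices, unweighted** — not
per-triangle area weights and not a solid-volume integral. That is the
algorithm under study, and it makes the result sensitive to vertex-density
gradients; the synthetic generator therefore samples surfaces at near-uniform
density, and users feeding real segmentations should be aware that strongly
non-uniform remeshing shifts the axes.

## Pose-error metrics

For a reference frame (the full-length bone, CS100) and a test frame (CSx or
a manual placement), the error transform is expressed in the reference frame:
$R = R_{ref}^\top R_{test}$, $t = R_{ref}^\top(o_{test}-o_{ref})$. Rotation
errors are the intrinsic y-x-z Euler angles of $R$
($R = R_y(\varphi_y)R_x(\varphi_x)R_z(\varphi_z)$, degrees, $\varphi_x \in
[-90°,90°]$, gimbal-lock convention $\varphi_z = 0$); translation errors are
the components of $t$ (mm). Totals are the quadratic sums
$d_{err}=\sqrt{\Delta x^2+\Delta y^2+\Delta z^2}$ and
$\varphi_{err}=\sqrt{\Delta\varphi_x^2+\Delta\varphi_y^2+\Delta\varphi_z^2}$.

Two properties of $\varphi_{err}$ deserve emphasis. It is **not** the
geodesic rotation angle: it can exceed 180° (a completely flipped axis at
severe shortening produces values near 190°), which is exactly how the
headline numbers of shortening studies should be read. And it is only
approximately symmetric under inversion of the rotation: we measured ~3%
relative asymmetry at 5° components, growing to ~14% at 30°. For small
rotations it agrees with the geodesic angle within 1%. Accuracy summaries use
medians of absolute values, precision uses interquartile ranges (type-7
quantiles; the choice of quantile rule is a convention, stated here because
no single rule is canonical).

The intrinsic-vs-extrinsic reading of "rotation sequence y, x, z" is
genuinely open; we fixed intrinsic y-x-z (equivalently extrinsic z-x-y), and
the compose-decompose round-trip property test pins the implementation to
that choice.

## The synthetic cohort

Clinical CT segmentations are not available at desk scale, so the evaluation
runs on parametric radius-like meshes with known ground truth: a
circular-arc midline (bow angle 2–10°) with the chord along +z, a linearly
tapering shaft (proximal radius 8–11 mm, distal 6.5–9 mm), a distal
metaphyseal flare (scale 1.3–1.7 over the distal 15%), and a smooth styloid
bump (8–15 mm) on the distal rim toward +x (±20°), plus a low-amplitude
seeded Fourier surface irregularity (0.15 mm) that breaks perfect symmetry.
Meshes are closed, watertight, and sampled at near-uniform ~2 mm vertex
spacing. Bone lengths are drawn from 200–260 mm. The ranges are configuration
choices that give the algorithm realistic asymmetry; they are stand-ins, not
claims about anatomy, and results on this cohort establish the *behaviour* of
the algorithm (direction and shape of the shortening effect, crossover with
manual placement), not its clinical error magnitudes.

The default vertex spacing of 2.0 mm keeps the 85-bone experiment fast
(≈15 s); halving the spacing quadruples vertex counts and left the placement
results essentially unchanged in our checks.

What the generator deliberately does **not** model: cortical thickness (the
meshes are single closed surfaces, not hollow shells — hence the origin-ray
fallback path matters for clipped bones), the two articular fossae, the ulnar
notch, segmentation artefacts beyond smooth radial noise, and any
population covariance between shape parameters. A green test on this cohort
therefore cannot certify clinical error magnitudes; it certifies mechanism
and ordering.

Repeated segmentation of the same bone is emulated by displacing every
vertex along its outward normal with Gaussian noise
(`segmentation_jitter`), and its effect on placement is verified to be small
next to the shortening effect.

## The simulated manual observer

Manual placements are modelled as perturbations of the generator's
ground-truth frame: isotropic Gaussian translation (per-axis SD 1.5 mm) and a
rotation about a uniformly random axis with half-normal angle, scale 6.6° at
full length growing by 0.42° per 10% shortening step. The calibration is
derived once, a priori, from published manual-placement error magnitudes: a
Maxwell total-translation mean of $2\sigma\sqrt{2/\pi} = 2.39$ mm (SD
≈ 1.0 mm), a half-normal rotation mean of 5.27° at full length and ≈ 6.8°
averaged over all lengths. Translation noise is length-independent because
manual translation error shows no association with shortening; only rotation
inflates. These parameters were never adjusted after seeing test outcomes.

One subtlety: the experiment evaluates simulated-manual frames against the
automatic full-length reference CS100, not against the generator truth the
perturbation starts from. The small truth-to-CS100 offset (sub-millimetre,
sub-degree on this cohort) is therefore part of the simulated manual error,
just as a human observer's landmark convention differs slightly from the
algorithmic reference.

## The experiment and statistics

`run_experiment` clips every bone to 10–100% of its full length — always from
the full mesh, along the fixed CS100 z-axis — re-places the frame, and tables
the pose error per (bone, length, method, observer, replicate). The manual
design mirrors a 3-observer × 5-bone × 10-replicate protocol (150 sets per
length). At 100% the automatic rows are identically zero by construction, a
built-in self-check.

The statistical battery follows standard method-comparison practice:

* **Length association**: linear mixed model, error ~ length percentage
  (continuous by default; categorical coding available) with a random
  intercept per bone, fitted by ML; the effect is tested by a 1-df nested
  likelihood-ratio test. ML rather than REML because REML likelihoods are not
  comparable across fixed-effect structures. Covariate hooks (age, gender
  label, growth-plate flag) reuse the same machinery.
* **Accuracy comparison** auto vs manual: two-sided Mann-Whitney U, exact by
  exhaustive enumeration for pooled n ≤ 12 without ties, otherwise a normal
  approximation with tie correction (no continuity correction).
* **Precision comparison**: Ansari-Bradley dispersion test on
  both-ends-inward rank scores, same exact/approximate split.
* **Observer agreement**: ICC(A,1), two-way absolute agreement from ANOVA
  mean squares, banded by the Landis-Koch cut points 0.20/0.40/0.60/0.80.
  Absolute agreement (not consistency) because a systematic rater offset is a
  real disagreement for coordinate placement.

No multiple-testing correction is applied; p-values are per-comparison and
flagged as such in the report output.

## Numerical choices and edge cases

* Eigen-degeneracy: relative gap $10^{-6}$ between the two smallest
  eigenvalues; below it the object is declared non-elongated instead of an
  arbitrary axis being picked silently.
* Clipping cuts crossing triangles at the plane (new edge vertices, exact
  retained extent) and leaves the cut open: a cap would add artificial
  vertex density right where the inertia tensor is most sensitive.
* Mirroring reflects x → −x and reverses winding, so mirrored left radii
  remain outward-oriented closed surfaces (signed volume preserved). Any
  fixed mirror plane is equivalent because the RCS is re-derived afterwards.
* Bit-identical input frames short-circuit to the exact identity transform in
  `cs_to_cs`, so self-comparisons are exactly zero rather than ~1e-15.
* Binary STL stores 32-bit floats by format definition (~1e-5 mm at bone
  scale); ASCII STL and both PLY variants round-trip doubles losslessly.
* All stochastic operations take explicit seeds; the cohort derives per-bone
  sub-seeds from the master seed so single bones are reproducible in
  isolation. RNG state of the caller is never disturbed.

## Known limitations

* The vertex-weighted inertia tensor inherits any vertex-density bias of the
  input mesh.
* The styloid rule ("highest vertex") is sensitive to the distal-most few
  millimetres of the segmentation; spikes or artefacts there move the x-axis.
* The simulated observer has no anatomical knowledge: it perturbs a frame,
  it does not "see" landmarks, so observer-specific systematic biases and
  inter-observer ICCs of real physicians are outside what this package can
  reproduce — the ICC machinery is exercised on simulated tables only.
* Below ~20% retained length the placement error is dominated by inertia-axis
  flips; results there describe failure, not noise, and should be read as
  such.
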