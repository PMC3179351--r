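---
title: "Orientation-resolved morphometry and micro-FE of vertebral phantoms: methods"
author: "vertrab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-resolved morphometry and micro-FE of vertebral phantoms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertrab)
```

## The scientific question

Whole-vertebra compressive strength varies widely across individuals, and a
long-standing hypothesis holds that the *vertically oriented* trabeculae —
the struts and plates aligned with the superoinferior (SI) loading axis —
carry most of that variation. Testing the idea computationally requires a
chain of image-analysis and mechanics stages: segmenting the trabecular
compartment away from the cortical shell and endplates, decomposing the
trabecular network into individual trabeculae, classifying each by its
orientation to the SI axis, reducing the classification to orientation-
resolved bone volume fractions (most importantly the vertical bone volume
fraction vBV/TV and the vertical tissue fraction vBV/BV = vertical bone /
all trabecular bone), solving voxel-based linear-elastic micro-finite-element
(micro-FE) models with and without the shell, locating the highly stressed
tissue, and finally comparing candidate predictors of strength across a
cohort.

`vertrab` implements that chain end to end at desk scale. Because no cadaver
micro-CT volumes ship with the package, every stage is driven and validated
by a synthetic phantom generator with exact, countable ground truth. The
`analysis/` scripts run the stages in sequence over a simulated cohort; the
test suite and `scripts/acceptance.R` exercise the same code paths.

## The phantom generator

`generate_phantom()` rasterizes a voxelized vertebral body on a
`(nx, ny, nz)` grid (axis 3 = SI) containing:

* **vertical struts** — axis-aligned columns of square cross-section on a
  lattice; a fraction `plate_fraction` of the lattice rows is realized as
  *vertical plates*, full-width sheets whose plane contains the SI axis;
* **horizontal struts** — in-plane beams along the x and y axes on alternate
  levels;
* **oblique struts** — nearest-voxel 3D lines at a stated angle (default
  45°) from the SI axis, dilated to the strut thickness; a line that reaches
  the compartment wall is reflected (triangular fold), so oblique struts
  crisscross the compartment the way oblique trabeculae do rather than
  terminating at the first wall contact;
* a closed lateral **cortical wall** of stated thickness whose porosity is
  modelled by independent per-voxel hole punching (`shell_hole_prob`,
  default 0), and **endplates** capping the structure; the wall ring runs
  the full structure height, so wall/endplate corner voxels are shell;
* a marrow **margin** outside the shell so the exterior background is
  flood-fillable from the volume border.

Each strut is deleted independently with probability `dropout_prob`
(settable per orientation class), which is how the cohort varies both bone
quantity and orientation balance. Where struts overlap, the orientation
label is resolved deterministically in the order horizontal < oblique <
vertical, so the ground-truth classes partition the trabecular voxels
exactly. Generation is a pure function of the spec, including its seed.

**Default geometry.** The default 64 × 64 × 80 grid at 60 µm with vertical
spacing 14, horizontal/oblique spacing 16 and `plate_fraction` 0.25 was
calibrated once, before any downstream tuning, so that the noise-free
phantom reproduces the morphology scale reported for elderly human T9
trabecular bone: BV/TV ≈ 0.15, vBV/BV ≈ 0.55, oBV/BV ≈ 0.24, hBV/BV ≈ 0.21.
One deliberate departure from anatomy: a desk-scale phantom has a far larger
surface-to-volume ratio than a 40-mm vertebral body, so its cortical *mass*
fraction (≈ 0.4–0.6) is several times the anatomical ≈ 0.15; conclusions
that depend on the shell-to-trabecular volume ratio should not be read off
these phantoms quantitatively.

**Strength model.** Simulated strength is linear-plus-noise in the true
vertical bone volume fraction,

$$F_\mathrm{ult} = \beta_0 + \beta_1\,\mathrm{vBV/TV} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with defaults β₀ = 0.5 kN, β₁ = 50 kN per unit vBV/TV and σ = 0.5 kN, chosen
once so that a cohort spanning vBV/TV ≈ 0.04–0.17 produces strengths of a
few kN with an r² against vBV/TV near 0.8–0.95 — the scale of elderly
whole-vertebra compression data. Making vBV/TV (not BV/TV) the generative
driver encodes the hypothesis under test; the statistics stage must then
*recover* that preference from data in which the two are strongly
correlated.

What the phantoms do **not** emulate: anatomical outer contours and
curvature (the wall is a rectangular prism), BMD calibration of grayscale
values, intra-vertebral gradients in thickness or spacing, marrow
inhomogeneity, and scanner artifacts. Passing tests therefore demonstrate
algorithmic correctness on idealized lattices, not clinical performance.

## Volume I/O, thresholding, coarsening

Volumes are exchanged as MetaImage (`.mha`/`.mhd` + raw; written
uncompressed, little-endian), NIfTI-1 (via `RNifti`; spacing is stored in mm
at float32 header precision, so the voxel size survives a round trip to six
significant digits), or numbered TIFF stacks (one slice per SI plane, with a
JSON sidecar carrying the voxel size, which TIFF itself lacks). Anisotropic
spacing is rejected with an error naming the offending header field.

`threshold_global()` maps intensity ≥ t to bone. `coarsen()` reduces by an
integer factor with block means; binary volumes re-threshold at a block mean
of 0.5 with ties resolving *to bone* (deterministic, and conservative for
connectivity); grids not divisible by the factor are zero-padded at the
high-index ends rather than cropped. The pipeline deliberately carries
binary voxels rather than fractional densities because the micro-FE stage
meshes binary voxels.

## Shell and endplate peeling

`peel_shell_endplates()` relabels the bone of a binary volume as
trabecular / shell / endplate using a moving-average boundary-thickness
rule:

1. rays are cast from the volume border along the four in-plane axis
   directions (per SI slice) and along ±SI; each ray records the entry depth
   and thickness of its first contiguous bone run;
2. rays are *valid* when their entry depth sits within `max_bridge_vox` of
   the direction's median depth (lateral directions) or within
   `endplate_search_depth_vox` of the surface (SI directions); a direction
   contributes a boundary only when at least half its rays are valid,
   which is what keeps shell-free volumes shell-free;
3. run thicknesses are informative only when they are neither truncated by a
   pore nor extended into abutting trabeculae or endplates, so thicknesses
   outside median ± `max_bridge_vox` are treated as missing and imputed;
   entry depths are smoothed by a `window_vox` moving average and
   thicknesses by a moving *median* over the same window (the median is the
   robust version of the smoothing principle: with 10 % porosity a plain
   mean of pore-shortened runs under-estimates the wall by a voxel);
4. bone voxels within the smoothed thickness of the smoothed entry surface
   become shell candidates; candidate connected components must span at
   least half the structure's height and half of one lateral extent (a
   cortical wall is a tall coherent sheet; first-hit strut rows are not).
   The SI-direction analogue labels endplates, whose components must span
   both lateral extents;
5. shell overwrites endplate where both claim a voxel, so wall/endplate
   corners resolve to shell, matching the generator's ground truth;
   remaining bone is trabecular. Peeling is label-conservative: it never
   changes the bone voxel count.

The peel also returns the smoothed *boundary region* (including pores) and
the exterior marrow mask. The trabecular compartment's total volume TV is
the interior of that boundary — trabecular bone plus enclosed marrow — and
the exterior flood fill is blocked by the boundary region, so a porous shell
does not leak the interior. On clean phantoms the recovered shell equals the
ground truth exactly; at 10 % per-voxel porosity the Dice overlap stays
above 0.97. Known limitations, acceptable for convex phantom walls and
flagged for real anatomy: ray directions are axis-aligned (no diagonal
rays), and wall coherence is judged against a per-direction global median
depth, which assumes the wall sits at a roughly uniform depth from the
bounding box.

## Individual trabecula segmentation and orientation

`skeletonize()` performs topology-preserving thinning (26-connectivity for
bone, 6 for marrow): deterministic six-directional boundary peeling in
raster order, deleting only *simple points* (checked at deletion time), with
a preservation rule that keeps curve endpoints and medial sheet/curve voxels
— a voxel thin along an axis whose foreground neighbours all lie in that
axis' mid-plane. The mid-plane condition rejects the diagonal two-voxel
bundles that naive "opposite background pair" preservation leaves behind. A
bounded number of sheet-rim erosion passes (`rim_passes`, default 2) then
collapses strut-scale ribbons to curves while extended plates survive as
sheets (each pass peels exactly one rim ring, so a plate only shrinks by
`rim_passes` voxels per side). Skeleton voxels are tagged curve / surface /
junction from their local neighbourhood.

`segment_trabeculae()` decomposes the network:

* **plates first** — connected *surface patches* of the skeleton of at
  least `min_patch_vox` voxels each seed one whole sheet. Seeding plates
  from their surface patches, rather than from branches of a medial curve,
  is essential: a plate's curve skeleton is a diagonal medial line, and
  growing from its fragments would carve the plate into diagonal bands that
  misclassify as oblique;
* **rods from the curve skeleton** — an endpoint-preserving homotopic
  thinning of the same volume yields one-voxel curves (a single tilted rod
  reduces to a single branch at any angle); a curve voxel with ≥ 3 skeleton
  neighbours is a junction; junction voxels cut the skeleton into branches;
  curve voxels adjacent to a plate patch are dropped so rod branches end at
  plate boundaries;
* dead-end branches shorter than `spur_vox` attached to a junction are
  pruned (thinning artifacts at strut ends); a junction where only two
  branches remain is healed by merging them (a spurious elbow, not a
  crossing); branches shorter than `min_branch_vox` merge into their
  largest neighbour;
* every trabecular voxel is assigned to the nearest seed by level-
  synchronous 26-connected region growing with ties to the lower id, and
  bone components left without a seed become their own trabeculae, so the
  map always partitions the compartment exactly.

**Type and angle.** Each trabecula's type and orientation come from the
eigendecomposition of its reconstructed voxel-coordinate covariance: it is a
plate when the second eigenvalue is at least `plate_eigenratio` (default
0.25) of the first — spread in two directions — and a rod otherwise. A rod's
angle is between its principal axis and the SI axis, folded to [0°, 90°]; a
plate's angle is 90° minus the angle between its normal and the SI axis, so
a plate whose plane contains the SI axis is vertical (0°), matching its
load-bearing role. Near-isotropic voxel sets (relative eigenvalue spread
< 5 %) are flagged, left with an undefined angle, and classified into the
middle (oblique) bin as the least prejudicial default. An earlier design
called plates by majority of surface-tagged skeleton voxels; that rule was
abandoned because surface thinning leaves strut-scale ribbons
surface-tagged, miscalling 3-voxel rods as plates — the covariance shape
test is scale-free.

**Binning.** `classify_orientation()` rounds the angle half-up to the
nearest whole degree and bins on the integer grid: vertical 0–30°, oblique
31–60°, horizontal 61–90°. Binning on whole degrees keeps boundary-angle
structures (a rod rasterized at exactly 60° is measured to ±0.15°) in their
intended class instead of coin-flipping on sub-degree rasterization noise,
and it reproduces the natural integer-boundary behaviour: 30° is vertical,
30.5° is oblique.

Junction tissue is apportioned by the competing growth fronts; there is no
uniquely correct assignment, and on dense lattices this inflates the
dominant class somewhat (measured vBV/BV runs above ground truth by roughly
5–15 % of tissue on the default phantom). Orientation recovery on isolated
rods is essentially exact: 200 seeded rods at 0–90° in 10°-or-finer steps,
including the bin-boundary angles 29/31 and 60/61, classify into their
intended bins at 100 %.

## Morphology metrics

`compute_morphology()` forms all ratios from integer voxel counts: BV/TV;
vBV/TV, oBV/TV, hBV/TV (which sum to BV/TV exactly); vBV/BV, oBV/BV, hBV/BV
(which sum to 1); vBV/BV_vertebra (vertical trabeculae over *all* bone
tissue: trabecular + shell + endplate); vBVvert/BV_vertebra (vertical
trabeculae + shell over all bone tissue — endplates count toward the
denominator but not the vertical numerator, which lists vertical trabeculae
plus shell only); and the cortical mass fraction. TV defaults to the
peeled-interior convention above; `total_volume = "grid"` supports excised
trabecular-core samples that have no shell at all, where the sample volume
is the field's TV convention. With an empty trabecular compartment the /TV
metrics are still defined and the /BV metrics are returned as `NA`
(undefined), R's idiom for an undefined ratio.

## Micro-FE

`build_fe_model()` converts every bone voxel into an eight-node hexahedral
element — trabecular and endplate bone always; shell elements only when
`include_shell = TRUE`, which is how the intact/trabecular model pair is
built from one segmentation with all other inputs unchanged. PMMA layers of
`pmma_layer_thickness_vox` (default 3) spanning the full cross-section are
appended above and below the bone, mimicking compression through endcaps.
Tissue is homogeneous and isotropic (E = 10 GPa, ν = 0.3; PMMA 2.5 GPa,
0.3). Because all voxels are identical cubes, one unit element stiffness
matrix per Poisson ratio (2×2×2 Gauss quadrature of the trilinear
hexahedron, exact for this integrand) serves all elements, scaled by each
element's modulus. Elements not face-connected to both loaded faces are
removed before solving (they contribute zero-energy modes; edge- and
corner-only contacts are treated as non-structural, the standard micro-FE
convention), and the removed count is reported.

`fe_solve()` prescribes a uniform SI displacement of
`apparent_strain × total model height` (PMMA included; the apparent-strain
denominator is a convention, and the full model height is the one used
here) on the exterior top face, fixes the bottom face in
SI, and solves with matrix-free element-by-element Jacobi-preconditioned
conjugate gradients (deterministic; iteration cap 20 000; relative residual
tolerance 1e-6 by default). Two lateral boundary conditions are available:
`frictionless` (default; loaded faces free laterally, rigid modes killed by
pinning a corner node and one lateral degree of freedom of a second node),
which admits exact closed-form oracles — a homogeneous block under
frictionless compression is in a uniform strain state representable exactly
by trilinear elements, so K = E·A/L to solver precision at any resolution —
and `bonded` (all face DOFs fixed), closer to a physical PMMA bond but with
no closed form. Stiffness is the SI reaction on the displaced face over the
applied displacement; `stiffness()` reports kN/mm. Equilibrium is checked as
|top + bottom reaction| against the solver tolerance times the Dirichlet
force norm ‖b‖ — the force scale the residual is actually controlled
against; normalizing by the (possibly small) trabecular reaction would make
the check tolerance-violating for compliant shell-removed models at any
solver setting.

Per-element von Mises stress comes from the centroid strain (trilinear
shape-function gradients), isotropic Hooke's law, and √(3 J₂) of the
deviatoric stress.

## Load paths

`highly_stressed_mask()` selects bone elements (PMMA excluded — the
percentile population is bone only, a choice the source methods leave open)
with von Mises stress *strictly above* the percentile value computed by
linear interpolation of the sorted stresses; ties therefore fall below the
cutoff and an all-equal stress field selects nothing.
`load_path_composition()` reports the fraction of selected elements in
vertical/oblique/horizontal trabeculae, shell, and endplate — composition by
element count, i.e. tissue volume at uniform voxel size.
`cutoff_sensitivity()` repeats this at cutoffs 75/80/85/90 by default. On
vertical-strut-dominated phantoms under SI compression the vertical fraction
ranks first among the trabecular classes at every cutoff, with the shell the
other major load path — the in-silico analogue of the published load-path
finding.

## Cohort statistics

`fit_simple_regression()` is ordinary least squares with the Pearson
correlation and its two-sided p from the t distribution on n − 2 df.
`compare_predictors_residuals()` is the paired two-sided t test on
|residual_A| − |residual_B| across specimens (absolute residuals, matching
how competing predictors of strength are compared in this literature).
`compare_predictors_slopes()` compares the slopes of two outcomes regressed
on one predictor by pairing leave-one-out slope estimates — the source
literature does not describe its pairing construction for the slope test, so
the jackknife pairing is this package's explicit choice; differences below
1e-9 of the slope scale are treated as exact ties so that analytically
identical slopes yield p = 1 rather than a spurious t on floating-point
noise. `multiple_regression()` is OLS with an intercept, per-coefficient t
tests and total R², guarded by a rank check and a condition-number bound on
the scaled design; `bonferroni_adjust()` is min(1, m·p). All tests are
two-sided at α = 0.05.

On synthetic cohorts in which strength is generated from vBV/TV and the
orientation fractions vary independently of BV/TV, the pipeline reproduces
the qualitative published ordering — r²(strength ~ vBV/TV) >
r²(strength ~ BV/TV), with the paired residual test preferring vBV/TV — and
the fitted β₁'s 95 % CI covers the generative value at the nominal rate
(90–99 % over 100 replicates).

## Problem sizes and numerical choices

The shipped study conditions are desk-scale choices made once: cohorts of
10–16 phantoms at 32 × 32 × 40 voxels for the micro-FE stages (both models
of a specimen solve in ~12 s), a 48 × 48 × 60 phantom for the load-path
analysis, n = 100 cohorts at 40 × 40 × 52 for the statistics stage (ground-
truth covariates with redrawn noise across replicates, so coverage is
assessed conditional on one design matrix), and 10 trabecular-core samples
at 80 × 80 × 104 / 30 µm for the factor-2 resolution-consistency check
(measured vBV/TV fine vs coarse: r² ≈ 0.98, slope ≈ 1). Degenerate inputs
are rejected with explicit errors: infeasible phantom geometry, anisotropic
headers, all-bone borders (no exterior), disconnected load paths,
zero-variance predictors, rank-deficient designs, out-of-range percentiles
and probabilities.

## Known limitations

* The peeling assumes a convex, roughly axis-aligned wall; concave anatomy
  would need diagonal rays and locally adaptive depth statistics.
* A plate lying at the structure's lateral surface is geometrically
  indistinguishable from a cortical wall to any boundary-based rule; the
  generator always encloses plates inside the wall.
* Junction tissue apportionment biases tissue fractions toward the dominant
  class on dense lattices; per-strut orientation is unbiased.
* The micro-FE is linear elastic: it predicts stiffness and load paths, not
  failure; simulated strength comes from the generative model, not from FE.
* The cortical mass fraction of desk-scale phantoms is anatomically too
  large (surface-to-volume artifact), so vertebra-level tissue fractions
  (vBV/BV_vertebra, vBVvert/BV_vertebra) are exercised but not anatomically
  scaled.
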