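# vertrab

Orientation-resolved trabecular morphometry and micro-finite-element
analysis of vertebral bodies, at desk scale.

## What this is for

In compression, a vertebra is carried largely by its vertically oriented
trabeculae — the struts and plates aligned with the superoinferior (SI)
axis — together with the thin cortical shell. `vertrab` implements the
computational chain needed to study that claim on voxel image data:

1. **Synthetic phantoms** (`generate_phantom()`, `simulate_cohort()`):
   voxelized vertebral bodies made of vertical columns and plates,
   horizontal beams, oblique struts, a porous cortical wall and endplates,
   with exact per-voxel ground truth; cohorts whose simulated strength
   follows a stated linear-plus-noise model,
   `F_ult = beta0 + beta1 * vBV/TV + N(0, sigma)`.
2. **Volume I/O** (`read_volume()`, `write_volume()`, `threshold_global()`,
   `coarsen()`): MetaImage / NIfTI-1 / TIFF stacks, global thresholding,
   integer-factor coarsening with block means.
3. **Compartment segmentation** (`peel_shell_endplates()`): the trabecular
   compartment is digitally isolated from the cortical shell and endplates
   by a moving-average boundary-thickness rule that bridges shell porosity;
   `cortical_mass_fraction()` reports shell bone over all bone.
4. **Individual trabecula segmentation** (`skeletonize()`,
   `segment_trabeculae()`): topology-preserving thinning to a
   surface-and-curve skeleton, branch decomposition at junctions,
   distance-ordered region growing, plate/rod typing, and the orientation
   angle of every trabecula to the SI axis, binned as vertical (0–30°),
   oblique (31–60°) or horizontal (61–90°).
5. **Morphometry** (`compute_morphology()`): the nine orientation-resolved
   bone volume fractions — BV/TV; vBV/TV, oBV/TV, hBV/TV; the tissue
   fractions vBV/BV, oBV/BV, hBV/BV; the vertebra-level variants
   vBV/BV_vertebra and vBVvert/BV_vertebra — plus the cortical mass
   fraction, all from integer voxel counts.
6. **Micro-FE** (`build_fe_model()`, `fe_solve()`, `element_von_mises()`):
   each 60-µm bone voxel becomes an eight-node brick element (tissue
   E = 10 GPa, ν = 0.3), PMMA layers (2.5 GPa) are appended above and below,
   and the model is compressed to 1 % apparent strain; solved matrix-free by
   Jacobi-preconditioned conjugate gradients. Intact (`K_intact`) and
   shell-removed (`K_trab`) stiffnesses come from the same segmentation.
7. **Load paths** (`highly_stressed_mask()`, `load_path_composition()`,
   `cutoff_sensitivity()`): the bone elements above the 75th (to 90th)
   von Mises percentile, decomposed by compartment and orientation class.
8. **Cohort statistics** (`fit_simple_regression()`,
   `compare_predictors_residuals()`, `compare_predictors_slopes()`,
   `multiple_regression()`, `bonferroni_adjust()`): Pearson correlations of
   strength/stiffness with each morphology parameter, paired t tests on
   absolute residuals and on jackknifed regression slopes, Bonferroni
   adjustment, and the two-predictor model `strength ~ BV/TV + vBV/BV`.

The central quantity throughout is the **vertical tissue fraction**
vBV/BV — the volume of vertical trabeculae divided by the volume of all
trabecular bone — and its companion vBV/TV, the bone volume fraction of
vertical trabeculae alone.

## Worked example

```r
library(vertrab)

# one phantom: 32 x 32 x 40 voxels at 60 um, porous shell, seeded
spec <- phantom_spec(grid_shape = c(32, 32, 40),
                     vertical_strut = list(thickness_vox = 2, spacing_vox = 7),
                     horizontal_strut = list(thickness_vox = 2, spacing_vox = 8),
                     oblique_strut = list(thickness_vox = 2, spacing_vox = 9,
                                          angle_deg = 45),
                     shell_thickness_vox = 2, endplate_thickness_vox = 2,
                     seed = 1)
ph <- generate_phantom(spec)

res <- analyze_specimen(as_binary(ph$volume), run_fe = TRUE)
round(unlist(res$morphology), 3)
#>   BV_TV  vBV_TV  oBV_TV  hBV_TV  vBV_BV  oBV_BV  hBV_BV
#>   0.167   0.109   0.032   0.026   0.652   0.190   0.158
#> vBV_BV_vertebra vBVvert_BV_vertebra cortical_mass_fraction
#>           0.156               0.738                  0.582

round(c(res$K_intact_kN_mm, res$K_trab_kN_mm), 3)
#> [1] 3.442 0.743
res$load_paths[1, ]
#>   percentile_cutoff vertical oblique horizontal shell endplate
#> 1                75    0.241  0.0211      0.027 0.711        0
```

Reading: this specimen's trabecular compartment is 16.7 % bone, 65 % of that
bone is vertically oriented, and removing the cortical shell drops the FE
compressive stiffness from 3.44 to 0.74 kN/mm. Of the tissue stressed above
the 75th von Mises percentile, 24 % is vertical trabecular bone, 71 % is
shell, and only 2–3 % each is oblique or horizontal trabecular bone — the
load paths are vertical columns of bone. (Desk-scale phantoms have an
anatomically oversized shell-to-trabecular volume ratio; see the vignette.)

## The cohort analysis

`analysis/` contains the numbered drivers of the full in-silico study over a
16-specimen cohort (outputs under `results/`, volumes under `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R      # phantoms + strengths -> cohort.csv
Rscript analysis/02_segment_morphometry.R  # peel + classify -> morphology.csv
Rscript analysis/03_micro_fe.R             # K_intact, K_trab -> stiffness.csv
Rscript analysis/04_load_paths.R           # von Mises composition -> load_paths.csv
Rscript analysis/05_statistics.R           # regressions + paired tests
```

On the shipped seed the chain reports, among other things: shell removal
reduces stiffness in 16/16 specimens; vertical trabeculae rank first among
the trabecular classes in the above-cutoff tissue in 64/64 specimen-cutoff
combinations; and strength correlates more strongly with vBV/TV (r = 0.96)
than with BV/TV (r = 0.94), with oBV/TV and hBV/TV uncorrelated.

## Layout

```
R/                  package code (one file per pipeline stage)
src/                C++ kernels (Rcpp): thinning, labelling, growing, PCG
tests/testthat/     unit, property and end-to-end acceptance tests
analysis/           numbered drivers of the cohort study
scripts/acceptance.R
vignettes/          methods vignette: models, algorithms, choices, limits
```
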