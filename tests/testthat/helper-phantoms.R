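# Shared phantom configurations for the test suite. Small grids keep the
# suite fast; geometric proportions mirror the package defaults.

# whole-vertebra phantom small enough for micro-FE in seconds
small_phantom_spec <- function(seed = 1L, ...) {
  args <- list(
    grid_shape = c(32L, 32L, 40L), voxel_size_um = 60,
    vertical_strut = list(thickness_vox = 2L, spacing_vox = 7L),
    horizontal_strut = list(thickness_vox = 2L, spacing_vox = 8L),
    oblique_strut = list(thickness_vox = 2L, spacing_vox = 9L, angle_deg = 45),
    plate_fraction = 0.25, shell_thickness_vox = 2L,
    endplate_thickness_vox = 2L, margin_vox = 2L, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# excised trabecular-core sample (no shell, no endplates) at fine resolution,
# for the resolution-consistency checks
core_phantom_spec <- function(seed, dropout = 0, grid = c(80L, 80L, 104L)) {
  phantom_spec(
    grid_shape = grid, voxel_size_um = 30,
    vertical_strut = list(thickness_vox = 4L, spacing_vox = 16L),
    horizontal_strut = list(thickness_vox = 4L, spacing_vox = 18L),
    oblique_strut = list(thickness_vox = 4L, spacing_vox = 20L, angle_deg = 45),
    plate_fraction = 0.25, shell_thickness_vox = 0L,
    endplate_thickness_vox = 0L, margin_vox = 1L,
    dropout_prob = dropout, seed = seed)
}

# measured vBV/TV of a binary trabecular-core volume (grid TV convention)
measure_core_vbvtv <- function(binary) {
  trab <- labeled_volume((binary$data == 1L) * 1L, binary$voxel_size_um)
  tmap <- segment_trabeculae(skeletonize(trab), trab)
  compute_morphology(trab, tmap, total_volume = "grid")$vBV_TV
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# solid bone cube as a labeled volume
solid_block <- function(n = 20L, voxel_size_um = 60) {
  labeled_volume(array(1L, dim = c(n, n, n)), voxel_size_um)
}
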