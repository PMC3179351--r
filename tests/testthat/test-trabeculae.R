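test_that("a straight thick rod thins to a single axis-aligned curve", {
  rod <- generate_rod_phantom(0, 0, length_vox = 20, thickness_vox = 3)
  sk <- skeletonize(rod)
  tab <- tabulate(sk$data + 1L, nbins = 4L)
  expect_gt(tab[2], 0)        # curve voxels present
  expect_equal(tab[3], 0)     # no surface voxels
  vox <- which(sk$data > 0L, arr.ind = TRUE)
  # one curve along the axis: a single voxel per SI level, straight in the
  # interior (end caps may pull the last voxels off-centre)
  expect_lte(nrow(vox), length(unique(vox[, 3])) + 2)  # near-1 voxel per level
  zmid <- vox[, 3] > min(vox[, 3]) + 2 & vox[, 3] < max(vox[, 3]) - 2
  expect_equal(length(unique(vox[zmid, 1])), 1)
  expect_equal(length(unique(vox[zmid, 2])), 1)
})

test_that("a flat plate thins to a one-voxel surface tagged surface", {
  arr <- array(0L, dim = c(30, 11, 30))
  arr[4:27, 5:7, 4:27] <- 1L
  pl <- labeled_volume(arr, 60)
  sk <- skeletonize(pl)
  tab <- tabulate(sk$data + 1L, nbins = 4L)
  expect_gt(tab[3], tab[2])   # dominated by surface voxels
  vox <- which(sk$data > 0L, arr.ind = TRUE)
  expect_equal(length(unique(vox[, 2])), 1)  # one voxel thick in its normal
})

test_that("thinning preserves topology: a loop stays one looped component", {
  arr <- array(0L, dim = c(20, 8, 20))
  arr[4:16, 3:5, 4:6] <- 1L; arr[4:16, 3:5, 14:16] <- 1L
  arr[4:6, 3:5, 4:16] <- 1L; arr[14:16, 3:5, 4:16] <- 1L
  ring <- labeled_volume(arr, 60)
  sk <- skeletonize(ring)
  m <- sk$data > 0L
  expect_equal(max(label_components(m, 26L)), 1L)
  # the loop survives: the 26-adjacency graph keeps at least one cycle
  # (cycle rank = edges - vertices + components >= 1)
  cycle_rank <- function(mask) {
    vox <- which(mask, arr.ind = TRUE)
    nnb <- vapply(seq_len(nrow(vox)), function(r) {
      xr <- pmax(1, vox[r, 1] - 1):pmin(dim(mask)[1], vox[r, 1] + 1)
      yr <- pmax(1, vox[r, 2] - 1):pmin(dim(mask)[2], vox[r, 2] + 1)
      zr <- pmax(1, vox[r, 3] - 1):pmin(dim(mask)[3], vox[r, 3] + 1)
      sum(mask[xr, yr, zr]) - 1L
    }, integer(1))
    edges <- sum(nnb) / 2
    edges - nrow(vox) + max(label_components(mask, 26L))
  }
  expect_gte(cycle_rank(m), 1)
  expect_gte(cycle_rank(ring$data == 1L), 1)
  # empty input: empty skeleton, not an error
  empty <- labeled_volume(array(0L, dim = c(5, 5, 5)), 60)
  expect_equal(sum(skeletonize(empty)$data), 0L)
})

test_that("segmentation separates disjoint rods and covers all bone voxels", {
  arr <- array(0L, dim = c(20, 20, 30))
  arr[3:5, 3:5, 3:27] <- 1L
  arr[12:14, 12:14, 3:27] <- 1L
  two <- labeled_volume(arr, 60)
  tm <- segment_trabeculae(skeletonize(two), two)
  expect_equal(nrow(tm$registry), 2L)
  expect_identical(sum(tm$registry$voxel_count), sum(arr == 1L))
  expect_true(all(tm$registry$orientation_class == "vertical"))
  # memberships equal the connected components
  comps <- label_components(arr == 1L, 26L)
  expect_equal(length(unique(tm$ids[comps == 1L])), 1L)
  expect_equal(length(unique(tm$ids[comps == 2L])), 1L)
})

test_that("crossing struts split into four arms at the junction", {
  arr <- array(0L, dim = c(41, 9, 41))
  arr[3:39, 4:6, 20:22] <- 1L
  arr[20:22, 4:6, 3:39] <- 1L
  cross <- labeled_volume(arr, 60)
  tm <- segment_trabeculae(skeletonize(cross), cross)
  expect_equal(nrow(tm$registry), 4L)
  expect_identical(sum(tm$registry$voxel_count), sum(arr == 1L))
  expect_setequal(tm$registry$orientation_class,
                  c("vertical", "horizontal"))
})

test_that("a single rod stays a single trabecula with the right angle", {
  for (ang in c(0, 45, 90)) {
    rod <- generate_rod_phantom(ang, 25, length_vox = 40, thickness_vox = 3)
    tm <- segment_trabeculae(skeletonize(rod), rod)
    expect_equal(nrow(tm$registry), 1L)
    expect_identical(tm$registry$voxel_count, sum(rod$data == 1L))
    expect_lt(abs(tm$registry$angle_deg - ang), 1.5)
    expect_equal(tm$registry$kind, "rod")
  }
})

test_that("orientation angles follow the rod and plate conventions", {
  # axis-aligned vertical rod -> 0; in-plane rod -> 90
  rod0 <- which(generate_rod_phantom(0, 0, 30, 3)$data == 1L, arr.ind = TRUE)
  expect_equal(orientation_angle(rod0, "rod")$angle_deg, 0, tolerance = 1e-8)
  rod90 <- which(generate_rod_phantom(90, 0, 30, 3)$data == 1L, arr.ind = TRUE)
  expect_equal(orientation_angle(rod90, "rod")$angle_deg, 90, tolerance = 1e-8)
  rod45 <- which(generate_rod_phantom(45, 0, 40, 3)$data == 1L, arr.ind = TRUE)
  expect_lt(abs(orientation_angle(rod45, "rod")$angle_deg - 45), 3)

  # a plate containing the SI axis scores 0 (vertical)
  arr <- array(0L, dim = c(20, 9, 20)); arr[3:17, 4:6, 3:17] <- 1L
  pl <- which(arr == 1L, arr.ind = TRUE)
  expect_equal(orientation_angle(pl, "plate")$angle_deg, 0, tolerance = 1e-8)
  # a horizontal plate (normal along SI) scores 90
  arrh <- array(0L, dim = c(20, 20, 9)); arrh[3:17, 3:17, 4:6] <- 1L
  plh <- which(arrh == 1L, arr.ind = TRUE)
  expect_equal(orientation_angle(plh, "plate")$angle_deg, 90, tolerance = 1e-8)

  # degenerate isotropic set is flagged
  cube <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  o <- orientation_angle(cube, "rod")
  expect_true(o$flagged)
  expect_true(is.na(o$angle_deg))
  expect_error(orientation_angle(cube[1:2, ], "rod"), "3 voxels")
})

test_that("orientation classes bin whole degrees as vertical/oblique/horizontal", {
  expect_equal(classify_orientation(15), "vertical")
  expect_equal(classify_orientation(45), "oblique")
  expect_equal(classify_orientation(75), "horizontal")
  expect_equal(classify_orientation(30), "vertical")
  expect_equal(classify_orientation(30.5), "oblique")
  expect_equal(classify_orientation(60), "oblique")
  expect_equal(classify_orientation(60.5), "horizontal")
  expect_equal(classify_orientation(0), "vertical")
  expect_equal(classify_orientation(90), "horizontal")
  expect_error(classify_orientation(91), "0, 90")
  expect_error(classify_orientation(-1), "0, 90")
})

test_that("trabecula map covers the trabecular compartment exactly", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  labels <- peel_shell_endplates(as_binary(ph$volume))
  trab <- labeled_volume((labels$data == 1L) * 1L, labels$voxel_size_um)
  tm <- segment_trabeculae(skeletonize(trab), trab)
  expect_identical(sum(tm$registry$voxel_count), sum(trab$data == 1L))
  expect_true(all(tm$ids[trab$data == 1L] > 0L))
  expect_true(all(tm$ids[trab$data != 1L] == 0L))
  # registry ids match the map
  expect_setequal(unique(tm$ids[tm$ids > 0L]), tm$registry$id)
})
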