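test_that("morphology fractions follow integer ground-truth counts", {
  # 40,000 vertical + 10,000 oblique + 10,000 horizontal voxels in a 100^3
  # compartment: BV/TV = 0.06, vBV/BV = 2/3
  dims <- c(100L, 100L, 100L)
  arr <- array(0L, dims)
  ids <- array(0L, dims)
  arr[1:40, 1:100, 1:10] <- 1L; ids[1:40, 1:100, 1:10] <- 1L  # 40k "vertical"
  arr[41:50, 1:100, 1:10] <- 1L; ids[41:50, 1:100, 1:10] <- 2L # 10k "oblique"
  arr[51:60, 1:100, 1:10] <- 1L; ids[51:60, 1:100, 1:10] <- 3L # 10k "horizontal"
  labels <- labeled_volume(arr, 60)
  registry <- data.frame(
    id = 1:3, kind = "rod", angle_deg = c(0, 45, 90),
    orientation_class = c("vertical", "oblique", "horizontal"),
    voxel_count = c(40000L, 10000L, 10000L),
    volume_mm3 = c(40000, 10000, 10000) * 0.06^3, flagged = FALSE)
  tmap <- structure(list(ids = ids, registry = registry, voxel_size_um = 60),
                    class = "trabecula_map")
  m <- compute_morphology(labels, tmap, total_volume = "grid")
  expect_equal(m$BV_TV, 0.06)
  expect_equal(m$vBV_BV, 2 / 3)
  expect_equal(m$vBV_TV, 0.04)
  expect_equal(m$oBV_TV + m$hBV_TV + m$vBV_TV, m$BV_TV)
  expect_equal(m$vBV_BV + m$oBV_BV + m$hBV_BV, 1)
  # no shell: the two vertebra-level variants coincide and cmf is 0
  expect_equal(m$vBV_BV_vertebra, m$vBVvert_BV_vertebra)
  expect_equal(m$cortical_mass_fraction, 0)
})

test_that("partition identities hold to integer exactness on real specimens", {
  for (seed in c(2, 9)) {
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    labels <- peel_shell_endplates(as_binary(ph$volume))
    trab <- labeled_volume((labels$data == 1L) * 1L, labels$voxel_size_um)
    tmap <- segment_trabeculae(skeletonize(trab), trab)
    m <- compute_morphology(labels, tmap)
    cnt <- attr(m, "counts")
    expect_identical(cnt$vBV + cnt$oBV + cnt$hBV, cnt$BV)
    expect_equal(m$vBV_TV + m$oBV_TV + m$hBV_TV, m$BV_TV, tolerance = 1e-12)
    expect_equal(m$vBV_BV + m$oBV_BV + m$hBV_BV, 1, tolerance = 1e-12)
    expect_lte(m$vBV_BV_vertebra, m$vBV_BV)
    expect_gte(m$vBVvert_BV_vertebra, m$vBV_BV_vertebra)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("metrics are invariant to trabecula id relabeling", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  labels <- peel_shell_endplates(as_binary(ph$volume))
  trab <- labeled_volume((labels$data == 1L) * 1L, labels$voxel_size_um)
  tmap <- segment_trabeculae(skeletonize(trab), trab)
  m1 <- compute_morphology(labels, tmap)

  # reverse the id numbering
  n <- nrow(tmap$registry)
  perm <- rev(seq_len(n))
  tmap2 <- tmap
  tmap2$ids[tmap$ids > 0L] <- perm[tmap$ids[tmap$ids > 0L]]
  tmap2$registry <- tmap$registry[order(perm), ]
  tmap2$registry$id <- seq_len(n)
  m2 <- compute_morphology(labels, tmap2)
  expect_equal(as.numeric(m1[1, ]), as.numeric(m2[1, ]))
})

test_that("an all-bone compartment has BV/TV = 1", {
  arr <- array(0L, dim = c(8, 8, 8))
  arr[2:7, 2:7, 2:7] <- 1L
  ids <- array(0L, dim = dim(arr)); ids[arr == 1L] <- 1L
  registry <- data.frame(id = 1L, kind = "rod", angle_deg = 0,
                         orientation_class = "vertical",
                         voxel_count = sum(arr), volume_mm3 = 1,
                         flagged = FALSE)
  tmap <- structure(list(ids = ids, registry = registry, voxel_size_um = 60),
                    class = "trabecula_map")
  m <- compute_morphology(labeled_volume(arr, 60), tmap)
  expect_equal(m$BV_TV, 1)
  expect_equal(m$vBV_BV, 1)
})
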