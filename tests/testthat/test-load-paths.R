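# helper: wrap a stress vector with the attributes element_von_mises attaches
stress_vec <- function(vm, orig_index = seq_along(vm)) {
  attr(vm, "element_index") <- seq_along(vm)
  attr(vm, "orig_index") <- orig_index
  vm
}

test_that("percentile masking counts strictly-above elements", {
  vm <- stress_vec(as.numeric(1:100))
  m75 <- highly_stressed_mask(vm, 75)
  expect_equal(sum(m75), 25L)
  # degenerate ties: nothing strictly above the percentile value
  flat <- stress_vec(rep(3, 50))
  expect_equal(sum(highly_stressed_mask(flat, 75)), 0L)
  # percentile 0 masks everything above the minimum
  m0 <- highly_stressed_mask(vm, 0)
  expect_equal(sum(m0), sum(vm > min(vm)))
  expect_error(highly_stressed_mask(numeric(0), 75), "empty")
  expect_error(highly_stressed_mask(vm, 100), "0, 100")
})

test_that("composition fractions follow hand-built element classes", {
  dims <- c(10L, 10L, 10L)
  arr <- array(0L, dims)
  arr[1:10, 1, 1] <- 2L            # 10 shell voxels
  arr[1:10, 2:4, 1] <- 1L          # 30 trabecular voxels
  labels <- labeled_volume(arr, 60)
  ids <- array(0L, dims); ids[arr == 1L] <- 1L
  registry <- data.frame(id = 1L, kind = "rod", angle_deg = 0,
                         orientation_class = "vertical", voxel_count = 30L,
                         volume_mm3 = 1, flagged = FALSE)
  tmap <- structure(list(ids = ids, registry = registry, voxel_size_um = 60),
                    class = "trabecula_map")
  orig <- which(arr > 0L)
  vm <- stress_vec(rep(1, 40), orig)
  mask <- rep(TRUE, 40)
  attributes(mask) <- attributes(vm)
  rep_ <- load_path_composition(mask, labels, tmap)
  expect_equal(rep_$shell, 0.25)
  expect_equal(rep_$vertical, 0.75)
  expect_equal(rep_$vertical + rep_$oblique + rep_$horizontal +
                 rep_$shell + rep_$endplate, 1)
  # mask entirely inside vertical trabeculae
  mask2 <- c(rep(FALSE, 10), rep(TRUE, 30))
  attributes(mask2) <- attributes(vm)
  expect_equal(load_path_composition(mask2, labels, tmap)$vertical, 1)
  mask3 <- rep(FALSE, 40); attributes(mask3) <- attributes(vm)
  expect_error(load_path_composition(mask3, labels, tmap), "empty")
})

test_that("cutoff table is consistent with single-cutoff composition", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  labels <- peel_shell_endplates(as_binary(ph$volume))
  trab <- labeled_volume((labels$data == 1L) * 1L, labels$voxel_size_um)
  tmap <- segment_trabeculae(skeletonize(trab), trab)
  r <- fe_solve(build_fe_model(labels))
  vm <- element_von_mises(r)
  tab <- cutoff_sensitivity(vm, labels, tmap, percentiles = c(75, 85))
  expect_equal(nrow(tab), 2L)
  single <- load_path_composition(highly_stressed_mask(vm, 75), labels, tmap)
  expect_equal(tab$vertical[1], single$vertical)
  # fractions sum to one at every cutoff
  sums <- rowSums(tab[, c("vertical", "oblique", "horizontal",
                          "shell", "endplate")])
  expect_equal(sums, rep(1, 2), ignore_attr = TRUE)
  # raising the cutoff never increases the masked element count
  n75 <- sum(highly_stressed_mask(vm, 75))
  n85 <- sum(highly_stressed_mask(vm, 85))
  n90 <- sum(highly_stressed_mask(vm, 90))
  expect_true(n85 <= n75 && n90 <= n85)
  # single-cutoff range: table of length 1 equal to the composition
  t1 <- cutoff_sensitivity(vm, labels, tmap, percentiles = 80)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$vertical, load_path_composition(
    highly_stressed_mask(vm, 80), labels, tmap)$vertical)
})
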