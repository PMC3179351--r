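test_that("model building counts elements and nodes as the voxel grid dictates", {
  v <- solid_block(10)
  m <- build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 0L))
  expect_equal(m$nel, 1000L)
  expect_equal(m$nnode, 11L^3)
  # no-op shell removal when there are no shell labels
  m2 <- build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 0L),
                       include_shell = FALSE)
  expect_equal(m2$nel, m$nel)
  expect_identical(m2$elems, m$elems)
  # PMMA layers appended above and below
  m3 <- build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 2L))
  expect_equal(m3$nel, 1000L + 2L * 2L * 100L)
  expect_equal(sum(m3$is_pmma), 400L)
})

test_that("removing the shell drops exactly the shell elements", {
  ph <- generate_phantom(small_phantom_spec(seed = 1))
  labels <- peel_shell_endplates(as_binary(ph$volume))
  mi <- build_fe_model(labels, include_shell = TRUE)
  mt <- build_fe_model(labels, include_shell = FALSE)
  n_shell <- sum(labels$data == 2L)
  expect_equal(mi$nel - mt$nel, n_shell - mi$n_removed + mt$n_removed)
})

test_that("homogeneous block stiffness matches E*A/L to solver precision", {
  v <- solid_block(12)  # 12^3 voxels at 60 um
  m <- build_fe_model(v, material_spec(),
                      load_case(pmma_layer_thickness_vox = 0L))
  r <- fe_solve(m, rel_tol = 1e-8)
  L <- 12 * 0.06
  K_exact <- 10000 * (12 * 0.06)^2 / L
  expect_lt(abs(r$stiffness_N_mm - K_exact) / K_exact, 1e-6)
  # equilibrium of the two face reactions
  expect_lt(abs(r$reaction_top + r$reaction_bottom), 1e-5 * abs(r$reaction_top))
  # uniform uniaxial state: von Mises = E * strain everywhere
  vm <- element_von_mises(r)
  expect_equal(mean(vm), 10000 * 0.01, tolerance = 1e-4)
  expect_lt(sd(vm), 0.1)
})

test_that("stiffness scales linearly in modulus and is strain-invariant", {
  v <- solid_block(8)
  base <- fe_solve(build_fe_model(v, material_spec(),
                                  load_case(pmma_layer_thickness_vox = 0L)))
  dbl <- fe_solve(build_fe_model(v, material_spec(tissue_modulus_GPa = 20),
                                 load_case(pmma_layer_thickness_vox = 0L)))
  expect_equal(dbl$stiffness_N_mm / base$stiffness_N_mm, 2, tolerance = 1e-6)
  half <- fe_solve(build_fe_model(v, material_spec(),
                                  load_case(apparent_strain = 0.005,
                                            pmma_layer_thickness_vox = 0L)))
  expect_equal(half$stiffness_N_mm, base$stiffness_N_mm, tolerance = 1e-6)
  expect_equal(stiffness(base), base$stiffness_N_mm / 1000)
})

test_that("floating components are removed and do not change stiffness", {
  arr <- array(0L, dim = c(10, 10, 12))
  arr[3:6, 3:6, 1:12] <- 1L          # load-bearing column
  arr[9, 9, 5:6] <- 1L               # floating fragment
  v <- labeled_volume(arr, 60)
  m <- build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 0L))
  expect_equal(m$n_removed, 2L)
  r <- fe_solve(m)
  arr2 <- arr; arr2[9, 9, ] <- 0L
  r2 <- fe_solve(build_fe_model(labeled_volume(arr2, 60),
                                load = load_case(pmma_layer_thickness_vox = 0L)))
  expect_equal(r$stiffness_N_mm, r2$stiffness_N_mm, tolerance = 1e-9)
})

test_that("a disconnected load path is a model error", {
  arr <- array(0L, dim = c(8, 8, 10))
  arr[3:5, 3:5, 1:4] <- 1L   # bottom stub
  arr[3:5, 3:5, 7:10] <- 1L  # top stub, no bridge between them
  expect_error(build_fe_model(labeled_volume(arr, 60),
                              load = load_case(pmma_layer_thickness_vox = 0L)),
               "load path")
  expect_error(build_fe_model(labeled_volume(array(0L, dim = c(4, 4, 4)), 60)),
               "no bone")
})

test_that("a single column carries von Mises stress near E*strain", {
  arr <- array(0L, dim = c(8, 8, 12))
  arr[4:5, 4:5, 1:12] <- 1L
  v <- labeled_volume(arr, 60)
  r <- fe_solve(build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 0L)))
  vm <- element_von_mises(r)
  expect_equal(median(vm), 100, tolerance = 0.02)
})

test_that("bonded boundary conditions stiffen a block relative to frictionless", {
  v <- solid_block(8)
  fr <- fe_solve(build_fe_model(v, load = load_case(pmma_layer_thickness_vox = 0L)))
  bd <- fe_solve(build_fe_model(
    v, load = load_case(bc_mode = "bonded", pmma_layer_thickness_vox = 0L)))
  expect_gte(bd$stiffness_N_mm, fr$stiffness_N_mm)
  expect_lt(abs(bd$reaction_top + bd$reaction_bottom),
            1e-4 * abs(bd$reaction_top))
})
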