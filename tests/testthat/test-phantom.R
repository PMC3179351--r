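test_that("phantom generation is a pure function of its spec", {
  ph1 <- generate_phantom(small_phantom_spec(seed = 7))
  ph2 <- generate_phantom(small_phantom_spec(seed = 7))
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$truth$orientation, ph2$truth$orientation)
  ph3 <- generate_phantom(small_phantom_spec(seed = 8))
  expect_false(identical(ph1$volume$data, ph3$volume$data))
})

test_that("vertical-only phantom has vBV/TV = BV/TV and all-vertical labels", {
  spec <- small_phantom_spec(seed = 2,
                             dropout_prob = c(oblique = 0.999, horizontal = 0.999))
  # delete all oblique/horizontal struts via dropout ~ 1
  spec$dropout_prob <- c(vertical = 0, oblique = 0.999, horizontal = 0.999)
  ph <- generate_phantom(spec)
  tr <- ph$truth
  expect_gt(tr$counts$vBV, 0)
  expect_identical(tr$counts$vBV, tr$counts$BV)
  expect_equal(tr$metrics$vBV_TV, tr$metrics$BV_TV)
  expect_true(all(tr$orientation[tr$compartment == 1L] == 1L))
})

test_that("ground-truth orientation classes partition the trabecular voxels", {
  for (seed in 1:3) {
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    tr <- ph$truth
    expect_identical(tr$counts$vBV + tr$counts$oBV + tr$counts$hBV,
                     tr$counts$BV)
    expect_true(all((tr$orientation > 0L) == (tr$compartment == 1L)))
  }
})

test_that("infeasible geometry is rejected with a parameter error", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 12)), "does not fit")
  expect_error(phantom_spec(vertical_strut = list(thickness_vox = 8L,
                                                  spacing_vox = 8L)),
               "thickness must be smaller")
  expect_error(phantom_spec(dropout_prob = 1), "dropout_prob")
  expect_error(phantom_spec(oblique_strut = list(thickness_vox = 3L,
                                                 spacing_vox = 16L,
                                                 angle_deg = 20)),
               "angle_deg")
})

test_that("grayscale overlay thresholds back to the exact mask", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  b <- as_binary(ph$volume)
  g0 <- add_grayscale_noise(b, bone_level = 200, marrow_level = 50,
                            noise_sd = 0, seed = 1)
  expect_identical(threshold_global(g0, 125)$data, b$data)

  # small noise: voxelwise error below the Gaussian-tail bound
  g <- add_grayscale_noise(b, 200, 50, noise_sd = 25, seed = 1)
  rec <- threshold_global(g, 125)
  err <- mean(rec$data != b$data)
  expect_lt(err, pnorm(-75 / 25) * 5)  # generous multiple of Phi(-gap/2sd)
  expect_lt(err, 0.01)

  # seeds change the grayscale, not the underlying mask
  g2 <- add_grayscale_noise(b, 200, 50, noise_sd = 25, seed = 2)
  expect_false(identical(g$data, g2$data))
  expect_identical(threshold_global(g, 125)$voxel_size_um, b$voxel_size_um)
  expect_error(add_grayscale_noise(b, 50, 200), "bone_level")
})

test_that("noise-free cohort strength is an exact linear function of vBV/TV", {
  cs <- cohort_spec(n = 6, base_spec = small_phantom_spec(),
                    strength_model = list(beta0 = 1, beta1 = 40, sigma = 0),
                    seed = 3)
  co <- simulate_cohort(cs, keep_volumes = FALSE)
  fit <- fit_simple_regression(co$table, "true_vBV_TV", "strength_kN")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 40, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
})

test_that("OLS refit recovers beta1 within its CI at n = 100", {
  cs <- cohort_spec(n = 100, base_spec = small_phantom_spec(), seed = 11)
  co <- simulate_cohort(cs, keep_volumes = FALSE)
  fit <- lm(strength_kN ~ true_vBV_TV, data = co$table)
  ci <- confint(fit)[2, ]
  expect_gt(cs$strength_model$beta1, ci[1])
  expect_lt(cs$strength_model$beta1, ci[2])
})

test_that("varying only horizontal dropout leaves vBV/TV fixed while BV/TV moves", {
  # plate_fraction 0 keeps the vertical structure deterministic per specimen
  cs <- cohort_spec(n = 5, base_spec = small_phantom_spec(plate_fraction = 0),
                    phantom_ranges = list(dropout_horizontal = c(0, 0.9)),
                    seed = 5)
  co <- simulate_cohort(cs, keep_volumes = FALSE)
  expect_equal(var(co$table$true_vBV_TV), 0, tolerance = 1e-18)
  expect_gt(var(co$table$true_BV_TV), 0)
})

test_that("degenerate cohort ranges are rejected", {
  expect_error(cohort_spec(phantom_ranges = list(dropout_vertical = c(0.5, 0.1))),
               "degenerate range")
  expect_error(cohort_spec(n = 2), "n >= 3")
  expect_error(cohort_spec(strength_model = list(beta0 = 0, beta1 = 1,
                                                 sigma = -1)), "sigma")
})

test_that("cohort simulation is reproducible and resimulation redraws noise only", {
  cs <- cohort_spec(n = 5, base_spec = small_phantom_spec(), seed = 9)
  co1 <- simulate_cohort(cs, keep_volumes = FALSE)
  co2 <- simulate_cohort(cs, keep_volumes = FALSE)
  expect_identical(co1$table, co2$table)
  t3 <- resimulate_strength(co1, seed = 99)
  expect_identical(t3$true_vBV_TV, co1$table$true_vBV_TV)
  expect_false(identical(t3$strength_kN, co1$table$strength_kN))
})
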