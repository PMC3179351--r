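test_that("simple regression recovers exact lines and rejects bad input", {
  x <- seq(0, 1, length.out = 10)
  tab <- data.frame(x = x, y = 2 * x + 1)
  fit <- fit_simple_regression(tab, "x", "y")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-12)

  # orthogonal construction: r = 0
  tab2 <- data.frame(x = c(-1, 0, 1, 0), y = c(0, 1, 0, -1))
  fit2 <- fit_simple_regression(tab2, "x", "y")
  expect_equal(fit2$pearson_r, 0, tolerance = 1e-12)
  expect_gt(fit2$p_value, 0.9)

  expect_error(fit_simple_regression(data.frame(x = rep(1, 5), y = 1:5),
                                     "x", "y"), "variance")
  expect_error(fit_simple_regression(tab[1:2, ], "x", "y"), "3 specimens")
  expect_error(fit_simple_regression(tab, "missing", "y"), "missing")
})

test_that("regression p value matches the t distribution with n-2 df", {
  set.seed(1)
  tab <- data.frame(x = rnorm(20), y = rnorm(20))
  tab$y <- tab$y + 0.5 * tab$x
  fit <- fit_simple_regression(tab, "x", "y")
  ref <- cor.test(tab$x, tab$y)
  expect_equal(fit$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(fit$pearson_r, unname(ref$estimate), tolerance = 1e-10)
})

test_that("paired residual comparison is symmetric and degenerate-safe", {
  set.seed(2)
  n <- 100
  x <- runif(n)
  y <- 3 * x + rnorm(n, 0, 0.1)          # x is the true driver
  z <- x + rnorm(n, 0, 0.3)              # z is a noisy proxy
  tab <- data.frame(x = x, z = z, y = y)
  ra <- fit_simple_regression(tab, "x", "y")
  rb <- fit_simple_regression(tab, "z", "y")
  cmp <- compare_predictors_residuals(ra, rb)
  expect_lt(cmp$mean_difference, 0)      # the true driver has lower residuals
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$df, n - 1)

  # swapping the reports negates the difference, p unchanged
  rev_ <- compare_predictors_residuals(rb, ra)
  expect_equal(rev_$mean_difference, -cmp$mean_difference)
  expect_equal(rev_$p_value, cmp$p_value)

  # identical inputs: zero difference, p = 1
  same <- compare_predictors_residuals(ra, ra)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
})

test_that("jackknife slope comparison detects scaling, ignores shifts", {
  set.seed(3)
  n <- 50
  x <- runif(n)
  a <- 2 * x + rnorm(n, 0, 0.05)
  tab <- data.frame(x = x, a = a, b_shift = a + 5, b_scale = 2 * a)
  same <- compare_predictors_slopes(tab, "x", "a", "a")
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
  shift <- compare_predictors_slopes(tab, "x", "a", "b_shift")
  expect_equal(shift$slope_a, shift$slope_b, tolerance = 1e-10)
  expect_equal(shift$p_value, 1)
  scale_ <- compare_predictors_slopes(tab, "x", "a", "b_scale")
  expect_lt(scale_$p_value, 0.05)
  expect_equal(scale_$slope_b / scale_$slope_a, 2, tolerance = 1e-8)
  expect_error(compare_predictors_slopes(tab[1:3, ], "x", "a", "b_scale"),
               "4 specimens")
})

test_that("multiple regression recovers exact coefficients and guards rank", {
  set.seed(4)
  n <- 40
  tab <- data.frame(x1 = runif(n), x2 = runif(n))
  tab$y <- 3 * tab$x1 + 2 * tab$x2
  fit <- suppressWarnings(multiple_regression(tab, "y", c("x1", "x2")))
  expect_equal(unname(fit$coefficients[-1]), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared_total, 1)
  # single predictor: total R^2 equals the simple r^2
  f1 <- multiple_regression(tab, "y", "x1")
  expect_equal(f1$r_squared_total, unname(f1$simple_r_squared), tolerance = 1e-12)
  # duplicated predictor column is rank deficient
  tab$x3 <- tab$x1
  expect_error(multiple_regression(tab, "y", c("x1", "x3")), "collinear")
})

test_that("pure-noise coefficient p values are calibrated near 5%", {
  set.seed(5)
  n <- 100
  hits <- vapply(1:200, function(i) {
    x1 <- runif(n); x2 <- runif(n)
    y <- 2 * x1 + rnorm(n)
    tab <- data.frame(x1 = x1, x2 = x2, y = y)
    multiple_regression(tab, "y", c("x1", "x2"))$p_values[["x2"]] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_equal(bonferroni_adjust(c(0.01, 0.02), 5), c(0.05, 0.1))
  # matches the field-standard implementation when m = length(p)
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_equal(sort(bonferroni_adjust(p)), sort(p.adjust(p, "bonferroni")))
  expect_error(bonferroni_adjust(1.2, 3), "0, 1")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})
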