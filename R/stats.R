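# Cohort statistics: simple regressions of outcome on each morphology
# parameter, paired comparisons of predictors via absolute residuals and via
# leave-one-out regression slopes, Bonferroni adjustment, and the
# two-predictor multiple regression.

#' Simple linear regression with Pearson correlation
#'
#' @param table data.frame with one row per specimen.
#' @param predictor,outcome column names.
#' @return list of class `regression_report`: slope, intercept, pearson_r,
#'   r_squared, per-specimen residuals, two-sided p for r (t distribution,
#'   n - 2 df), n.
#' @export
fit_simple_regression <- function(table, predictor, outcome) {
  x <- table[[predictor]]; y <- table[[outcome]]
  if (is.null(x) || is.null(y)) stop("predictor or outcome column missing")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y))))
    stop("analyzed columns must be finite with no missing values")
  n <- length(x)
  if (n < 3L) stop("need at least 3 specimens")
  if (var(x) == 0) stop("zero-variance predictor: ", predictor)
  fit <- lm(y ~ x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  structure(list(predictor = predictor, outcome = outcome,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 pearson_r = r, r_squared = r^2,
                 residuals = unname(residuals(fit)), p_value = p, n = n),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression> %s ~ %s: slope %.4g, r = %.3f (r2 = %.3f), p = %.3g\n",
              x$outcome, x$predictor, x$slope, x$pearson_r, x$r_squared,
              x$p_value))
  invisible(x)
}

#' Paired t test on absolute regression residuals of two predictors
#'
#' Compares how well two predictors explain the same outcome over the same
#' specimens: paired two-sided t test on |residual_A| - |residual_B|. A
#' negative mean difference favours predictor A.
#'
#' @param report_a,report_b `regression_report`s for the same outcome and
#'   specimen set.
#' @return list: mean_difference, t, df, p_value.
#' @export
compare_predictors_residuals <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "regression_report"),
            inherits(report_b, "regression_report"))
  if (report_a$n != report_b$n || report_a$outcome != report_b$outcome)
    stop("reports must share the outcome and specimen set")
  d <- abs(report_a$residuals) - abs(report_b$residuals)
  if (sd(d) == 0) {
    return(list(mean_difference = mean(d), t = NA_real_, df = report_a$n - 1,
                p_value = if (all(d == 0)) 1 else NA_real_,
                note = "zero-variance difference"))
  }
  tt <- t.test(d)
  list(mean_difference = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Paired t test on regression slopes of two outcomes
#'
#' Compares the slopes of `outcome_a ~ predictor` and `outcome_b ~ predictor`
#' over the same specimens by pairing leave-one-out (jackknife) slope
#' estimates, two-sided.
#'
#' @param table cohort data.frame.
#' @param predictor common predictor column.
#' @param outcome_a,outcome_b outcome columns (e.g. intact and trabecular
#'   stiffness).
#' @return list: slope_a, slope_b, mean_difference (of jackknife pairs), t,
#'   df, p_value.
#' @export
compare_predictors_slopes <- function(table, predictor, outcome_a, outcome_b) {
  x <- table[[predictor]]
  ya <- table[[outcome_a]]; yb <- table[[outcome_b]]
  if (is.null(x) || is.null(ya) || is.null(yb)) stop("column missing")
  n <- length(x)
  if (n < 4L) stop("slope comparison needs at least 4 specimens")
  loo_slope <- function(y, i) {
    xi <- x[-i]; yi <- y[-i]
    cov(xi, yi) / var(xi)
  }
  sa <- vapply(seq_len(n), function(i) loo_slope(ya, i), numeric(1))
  sb <- vapply(seq_len(n), function(i) loo_slope(yb, i), numeric(1))
  d <- sa - sb
  d[abs(d) < 1e-9 * max(abs(c(sa, sb)), 1e-300)] <- 0  # numerical-noise floor
  full_a <- cov(x, ya) / var(x)
  full_b <- cov(x, yb) / var(x)
  if (sd(d) == 0) {
    return(list(slope_a = full_a, slope_b = full_b, mean_difference = mean(d),
                t = NA_real_, df = n - 1,
                p_value = if (all(d == 0)) 1 else NA_real_,
                note = "zero-variance difference"))
  }
  tt <- t.test(d)
  list(slope_a = full_a, slope_b = full_b, mean_difference = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Multiple linear regression of an outcome on several predictors
#'
#' OLS with intercept; per-coefficient t tests; total R-squared reported
#' alongside each predictor's simple r-squared. Rank-deficient or severely
#' collinear designs are rejected.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column.
#' @param predictors character vector of predictor columns.
#' @param max_condition condition-number guard for the scaled design.
#' @return list: coefficients, p_values, r_squared_total, simple_r_squared,
#'   n, fit (the `lm` object).
#' @export
multiple_regression <- function(table, outcome,
                                predictors = c("BV_TV", "vBV_BV"),
                                max_condition = 1e8) {
  X <- as.matrix(table[, predictors, drop = FALSE])
  y <- table[[outcome]]
  if (anyNA(X) || anyNA(y)) stop("analyzed columns must have no missing values")
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("rank-deficient design: predictors are collinear (",
         paste(predictors, collapse = ", "), ")")
  Xs <- scale(X)
  kap <- kappa(cbind(1, Xs), exact = TRUE)
  if (kap > max_condition)
    stop(sprintf("design too ill-conditioned (condition number %.3g)", kap))
  dat <- data.frame(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  simple_r2 <- vapply(predictors, function(p)
    fit_simple_regression(table, p, outcome)$r_squared, numeric(1))
  list(coefficients = coef(fit), p_values = sm$coefficients[, 4],
       r_squared_total = sm$r.squared, simple_r_squared = simple_r2,
       n = length(y), fit = fit)
}

#' Bonferroni adjustment
#'
#' adjusted p = min(1, m p).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param m number of comparisons (>= length(p_values)).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of p values")
  out <- pmin(1, m * p_values)
  names(out) <- names(p_values)
  out
}
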