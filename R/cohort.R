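# Cohort simulation: specimens sampled from per-parameter phantom ranges,
# with simulated compressive strength following a stated linear-plus-noise
# generative model in the true vertical bone volume fraction:
#   strength_kN = beta0 + beta1 * vBV/TV + Normal(0, sigma).

#' Cohort specification
#'
#' @param n number of specimens (>= 3).
#' @param base_spec a [phantom_spec()] giving the fixed phantom parameters.
#' @param phantom_ranges named list of c(min, max) sampling ranges; supported
#'   names: `dropout_vertical`, `dropout_oblique`, `dropout_horizontal`,
#'   `plate_fraction`.
#' @param strength_model list(beta0, beta1, sigma): kN intercept, kN per unit
#'   vBV/TV, and kN noise SD.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 16L,
                        base_spec = phantom_spec(),
                        phantom_ranges = list(
                          dropout_vertical = c(0, 0.4),
                          dropout_oblique = c(0, 0.6),
                          dropout_horizontal = c(0, 0.6)),
                        strength_model = list(beta0 = 0.5, beta1 = 50,
                                              sigma = 0.5),
                        seed = 1L) {
  if (n < 3L) stop("cohort needs n >= 3")
  if (strength_model$sigma < 0) stop("sigma must be >= 0")
  for (nm in names(phantom_ranges)) {
    r <- phantom_ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("degenerate range for ", nm, ": min must not exceed max")
    if (!nm %in% c("dropout_vertical", "dropout_oblique",
                   "dropout_horizontal", "plate_fraction"))
      stop("unsupported phantom range: ", nm)
  }
  structure(list(n = as.integer(n), base_spec = base_spec,
                 phantom_ranges = phantom_ranges,
                 strength_model = strength_model, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of phantoms with strengths
#'
#' Samples `n` specimens from the phantom ranges, generates each phantom,
#' and assigns simulated strength from the generative model applied to the
#' specimen's true vBV/TV. Reproducible under the cohort seed.
#'
#' @param cohort a [cohort_spec()].
#' @param keep_volumes keep the phantom volumes/truths in the result (set
#'   FALSE for large replicate studies).
#' @return list of class `cohort_result`: `table` (one row per specimen:
#'   specimen_id, strength_kN, true_vBV_TV, true_BV_TV, sampled parameters,
#'   specimen seed) and `phantoms` (list, or NULL).
#' @export
simulate_cohort <- function(cohort, keep_volumes = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n
  rng <- cohort$phantom_ranges
  draws <- with_seed(cohort$seed, {
    par <- lapply(rng, function(r) runif(n, r[1], r[2]))
    list(par = par,
         seeds = sample.int(.Machine$integer.max - 1L, n),
         eps = rnorm(n, 0, cohort$strength_model$sigma))
  })
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- cohort$base_spec
    dp <- .dropout_vec(spec$dropout_prob)
    if (!is.null(draws$par$dropout_vertical))
      dp[["vertical"]] <- draws$par$dropout_vertical[i]
    if (!is.null(draws$par$dropout_oblique))
      dp[["oblique"]] <- draws$par$dropout_oblique[i]
    if (!is.null(draws$par$dropout_horizontal))
      dp[["horizontal"]] <- draws$par$dropout_horizontal[i]
    spec$dropout_prob <- dp
    if (!is.null(draws$par$plate_fraction))
      spec$plate_fraction <- draws$par$plate_fraction[i]
    spec$seed <- draws$seeds[i]
    ph <- generate_phantom(spec)
    sm <- cohort$strength_model
    rows[[i]] <- data.frame(
      specimen_id = sprintf("S%03d", i),
      strength_kN = sm$beta0 + sm$beta1 * ph$truth$metrics$vBV_TV +
        draws$eps[i],
      true_vBV_TV = ph$truth$metrics$vBV_TV,
      true_BV_TV = ph$truth$metrics$BV_TV,
      dropout_vertical = dp[["vertical"]],
      dropout_oblique = dp[["oblique"]],
      dropout_horizontal = dp[["horizontal"]],
      plate_fraction = spec$plate_fraction,
      seed = draws$seeds[i])
    if (keep_volumes) phantoms[[i]] <- ph
  }
  structure(list(table = do.call(rbind, rows),
                 phantoms = if (keep_volumes) phantoms else NULL,
                 spec = cohort),
            class = "cohort_result")
}

#' Redraw the strength noise of an existing cohort
#'
#' Keeps the phantoms (hence the true covariates) and redraws only the
#' Gaussian strength noise; used for replicate studies of estimator coverage
#' without regenerating volumes.
#'
#' @param cohort_result a `cohort_result`.
#' @param seed RNG seed for the new noise draw.
#' @param strength_model optional replacement generative model.
#' @return The cohort table with a fresh `strength_kN` column.
#' @export
resimulate_strength <- function(cohort_result, seed,
                                strength_model = NULL) {
  stopifnot(inherits(cohort_result, "cohort_result"))
  tab <- cohort_result$table
  sm <- strength_model %||% cohort_result$spec$strength_model
  eps <- with_seed(seed, rnorm(nrow(tab), 0, sm$sigma))
  tab$strength_kN <- sm$beta0 + sm$beta1 * tab$true_vBV_TV + eps
  tab
}
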