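# Specimen- and cohort-level drivers tying the stages together: peel ->
# segment trabeculae -> morphology -> micro-FE (intact and shell-removed) ->
# load paths.

#' Analyze one specimen end to end
#'
#' Peels the shell and endplates from a binary volume, segments and
#' classifies the trabeculae, computes the morphology report, and (optional)
#' solves the intact and shell-removed micro-FE models and the load-path
#' composition.
#'
#' @param binary a binary `labeled_volume` (use [as_binary()] on generator
#'   output or [threshold_global()] on grayscale input).
#' @param params a [peel_params()].
#' @param run_fe solve the micro-FE models?
#' @param mat,load material and load case for the FE stage.
#' @param cutoffs load-path percentile cutoffs.
#' @param rel_tol FE solver tolerance.
#' @return list: labels, tmap, morphology, and when `run_fe` is TRUE also
#'   fe_intact, fe_trab, K_intact_kN_mm, K_trab_kN_mm, load_paths (cutoff
#'   sensitivity table of the intact model).
#' @export
analyze_specimen <- function(binary, params = peel_params(), run_fe = FALSE,
                             mat = material_spec(), load = load_case(),
                             cutoffs = c(75, 80, 85, 90), rel_tol = 1e-6) {
  labels <- peel_shell_endplates(binary, params)
  trab_only <- labeled_volume((labels$data == 1L) * 1L, labels$voxel_size_um)
  skel <- skeletonize(trab_only)
  tmap <- segment_trabeculae(skel, trab_only)
  morph <- compute_morphology(labels, tmap)
  out <- list(labels = labels, tmap = tmap, morphology = morph)
  if (run_fe) {
    m_int <- build_fe_model(labels, mat, load, include_shell = TRUE)
    r_int <- fe_solve(m_int, rel_tol = rel_tol)
    m_trb <- build_fe_model(labels, mat, load, include_shell = FALSE)
    r_trb <- fe_solve(m_trb, rel_tol = rel_tol)
    vm <- element_von_mises(r_int)
    out$fe_intact <- r_int
    out$fe_trab <- r_trb
    out$K_intact_kN_mm <- stiffness(r_int)
    out$K_trab_kN_mm <- stiffness(r_trb)
    out$load_paths <- cutoff_sensitivity(vm, labels, tmap, cutoffs)
  }
  out
}

#' Run the full cohort analysis
#'
#' For every specimen of a simulated cohort: peel, classify, measure
#' morphology, and optionally solve the intact and trabecular micro-FE
#' models. Returns the cohort table augmented with the measured morphology
#' fields (and stiffnesses), ready for the statistics stage.
#'
#' @param cohort_result a `cohort_result` from [simulate_cohort()] with
#'   volumes kept.
#' @param run_fe solve FE models per specimen?
#' @param ... passed to [analyze_specimen()].
#' @return data.frame: the cohort table plus measured BV_TV, vBV_TV, oBV_TV,
#'   hBV_TV, vBV_BV, oBV_BV, hBV_BV, vBV_BV_vertebra, vBVvert_BV_vertebra,
#'   cortical_mass_fraction (and K_intact_kN_mm / K_trab_kN_mm with FE).
#' @export
run_cohort_analysis <- function(cohort_result, run_fe = FALSE, ...) {
  stopifnot(inherits(cohort_result, "cohort_result"))
  if (is.null(cohort_result$phantoms))
    stop("cohort was simulated with keep_volumes = FALSE")
  tab <- cohort_result$table
  extra <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ph <- cohort_result$phantoms[[i]]
    res <- analyze_specimen(as_binary(ph$volume), run_fe = run_fe, ...)
    row <- as.data.frame(res$morphology)
    if (run_fe) {
      row$K_intact_kN_mm <- res$K_intact_kN_mm
      row$K_trab_kN_mm <- res$K_trab_kN_mm
    }
    extra[[i]] <- row
  }
  cbind(tab, do.call(rbind, extra))
}
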