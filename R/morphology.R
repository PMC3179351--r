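# Orientation-resolved bone-fraction morphometry: the nine bone volume
# fractions plus the cortical mass fraction, all ratios of integer voxel
# counts. TV is the interior of the peeled shell/endplate boundary
# (trabecular bone + interior marrow).

#' Compute the orientation-resolved morphology report for one specimen
#'
#' Fractions computed: BV/TV; vBV/TV, oBV/TV, hBV/TV (bone volume fractions
#' of vertical/oblique/horizontal trabeculae); vBV/BV, oBV/BV, hBV/BV
#' (tissue fractions, of all trabecular bone); vBV/BV_vertebra (vertical
#' trabeculae over all bone tissue in the vertebra); vBVvert/BV_vertebra
#' (vertical trabeculae + cortical shell, over all bone tissue); and the
#' cortical mass fraction. BV_vertebra counts trabecular + shell + endplate
#' bone; the vertical vertebral tissue adds the shell only (not endplates).
#'
#' @param labels a peeled `labeled_volume` (from [peel_shell_endplates()] or
#'   a phantom's ground-truth labels).
#' @param tmap a `trabecula_map` for the same specimen.
#' @param total_volume "peeled_interior" (default; trabecular bone plus
#'   marrow inside the peeled shell/endplate boundary) or "grid" (the whole
#'   volume; for excised trabecular-bone samples without a shell).
#' @return A one-row data.frame of class `morphology_report`.
#' @export
compute_morphology <- function(labels, tmap,
                               total_volume = c("peeled_interior", "grid")) {
  total_volume <- match.arg(total_volume)
  stopifnot(inherits(labels, "labeled_volume"), inherits(tmap, "trabecula_map"))
  if (!identical(dim(labels$data), dim(tmap$ids)))
    stop("labels and trabecula map refer to different grids")
  arr <- labels$data
  n_trab <- sum(arr == 1L)
  n_shell <- sum(arr == 2L)
  n_plate <- sum(arr == 3L)

  # TV: interior of the peeled boundary = trabecular bone + interior marrow
  if (total_volume == "grid") {
    exterior <- array(FALSE, dim(arr))
    boundary <- array(FALSE, dim(arr))
  } else {
  exterior <- attr(labels, "exterior")
  boundary <- attr(labels, "boundary_region")
  if (is.null(exterior)) {
    # ground-truth labels: interior marrow = marrow not reachable from the
    # border without crossing bone
    blocked <- arr > 0L
    ext_lab <- label_components(!blocked, 6L)
    dims <- dim(arr)
    border <- array(FALSE, dims)
    border[c(1L, dims[1]), , ] <- TRUE
    border[, c(1L, dims[2]), ] <- TRUE
    border[, , c(1L, dims[3])] <- TRUE
    border_ids <- unique(ext_lab[border & ext_lab > 0L])
    exterior <- array(ext_lab %in% border_ids & !blocked, dims)
    boundary <- array(FALSE, dims)
  }
  }
  interior_marrow <- arr == 0L & !exterior & !boundary
  TV <- n_trab + sum(interior_marrow)

  reg <- tmap$registry
  if (sum(reg$voxel_count) != n_trab)
    stop("trabecula map does not cover the trabecular compartment exactly")
  vBV <- sum(reg$voxel_count[reg$orientation_class == "vertical"])
  oBV <- sum(reg$voxel_count[reg$orientation_class == "oblique"])
  hBV <- sum(reg$voxel_count[reg$orientation_class == "horizontal"])
  BV_vert <- n_trab + n_shell + n_plate

  if (TV == 0L) stop("empty trabecular compartment: TV is zero")
  bv_ratio <- function(x) if (n_trab > 0L) x / n_trab else NA_real_
  out <- data.frame(
    BV_TV = n_trab / TV,
    vBV_TV = vBV / TV,
    oBV_TV = oBV / TV,
    hBV_TV = hBV / TV,
    vBV_BV = bv_ratio(vBV),
    oBV_BV = bv_ratio(oBV),
    hBV_BV = bv_ratio(hBV),
    vBV_BV_vertebra = if (BV_vert > 0L) vBV / BV_vert else NA_real_,
    vBVvert_BV_vertebra = if (BV_vert > 0L) (vBV + n_shell) / BV_vert else NA_real_,
    cortical_mass_fraction = if (BV_vert > 0L) n_shell / BV_vert else NA_real_)
  attr(out, "counts") <- list(TV = TV, BV = n_trab, vBV = vBV, oBV = oBV,
                              hBV = hBV, shell = n_shell, endplate = n_plate)
  class(out) <- c("morphology_report", class(out))
  out
}
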