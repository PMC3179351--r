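# Load-path analysis: the highly stressed tissue (elements above a von Mises
# percentile) decomposed by compartment and trabecular orientation class.

#' Mask of highly stressed elements
#'
#' Elements with von Mises stress strictly greater than the requested
#' percentile of the bone-element stress distribution. The percentile value
#' is computed by linear interpolation over the sorted stresses.
#'
#' @param vm per-element von Mises stresses from [element_von_mises()]
#'   (bone elements only).
#' @param percentile cutoff percentile in \[0, 100).
#' @return Logical vector over the same elements; attributes of `vm`
#'   (`element_index`, `orig_index`) are carried along.
#' @export
highly_stressed_mask <- function(vm, percentile = 75) {
  if (length(vm) == 0L) stop("empty stress set")
  if (percentile < 0 || percentile >= 100) stop("percentile must lie in [0, 100)")
  cut <- unname(quantile(vm, percentile / 100, type = 7))
  mask <- as.vector(vm) > cut
  attr(mask, "element_index") <- attr(vm, "element_index")
  attr(mask, "orig_index") <- attr(vm, "orig_index")
  attr(mask, "percentile") <- percentile
  mask
}

#' Composition of the highly stressed tissue
#'
#' Fractions of above-cutoff bone elements belonging to vertical, oblique and
#' horizontal trabeculae, the cortical shell and the endplates. Measured in
#' element counts (tissue volume at uniform voxel size).
#'
#' @param mask logical element mask from [highly_stressed_mask()].
#' @param labels the peeled `labeled_volume` of the specimen.
#' @param tmap the specimen's `trabecula_map`.
#' @return One-row data.frame: percentile_cutoff and the five fractions
#'   (summing to 1).
#' @export
load_path_composition <- function(mask, labels, tmap) {
  stopifnot(inherits(labels, "labeled_volume"), inherits(tmap, "trabecula_map"))
  if (!any(mask)) stop("empty load-path mask: composition undefined")
  orig <- attr(mask, "orig_index")
  if (is.null(orig)) stop("mask carries no element-to-voxel mapping")
  sel <- orig[mask]
  lab <- labels$data[sel]
  cls <- character(length(sel))
  cls[lab == 2L] <- "shell"
  cls[lab == 3L] <- "endplate"
  tr <- lab == 1L
  if (any(tr)) {
    tid <- tmap$ids[sel[tr]]
    if (any(tid == 0L)) stop("trabecula map does not cover masked elements")
    cls[tr] <- tmap$registry$orientation_class[tid]
  }
  n <- length(cls)
  out <- data.frame(
    percentile_cutoff = attr(mask, "percentile") %||% NA_real_,
    vertical = sum(cls == "vertical") / n,
    oblique = sum(cls == "oblique") / n,
    horizontal = sum(cls == "horizontal") / n,
    shell = sum(cls == "shell") / n,
    endplate = sum(cls == "endplate") / n)
  class(out) <- c("load_path_report", class(out))
  out
}

#' Cutoff sensitivity of the load-path composition
#'
#' One composition report per percentile cutoff.
#'
#' @param vm per-element von Mises stresses (bone elements).
#' @param labels,tmap as in [load_path_composition()].
#' @param percentiles cutoffs in \[0, 100).
#' @return data.frame with one row per cutoff.
#' @export
cutoff_sensitivity <- function(vm, labels, tmap,
                               percentiles = c(75, 80, 85, 90)) {
  if (any(percentiles < 0 | percentiles >= 100))
    stop("percentiles must lie in [0, 100)")
  do.call(rbind, lapply(percentiles, function(p) {
    load_path_composition(highly_stressed_mask(vm, p), labels, tmap)
  }))
}
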