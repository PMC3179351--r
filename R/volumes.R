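# Volume containers. Arrays are (x, y, z) with axis 3 the superoinferior
# (SI) axis; compartment labels: 0 marrow, 1 trabecular bone, 2 cortical
# shell, 3 endplate.

#' Labelled voxel volume
#'
#' A 3D integer array of compartment labels plus an isotropic voxel size.
#' Labels: 0 = marrow, 1 = trabecular bone, 2 = cortical shell,
#' 3 = endplate. Axis 3 is the superoinferior (SI) axis.
#'
#' @param data 3D integer array with values in 0..3.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(data, voxel_size_um) {
  stopifnot(length(dim(data)) == 3, all(dim(data) > 0))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L | data > 3L))
    stop("labels must be integers in {0, 1, 2, 3}")
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = "labeled_volume")
}

#' Grayscale voxel volume
#'
#' @param data 3D numeric array of finite intensities.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_size_um) {
  stopifnot(length(dim(data)) == 3, all(dim(data) > 0))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("intensities must be finite")
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = "gray_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %.3g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  tab <- tabulate(x$data + 1L, nbins = 4L)
  cat(sprintf("  marrow %d | trabecular %d | shell %d | endplate %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d voxels @ %.3g um, range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size_um, min(x$data), max(x$data)))
  invisible(x)
}

#' Collapse all bone compartments of a labelled volume to a binary mask
#'
#' @param volume a `labeled_volume`.
#' @return A `labeled_volume` with labels in {0, 1} only.
#' @export
as_binary <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  labeled_volume((volume$data > 0L) * 1L, volume$voxel_size_um)
}

#' 3D connected-component labelling
#'
#' @param mask logical (or coercible) 3D array.
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  .label_components_cpp(as.logical(mask), as.integer(dim(mask)),
                        as.integer(connectivity))
}
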