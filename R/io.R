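# Volume I/O: MetaImage (.mha/.mhd + raw), NIfTI-1 (via RNifti) and numbered
# TIFF stacks; global thresholding; integer-factor coarsening.

.meta_type <- function(data) {
  if (is.integer(data)) {
    if (min(data) >= 0L && max(data) <= 255L) "MET_UCHAR" else "MET_INT"
  } else "MET_DOUBLE"
}

.meta_size <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
                MET_UINT = 4L, MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

#' Write a volume to disk
#'
#' Supported formats: MetaImage (`.mha`, uncompressed, local data; `.mhd`
#' writes a header plus sibling `.raw`), NIfTI-1 (`.nii`/`.nii.gz`), and a
#' directory of numbered TIFF slices (one per SI plane).
#'
#' @param volume a `labeled_volume` or `gray_volume`.
#' @param path output file (or directory for a TIFF stack).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, c("labeled_volume", "gray_volume")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mha", "mhd")) {
    .write_meta(volume, path, ext)
  } else if (ext == "nii" || grepl("\\.nii\\.gz$", tolower(path))) {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- rep(volume$voxel_size_um / 1000, 3)  # mm
    RNifti::writeNifti(img, path)
  } else if (ext == "" || dir.exists(path)) {
    .write_tiff_stack(volume, path)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

.write_meta <- function(volume, path, ext) {
  data <- volume$data
  type <- .meta_type(data)
  datafile <- if (ext == "mha") "LOCAL" else
    basename(sub("\\.mhd$", ".raw", path, ignore.case = TRUE))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    sprintf("ElementSpacing = %.9g %.9g %.9g", volume$voxel_size_um,
            volume$voxel_size_um, volume$voxel_size_um),
    sprintf("DimSize = %d %d %d", dim(data)[1], dim(data)[2], dim(data)[3]),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", datafile)
  )
  raw_vals <- as.vector(data)
  size <- .meta_size[[type]]
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(raw_vals, con, size = size, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    writeBin(raw_vals, con, size = size, endian = "little")
  }
}

.write_tiff_stack <- function(volume, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  data <- volume$data
  is_label <- is.integer(data)
  rng <- range(data)
  nz <- dim(data)[3]
  for (k in seq_len(nz)) {
    slice <- data[, , k]
    if (is_label) {
      tiff::writeTIFF(array(as.integer(slice), dim = c(nrow(slice), ncol(slice))) / 255,
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 8)
    } else {
      tiff::writeTIFF(slice, file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 32)
    }
  }
  meta <- list(voxel_size_um = volume$voxel_size_um,
               kind = if (is_label) "labeled" else "gray",
               dim = dim(data), range = rng)
  jsonlite::write_json(meta, file.path(path, "stack.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a volume from disk
#'
#' Reads MetaImage, NIfTI-1, or a numbered TIFF stack directory. The voxel
#' size is taken from the header (MetaImage `ElementSpacing`, NIfTI
#' `pixdim`); anisotropic spacing is rejected. TIFF stacks carry no spacing,
#' so `voxel_size_um` is required for them (a `stack.json` sidecar written by
#' [write_volume()] is honoured).
#'
#' @param path file or TIFF-stack directory.
#' @param format_hint optional: one of "mha", "nii", "tiff".
#' @param voxel_size_um override / supply the voxel size in micrometres.
#' @return A `labeled_volume` (integer data in 0..3) or `gray_volume`.
#' @export
read_volume <- function(path, format_hint = NULL, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- format_hint %||%
    if (ext %in% c("mha", "mhd")) "mha"
    else if (ext == "nii" || grepl("\\.nii\\.gz$", tolower(path))) "nii"
    else if (dir.exists(path)) "tiff"
    else stop("cannot infer format of ", path)
  out <- switch(fmt,
    mha = .read_meta(path),
    nii = .read_nifti(path),
    tiff = .read_tiff_stack(path, voxel_size_um),
    stop("unknown format_hint: ", fmt))
  if (!is.null(voxel_size_um)) out$voxel_size_um <- voxel_size_um
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_meta <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("MetaImage header truncated: missing ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (req in c("DimSize", "ElementSpacing", "ElementType"))
    if (is.null(hdr[[req]])) stop("MetaImage header missing field: ", req)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("MetaImage field CompressedData = True is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  if (length(dims) != 3) stop("MetaImage field DimSize: expected 3 dimensions")
  if (length(unique(sp)) != 1)
    stop("MetaImage field ElementSpacing: anisotropic spacing is not supported")
  type <- hdr$ElementType
  if (!type %in% names(.meta_size))
    stop("MetaImage field ElementType: unsupported type ", type)
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) &&
    toupper(hdr$BinaryDataByteOrderMSB) == "TRUE"
  n <- prod(dims)
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  if (hdr$ElementDataFile == "LOCAL") {
    vals <- readBin(con, what, n = n, size = .meta_size[[type]],
                    signed = signed || .meta_size[[type]] >= 4,
                    endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage data file not found: ", rawpath)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- readBin(con2, what, n = n, size = .meta_size[[type]],
                    signed = signed || .meta_size[[type]] >= 4,
                    endian = if (msb) "big" else "little")
  }
  if (length(vals) != n) stop("MetaImage data shorter than DimSize implies")
  arr <- array(vals, dim = dims)
  if (what == "integer" && all(vals >= 0 & vals <= 3))
    labeled_volume(arr, sp[1]) else gray_volume(arr, sp[1])
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (length(unique(round(pd, 9))) != 1)
    stop("NIfTI field pixdim: anisotropic spacing is not supported")
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  vs_um <- signif(pd[1] * 1000, 6)  # spacing in mm, float32 header precision
  if (all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 3)
    labeled_volume(array(as.integer(arr), dim = dim(arr)), vs_um)
  else gray_volume(arr, vs_um)
}

.read_tiff_stack <- function(path, voxel_size_um) {
  meta_path <- file.path(path, "stack.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  vs <- voxel_size_um %||% meta$voxel_size_um
  if (is.null(vs)) stop("TIFF stacks carry no spacing; supply voxel_size_um")
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0) stop("no TIFF slices found in ", path)
  slices <- lapply(files, tiff::readTIFF)
  d1 <- dim(slices[[1]])
  arr <- array(0, dim = c(d1[1], d1[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  if (!is.null(meta) && identical(meta$kind, "labeled")) {
    labeled_volume(array(as.integer(round(arr * 255)), dim = dim(arr)), vs)
  } else gray_volume(arr, vs)
}

#' Segment a grayscale volume with a global threshold
#'
#' Voxels with intensity at or above `t` become bone (label 1), the rest
#' marrow (label 0). No compartment distinction is made at this stage.
#'
#' @param gray a `gray_volume`.
#' @param t finite threshold intensity.
#' @return A binary `labeled_volume`.
#' @export
threshold_global <- function(gray, t) {
  stopifnot(inherits(gray, "gray_volume"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t))
    stop("threshold t must be a single finite number")
  labeled_volume((gray$data >= t) * 1L, gray$voxel_size_um)
}

# block mean along one axis by integer factor (axis pre-padded to a multiple)
.block_reduce_axis <- function(arr, axis, factor) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(factor, d[axis] / factor, prod(d[-axis]))
  x <- colMeans(x)
  dim(x) <- c(d[axis] / factor, d[perm[2]], d[perm[3]])
  aperm(x, order(perm))
}

#' Coarsen a volume by an integer factor
#'
#' Block mean over `factor`^3 blocks. Binary volumes are re-thresholded at a
#' block mean of 0.5, ties resolving to bone. Grids not divisible by the
#' factor are zero-padded at the high-index ends. The voxel size is
#' multiplied by the factor.
#'
#' @param volume a `gray_volume` or binary `labeled_volume`.
#' @param factor positive integer.
#' @return A volume of the same class.
#' @export
coarsen <- function(volume, factor) {
  stopifnot(inherits(volume, c("labeled_volume", "gray_volume")))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  is_lab <- inherits(volume, "labeled_volume")
  if (is_lab && any(volume$data > 1L))
    stop("coarsen() expects a binary volume; peel compartments after coarsening")
  arr <- volume$data * 1.0
  d <- dim(arr)
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0)) {
    padded <- array(0, dim = d + pad)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- padded
  }
  for (ax in 1:3) arr <- .block_reduce_axis(arr, ax, factor)
  vs <- volume$voxel_size_um * factor
  if (is_lab) labeled_volume((arr >= 0.5) * 1L, vs) else gray_volume(arr, vs)
}
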