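# Compartment segmentation: digitally isolate the trabecular compartment
# from the cortical shell and endplates. Lateral rays per SI slice record the
# first-entered bone run; run thickness is smoothed by a moving average along
# the boundary (bridging locally porous patches), and the voxels within the
# smoothed thickness of the exterior surface become shell. The analogous
# procedure along SI rays within a search depth yields the endplates.

#' Peeling parameters
#'
#' @param window_vox odd moving-average window (>= 3) used to smooth the
#'   boundary thickness along the shell surface.
#' @param max_bridge_vox maximum entry-depth deviation bridged when the shell
#'   is locally porous.
#' @param endplate_search_depth_vox depth from the top/bottom bone surface
#'   searched for endplate plates.
#' @return An object of class `peel_params`.
#' @export
peel_params <- function(window_vox = 5L, max_bridge_vox = 2L,
                        endplate_search_depth_vox = 10L) {
  if (window_vox < 3L || window_vox %% 2L == 0L)
    stop("window_vox must be odd and >= 3")
  if (max_bridge_vox < 1L || endplate_search_depth_vox < 1L)
    stop("max_bridge_vox and endplate_search_depth_vox must be positive")
  structure(list(window_vox = as.integer(window_vox),
                 max_bridge_vox = as.integer(max_bridge_vox),
                 endplate_search_depth_vox = as.integer(endplate_search_depth_vox)),
            class = "peel_params")
}

# running (clamped-window) sum along rows of a matrix
.runsum_rows <- function(m, w) {
  h <- (w - 1L) %/% 2L
  n <- nrow(m)
  cs <- apply(m, 2L, cumsum)
  if (n == 1L) cs <- matrix(cs, nrow = 1L)
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  cs0 <- rbind(matrix(0, 1L, ncol(m)), cs)
  cs[hi, , drop = FALSE] - cs0[lo, , drop = FALSE]
}

# 2D moving-average with NA handling; returns NA where the window is empty
.box_mean <- function(m, w) {
  vals <- ifelse(is.na(m), 0, m)
  cnt <- (!is.na(m)) * 1
  sv <- t(.runsum_rows(t(.runsum_rows(vals, w)), w))
  sc <- t(.runsum_rows(t(.runsum_rows(cnt, w)), w))
  out <- sv / sc
  out[sc == 0] <- NA
  out
}

# 2D moving median with NA handling (windows clamped at the edges)
.box_median <- function(m, w) {
  h <- (w - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  A <- array(NA_real_, dim = c(n1, n2, (2L * h + 1L)^2))
  k <- 0L
  for (dx in -h:h) for (dy in -h:h) {
    k <- k + 1L
    sx <- intersect(seq_len(n1), seq_len(n1) + dx)
    sy <- intersect(seq_len(n2), seq_len(n2) + dy)
    A[sx - dx, sy - dy, k] <- m[sx, sy]
  }
  apply(A, c(1, 2), median, na.rm = TRUE)
}

# fraction of valid rays in the window (window size included empty cells)
.box_frac <- function(valid, w) {
  v <- valid * 1
  sv <- t(.runsum_rows(t(.runsum_rows(v, w)), w))
  n <- t(.runsum_rows(t(.runsum_rows(matrix(1, nrow(v), ncol(v)), w)), w))
  sv / n
}

# first bone run along dim 1 (from index 1): entry index and run length;
# marrow gaps up to `bridge` voxels inside the run are crossed (pores)
.first_run <- function(B, bridge = 0L) {
  n1 <- dim(B)[1]
  M <- matrix(B, nrow = n1)
  res <- apply(M, 2L, function(v) {
    i <- which(v)
    if (length(i) == 0L) return(c(NA_integer_, NA_integer_))
    a <- i[1]
    gaps <- which(diff(i) > bridge + 1L)
    b <- if (length(gaps) == 0L) i[length(i)] else i[gaps[1]]
    c(a, b - a + 1L)
  })
  list(D = matrix(res[1L, ], dim(B)[2], dim(B)[3]),
       T = matrix(res[2L, ], dim(B)[2], dim(B)[3]))
}

# orientations of the 6 ray families: (axis the ray runs along, from low end?)
.ray_views <- list(
  list(axis = 1L, rev = FALSE), list(axis = 1L, rev = TRUE),
  list(axis = 2L, rev = FALSE), list(axis = 2L, rev = TRUE),
  list(axis = 3L, rev = FALSE), list(axis = 3L, rev = TRUE))

# permute so the ray axis is dim 1 ascending from the ray origin
.to_view <- function(arr, view) {
  perm <- c(view$axis, setdiff(1:3, view$axis))
  x <- aperm(arr, perm)
  if (view$rev) x <- x[dim(x)[1]:1, , , drop = FALSE]
  x
}
.from_view <- function(x, view) {
  if (view$rev) x <- x[dim(x)[1]:1, , , drop = FALSE]
  aperm(x, order(c(view$axis, setdiff(1:3, view$axis))))
}

# mark ray intervals [a, b] in view coordinates
.mark_rays <- function(dims, a, b) {
  out <- array(FALSE, dim = dims)
  n1 <- dims[1]
  ok <- which(!is.na(a) & !is.na(b) & b >= a)
  for (k in ok) {
    lo <- max(1L, a[k]); hi <- min(n1, b[k])
    if (lo > hi) next
    p2 <- (k - 1L) %% dims[2] + 1L
    p3 <- (k - 1L) %/% dims[2] + 1L
    out[lo:hi, p2, p3] <- TRUE
  }
  out
}

.span <- function(idx) if (length(idx) == 0L) 0L else diff(range(idx)) + 1L

#' Peel the cortical shell and endplates from a binary volume
#'
#' Relabels bone voxels of a binary volume as trabecular, shell or endplate.
#' The bone voxel count is conserved; only labels change. See the package
#' vignette for the full algorithm.
#'
#' @param binary a `labeled_volume` with labels in {0, 1}.
#' @param params a [peel_params()].
#' @return A `labeled_volume` with labels 0..3. Attributes: `boundary_region`
#'   (the smoothed shell/endplate wall region, including pores) and
#'   `exterior` (exterior marrow mask), both logical arrays used downstream
#'   to delimit the trabecular compartment.
#' @export
peel_shell_endplates <- function(binary, params = peel_params()) {
  stopifnot(inherits(binary, "labeled_volume"), inherits(params, "peel_params"))
  if (any(binary$data > 1L))
    stop("peel_shell_endplates() expects a binary {marrow, bone} volume")
  bone <- binary$data == 1L
  dims <- dim(bone)
  w <- params$window_vox; bridge <- params$max_bridge_vox

  border <- array(FALSE, dims)
  border[c(1L, dims[1]), , ] <- TRUE
  border[, c(1L, dims[2]), ] <- TRUE
  border[, , c(1L, dims[3])] <- TRUE
  if (!any(!bone & border))
    stop("volume is entirely bone at the border: no exterior background")

  shell_cand <- array(FALSE, dims)
  plate_cand <- array(FALSE, dims)
  boundary <- array(FALSE, dims)

  for (vi in seq_along(.ray_views)) {
    view <- .ray_views[[vi]]
    lateral <- view$axis != 3L
    B <- .to_view(bone, view)
    fr <- .first_run(B)
    D <- fr$D; Tn <- fr$T
    if (all(is.na(D))) next
    Dm <- median(D, na.rm = TRUE)
    valid <- !is.na(D) &
      (if (lateral) abs(D - Dm) <= bridge
       else D <= params$endplate_search_depth_vox)
    # a wall/endplate must be seen coherently by most rays of the family
    if (mean(valid) < 0.5) next
    Tm <- median(Tn[valid])
    # runs continuing into deeper structure (wall + abutting trabecula or
    # endplate) or cut short by a pore carry no thickness information:
    # impute those from the neighbourhood moving average
    Tv <- ifelse(valid & abs(Tn - Tm) <= bridge, Tn, NA)
    Ds <- .box_mean(ifelse(valid, D, NA), w)
    Ts <- .box_median(Tv, w)
    Ts[is.na(Ts)] <- Tm
    cov <- .box_frac(valid, w)
    use <- !is.na(Ds) & cov >= 1 / 3
    a <- ifelse(use, as.integer(round(Ds)), NA_integer_)
    b <- a + ifelse(use, as.integer(round(Ts)), NA_integer_) - 1L
    marked <- .mark_rays(dim(B), a, b)
    marked_back <- .from_view(marked, view)
    boundary <- boundary | marked_back
    if (lateral) shell_cand <- shell_cand | (marked_back & bone)
    else plate_cand <- plate_cand | (marked_back & bone)
  }

  bone_idx <- which(bone, arr.ind = TRUE)
  xext <- .span(bone_idx[, 1]); yext <- .span(bone_idx[, 2])
  zext <- .span(bone_idx[, 3])

  # a shell component must span the structure's height and one lateral extent
  if (any(shell_cand)) {
    comps <- label_components(shell_cand, 26L)
    keep <- array(FALSE, dims)
    for (id in seq_len(max(comps))) {
      ci <- which(comps == id, arr.ind = TRUE)
      if (.span(ci[, 3]) >= 0.5 * zext &&
          max(.span(ci[, 1]) / xext, .span(ci[, 2]) / yext) >= 0.5)
        keep[ci] <- TRUE
    }
    shell_cand <- keep
  }
  # an endplate component must span both lateral extents
  if (any(plate_cand)) {
    comps <- label_components(plate_cand, 26L)
    keep <- array(FALSE, dims)
    for (id in seq_len(max(comps))) {
      ci <- which(comps == id, arr.ind = TRUE)
      if (.span(ci[, 1]) >= 0.5 * xext && .span(ci[, 2]) >= 0.5 * yext)
        keep[ci] <- TRUE
    }
    plate_cand <- keep
  }

  out <- array(0L, dims)
  out[bone] <- 1L
  out[plate_cand] <- 3L
  out[shell_cand] <- 2L   # corners resolve to shell

  # exterior marrow: flood from the border, blocked by bone and by the
  # smoothed boundary region (so shell pores do not leak the interior)
  blocked <- bone | (boundary & (shell_cand | plate_cand | !bone))
  ext_lab <- label_components(!blocked, 6L)
  border_ids <- unique(ext_lab[border & ext_lab > 0L])
  exterior <- array(ext_lab %in% border_ids & !blocked, dims)

  res <- labeled_volume(out, binary$voxel_size_um)
  attr(res, "boundary_region") <- shell_cand | plate_cand | (boundary & !bone)
  attr(res, "exterior") <- exterior
  res
}

#' Cortical mass fraction
#'
#' Shell bone volume divided by total bone volume of the vertebra.
#'
#' @param labels a `labeled_volume` with compartment labels.
#' @return A fraction in \[0, 1\].
#' @export
cortical_mass_fraction <- function(labels) {
  stopifnot(inherits(labels, "labeled_volume"))
  nb <- sum(labels$data > 0L)
  if (nb == 0L) stop("cortical mass fraction undefined: no bone voxels")
  sum(labels$data == 2L) / nb
}
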