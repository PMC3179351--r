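# Synthetic vertebral-body phantoms: a lattice of vertical columns (a stated
# fraction realized as plates), horizontal in-plane beams, oblique struts
# rasterized by 3D line drawing, a closed (optionally porous) lateral cortical
# wall, and endplates capping the structure. Every voxel carries ground-truth
# compartment and orientation labels so all downstream stages are testable.

#' Phantom specification
#'
#' @param grid_shape voxels per axis (3 positive integers); axis 3 is SI.
#' @param voxel_size_um isotropic voxel edge length (micrometres).
#' @param vertical_strut,horizontal_strut list(thickness_vox, spacing_vox).
#' @param oblique_strut list(thickness_vox, spacing_vox, angle_deg) with
#'   angle_deg in (30, 60), measured from the SI axis.
#' @param plate_fraction fraction of vertical lattice rows realized as plates.
#' @param shell_thickness_vox lateral cortical wall thickness (0 = no wall).
#' @param endplate_thickness_vox endplate cap thickness (0 = no caps).
#' @param shell_hole_prob per-voxel probability of punching a hole in the
#'   wall (models shell porosity; default 0).
#' @param dropout_prob probability each strut is deleted (models trabecular
#'   loss); a scalar or a named vector with entries `vertical`, `oblique`,
#'   `horizontal`.
#' @param margin_vox marrow margin outside the wall so the exterior is
#'   flood-fillable from the volume border.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 80L),
                         voxel_size_um = 60,
                         vertical_strut = list(thickness_vox = 3L, spacing_vox = 14L),
                         horizontal_strut = list(thickness_vox = 3L, spacing_vox = 16L),
                         oblique_strut = list(thickness_vox = 3L, spacing_vox = 16L,
                                              angle_deg = 45),
                         plate_fraction = 0.25,
                         shell_thickness_vox = 3L,
                         endplate_thickness_vox = 3L,
                         shell_hole_prob = 0,
                         dropout_prob = 0,
                         margin_vox = 2L,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_um = voxel_size_um,
               vertical_strut = vertical_strut,
               horizontal_strut = horizontal_strut,
               oblique_strut = oblique_strut,
               plate_fraction = plate_fraction,
               shell_thickness_vox = as.integer(shell_thickness_vox),
               endplate_thickness_vox = as.integer(endplate_thickness_vox),
               shell_hole_prob = shell_hole_prob,
               dropout_prob = dropout_prob,
               margin_vox = as.integer(margin_vox),
               seed = seed)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  g <- spec$grid_shape
  if (length(g) != 3 || any(g <= 0)) stop("grid_shape must be 3 positive integers")
  if (spec$voxel_size_um <= 0) stop("voxel_size_um must be positive")
  for (nm in c("vertical_strut", "horizontal_strut", "oblique_strut")) {
    s <- spec[[nm]]
    if (s$thickness_vox < 1 || s$spacing_vox < 1)
      stop(nm, ": thickness and spacing must be positive")
    if (s$thickness_vox >= s$spacing_vox)
      stop(nm, ": strut thickness must be smaller than spacing")
  }
  a <- spec$oblique_strut$angle_deg
  if (a <= 30 || a >= 60) stop("oblique_strut$angle_deg must lie in (30, 60)")
  if (spec$plate_fraction < 0 || spec$plate_fraction > 1)
    stop("plate_fraction must lie in [0, 1]")
  if (spec$shell_thickness_vox < 0 || spec$endplate_thickness_vox < 0 ||
      spec$margin_vox < 0)
    stop("shell, endplate and margin thicknesses must be non-negative")
  dp <- .dropout_vec(spec$dropout_prob)
  if (any(dp < 0) || any(dp >= 1)) stop("dropout_prob must lie in [0, 1)")
  if (spec$shell_hole_prob < 0 || spec$shell_hole_prob >= 1)
    stop("shell_hole_prob must lie in [0, 1)")
  lo <- spec$margin_vox + spec$shell_thickness_vox + 1L
  hi_x <- g[1] - spec$margin_vox - spec$shell_thickness_vox
  hi_y <- g[2] - spec$margin_vox - spec$shell_thickness_vox
  zlo <- spec$margin_vox + spec$endplate_thickness_vox + 1L
  zhi <- g[3] - spec$margin_vox - spec$endplate_thickness_vox
  if (hi_x - lo + 1 < spec$vertical_strut$spacing_vox ||
      hi_y - lo + 1 < spec$vertical_strut$spacing_vox ||
      zhi - zlo + 1 < 2)
    stop("geometry does not fit: shell/endplates/struts exceed grid_shape")
  invisible(spec)
}

.dropout_vec <- function(dp) {
  if (length(dp) == 1 && is.null(names(dp)))
    return(c(vertical = dp, oblique = dp, horizontal = dp))
  out <- c(vertical = 0, oblique = 0, horizontal = 0)
  out[names(dp)] <- dp
  out
}

# lattice start positions for struts of thickness t inside [lo, hi]
.lat <- function(lo, hi, t, by) {
  if (lo + 1L > hi - t) integer(0) else seq(lo + 1L, hi - t, by = by)
}

# interior bounds (1-based, inclusive) of the trabecular compartment
.phantom_interior <- function(spec) {
  g <- spec$grid_shape
  m <- spec$margin_vox; s <- spec$shell_thickness_vox
  e <- spec$endplate_thickness_vox
  list(x = c(m + s + 1L, g[1] - m - s), y = c(m + s + 1L, g[2] - m - s),
       z = c(m + e + 1L, g[3] - m - e))
}

#' Generate a voxelized vertebral-body phantom
#'
#' Vertical struts are SI-aligned columns (a fraction realized as plates
#' whose plane contains the SI axis), horizontal struts are axis-aligned
#' in-plane beams, oblique struts are 3D lines at the stated angle from the
#' SI axis dilated to thickness. A closed lateral wall of the stated
#' thickness (optionally porous) and endplate caps enclose the compartment.
#' Deterministic for a fixed spec (including seed).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a `labeled_volume` with compartment labels),
#'   `truth` (per-voxel orientation array: 0 none, 1 vertical, 2 oblique,
#'   3 horizontal; plus exact per-specimen metrics), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- spec$grid_shape
  m <- spec$margin_vox; s <- spec$shell_thickness_vox
  e <- spec$endplate_thickness_vox
  inr <- .phantom_interior(spec)
  xlo <- inr$x[1]; xhi <- inr$x[2]; ylo <- inr$y[1]; yhi <- inr$y[2]
  zlo <- inr$z[1]; zhi <- inr$z[2]
  dp <- .dropout_vec(spec$dropout_prob)

  orient <- array(0L, dim = g)     # 0 none, 1 vertical, 2 oblique, 3 horizontal
  comp <- array(0L, dim = g)

  with_seed(spec$seed, {
    tv <- spec$vertical_strut$thickness_vox
    sv <- spec$vertical_strut$spacing_vox
    xs <- .lat(xlo, xhi, tv, sv)
    ys <- .lat(ylo, yhi, tv, sv)
    plate_row <- runif(length(ys)) < spec$plate_fraction

    th <- spec$horizontal_strut$thickness_vox
    sh <- spec$horizontal_strut$spacing_vox
    ys_h <- .lat(ylo, yhi, th, sh)
    xs_h <- .lat(xlo, xhi, th, sh)
    zs_h <- .lat(zlo, zhi, th, sh)

    to <- spec$oblique_strut$thickness_vox
    so <- spec$oblique_strut$spacing_vox
    ang <- spec$oblique_strut$angle_deg
    xs_o <- .lat(xlo, xhi, to, so)
    ys_o <- .lat(ylo, yhi, to, so)

    # --- horizontal beams (painted first; vertical wins overlaps) ---------
    k <- 0L
    for (zc in zs_h) {
      k <- k + 1L
      zz <- zc:min(zc + th - 1L, zhi)
      if (k %% 2L == 1L) {
        for (yc in ys_h) {
          if (runif(1) < dp[["horizontal"]]) next
          orient[xlo:xhi, yc:(yc + th - 1L), zz] <- 3L
        }
      } else {
        for (xc in xs_h) {
          if (runif(1) < dp[["horizontal"]]) next
          orient[xc:(xc + th - 1L), ylo:yhi, zz] <- 3L
        }
      }
    }

    # --- oblique struts: nearest-voxel 3D lines dilated to thickness ------
    slope <- tan(ang * pi / 180)   # lateral advance per SI voxel
    oi <- 0L
    for (y0 in ys_o) {
      for (x0 in xs_o) {
        oi <- oi + 1L
        if (runif(1) < dp[["oblique"]]) next
        dir <- if (oi %% 2L == 0L) 1 else -1
        W <- xhi - xlo - to + 1L   # lateral travel folds back at the walls
        for (z in zlo:zhi) {
          xraw <- (x0 - xlo) + dir * slope * (z - zlo)
          xfold <- abs((xraw %% (2 * W)) - W)  # triangular reflection
          xc <- xlo + as.integer(round(W - xfold))
          orient[xc:(xc + to - 1L), y0:(y0 + to - 1L), z] <- 2L
        }
      }
    }

    # --- vertical columns and plates (painted last: vertical wins) --------
    for (j in seq_along(ys)) {
      yc <- ys[j]
      if (plate_row[j]) {
        if (runif(1) < dp[["vertical"]]) next
        orient[xlo:xhi, yc:(yc + tv - 1L), zlo:zhi] <- 1L
      } else {
        for (xc in xs) {
          if (runif(1) < dp[["vertical"]]) next
          orient[xc:(xc + tv - 1L), yc:(yc + tv - 1L), zlo:zhi] <- 1L
        }
      }
    }

    comp[orient > 0L] <- 1L

    # --- endplates (footprint inside the wall ring) ------------------------
    if (e > 0L) {
      fx <- (m + s + 1L):(g[1] - m - s); fy <- (m + s + 1L):(g[2] - m - s)
      comp[fx, fy, (m + 1L):(m + e)] <- 3L
      comp[fx, fy, (g[3] - m - e + 1L):(g[3] - m)] <- 3L
    }

    # --- lateral cortical wall, full structure height; corners are shell ---
    if (s > 0L) {
      wx <- (m + 1L):(g[1] - m); wy <- (m + 1L):(g[2] - m)
      wz <- (m + 1L):(g[3] - m)
      wall <- array(FALSE, dim = g)
      wall[(m + 1L):(m + s), wy, wz] <- TRUE
      wall[(g[1] - m - s + 1L):(g[1] - m), wy, wz] <- TRUE
      wall[wx, (m + 1L):(m + s), wz] <- TRUE
      wall[wx, (g[2] - m - s + 1L):(g[2] - m), wz] <- TRUE
      if (spec$shell_hole_prob > 0) {
        idx <- which(wall)
        punch <- idx[runif(length(idx)) < spec$shell_hole_prob]
        wall[punch] <- FALSE
      }
      comp[wall] <- 2L
    }
  })

  tv_true <- prod(c(xhi - xlo + 1L, yhi - ylo + 1L, zhi - zlo + 1L))
  counts <- list(
    TV = tv_true,
    BV = sum(comp == 1L),
    vBV = sum(comp == 1L & orient == 1L),
    oBV = sum(comp == 1L & orient == 2L),
    hBV = sum(comp == 1L & orient == 3L),
    shell = sum(comp == 2L),
    endplate = sum(comp == 3L))
  metrics <- list(
    BV_TV = counts$BV / counts$TV,
    vBV_TV = counts$vBV / counts$TV,
    oBV_TV = counts$oBV / counts$TV,
    hBV_TV = counts$hBV / counts$TV,
    vBV_BV = if (counts$BV > 0) counts$vBV / counts$BV else NA_real_,
    cortical_mass_fraction =
      counts$shell / (counts$BV + counts$shell + counts$endplate))

  orient[comp != 1L] <- 0L
  list(volume = labeled_volume(comp, spec$voxel_size_um),
       truth = list(compartment = comp, orientation = orient,
                    counts = counts, metrics = metrics),
       spec = spec)
}

#' Rasterize a single rod at a stated angle to the SI axis
#'
#' Draws a straight rod through the grid centre with polar angle `angle_deg`
#' from the SI axis and the given azimuth, dilated to `thickness_vox`
#' (nearest-voxel line drawing). Used to probe orientation recovery.
#'
#' @param angle_deg polar angle from the SI axis, degrees in \[0, 90\].
#' @param azimuth_deg in-plane direction of tilt, degrees.
#' @param length_vox rod length in voxels.
#' @param thickness_vox rod thickness in voxels.
#' @param voxel_size_um voxel size.
#' @param pad_vox marrow padding around the rod.
#' @return A binary `labeled_volume` containing the rod.
#' @export
generate_rod_phantom <- function(angle_deg, azimuth_deg = 0, length_vox = 48L,
                                 thickness_vox = 3L, voxel_size_um = 60,
                                 pad_vox = 4L) {
  stopifnot(angle_deg >= 0, angle_deg <= 90)
  th <- angle_deg * pi / 180; ph <- azimuth_deg * pi / 180
  d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  half <- length_vox / 2
  ext <- ceiling(abs(d) * half) + thickness_vox + pad_vox
  dims <- as.integer(2 * ext + 1)
  ctr <- ext + 1
  arr <- array(0L, dim = dims)
  r <- (thickness_vox - 1) / 2
  steps <- seq(-half, half, by = 0.4)
  for (t in steps) {
    p <- round(ctr + d * t)
    xr <- max(1, p[1] - floor(r)):min(dims[1], p[1] + ceiling(r))
    yr <- max(1, p[2] - floor(r)):min(dims[2], p[2] + ceiling(r))
    zr <- max(1, p[3] - floor(r)):min(dims[3], p[3] + ceiling(r))
    arr[xr, yr, zr] <- 1L
  }
  labeled_volume(arr, voxel_size_um)
}

#' Overlay grayscale intensities and Gaussian noise on a binary volume
#'
#' @param volume a `labeled_volume` (any bone label counts as bone).
#' @param bone_level,marrow_level class mean intensities; bone must exceed
#'   marrow.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return A `gray_volume`.
#' @export
add_grayscale_noise <- function(volume, bone_level = 200, marrow_level = 50,
                                noise_sd = 10, seed = 1L) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (bone_level <= marrow_level) stop("bone_level must exceed marrow_level")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  base <- ifelse(volume$data > 0L, bone_level, marrow_level)
  gray <- with_seed(seed, base + rnorm(length(base), 0, noise_sd))
  gray_volume(array(gray, dim = dim(volume$data)), volume$voxel_size_um)
}
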