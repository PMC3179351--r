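# Voxel micro-FE: every bone voxel becomes an 8-noded hexahedral element with
# homogeneous isotropic tissue properties; PMMA layers are appended above and
# below; the model is compressed to a stated apparent strain and solved by
# matrix-free Jacobi-preconditioned conjugate gradients.

#' Material specification
#'
#' @param tissue_modulus_GPa hard-tissue elastic modulus (GPa).
#' @param tissue_poisson hard-tissue Poisson's ratio.
#' @param pmma_modulus_GPa PMMA layer modulus (GPa).
#' @param pmma_poisson PMMA Poisson's ratio.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(tissue_modulus_GPa = 10, tissue_poisson = 0.3,
                          pmma_modulus_GPa = 2.5, pmma_poisson = 0.3) {
  if (tissue_modulus_GPa <= 0 || pmma_modulus_GPa <= 0)
    stop("moduli must be positive")
  if (tissue_poisson < 0 || tissue_poisson >= 0.5 ||
      pmma_poisson < 0 || pmma_poisson >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5)")
  structure(list(tissue_modulus_GPa = tissue_modulus_GPa,
                 tissue_poisson = tissue_poisson,
                 pmma_modulus_GPa = pmma_modulus_GPa,
                 pmma_poisson = pmma_poisson), class = "material_spec")
}

#' Load case
#'
#' @param apparent_strain applied compressive apparent strain (displacement
#'   over total model height including PMMA).
#' @param bc_mode "frictionless" (lateral dofs free on the loaded faces, one
#'   corner pinned) or "bonded" (all dofs fixed on both faces).
#' @param pmma_layer_thickness_vox PMMA layer thickness in voxels.
#' @return An object of class `load_case`.
#' @export
load_case <- function(apparent_strain = 0.01,
                      bc_mode = c("frictionless", "bonded"),
                      pmma_layer_thickness_vox = 3L) {
  bc_mode <- match.arg(bc_mode)
  if (apparent_strain <= 0) stop("apparent_strain must be positive")
  if (pmma_layer_thickness_vox < 0) stop("PMMA thickness must be >= 0")
  structure(list(apparent_strain = apparent_strain, bc_mode = bc_mode,
                 pmma_layer_thickness_vox = as.integer(pmma_layer_thickness_vox)),
            class = "load_case")
}

# trilinear hexahedron: node offsets and natural coordinates
.hex_offsets <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                      c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))

# isotropic elasticity matrix (Voigt xx, yy, zz, xy, yz, zx; engineering shear)
.elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# B matrix (6 x 24) at natural coordinates (xi, eta, zeta); cube edge h (mm)
.hex_B <- function(xi, eta, zeta, h) {
  xa <- 2 * .hex_offsets - 1
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    dN <- c(xa[a, 1] * (1 + xa[a, 2] * eta) * (1 + xa[a, 3] * zeta),
            xa[a, 2] * (1 + xa[a, 1] * xi) * (1 + xa[a, 3] * zeta),
            xa[a, 3] * (1 + xa[a, 1] * xi) * (1 + xa[a, 2] * eta)) / 8 * (2 / h)
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[1]
    B[2, c0 + 2] <- dN[2]
    B[3, c0 + 3] <- dN[3]
    B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
    B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
    B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
  }
  B
}

#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' 2x2x2 Gauss quadrature (exact for the trilinear integrand). Units: E in
#' MPa, edge length h in mm, so stiffness entries are N/mm.
#'
#' @param E elastic modulus (MPa).
#' @param nu Poisson's ratio.
#' @param h cube edge length (mm).
#' @return 24 x 24 symmetric matrix.
#' @export
fe_hex_ke <- function(E, nu, h) {
  D <- .elastic_D(E, nu)
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- .hex_B(xi, eta, zeta, h)
    Ke <- Ke + t(B) %*% D %*% B * (h / 2)^3
  }
  (Ke + t(Ke)) / 2
}

#' Build a voxel micro-FE model from a labelled volume
#'
#' Every bone voxel (shell voxels dropped when `include_shell` is FALSE;
#' trabecular and endplate voxels always kept) becomes one hexahedral element
#' with tissue properties. PMMA layers of the stated thickness, spanning the
#' full cross-section, are appended above and below the bone. Components not
#' face-connected to both loaded faces are removed before solving (their
#' count is reported in the model).
#'
#' @param labels a `labeled_volume` with compartment labels.
#' @param mat a [material_spec()].
#' @param load a [load_case()].
#' @param include_shell keep shell elements?
#' @return An object of class `fe_model`.
#' @export
build_fe_model <- function(labels, mat = material_spec(), load = load_case(),
                           include_shell = TRUE) {
  stopifnot(inherits(labels, "labeled_volume"), inherits(mat, "material_spec"),
            inherits(load, "load_case"))
  arr <- labels$data
  keep <- arr == 1L | arr == 3L | (include_shell & arr == 2L)
  if (!any(keep)) stop("no bone elements in the model")
  d <- dim(arr)
  zr <- range(which(apply(keep, 3, any)))
  p <- load$pmma_layer_thickness_vox
  nzm <- (zr[2] - zr[1] + 1L) + 2L * p
  emask <- array(FALSE, dim = c(d[1], d[2], nzm))
  emask[, , seq_len(nzm) > p & seq_len(nzm) <= nzm - p] <-
    keep[, , zr[1]:zr[2]]
  is_pmma <- array(FALSE, dim = dim(emask))
  if (p > 0L) {
    is_pmma[, , 1:p] <- TRUE
    is_pmma[, , (nzm - p + 1L):nzm] <- TRUE
    emask <- emask | is_pmma
  }

  # keep only face-connected components spanning bottom to top
  comps <- label_components(emask, 6L)
  bottom_ids <- unique(comps[, , 1][emask[, , 1]])
  top_ids <- unique(comps[, , nzm][emask[, , nzm]])
  span_ids <- intersect(bottom_ids, top_ids)
  if (length(span_ids) == 0L)
    stop("no connected load path between the loaded faces")
  connected <- array(comps %in% span_ids & emask, dim = dim(emask))
  n_removed <- sum(emask) - sum(connected)
  emask <- connected

  eidx <- which(emask, arr.ind = TRUE)
  nel <- nrow(eidx)
  pm <- is_pmma[emask]
  matid <- ifelse(pm, 1L, 0L)
  # map back to the original array for compartment lookup
  orig_index <- rep(NA_integer_, nel)
  bone_el <- !pm
  oz <- eidx[bone_el, 3] - p + zr[1] - 1L
  orig_index[bone_el] <- eidx[bone_el, 1] +
    d[1] * ((eidx[bone_el, 2] - 1L) + d[2] * (oz - 1L))

  # node ids on the (nx+1) x (ny+1) x (nzm+1) grid, compacted to used nodes
  nxn <- d[1] + 1L; nyn <- d[2] + 1L
  nodeid <- matrix(0L, nel, 8L)
  for (a in 1:8) {
    o <- .hex_offsets[a, ]
    nodeid[, a] <- (eidx[, 1] + o[1]) +
      nxn * ((eidx[, 2] + o[2] - 1L) + nyn * (eidx[, 3] + o[3] - 1L))
  }
  uid <- sort(unique(as.vector(nodeid)))
  elems0 <- matrix(match(nodeid, uid) - 1L, nel, 8L)
  nnode <- length(uid)
  node_z <- ((uid - 1L) %/% (nxn * nyn)) + 1L    # node plane 1 .. nzm+1
  node_x <- ((uid - 1L) %% nxn) + 1L
  node_y <- (((uid - 1L) %/% nxn) %% nyn) + 1L

  h_mm <- labels$voxel_size_um / 1000
  H <- nzm * h_mm
  delta <- load$apparent_strain * H

  top_nodes <- which(node_z == nzm + 1L)
  bottom_nodes <- which(node_z == 1L)
  fixed <- c(3L * (top_nodes - 1L) + 2L,      # 0-based z dof = 3*i + 2
             3L * (bottom_nodes - 1L) + 2L)
  vals <- c(rep(-delta, length(top_nodes)), rep(0, length(bottom_nodes)))
  if (load$bc_mode == "bonded") {
    lat <- c(3L * (c(top_nodes, bottom_nodes) - 1L),
             3L * (c(top_nodes, bottom_nodes) - 1L) + 1L)
    fixed <- c(fixed, lat)
    vals <- c(vals, rep(0, length(lat)))
  } else {
    # pin rigid lateral modes: corner node A (ux = uy = 0) plus one more
    # bottom node constrained perpendicular to the A-B line
    ord <- order(node_y[bottom_nodes], node_x[bottom_nodes])
    A <- bottom_nodes[ord[1]]
    others <- bottom_nodes[bottom_nodes != A]
    sameY <- others[node_y[others] == node_y[A] & node_x[others] != node_x[A]]
    if (length(sameY) > 0L) {
      B2 <- sameY[which.max(abs(node_x[sameY] - node_x[A]))]
      extra <- 3L * (B2 - 1L) + 1L               # uy of B
    } else {
      B2 <- others[which.max((node_x[others] - node_x[A])^2 +
                               (node_y[others] - node_y[A])^2)]
      extra <- if (node_x[B2] != node_x[A]) 3L * (B2 - 1L) + 1L
               else 3L * (B2 - 1L)
    }
    fixed <- c(fixed, 3L * (A - 1L), 3L * (A - 1L) + 1L, extra)
    vals <- c(vals, 0, 0, 0)
  }

  ke <- list(fe_hex_ke(1, mat$tissue_poisson, h_mm),
             fe_hex_ke(1, mat$pmma_poisson, h_mm))
  escale <- ifelse(pm, mat$pmma_modulus_GPa, mat$tissue_modulus_GPa) * 1000

  structure(list(elems = elems0, matid = matid, escale = escale, ke = ke,
                 nnode = nnode, fixed_dofs = as.integer(fixed),
                 fixed_vals = vals, top_nodes = top_nodes,
                 bottom_nodes = bottom_nodes, delta = delta, h_mm = h_mm,
                 height_mm = H, dims_model = dim(emask),
                 orig_index = orig_index, is_pmma = pm,
                 n_removed = n_removed, include_shell = include_shell,
                 mat = mat, load = load, nel = nel),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf(
    "<fe_model> %d elements (%d PMMA), %d nodes, %s BCs, strain %.3g\n",
    x$nel, sum(x$is_pmma), x$nnode, x$load$bc_mode, x$load$apparent_strain))
  if (x$n_removed > 0)
    cat(sprintf("  %d elements removed (not connected to both faces)\n",
                x$n_removed))
  invisible(x)
}

#' Solve a micro-FE model
#'
#' Displacement is prescribed on the exterior face of the top PMMA layer
#' (uniform SI displacement = apparent strain x total model height); the
#' bottom exterior face is fixed in SI. Solved by matrix-free
#' Jacobi-preconditioned conjugate gradients.
#'
#' @param model an `fe_model`.
#' @param rel_tol relative residual convergence tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `fe_result` with the displacement field,
#'   reaction forces (N), stiffness (N/mm) and solver diagnostics.
#' @export
fe_solve <- function(model, rel_tol = 1e-6, max_iter = 20000L) {
  stopifnot(inherits(model, "fe_model"))
  sol <- .hex_pcg_cpp(model$elems, model$escale, model$matid, model$ke,
                      model$nnode, model$fixed_dofs, model$fixed_vals,
                      rel_tol, as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf("PCG did not converge in %d iterations (rel. residual %.3g)",
                 sol$iterations, sol$relres))
  u <- sol$u
  r <- .hex_matvec_cpp(model$elems, model$escale, model$matid, model$ke,
                       model$nnode, u)
  reaction_top <- sum(r[3L * model$top_nodes])       # z dof of node i is 3i
  reaction_bottom <- sum(r[3L * model$bottom_nodes])
  structure(list(u = u, reaction_top = reaction_top,
                 reaction_bottom = reaction_bottom,
                 stiffness_N_mm = abs(reaction_top) / model$delta,
                 iterations = sol$iterations, relres = sol$relres,
                 rel_tol = rel_tol, force_norm_N = sol$force_norm,
                 include_shell = model$include_shell, model = model),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> K = %.4g N/mm (%s shell), reactions %.4g / %.4g N, %d iters\n",
    x$stiffness_N_mm, if (x$include_shell) "with" else "without",
    x$reaction_top, x$reaction_bottom, x$iterations))
  invisible(x)
}

#' Stiffness of a solved model
#'
#' Ratio of the SI reaction force on the displaced face to the applied
#' displacement.
#'
#' @param result an `fe_result`.
#' @return Stiffness in kN/mm.
#' @export
stiffness <- function(result) {
  stopifnot(inherits(result, "fe_result"))
  if (result$model$delta == 0) stop("zero applied displacement")
  result$stiffness_N_mm / 1000
}

#' Per-element von Mises stress
#'
#' Strain at each element centroid from trilinear shape-function gradients,
#' stress by isotropic Hooke's law, von Mises from the deviatoric stress.
#'
#' @param result an `fe_result`.
#' @param bone_only drop PMMA elements (default TRUE).
#' @return Numeric vector of von Mises stress (MPa), one per element, with
#'   attribute `element_index` giving row indices into the model's element
#'   list.
#' @export
element_von_mises <- function(result, bone_only = TRUE) {
  stopifnot(inherits(result, "fe_result"))
  model <- result$model
  el_sel <- if (bone_only) which(!model$is_pmma) else seq_len(model$nel)
  elems <- model$elems[el_sel, , drop = FALSE]
  B0 <- .hex_B(0, 0, 0, model$h_mm)
  # gather nodal displacements: 24 x nel
  dofs <- matrix(0L, nrow(elems), 24L)
  for (a in 1:8) for (c0 in 1:3)
    dofs[, 3L * (a - 1L) + c0] <- 3L * elems[, a] + c0
  U <- matrix(result$u[t(dofs)], nrow = 24L)
  eps <- B0 %*% U                                   # 6 x nel
  vm <- numeric(length(el_sel))
  for (mid in unique(model$matid[el_sel])) {
    grp <- model$matid[el_sel] == mid
    nu <- if (mid == 0L) model$mat$tissue_poisson else model$mat$pmma_poisson
    D <- .elastic_D(1, nu)
    sig <- D %*% eps[, grp, drop = FALSE]
    sig <- sweep(sig, 2, model$escale[el_sel][grp], `*`)
    vm[grp] <- sqrt(0.5 * ((sig[1, ] - sig[2, ])^2 + (sig[2, ] - sig[3, ])^2 +
                             (sig[3, ] - sig[1, ])^2) +
                      3 * (sig[4, ]^2 + sig[5, ]^2 + sig[6, ]^2))
  }
  attr(vm, "element_index") <- el_sel
  attr(vm, "orig_index") <- model$orig_index[el_sel]
  vm
}
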