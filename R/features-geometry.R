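# Marching-tetrahedra iso-surface area of a scalar field sampled at voxel
# centres. Each grid cube is split into six tetrahedra sharing the main
# diagonal; within a tetrahedron the field is linear, so the level crossing is
# a triangle (1-vs-3 sign split) or a planar quad (2-vs-2). Fully vectorised
# over the boundary cells.
marching_tet_area <- function(f, spacing_mm, level = 0.5) {
  d <- dim(f)
  n <- d - 1L
  if (any(n < 1L)) return(0)
  # cube corner offsets, 0-indexed unit cube, corners numbered 1..8
  offs <- list(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  corner_vals <- lapply(offs, function(o) {
    as.vector(f[(1:n[1]) + o[1], (1:n[2]) + o[2], (1:n[3]) + o[3]])
  })
  vmin <- Reduce(pmin, corner_vals)
  vmax <- Reduce(pmax, corner_vals)
  active <- which(vmin < level & vmax >= level)
  if (!length(active)) return(0)
  corner_vals <- lapply(corner_vals, function(v) v[active])
  pos <- lapply(offs, function(o) o * spacing_mm)

  # six tetrahedra sharing the diagonal corner1-corner7
  tets <- list(
    c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
  )
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1
    v <- p3 - p1
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total <- 0
  for (tet in tets) {
    va <- corner_vals[[tet[1]]]; vb <- corner_vals[[tet[2]]]
    vc <- corner_vals[[tet[3]]]; vd <- corner_vals[[tet[4]]]
    pa <- pos[[tet[1]]]; pb <- pos[[tet[2]]]; pc <- pos[[tet[3]]]; pd <- pos[[tet[4]]]
    above <- cbind(va >= level, vb >= level, vc >= level, vd >= level)
    code <- above[, 1] + 2L * above[, 2] + 4L * above[, 3] + 8L * above[, 4]
    vals <- list(va, vb, vc, vd)
    pts <- list(pa, pb, pc, pd)
    interp <- function(i, j, sel) {
      # crossing point on edge (vertex i -> vertex j) for selected tets
      vi <- vals[[i]][sel]; vj <- vals[[j]][sel]
      t <- (level - vi) / (vj - vi)
      outer(rep(1, length(t)), pts[[i]]) + t %o% (pts[[j]] - pts[[i]])
    }
    # lone-vertex cases: lone vertex w against others o1, o2, o3
    lone <- list(
      `1` = c(1, 2, 3, 4), `2` = c(2, 1, 3, 4), `4` = c(3, 1, 2, 4), `8` = c(4, 1, 2, 3),
      `14` = c(1, 2, 3, 4), `13` = c(2, 1, 3, 4), `11` = c(3, 1, 2, 4), `7` = c(4, 1, 2, 3)
    )
    for (cd in names(lone)) {
      sel <- which(code == as.integer(cd))
      if (!length(sel)) next
      w <- lone[[cd]]
      p1 <- interp(w[1], w[2], sel)
      p2 <- interp(w[1], w[3], sel)
      p3 <- interp(w[1], w[4], sel)
      total <- total + sum(tri_area(p1, p2, p3))
    }
    # two-two cases: vertices (A, B) on one side, (C, D) on the other;
    # quad A-C, A-D, B-D, B-C split into two triangles
    two <- list(
      `3` = c(1, 2, 3, 4), `5` = c(1, 3, 2, 4), `9` = c(1, 4, 2, 3),
      `12` = c(3, 4, 1, 2), `10` = c(2, 4, 1, 3), `6` = c(2, 3, 1, 4)
    )
    for (cd in names(two)) {
      sel <- which(code == as.integer(cd))
      if (!length(sel)) next
      w <- two[[cd]]
      q1 <- interp(w[1], w[3], sel)
      q2 <- interp(w[1], w[4], sel)
      q3 <- interp(w[2], w[4], sel)
      q4 <- interp(w[2], w[3], sel)
      total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
    }
  }
  total
}

#' Mesh surface area of a binary mask
#'
#' The mask is zero-padded, lightly Gaussian-smoothed (`smooth_sigma_vox`, an
#' anti-aliasing step that turns the staircase indicator into a smooth field
#' whose 0.5 level set tracks the underlying surface), and meshed at level 0.5
#' by marching tetrahedra with the voxel spacing applied; the triangle areas
#' are summed.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel size per axis (mm).
#' @param smooth_sigma_vox anti-aliasing sigma in voxels (default 1; 0 meshes
#'   the raw indicator).
#' @return surface area in mm^2.
#' @export
mask_surface_area <- function(mask, spacing_mm, smooth_sigma_vox = 1) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  pad <- as.integer(ceiling(3 * smooth_sigma_vox) + 1L)
  padded <- array(0, dim = d + 2L * pad)
  padded[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- as.numeric(mask)
  if (smooth_sigma_vox > 0) padded <- gaussian_smooth3d(padded, smooth_sigma_vox)
  marching_tet_area(padded, spacing_mm, level = 0.5)
}

# Voxel indices of the mask surface shell: mask voxels with at least one
# 6-neighbour outside the mask (grid faces count as outside).
surface_shell <- function(mask) {
  inner <- mask
  for (off in asplit(neighbourhood_offsets(6L), 1)) {
    inner <- inner & shift3d(mask, off)
  }
  mask & !inner
}

# mm coordinates (rows) of TRUE voxels.
voxel_coords_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing_mm, "*")
}

# Maximum pairwise Euclidean distance between rows of P (n x 3), chunked so the
# distance matrix never materialises in full.
max_pairwise_distance <- function(P, chunk = 512L) {
  n <- nrow(P)
  if (n < 2) return(0)
  nrm <- rowSums(P^2)
  tP <- t(P)
  best <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D2 <- outer(nrm[s:e], nrm, "+") - 2 * (P[s:e, , drop = FALSE] %*% tP)
    best <- max(best, max(D2))
  }
  sqrt(max(best, 0))
}

#' Size features of a segmented lesion
#'
#' Volume (voxel count times voxel volume), effective diameter
#' (`(6 V / pi)^(1/3)`, the diameter of the equal-volume sphere), mesh surface
#' area ([mask_surface_area()]), and maximum linear size (largest Euclidean
#' distance between surface-voxel centres, a 3D analogue of the longest-
#' diameter size measurement). A single-voxel mask has `max_linear_size_mm = 0`
#' under the pairwise definition.
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing_mm voxel size per axis (mm).
#' @return named list: `volume_mm3`, `effective_diameter_mm`,
#'   `surface_area_mm2`, `max_linear_size_mm`.
#' @export
size_features <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty mask")
  volume <- sum(mask) * prod(spacing_mm)
  shell <- surface_shell(mask)
  list(
    volume_mm3 = volume,
    effective_diameter_mm = (6 * volume / pi)^(1 / 3),
    surface_area_mm2 = mask_surface_area(mask, spacing_mm),
    max_linear_size_mm = max_pairwise_distance(voxel_coords_mm(shell, spacing_mm))
  )
}

#' In-plane (per-slice) maximum linear size
#'
#' The 2D analogue of `max_linear_size_mm` for parity experiments with human
#' longest-diameter measurements, which are made on a single slice: the
#' maximum, over axial slices, of the largest pairwise in-plane distance
#' between surface-voxel centres of that slice.
#'
#' @inheritParams size_features
#' @return in-plane maximum linear size in mm.
#' @export
max_linear_size_2d <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty mask")
  best <- 0
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    P <- cbind(sweep(idx - 1, 2, spacing_mm[1:2], "*"), 0)
    best <- max(best, max_pairwise_distance(P))
  }
  best
}

#' Shape features of a segmented lesion
#'
#' Sphericity is the fraction of lesion voxels covered by the equal-volume
#' ball centred at the lesion's centre of mass, voxelised on the same grid
#' (1 for a perfect digital sphere). Irregularity is the relative surface
#' excess over the equal-volume sphere,
#' `1 - pi * effective_diameter^2 / surface_area`, clamped into `[0, 1)`.
#' The two are deliberately distinct functionals: one measures bulk overlap,
#' the other surface roughness. `surface_to_volume_ratio_per_mm` is the mesh
#' area over the volume.
#'
#' @inheritParams size_features
#' @return named list: `sphericity`, `irregularity`,
#'   `surface_to_volume_ratio_per_mm`.
#' @export
shape_features <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty mask")
  sz <- size_features(mask, spacing_mm)
  com <- colMeans(voxel_coords_mm(mask, spacing_mm))
  d <- dim(mask)
  r_eq <- sz$effective_diameter_mm / 2
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing_mm[a] - com[a])
  dx2 <- array(rep(ax[[1]]^2, times = d[2] * d[3]), dim = d)
  dy2 <- aperm(array(rep(ax[[2]]^2, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  dz2 <- aperm(array(rep(ax[[3]]^2, times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  ball <- (dx2 + dy2 + dz2) <= r_eq^2
  sphericity <- sum(mask & ball) / sum(mask)
  irregularity <- 1 - pi * sz$effective_diameter_mm^2 / sz$surface_area_mm2
  irregularity <- min(max(irregularity, 0), 1 - .Machine$double.eps)
  list(
    sphericity = sphericity,
    irregularity = irregularity,
    surface_to_volume_ratio_per_mm = sz$surface_area_mm2 / sz$volume_mm3
  )
}
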