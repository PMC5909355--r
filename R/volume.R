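#' 3D scalar volume with physical spacing
#'
#' Lightweight container for a 3D image: a numeric array plus per-axis voxel
#' spacing and origin in millimetres. Voxel indices are 1-based in R; the world
#' coordinate of voxel (i, j, k) is `origin_mm + (c(i, j, k) - 1) * spacing_mm`.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing_mm numeric length-3, strictly positive voxel size per axis (mm).
#' @param origin_mm numeric length-3 world position of voxel (1,1,1), in mm.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three strictly positive finite numbers")
  }
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop("`origin_mm` must be three finite numbers")
  }
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(
    "volume_image:", paste(dim(x$values), collapse = " x "), "voxels,",
    "spacing", paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n"
  )
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "volume_image")

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9 ||
      max(abs(a$origin_mm - b$origin_mm)) > 1e-9) {
    stop(sprintf("%s are not on the same grid (shape/spacing/origin mismatch)", what))
  }
  invisible(TRUE)
}

#' Axis coordinate vectors of a volume (world mm)
#' @param vol a `volume_image`.
#' @return list of three numeric vectors (voxel-centre coordinates per axis).
#' @keywords internal
axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin_mm[a] + (seq_len(d[a]) - 1) * vol$spacing_mm[a])
}

#' Nearest voxel index of a world-coordinate point
#' @keywords internal
world_to_voxel <- function(vol, point_mm) {
  idx <- round((point_mm - vol$origin_mm) / vol$spacing_mm) + 1
  d <- dim(vol$values)
  if (any(idx < 1) || any(idx > d)) {
    stop(sprintf(
      "point (%s) mm lies outside the volume", paste(signif(point_mm, 4), collapse = ", ")
    ))
  }
  as.integer(idx)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry spacing and origin into/out of a [volume_image].
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume_image].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img)[1:3])
  spacing <- abs(RNifti::pixdim(img)[1:3])
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  volume_image(values, spacing_mm = spacing, origin_mm = origin)
}

#' @param vol a [volume_image] (for `write_volume()`).
#' @param datatype NIfTI storage type, e.g. `"float"` or `"uint8"`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  xf <- diag(c(vol$spacing_mm, 1))
  xf[1:3, 4] <- vol$origin_mm
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# ---- array helpers ----------------------------------------------------------

#' Separable Gaussian smoothing of a 3D array
#'
#' Boundary handling renormalises the truncated kernel (no flux in from outside
#' the grid), so a constant array is a fixed point.
#'
#' @param arr 3D numeric array.
#' @param sigma_vox per-axis Gaussian sigma in voxel units (length 1 or 3);
#'   a zero sigma skips that axis.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth3d <- function(arr, sigma_vox) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3L)
  if (any(sigma_vox < 0)) stop("sigma must be non-negative")
  d <- dim(arr)
  smooth_axis1 <- function(a, sigma) {
    n <- dim(a)[1]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    array(K %*% matrix(a, nrow = n), dim = dim(a))
  }
  if (sigma_vox[1] > 0) arr <- smooth_axis1(arr, sigma_vox[1])
  if (sigma_vox[2] > 0) {
    arr <- aperm(smooth_axis1(aperm(arr, c(2, 1, 3)), sigma_vox[2]), c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    arr <- aperm(smooth_axis1(aperm(arr, c(3, 2, 1)), sigma_vox[3]), c(3, 2, 1))
  }
  arr
}

# Shift a logical/numeric 3D array by integer offset, padding with `fill`.
shift3d <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbourhood_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  g
}

# Connected component of `mask` containing `seed_idx` (voxel index, length 3),
# by iterated geodesic dilation.
flood_component <- function(mask, seed_idx, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!mask[seed_idx[1], seed_idx[2], seed_idx[3]]) {
    stop("seed voxel is not inside the mask")
  }
  offs <- neighbourhood_offsets(connectivity)
  cur <- array(FALSE, dim = dim(mask))
  cur[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  repeat {
    grown <- cur
    for (r in seq_len(nrow(offs))) {
      grown <- grown | shift3d(cur, offs[r, ])
    }
    grown <- grown & mask
    if (sum(grown) == sum(cur)) break
    cur <- grown
  }
  cur
}

# Fill holes: background voxels not 6-connected to the array border become mask.
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, dim = d)
  reach[1, , ] <- bg[1, , ]; reach[d[1], , ] <- bg[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | bg[, 1, ]; reach[, d[2], ] <- reach[, d[2], ] | bg[, d[2], ]
  reach[, , 1] <- reach[, , 1] | bg[, , 1]; reach[, , d[3]] <- reach[, , d[3]] | bg[, , d[3]]
  offs <- neighbourhood_offsets(6L)
  repeat {
    grown <- reach
    for (r in seq_len(nrow(offs))) grown <- grown | shift3d(reach, offs[r, ])
    grown <- grown & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Central-difference gradient of a 3D array, scaled to physical units (per mm).
# One-sided differences at the grid faces.
gradient3d <- function(arr, spacing_mm) {
  d <- dim(arr)
  grad_axis <- function(a, ax, h) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    den <- (ip - im) * h
    take <- function(idx) {
      switch(ax,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE]
      )
    }
    num <- take(ip) - take(im)
    sweep_den <- switch(ax,
      array(rep(den, times = d[2] * d[3]), dim = d),
      aperm(array(rep(den, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(rep(den, times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
    )
    array(num, dim = d) / sweep_den
  }
  list(
    gx = grad_axis(arr, 1L, spacing_mm[1]),
    gy = grad_axis(arr, 2L, spacing_mm[2]),
    gz = grad_axis(arr, 3L, spacing_mm[3])
  )
}

# Deterministic substream seed derivation: keeps every RNG use tied to one
# user-facing seed while decoupling the streams of different pipeline stages.
substream_seed <- function(seed, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483629) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
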