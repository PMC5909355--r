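#' Enhancement map (post minus pre)
#'
#' Voxelwise signed subtraction of the pre-contrast from the first
#' post-contrast volume. Signed subtraction (rather than a ratio) is used as
#' the enhancement signal because the fat-suppressed background can be close
#' to zero.
#'
#' @param pre,post [volume_image]s on the same grid.
#' @return a [volume_image] of the enhancement signal.
#' @export
enhancement_map <- function(pre, post) {
  stopifnot(is_volume(pre), is_volume(post))
  stopifnot_same_grid(pre, post, "pre/post volumes")
  volume_image(post$values - pre$values, pre$spacing_mm, pre$origin_mm)
}

#' Fuzzy c-means lesion segmentation from the enhancement signal
#'
#' Runs scalar two-class fuzzy c-means (fuzzifier `m`) on the enhancement
#' values inside a cubic volume of interest (VOI) around the seed point,
#' labels the cluster with the higher centroid as tumour, binarises the tumour
#' membership at 0.5, keeps the 26-connected component containing the seed and
#' fills fully enclosed holes (6-connected background). Centroids are
#' initialised at the 10th and 90th percentile of the VOI intensities, so the
#' algorithm is fully deterministic.
#'
#' @param enh enhancement [volume_image] (see [enhancement_map()]).
#' @param seed_mm approximate lesion centre in world mm.
#' @param voi_half_width_mm half-width of the VOI cube (mm); a sensible choice
#'   is twice the expected lesion radius. The VOI is clipped to the volume.
#' @param m fuzzifier (> 1), default 2.
#' @param tol relative convergence tolerance on the objective, default 1e-5.
#' @param max_iter iteration cap, default 100.
#' @return An object of class `segmentation_result`: `mask` (logical array),
#'   `membership` (tumour-class membership in `[0,1]`, zero outside the VOI),
#'   `n_iterations`, `objective_trace`, `voi_bounds` (index ranges), and
#'   `spacing_mm`.
#' @export
fuzzy_cmeans_segment <- function(enh, seed_mm, voi_half_width_mm = 20,
                                 m = 2, tol = 1e-5, max_iter = 100L) {
  stopifnot(is_volume(enh), m > 1, voi_half_width_mm > 0)
  d <- dim(enh$values)
  seed_idx <- world_to_voxel(enh, seed_mm)
  half_vox <- ceiling(voi_half_width_mm / enh$spacing_mm)
  lo <- pmax(seed_idx - half_vox, 1L)
  hi <- pmin(seed_idx + half_vox, d)
  voi <- enh$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  x <- as.vector(voi)
  if (diff(range(x)) == 0) stop("no contrast in VOI (constant intensity)")

  centroids <- as.numeric(stats::quantile(x, c(0.10, 0.90), names = FALSE))
  if (centroids[1] == centroids[2]) centroids <- range(x)
  trace <- numeric(0)
  u <- NULL
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d2 <- cbind((x - centroids[1])^2, (x - centroids[2])^2)
    d2 <- pmax(d2, .Machine$double.xmin)
    # u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)), vectorised for c = 2
    ratio <- (d2[, 1] / d2[, 2])^(expo / 2) # (d1/d2)^(2/(m-1)) with d2 = dist^2
    u1 <- 1 / (1 + ratio)
    u <- cbind(u1, 1 - u1)
    um <- u^m
    centroids_new <- colSums(um * x) / colSums(um)
    obj <- sum(um * d2)
    trace <- c(trace, obj)
    if (it > 1 && abs(trace[it - 1] - obj) <= tol * max(obj, .Machine$double.eps)) {
      centroids <- centroids_new
      break
    }
    centroids <- centroids_new
  }
  tumour_class <- which.max(centroids)
  memb <- array(u[, tumour_class], dim = dim(voi))
  bin <- memb >= 0.5
  seed_local <- seed_idx - lo + 1L
  if (!bin[seed_local[1], seed_local[2], seed_local[3]]) {
    stop("seed voxel is not inside any suprathreshold (membership >= 0.5) component")
  }
  comp <- flood_component(bin, seed_local, connectivity = 26L)
  comp <- fill_holes(comp)

  mask <- array(FALSE, dim = d)
  membership <- array(0, dim = d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  membership[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- memb
  structure(
    list(
      mask = mask, membership = membership,
      n_iterations = length(trace), objective_trace = trace,
      voi_bounds = rbind(lo = lo, hi = hi),
      centroids = sort(centroids), spacing_mm = enh$spacing_mm
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(
    "segmentation_result:", sum(x$mask), "voxels,",
    x$n_iterations, "FCM iterations, centroids",
    paste(signif(x$centroids, 4), collapse = " / "), "\n"
  )
  invisible(x)
}

#' Dice overlap of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; 1 iff the masks are identical and nonempty.
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("masks are not on the same grid")
  a <- sum(mask_a)
  b <- sum(mask_b)
  if (a + b == 0) stop("both masks are empty; Dice undefined")
  2 * sum(mask_a & mask_b) / (a + b)
}
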