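#' 3D grey-level co-occurrence matrix (pooled over 13 directions)
#'
#' Intensities are min-max quantised to `levels` grey bins inside the mask;
#' co-occurrences are accumulated over the 13 unique 3D direction offsets at
#' the given voxel displacement (both voxels inside the mask), symmetrised and
#' pooled into a single matrix normalised to sum 1. Pooling the directions is
#' the common choice for DCE-MRI radiomics, where the in-plane/through-plane
#' anisotropy makes per-direction matrices sparse.
#'
#' A constant-intensity mask yields a defined degenerate GLCM (all mass in one
#' diagonal cell) with a warning, so downstream limits stay testable.
#'
#' @param post_volume [volume_image] (first post-contrast image).
#' @param mask logical lesion mask on the same grid, `>= 2` voxels.
#' @param levels number of grey levels (default 32).
#' @param displacement voxel displacement of the offsets (default 1).
#' @return object of class `glcm`: `matrix` (levels x levels, sums to 1,
#'   symmetric), `levels`, `displacement`, `n_pairs`.
#' @export
glcm_matrix <- function(post_volume, mask, levels = 32L, displacement = 1L) {
  stopifnot(is_volume(post_volume), levels >= 2, displacement >= 1)
  if (!identical(dim(post_volume$values), dim(mask))) stop("mask and volume grids differ")
  if (sum(mask) < 2) stop("mask must contain at least 2 voxels")
  vals <- post_volume$values
  v <- vals[mask]
  rng <- range(v)
  M <- matrix(0, levels, levels)
  if (diff(rng) == 0) {
    warning("constant intensity in mask: returning degenerate single-cell GLCM")
    M[1, 1] <- 1
    return(structure(
      list(matrix = M, levels = as.integer(levels),
           displacement = as.integer(displacement), n_pairs = 0L),
      class = "glcm"
    ))
  }
  q <- array(0L, dim = dim(vals))
  q[mask] <- pmin(as.integer(floor((vals[mask] - rng[1]) / diff(rng) * levels)) + 1L, levels)
  d <- dim(q)
  offs <- neighbourhood_offsets(26L)
  # keep the 13 lexicographically positive offsets (the other 13 are covered
  # by symmetrisation)
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs <- offs[keep, , drop = FALSE] * displacement
  counts <- numeric(levels * levels)
  n_pairs <- 0L
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    a_rng <- lapply(1:3, function(ax) {
      if (o[ax] >= 0) seq_len(d[ax] - o[ax]) else (1 - o[ax]):d[ax]
    })
    b_rng <- lapply(1:3, function(ax) a_rng[[ax]] + o[ax])
    qa <- q[a_rng[[1]], a_rng[[2]], a_rng[[3]], drop = FALSE]
    qb <- q[b_rng[[1]], b_rng[[2]], b_rng[[3]], drop = FALSE]
    ok <- qa > 0L & qb > 0L
    if (!any(ok)) next
    ia <- qa[ok]; ib <- qb[ok]
    counts <- counts + tabulate(ia + levels * (ib - 1L), nbins = levels * levels)
    n_pairs <- n_pairs + length(ia)
  }
  if (n_pairs == 0L) stop("no co-occurring voxel pairs inside the mask at this displacement")
  M <- matrix(counts, levels, levels)
  M <- M + t(M)
  M <- M / sum(M)
  structure(
    list(matrix = M, levels = as.integer(levels),
         displacement = as.integer(displacement), n_pairs = n_pairs),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("glcm:", x$levels, "levels, displacement", x$displacement,
      "-", x$n_pairs, "directed pairs\n")
  invisible(x)
}

log2_safe <- function(x) ifelse(x > 0, log2(x), 0) # 0 * log 0 == 0 convention

#' Haralick texture features (f1-f14) of a GLCM
#'
#' The fourteen classical co-occurrence statistics: energy (angular second
#' moment), contrast, correlation, sum of squares (variance), inverse
#' difference moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, the two information measures of correlation, and the
#' maximal correlation coefficient (square root of the second-largest
#' eigenvalue of the Markov-like matrix `Q`). Logs are base 2 with the
#' `0 log 0 = 0` convention. Sum variance is taken about the sum average, and
#' difference variance is the variance of the difference marginal; degenerate
#' GLCMs take defined limits (correlation and the information measures are 0
#' when a marginal is concentrated on one level, as is the maximal correlation
#' coefficient when fewer than two levels occur).
#'
#' @param glcm a [glcm_matrix()] result (or a plain symmetric matrix summing
#'   to 1).
#' @return named list of the 14 texture features.
#' @export
texture_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$matrix else glcm
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("GLCM must be a square matrix")
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalised to sum 1")
  ng <- nrow(P)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))

  # sum and difference marginals
  p_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), 0) # index k = 2..2ng
  k_sum <- 2:(2 * ng)
  p_diff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  k_diff <- 0:(ng - 1)

  energy <- sum(P^2)
  contrast <- sum(k_diff^2 * p_diff)
  correlation <- if (sd_x * sd_y > 0) {
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else {
    0
  }
  sum_of_squares <- sum((i - mu_x)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- -sum(p_sum * log2_safe(p_sum))
  entropy <- -sum(P * log2_safe(P))
  diff_mean <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - diff_mean)^2 * p_diff)
  difference_entropy <- -sum(p_diff * log2_safe(p_diff))

  hx <- -sum(px * log2_safe(px))
  hy <- -sum(py * log2_safe(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2_safe(pxy))
  hxy2 <- -sum(pxy * log2_safe(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  # maximal correlation coefficient: sqrt of the 2nd-largest eigenvalue of
  # Q_ij = sum_k P_ik P_jk / (px_i py_k), on the support of the marginals
  supp <- which(px > 0)
  mcc <- 0
  if (length(supp) >= 2) {
    Ps <- P[supp, supp, drop = FALSE]
    Q <- (Ps / px[supp]) %*% (t(Ps) / py[supp])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }

  list(
    energy = energy, contrast = contrast, correlation = correlation,
    sum_of_squares = sum_of_squares, inverse_difference_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    imc1 = imc1, imc2 = imc2, max_correlation_coefficient = mcc
  )
}
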