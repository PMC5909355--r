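# Latent-category thresholds of the generator. The latent BI-RADS categories a
# simulated reader sees are defined directly on the generating parameters (not
# re-measured from the rasterised mask), so the reader simulation stays
# independent of the feature-extraction code under test.
SHAPE_IRREGULAR_AMP <- 0.12     # lobulation_amp at/above which latent shape = irregular
MARGIN_SPICULATED_AMP <- 0.25   # lobulation_amp at/above which latent margin = spiculated
ENHANCEMENT_HETEROGENEOUS_SD <- 0.10 # texture_sd at/above which latent enhancement = heterogeneous

#' Specification of a single synthetic lesion phantom
#'
#' Describes a star-shaped lesion whose surface radius is
#' `r(theta, phi) = base_radius_mm * (1 + lobulation_amp * Y(theta, phi))`,
#' with `Y` a real spherical harmonic of degree `lobulation_order`
#' (max-normalised to 1), rasterised on an anisotropic voxel grid and embedded
#' in a pre/post-contrast volume pair.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3, voxel size per axis in mm (defaults
#'   mimic a typical fat-suppressed T1 acquisition: 0.7 mm in-plane, 2.5 mm
#'   slice spacing).
#' @param centre_mm lesion centre in world mm; default is the grid centre.
#' @param base_radius_mm equivalent-sphere radius of the unperturbed lesion (mm).
#' @param lobulation_amp dimensionless surface perturbation amplitude in
#'   `[0, 0.5]`; 0 gives a sphere.
#' @param lobulation_order integer spherical-harmonic degree `>= 2`.
#' @param margin_blur_mm Gaussian sigma of the margin blur (mm).
#' @param texture_sd intra-lesion enhancement heterogeneity, as a fraction of
#'   `contrast_level` (standard deviation of the multiplicative field).
#' @param texture_corr_mm correlation length of the heterogeneity field (mm).
#' @param contrast_level lesion enhancement amplitude (arbitrary intensity units).
#' @param noise_sd additive Gaussian image noise (intensity units).
#' @param rng_seed integer seed; all phantom randomness is a pure function of
#'   the spec including this seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 28),
                         spacing_mm = c(0.7, 0.7, 2.5),
                         centre_mm = NULL,
                         base_radius_mm = 10,
                         lobulation_amp = 0,
                         lobulation_order = 4L,
                         margin_blur_mm = 0.7,
                         texture_sd = 0.1,
                         texture_corr_mm = 2,
                         contrast_level = 200,
                         noise_sd = 5,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (is.null(centre_mm)) centre_mm <- (grid_shape - 1) / 2 * spacing_mm
  centre_mm <- as.numeric(centre_mm)
  if (base_radius_mm <= 0) stop("base_radius_mm must be > 0")
  if (lobulation_amp < 0 || lobulation_amp > 0.5) stop("lobulation_amp must be in [0, 0.5]")
  if (lobulation_order < 2 || lobulation_order != round(lobulation_order)) {
    stop("lobulation_order must be an integer >= 2")
  }
  if (margin_blur_mm < 0) stop("margin_blur_mm must be >= 0")
  if (texture_sd < 0 || texture_corr_mm <= 0) stop("texture parameters must be non-negative (corr > 0)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  spec <- structure(
    list(
      grid_shape = grid_shape, spacing_mm = spacing_mm, centre_mm = centre_mm,
      base_radius_mm = base_radius_mm, lobulation_amp = lobulation_amp,
      lobulation_order = as.integer(lobulation_order),
      margin_blur_mm = margin_blur_mm, texture_sd = texture_sd,
      texture_corr_mm = texture_corr_mm, contrast_level = contrast_level,
      noise_sd = noise_sd, rng_seed = as.integer(rng_seed)
    ),
    class = "phantom_spec"
  )
  # lesion (max radius) must fit inside the grid with >= 2 voxels to spare
  r_max <- base_radius_mm * (1 + lobulation_amp)
  extent <- (grid_shape - 1) * spacing_mm
  lo <- centre_mm - r_max
  hi <- centre_mm + r_max
  margin <- 2 * spacing_mm
  for (ax in 1:3) {
    if (lo[ax] < margin[ax] || hi[ax] > extent[ax] - margin[ax]) {
      stop(sprintf(
        "lesion (max radius %.1f mm) violates the 2-voxel margin on axis %d (grid extent %.1f mm)",
        r_max, ax, extent[ax]
      ))
    }
  }
  spec
}

# Real spherical harmonic of degree l, order m = floor(l / 2), normalised so
# that max |Y| = 1 over the sphere. theta is the polar angle, phi azimuth.
real_spherical_harmonic <- function(l, theta, phi) {
  m <- l %/% 2L
  P <- pracma::legendre(l, cos(theta))     # (l+1) x n matrix, rows m = 0..l
  p_m <- if (is.matrix(P)) P[m + 1L, ] else P[m + 1L]
  # max of |P_l^m(cos theta)| over theta, on a fine grid (deterministic constant)
  tg <- seq(0, pi, length.out = 2001)
  Pg <- pracma::legendre(l, cos(tg))
  norm <- max(abs(Pg[m + 1L, ]))
  (p_m / norm) * cos(m * phi)
}

# Surface radius r(theta, phi) for a spec.
surface_radius <- function(spec, theta, phi) {
  y <- if (spec$lobulation_amp > 0) {
    real_spherical_harmonic(spec$lobulation_order, theta, phi)
  } else {
    numeric(length(theta))
  }
  spec$base_radius_mm * (1 + spec$lobulation_amp * y)
}

# Maximum caliper diameter of the analytic surface: max over directions u of
# r(u) + r(-u), evaluated on a fine direction grid.
analytic_max_diameter <- function(spec) {
  th <- seq(0, pi, length.out = 121)
  ph <- seq(0, 2 * pi, length.out = 241)[-241]
  g <- expand.grid(theta = th, phi = ph)
  r1 <- surface_radius(spec, g$theta, g$phi)
  r2 <- surface_radius(spec, pi - g$theta, (g$phi + pi) %% (2 * pi))
  max(r1 + r2)
}

# Analytic volume of the star-shaped surface by quadrature:
# V = (1/3) int int r^3 sin(theta) dtheta dphi.
analytic_volume <- function(spec, n_theta = 241, n_phi = 480) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  dph <- 2 * pi / n_phi
  r3 <- outer(th, ph, function(t, p) surface_radius(spec, t, p)^3)
  integrand <- r3 * sin(th)   # recycles sin(th) down columns
  # trapezoid in theta, rectangle in (periodic) phi
  w <- rep(th[2] - th[1], n_theta); w[c(1, n_theta)] <- w[1] / 2
  sum(colSums(integrand * w)) * dph / 3
}

latent_categories <- function(spec) {
  list(
    latent_shape = if (spec$lobulation_amp >= SHAPE_IRREGULAR_AMP) "irregular" else "round_oval",
    latent_enhancement = if (spec$texture_sd >= ENHANCEMENT_HETEROGENEOUS_SD) {
      "heterogeneous"
    } else {
      "homogeneous"
    },
    latent_margin = if (spec$lobulation_amp >= MARGIN_SPICULATED_AMP) {
      "spiculated"
    } else if (spec$lobulation_amp >= SHAPE_IRREGULAR_AMP) {
      "irregular"
    } else {
      "circumscribed"
    }
  )
}

#' Generate a synthetic pre/post-contrast phantom
#'
#' Rasterises the spec's star-shaped lesion on the voxel grid (a voxel belongs
#' to the truth mask iff its centre lies inside the analytic surface), builds
#' `post = pre_baseline + blur(contrast_level * (1 + heterogeneity) * mask)`
#' with Gaussian margin blur and additive Gaussian noise on both volumes, and
#' records the ground truth used by the simulated readers.
#'
#' @param spec a [phantom_spec()].
#' @param case_id optional case identifier stored in the truth record.
#' @return A list of class `phantom` with elements `pre`, `post`
#'   ([volume_image]s), `truth_mask` (logical array), `spacing_mm`, `seed_mm`
#'   (the lesion centre, usable as a segmentation seed) and `truth` (one-row
#'   data.frame of ground-truth parameters and latent HEIP categories).
#' @export
generate_phantom <- function(spec, case_id = "case_001") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec$spacing_mm[a])
  dx <- array(rep(ax[[1]] - spec$centre_mm[1], times = d[2] * d[3]), dim = d)
  dy <- aperm(array(rep(ax[[2]] - spec$centre_mm[2], times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  dz <- aperm(array(rep(ax[[3]] - spec$centre_mm[3], times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  theta <- acos(ifelse(rho > 0, pmin(1, pmax(-1, dz / pmax(rho, 1e-12))), 1))
  phi <- atan2(dy, dx)
  rsurf <- array(surface_radius(spec, as.vector(theta), as.vector(phi)), dim = d)
  mask <- rho <= rsurf
  if (!any(mask)) stop("truth mask is empty; lesion smaller than one voxel")

  baseline <- 100
  with_local_seed(spec$rng_seed, {
    het <- array(0, dim = d)
    if (spec$texture_sd > 0) {
      white <- array(stats::rnorm(prod(d)), dim = d)
      het <- gaussian_smooth3d(white, spec$texture_corr_mm / spec$spacing_mm)
      mu <- mean(het[mask])
      s <- stats::sd(het[mask])
      het <- if (is.na(s) || s == 0) array(0, dim = d) else (het - mu) / s * spec$texture_sd
    }
    lesion_term <- spec$contrast_level * (1 + het) * mask
    if (spec$margin_blur_mm > 0) {
      lesion_term <- gaussian_smooth3d(lesion_term, spec$margin_blur_mm / spec$spacing_mm)
    }
    pre_noise <- if (spec$noise_sd > 0) array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d) else 0
    post_noise <- if (spec$noise_sd > 0) array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d) else 0
    pre_vals <- baseline + pre_noise
    post_vals <- baseline + lesion_term + post_noise
  })
  if (!is.array(pre_vals)) pre_vals <- array(pre_vals, dim = d)

  cats <- latent_categories(spec)
  truth <- data.frame(
    case_id = case_id,
    latent_size_mm = analytic_max_diameter(spec),
    latent_shape = cats$latent_shape,
    latent_enhancement = cats$latent_enhancement,
    latent_margin = cats$latent_margin,
    true_volume_mm3 = sum(mask) * prod(spec$spacing_mm),
    analytic_volume_mm3 = analytic_volume(spec),
    base_radius_mm = spec$base_radius_mm,
    lobulation_amp = spec$lobulation_amp,
    lobulation_order = spec$lobulation_order,
    margin_blur_mm = spec$margin_blur_mm,
    texture_sd = spec$texture_sd,
    contrast_level = spec$contrast_level,
    noise_sd = spec$noise_sd,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pre = volume_image(pre_vals, spec$spacing_mm),
      post = volume_image(post_vals, spec$spacing_mm),
      truth_mask = mask,
      spacing_mm = spec$spacing_mm,
      seed_mm = spec$centre_mm,
      truth = truth,
      spec = spec
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(
    "phantom:", x$truth$case_id, "-",
    sum(x$truth_mask), "lesion voxels,",
    sprintf("latent size %.1f mm, shape %s, margin %s\n",
            x$truth$latent_size_mm, x$truth$latent_shape, x$truth$latent_margin)
  )
  invisible(x)
}
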