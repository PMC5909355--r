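#' The 24-feature CEIP inventory
#'
#' Names and category assignment of the computer-extracted imaging phenotypes:
#' 4 size, 3 shape, 3 morphology and 14 enhancement-texture features.
#'
#' @return data.frame with columns `name` and `category`.
#' @export
ceip_inventory <- function() {
  data.frame(
    name = c(
      "volume_mm3", "effective_diameter_mm", "surface_area_mm2", "max_linear_size_mm",
      "sphericity", "irregularity", "surface_to_volume_ratio_per_mm",
      "margin_sharpness_mean", "margin_sharpness_var", "var_radial_gradient_hist",
      "energy", "contrast", "correlation", "sum_of_squares",
      "inverse_difference_moment", "sum_average", "sum_variance", "sum_entropy",
      "entropy", "difference_variance", "difference_entropy", "imc1", "imc2",
      "max_correlation_coefficient"
    ),
    category = c(
      rep("size", 4), rep("shape", 3), rep("morphology", 3), rep("texture", 14)
    ),
    stringsAsFactors = FALSE
  )
}

#' Extract all 24 CEIP from a segmented lesion
#'
#' Runs [size_features()], [shape_features()], [morphology_features()],
#' [glcm_matrix()] and [texture_features()] on the post-contrast volume and the
#' lesion mask, and returns the full named feature vector. All values are
#' finite: degenerate inputs either error in the component extractors or take
#' their documented limits.
#'
#' @param post_volume [volume_image] of the first post-contrast image.
#' @param mask logical lesion mask on the same grid.
#' @param levels,displacement GLCM parameters (see [glcm_matrix()]).
#' @param margin_source which image the margin-sharpness features differentiate:
#'   the post-contrast volume (default) or an enhancement map supplied instead.
#' @return named numeric vector of the 24 features, ordered as
#'   [ceip_inventory()].
#' @export
extract_features <- function(post_volume, mask, levels = 32L, displacement = 1L,
                             margin_source = post_volume) {
  spacing <- post_volume$spacing_mm
  sz <- size_features(mask, spacing)
  sh <- shape_features(mask, spacing)
  mo <- morphology_features(margin_source, mask)
  tx <- texture_features(glcm_matrix(post_volume, mask, levels = levels,
                                     displacement = displacement))
  out <- unlist(c(sz, sh, mo, tx))
  inv <- ceip_inventory()$name
  if (!identical(names(out), inv)) out <- out[inv]
  if (any(!is.finite(out))) {
    stop("non-finite feature value(s): ", paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Extract features for every case of a cohort
#'
#' Segments each phantom from its enhancement map (seeded at the stored lesion
#' centre) and extracts the 24 CEIP, or extracts directly from the truth masks
#' with `use_truth_mask = TRUE`.
#'
#' @param cohort result of [generate_cohort()].
#' @param use_truth_mask skip segmentation and use the ground-truth masks.
#' @param voi_half_width_factor VOI half-width as a multiple of each case's
#'   latent radius (default 2).
#' @param levels,displacement GLCM parameters.
#' @return data.frame: `case_id` plus the 24 feature columns; attribute
#'   `dice` holds per-case Dice overlap with the truth mask when segmentation
#'   was run.
#' @export
cohort_features <- function(cohort, use_truth_mask = FALSE,
                            voi_half_width_factor = 2,
                            levels = 32L, displacement = 1L) {
  rows <- vector("list", length(cohort$phantoms))
  dices <- rep(NA_real_, length(rows))
  for (k in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[k]]
    if (use_truth_mask) {
      mask <- ph$truth_mask
    } else {
      enh <- enhancement_map(ph$pre, ph$post)
      half <- voi_half_width_factor * ph$truth$latent_size_mm / 2
      seg <- fuzzy_cmeans_segment(enh, ph$seed_mm, voi_half_width_mm = half)
      mask <- seg$mask
      dices[k] <- dice(mask, ph$truth_mask)
    }
    fv <- extract_features(ph$post, mask, levels = levels, displacement = displacement)
    rows[[k]] <- data.frame(case_id = ph$truth$case_id, t(fv), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dice") <- dices
  out
}
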