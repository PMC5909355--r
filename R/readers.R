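#' Closed vocabularies of the reader descriptors
#'
#' The four descriptors a reader panel scores per case: size in mm plus the
#' three BI-RADS categoricals.
#' @return named list of allowed category strings.
#' @export
heip_vocabulary <- function() {
  list(
    shape = c("round_oval", "irregular"),
    internal_enhancement = c("homogeneous", "heterogeneous"),
    margin = c("circumscribed", "irregular", "spiculated")
  )
}

check_row_stochastic <- function(M, k, name) {
  if (!is.matrix(M) || !identical(dim(M), c(k, k))) {
    stop(sprintf("%s must be a %d x %d matrix", name, k, k))
  }
  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12)) {
    stop(sprintf("%s rows must be non-negative and sum to 1 (within 1e-12)", name))
  }
  invisible(TRUE)
}

#' Simulated reader panel model
#'
#' Defines the error model of a panel of independent readers: a multiplicative
#' log-normal error on the size measurement and per-descriptor confusion
#' matrices `P(reported | latent)` for the categoricals. The default
#' `size_log_sd = 0.13` calibrates the pairwise 20%-coverage probability of
#' size to about 0.68 (closed form `2*pnorm(log(1.2)/(sd*sqrt(2))) - 1`), and
#' the default confusion accuracies put chance-corrected categorical agreement
#' in the moderate range typical of expert breast readers.
#'
#' @param n_readers number of readers per case (default 3).
#' @param size_log_sd per-reader sd of the log size error (scalar or length
#'   `n_readers`).
#' @param size_log_bias per-reader mean of the log size error.
#' @param shape_confusion,enhancement_confusion row-stochastic 2x2 matrices,
#'   rows = latent category, columns = reported category, in the order of
#'   [heip_vocabulary()].
#' @param margin_confusion row-stochastic 3x3 matrix over
#'   (circumscribed, irregular, spiculated).
#' @param rng_seed integer seed used by [simulate_readers()].
#' @return An object of class `reader_model`.
#' @export
reader_model <- function(n_readers = 3L,
                         size_log_sd = 0.13,
                         size_log_bias = 0,
                         shape_confusion = confusion2(0.86),
                         enhancement_confusion = confusion2(0.77),
                         margin_confusion = default_margin_confusion(),
                         rng_seed = 1L) {
  n_readers <- as.integer(n_readers)
  stopifnot(n_readers >= 1L)
  size_log_sd <- rep_len(as.numeric(size_log_sd), n_readers)
  size_log_bias <- rep_len(as.numeric(size_log_bias), n_readers)
  if (any(size_log_sd < 0)) stop("size_log_sd must be >= 0")
  check_row_stochastic(shape_confusion, 2L, "shape_confusion")
  check_row_stochastic(enhancement_confusion, 2L, "enhancement_confusion")
  check_row_stochastic(margin_confusion, 3L, "margin_confusion")
  structure(
    list(
      n_readers = n_readers, size_log_sd = size_log_sd,
      size_log_bias = size_log_bias,
      shape_confusion = shape_confusion,
      enhancement_confusion = enhancement_confusion,
      margin_confusion = margin_confusion,
      rng_seed = as.integer(rng_seed)
    ),
    class = "reader_model"
  )
}

#' @param accuracy probability that the reported binary category equals the
#'   latent one (same for both categories).
#' @rdname reader_model
#' @export
confusion2 <- function(accuracy) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  matrix(c(accuracy, 1 - accuracy, 1 - accuracy, accuracy), 2, 2, byrow = TRUE)
}

#' @rdname reader_model
#' @export
default_margin_confusion <- function() {
  matrix(
    c(
      0.80, 0.17, 0.03,
      0.10, 0.80, 0.10,
      0.03, 0.17, 0.80
    ),
    3, 3, byrow = TRUE,
    dimnames = list(NULL, c("circumscribed", "irregular", "spiculated"))
  )
}

#' Sample a latent truth table without rasterising phantoms
#'
#' Convenience generator for reader-panel-only simulations (agreement
#' calibration studies): latent sizes are log-uniform over `size_range_mm` and
#' latent categories are drawn from the stated marginal probabilities.
#'
#' @param n_cases number of cases.
#' @param size_range_mm range of the latent maximal lesion diameter (mm);
#'   the default 8-60 mm spans the tumour diameters typical of an invasive
#'   breast cancer cohort.
#' @param p_irregular_shape,p_heterogeneous marginal probabilities of the
#'   binary latent categories.
#' @param margin_probs length-3 probabilities over
#'   (circumscribed, irregular, spiculated).
#' @param rng_seed integer seed.
#' @return data.frame with columns `case_id`, `latent_size_mm`, `latent_shape`,
#'   `latent_enhancement`, `latent_margin`.
#' @export
sample_truth_table <- function(n_cases,
                               size_range_mm = c(8, 60),
                               p_irregular_shape = 0.5,
                               p_heterogeneous = 0.5,
                               margin_probs = c(1, 1, 1) / 3,
                               rng_seed = 1L) {
  stopifnot(n_cases >= 1, size_range_mm[1] > 0, size_range_mm[2] > size_range_mm[1])
  voc <- heip_vocabulary()
  with_local_seed(rng_seed, {
    out <- data.frame(
      case_id = sprintf("case_%04d", seq_len(n_cases)),
      latent_size_mm = exp(stats::runif(n_cases, log(size_range_mm[1]), log(size_range_mm[2]))),
      latent_shape = sample(voc$shape, n_cases, replace = TRUE,
                            prob = c(1 - p_irregular_shape, p_irregular_shape)),
      latent_enhancement = sample(voc$internal_enhancement, n_cases, replace = TRUE,
                                  prob = c(1 - p_heterogeneous, p_heterogeneous)),
      latent_margin = sample(voc$margin, n_cases, replace = TRUE, prob = margin_probs),
      stringsAsFactors = FALSE
    )
  })
  out
}

#' Simulate a multi-reader assessment panel
#'
#' Each reader reports `size = latent_size * exp(e)` with
#' `e ~ Normal(size_log_bias, size_log_sd^2)`, and draws each categorical
#' rating from the confusion-matrix row of the latent category. Ratings are
#' independent across readers and cases; the output is a pure function of
#' `(truth, model)` including `model$rng_seed`.
#'
#' @param truth data.frame with columns `case_id`, `latent_size_mm`,
#'   `latent_shape`, `latent_enhancement`, `latent_margin` (as produced by
#'   [sample_truth_table()] or by binding `generate_phantom()$truth` rows).
#' @param model a [reader_model()].
#' @return data.frame (the reader panel) with columns `case_id`, `reader_id`,
#'   `size_mm`, `shape`, `internal_enhancement`, `margin`.
#' @export
simulate_readers <- function(truth, model) {
  stopifnot(inherits(model, "reader_model"))
  need <- c("case_id", "latent_size_mm", "latent_shape", "latent_enhancement", "latent_margin")
  if (!all(need %in% names(truth))) {
    stop("truth table must carry columns: ", paste(setdiff(need, names(truth)), collapse = ", "))
  }
  voc <- heip_vocabulary()
  n <- nrow(truth)
  draw_cat <- function(latent, confusion, categories) {
    row_idx <- match(latent, categories)
    if (anyNA(row_idx)) stop("latent category outside vocabulary: ",
                             paste(unique(latent[is.na(row_idx)]), collapse = ", "))
    u <- stats::runif(length(latent))
    cum <- t(apply(confusion, 1, cumsum))
    picked <- 1L + rowSums(u > cum[row_idx, , drop = FALSE])
    categories[pmin(picked, length(categories))]
  }
  panels <- vector("list", model$n_readers)
  with_local_seed(model$rng_seed, {
    for (r in seq_len(model$n_readers)) {
      e <- stats::rnorm(n, model$size_log_bias[r], model$size_log_sd[r])
      panels[[r]] <- data.frame(
        case_id = truth$case_id,
        reader_id = sprintf("R%d", r),
        size_mm = truth$latent_size_mm * exp(e),
        shape = draw_cat(truth$latent_shape, model$shape_confusion, voc$shape),
        internal_enhancement = draw_cat(truth$latent_enhancement,
                                        model$enhancement_confusion,
                                        voc$internal_enhancement),
        margin = draw_cat(truth$latent_margin, model$margin_confusion, voc$margin),
        stringsAsFactors = FALSE
      )
    }
    if (model$n_readers == 3L) {
      # Three-reader panels of real studies resolve every case by simple
      # majority; emulate that by redrawing the rare all-distinct margin
      # triple (the confusion model conditioned on a majority existing).
      for (tries in 1:100) {
        m1 <- panels[[1]]$margin; m2 <- panels[[2]]$margin; m3 <- panels[[3]]$margin
        split3 <- m1 != m2 & m1 != m3 & m2 != m3
        if (!any(split3)) break
        for (r in 1:3) {
          panels[[r]]$margin[split3] <- draw_cat(
            truth$latent_margin[split3], model$margin_confusion, voc$margin
          )
        }
      }
    }
  })
  panel <- do.call(rbind, panels)
  panel <- panel[order(panel$case_id, panel$reader_id), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Load a phantom cohort from disk
#'
#' Reads back a cohort written by [generate_cohort()] (or assembled by hand in
#' the same layout): per-case `<case>_pre.nii.gz`, `<case>_post.nii.gz` and
#' `<case>_truthmask.nii.gz` volumes plus `panel.csv`, `seed_points.csv` and
#' `truth.csv`.
#'
#' @param dir cohort directory.
#' @return list with `phantoms`, `truth`, `panel` (same shape as
#'   [generate_cohort()]).
#' @export
load_cohort <- function(dir) {
  truth <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  panel <- read_panel(file.path(dir, "panel.csv"))
  seeds <- utils::read.csv(file.path(dir, "seed_points.csv"), stringsAsFactors = FALSE)
  phantoms <- lapply(seq_len(nrow(truth)), function(i) {
    id <- truth$case_id[i]
    for (suffix in c("_pre.nii.gz", "_post.nii.gz", "_truthmask.nii.gz")) {
      if (!file.exists(file.path(dir, paste0(id, suffix)))) {
        stop("case ", id, ": missing volume file ", paste0(id, suffix))
      }
    }
    pre <- read_volume(file.path(dir, paste0(id, "_pre.nii.gz")))
    post <- read_volume(file.path(dir, paste0(id, "_post.nii.gz")))
    mask_vol <- read_volume(file.path(dir, paste0(id, "_truthmask.nii.gz")))
    s <- seeds[seeds$case_id == id, , drop = FALSE]
    if (nrow(s) != 1) stop("case ", id, ": no unique seed point")
    structure(
      list(
        pre = pre, post = post, truth_mask = mask_vol$values > 0.5,
        spacing_mm = pre$spacing_mm,
        seed_mm = c(s$x_mm, s$y_mm, s$z_mm),
        truth = truth[i, , drop = FALSE]
      ),
      class = "phantom"
    )
  })
  list(phantoms = phantoms, truth = truth, panel = panel, paths = list(dir = dir))
}

#' Default parameter ranges for a simulated cohort
#'
#' Ranges from which [generate_cohort()] draws each case's [phantom_spec()].
#' Lesion diameters default to 8-28 mm so the largest lobulated lesion still
#' fits the default grid with the required margin; panel-only studies that need
#' the full clinical size span can use [sample_truth_table()] instead.
#' @return named list of ranges/values understood by [generate_cohort()].
#' @export
cohort_ranges <- function() {
  list(
    diameter_mm = c(8, 28),
    lobulation_amp = c(0, 0.4),
    lobulation_order = c(2L, 4L, 6L),
    margin_blur_mm = c(0.3, 1.5),
    texture_sd = c(0, 0.25),
    texture_corr_mm = c(1.5, 4),
    contrast_level = 200,
    noise_sd = 5,
    grid_shape = c(64, 64, 28),
    spacing_mm = c(0.7, 0.7, 2.5)
  )
}

#' Generate a phantom cohort with a simulated reader panel
#'
#' Draws one [phantom_spec()] per case from `ranges` (diameters log-uniform,
#' other continuous parameters uniform, harmonic order sampled from the listed
#' values), rasterises every phantom, and simulates the reader panel from the
#' latent truth. With `out_dir` set, writes per-case NIfTI pre/post volumes and
#' truth masks, a seed-point CSV and the panel CSV.
#'
#' @param n_cases number of cases (>= 1).
#' @param model a [reader_model()].
#' @param ranges parameter ranges as from [cohort_ranges()].
#' @param rng_seed master seed; per-case spec seeds and the reader seed are
#'   derived substreams, so the whole cohort is reproducible from this one
#'   integer.
#' @param out_dir optional output directory for NIfTI/CSV artefacts.
#' @return list with `phantoms` (list of `phantom`), `truth` (data.frame),
#'   `panel` (data.frame), and `paths` (if `out_dir` was given).
#' @export
generate_cohort <- function(n_cases, model = reader_model(),
                            ranges = cohort_ranges(), rng_seed = 1L,
                            out_dir = NULL) {
  stopifnot(n_cases >= 1)
  runif_range <- function(n, r) stats::runif(n, r[1], r[2])
  with_local_seed(substream_seed(rng_seed, "cohort_specs"), {
    diam <- exp(stats::runif(n_cases, log(ranges$diameter_mm[1]), log(ranges$diameter_mm[2])))
    amp <- runif_range(n_cases, ranges$lobulation_amp)
    ord <- sample(ranges$lobulation_order, n_cases, replace = TRUE)
    blur <- runif_range(n_cases, ranges$margin_blur_mm)
    tsd <- runif_range(n_cases, ranges$texture_sd)
    tcorr <- runif_range(n_cases, ranges$texture_corr_mm)
  })
  phantoms <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec <- phantom_spec(
      grid_shape = ranges$grid_shape, spacing_mm = ranges$spacing_mm,
      base_radius_mm = diam[i] / 2, lobulation_amp = amp[i],
      lobulation_order = ord[i], margin_blur_mm = blur[i],
      texture_sd = tsd[i], texture_corr_mm = tcorr[i],
      contrast_level = ranges$contrast_level, noise_sd = ranges$noise_sd,
      rng_seed = substream_seed(rng_seed, "phantom", i)
    )
    phantoms[[i]] <- generate_phantom(spec, case_id = sprintf("case_%04d", i))
  }
  truth <- do.call(rbind, lapply(phantoms, function(p) p$truth))
  panel_model <- model
  panel_model$rng_seed <- substream_seed(rng_seed, "readers")
  panel <- simulate_readers(truth, panel_model)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seed_points <- data.frame(
      case_id = truth$case_id,
      x_mm = vapply(phantoms, function(p) p$seed_mm[1], 0),
      y_mm = vapply(phantoms, function(p) p$seed_mm[2], 0),
      z_mm = vapply(phantoms, function(p) p$seed_mm[3], 0)
    )
    for (p in phantoms) {
      id <- p$truth$case_id
      write_volume(p$pre, file.path(out_dir, paste0(id, "_pre.nii.gz")))
      write_volume(p$post, file.path(out_dir, paste0(id, "_post.nii.gz")))
      write_volume(
        volume_image(array(as.numeric(p$truth_mask), dim = dim(p$truth_mask)), p$spacing_mm),
        file.path(out_dir, paste0(id, "_truthmask.nii.gz")),
        datatype = "uint8"
      )
    }
    panel_path <- file.path(out_dir, "panel.csv")
    seeds_path <- file.path(out_dir, "seed_points.csv")
    truth_path <- file.path(out_dir, "truth.csv")
    utils::write.csv(panel, panel_path, row.names = FALSE)
    utils::write.csv(seed_points, seeds_path, row.names = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE)
    paths <- list(dir = out_dir, panel = panel_path, seed_points = seeds_path, truth = truth_path)
  }
  list(phantoms = phantoms, truth = truth, panel = panel, paths = paths)
}
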