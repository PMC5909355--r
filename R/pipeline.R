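#' Read a reader-panel CSV
#'
#' Expects the documented header (`case_id, reader_id, size_mm, shape,
#' internal_enhancement, margin`); validates sizes and the closed BI-RADS
#' vocabularies, reporting the offending row numbers. Unknown extra columns
#' are preserved.
#'
#' @param path CSV file path.
#' @return panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "reader_id", "size_mm", "shape", "internal_enhancement", "margin")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.na(panel$size_mm) & panel$size_mm <= 0)) {
    bad <- which(!is.na(panel$size_mm) & panel$size_mm <= 0)
    stop("non-positive size_mm at row(s): ", paste(bad, collapse = ", "))
  }
  voc <- heip_vocabulary()
  for (col in names(voc)) {
    vals <- panel[[col]]
    bad <- which(!is.na(vals) & !(vals %in% voc[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "unknown %s value %s at row %d; allowed: %s",
        col, sQuote(vals[bad[1]]), bad[1], paste(voc[[col]], collapse = ", ")
      ))
    }
  }
  panel
}

#' Write a table as CSV (RFC-4180, UTF-8)
#'
#' @param rows data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default. A YAML
#' file with any subset of these names can override the defaults.
#'
#' @param n_cases simulated cohort size.
#' @param rng_seed master seed; all stage seeds are derived substreams.
#' @param use_truth_mask bypass segmentation and use ground-truth masks.
#' @param voi_half_width_factor segmentation VOI half-width as a multiple of
#'   the latent lesion radius.
#' @param levels,displacement GLCM parameters.
#' @param agreement_B bootstrap replicates for the agreement report.
#' @param n_perm_assoc permutations per association test.
#' @param n_perm_replicate permutations per replication signal test.
#' @param q significance level.
#' @param outer_folds,inner_folds nested-CV fold counts.
#' @param l1_ratio_grid elastic-net mixing grid.
#' @param selection hyperparameter rule, `"min"` or `"1se"`.
#' @param config_file optional YAML file overriding any of the above.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 20L, rng_seed = 1L,
                            use_truth_mask = FALSE, voi_half_width_factor = 2,
                            levels = 32L, displacement = 1L,
                            agreement_B = 500L, n_perm_assoc = 1000L,
                            n_perm_replicate = 99L, q = 0.05,
                            outer_folds = 10L, inner_folds = 10L,
                            l1_ratio_grid = c(0.2, 0.5, 0.8, 1),
                            selection = "1se",
                            config_file = NULL) {
  cfg <- list(
    n_cases = n_cases, rng_seed = rng_seed, use_truth_mask = use_truth_mask,
    voi_half_width_factor = voi_half_width_factor, levels = levels,
    displacement = displacement, agreement_B = agreement_B,
    n_perm_assoc = n_perm_assoc, n_perm_replicate = n_perm_replicate, q = q,
    outer_folds = outer_folds, inner_folds = inner_folds,
    l1_ratio_grid = l1_ratio_grid, selection = selection
  )
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    over <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (cfg$q <= 0 || cfg$q >= 1) stop("q must be in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

config_digest <- function(cfg) {
  # deterministic config fingerprint without external hashing packages
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 4294967291)
}

write_sidecar <- function(path, cfg, stage) {
  side <- list(stage = stage, config_digest = config_digest(cfg),
               rng_seed = cfg$rng_seed, package_version = "0.1.0")
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end simulated analysis
#'
#' Executes simulate -> segment -> extract -> consensus/agreement ->
#' associate -> replicate on a synthetic cohort and writes every artefact
#' (features CSV, agreement report, 24-row association table, 4-row
#' replication report) with a deterministic JSON provenance sidecar.
#' Re-running with an identical configuration reproduces all non-log outputs
#' byte-identically; wall-clock timestamps appear only in the run log.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param reader a [reader_model()] for the simulated panel.
#' @param ranges cohort parameter ranges, see [cohort_ranges()].
#' @param cohort_dir optional directory of an existing on-disk cohort
#'   ([load_cohort()] layout); when given, the simulate stage is skipped.
#' @return invisibly, a list with the in-memory `features`, `consensus`,
#'   `agreement`, `association` and `replication` tables and the written
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         reader = reader_model(), ranges = cohort_ranges(),
                         cohort_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  cat(sprintf("run started; config digest %s\n", config_digest(config)),
      file = log_path)
  inv <- ceip_inventory()
  logf("feature inventory (%d): %s", nrow(inv), paste(inv$name, collapse = ", "))
  logf("resolved config: %s",
       jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))

  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort_dir)) {
      logf("stage simulate: %d cases", config$n_cases)
      cohort <- generate_cohort(
        config$n_cases, model = reader, ranges = ranges,
        rng_seed = substream_seed(config$rng_seed, "simulate")
      )
    } else {
      stage <- "load"
      logf("stage load: cohort from %s", cohort_dir)
      cohort <- load_cohort(cohort_dir)
    }
    stage <- "segment/extract"
    logf("stage segment/extract (use_truth_mask = %s)", config$use_truth_mask)
    features <- cohort_features(
      cohort, use_truth_mask = config$use_truth_mask,
      voi_half_width_factor = config$voi_half_width_factor,
      levels = config$levels, displacement = config$displacement
    )
    stage <- "agreement"
    consensus <- reader_consensus(cohort$panel)
    agreement <- agreement_report(
      cohort$panel, B = config$agreement_B,
      rng_seed = substream_seed(config$rng_seed, "agreement")
    )
    stage <- "associate"
    association <- associate_features(
      consensus, features, n_perm = config$n_perm_assoc,
      rng_seed = substream_seed(config$rng_seed, "associate"), q = config$q
    )
    stage <- "replicate"
    replication <- replicate_heip(
      consensus, features, n_perm = config$n_perm_replicate,
      rng_seed = substream_seed(config$rng_seed, "replicate"),
      l1_ratio_grid = config$l1_ratio_grid,
      outer_folds = config$outer_folds, inner_folds = config$inner_folds,
      selection = config$selection
    )
    list(cohort = cohort, features = features, consensus = consensus,
         agreement = agreement, association = association,
         replication = replication)
  }, error = function(e) {
    writeLines(
      c("INCOMPLETE RUN", paste("failed stage:", stage), paste("error:", conditionMessage(e))),
      file.path(out_dir, "MANIFEST")
    )
    stop(sprintf("pipeline aborted in stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    panel = file.path(out_dir, "panel.csv"),
    consensus = file.path(out_dir, "consensus.csv"),
    agreement = file.path(out_dir, "agreement.csv"),
    agreement_json = file.path(out_dir, "agreement.json"),
    association = file.path(out_dir, "association.csv"),
    replication = file.path(out_dir, "replication.csv"),
    replication_json = file.path(out_dir, "replication.json")
  )
  write_table(result$features, paths$features)
  write_table(result$cohort$panel, paths$panel)
  write_table(result$consensus, paths$consensus)
  write_table(result$agreement, paths$agreement)
  jsonlite::write_json(result$agreement, paths$agreement_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_table(result$association, paths$association)
  write_table(result$replication, paths$replication)
  jsonlite::write_json(result$replication, paths$replication_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (p in paths) write_sidecar(p, config, stage = "run_pipeline")
  writeLines(c("COMPLETE", basename(unlist(paths))), file.path(out_dir, "MANIFEST"))
  logf("run complete")
  invisible(c(result[-1], list(paths = paths)))
}
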