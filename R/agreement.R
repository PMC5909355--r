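#' Pairwise coverage probability of size measurements
#'
#' The probability that two readers' size measurements of the same case are
#' within a stated ratio of each other: the fraction, over all same-case
#' reader pairs pooled across cases, of pairs with
#' `|log s_i - log s_j| < log(tolerance_ratio)`. With the default ratio 1.20
#' this is the "within 20% of each other" agreement measure. Being a log-ratio
#' statistic it is invariant to rescaling all sizes by a common factor.
#'
#' @param panel reader-panel data.frame with columns `case_id` and `size_mm`
#'   (missing sizes are dropped).
#' @param tolerance_ratio agreement tolerance (> 1), default 1.20.
#' @return the coverage probability, in `[0, 1]`.
#' @export
coverage_probability <- function(panel, tolerance_ratio = 1.20) {
  stopifnot(tolerance_ratio > 1)
  ok <- !is.na(panel$size_mm)
  if (any(panel$size_mm[ok] <= 0)) stop("size_mm must be positive")
  logs <- split(log(panel$size_mm[ok]), panel$case_id[ok])
  thr <- log(tolerance_ratio)
  hits <- 0
  total <- 0
  for (s in logs) {
    m <- length(s)
    if (m < 2) next
    dif <- abs(outer(s, s, "-"))[upper.tri(diag(m))]
    hits <- hits + sum(dif < thr)
    total <- total + length(dif)
  }
  if (total == 0) stop("no case has two or more size readings")
  hits / total
}

#' Krippendorff's alpha for a panel column
#'
#' Chance-corrected inter-rater agreement from the coincidence matrix:
#' `alpha = 1 - D_o / D_e` with observed and expected disagreement computed
#' from all rating pairs within cases. The nominal metric uses the 0/1
#' distance; the ordinal metric uses the classical cumulative-frequency rank
#' distance `(sum_{g=c}^{k} n_g - (n_c + n_k)/2)^2`. Cases with fewer than two
#' ratings are ignored; missing ratings are allowed.
#'
#' @param values vector of ratings (character or factor).
#' @param case_ids vector of case identifiers, same length.
#' @param metric `"nominal"` or `"ordinal"`.
#' @param level_order for the ordinal metric, the category levels from lowest
#'   to highest; defaults to the sorted unique values.
#' @return alpha in `[-1, 1]`; exactly 1 (with a warning) if every rating in
#'   the data is identical, the `D_e = 0` limit.
#' @export
krippendorff_alpha <- function(values, case_ids,
                               metric = c("nominal", "ordinal"),
                               level_order = NULL) {
  metric <- match.arg(metric)
  keep <- !is.na(values)
  values <- as.character(values[keep])
  case_ids <- case_ids[keep]
  cats <- if (is.null(level_order)) sort(unique(values)) else level_order
  if (!all(values %in% cats)) {
    stop("ratings outside level_order: ",
         paste(setdiff(unique(values), cats), collapse = ", "))
  }
  K <- length(cats)
  if (K < 2) {
    warning("all ratings identical: expected disagreement is 0; alpha defined as 1")
    return(1)
  }
  # units x categories count matrix, restricted to units with >= 2 ratings
  U <- table(case_ids, factor(values, levels = cats))
  U <- matrix(as.numeric(U), nrow = nrow(U), dimnames = dimnames(U))
  m_u <- rowSums(U)
  U <- U[m_u >= 2, , drop = FALSE]
  m_u <- m_u[m_u >= 2]
  if (nrow(U) < 2) stop("need at least 2 cases with at least 2 ratings")
  # coincidence matrix: o_ck = sum_u n_uc (n_uk - [c == k]) / (m_u - 1)
  W <- U / (m_u - 1)
  O <- t(U) %*% W - diag(colSums(W), K)
  n_c <- rowSums(O)
  n <- sum(n_c)
  delta2 <- if (metric == "nominal") {
    1 - diag(K)
  } else {
    D <- matrix(0, K, K)
    for (c in 1:(K - 1)) {
      for (k in (c + 1):K) {
        v <- sum(n_c[c:k]) - (n_c[c] + n_c[k]) / 2
        D[c, k] <- D[k, c] <- v^2
      }
    }
    D
  }
  D_o <- sum(O * delta2) / n
  D_e <- sum(outer(n_c, n_c) * delta2) / (n * (n - 1))
  if (D_e == 0) {
    warning("expected disagreement is 0; alpha defined as 1")
    return(1)
  }
  1 - D_o / D_e
}

#' Nonparametric bootstrap CI for a panel statistic
#'
#' Resamples *cases* (the exchangeable unit) with replacement and returns the
#' percentile interval of the statistic over `B` replicates. Deterministic
#' given `rng_seed`.
#'
#' @param statistic_fn function taking a panel data.frame and returning a
#'   scalar.
#' @param panel reader-panel data.frame with a `case_id` column.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level, default 0.95.
#' @param rng_seed integer seed.
#' @return named numeric `c(lo, hi)`; attribute `"replicates"` holds the
#'   bootstrap distribution.
#' @export
bootstrap_ci <- function(statistic_fn, panel, B = 2000L, level = 0.95,
                         rng_seed = 1L) {
  stopifnot(B >= 100, level > 0, level < 1)
  ids <- unique(panel$case_id)
  by_case <- split(panel, panel$case_id)
  stats <- rep(NA_real_, B)
  with_local_seed(rng_seed, {
    for (b in seq_len(B)) {
      pick <- sample(ids, length(ids), replace = TRUE)
      rep_panel <- do.call(rbind, lapply(seq_along(pick), function(i) {
        block <- by_case[[pick[i]]]
        block$case_id <- sprintf("bs_%06d", i) # resampled copies are distinct units
        block
      }))
      stats[b] <- tryCatch(statistic_fn(rep_panel), error = function(e) NA_real_)
    }
  })
  fail <- mean(is.na(stats))
  if (fail > 0.10) {
    stop(sprintf("statistic undefined on %.0f%% of bootstrap replicates", 100 * fail))
  }
  qs <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- c(lo = qs[1], hi = qs[2])
  attr(out, "replicates") <- stats
  out
}

#' Per-case consensus of a three-reader panel
#'
#' Categorical descriptors take the simple-majority value (the value chosen by
#' at least two of the three readers); a three-way split (possible only for
#' margin) is an error naming the offending cases. The size consensus is the
#' median of the three readings, a majority-compatible and robust summary of a
#' continuous measurement.
#'
#' @param panel reader-panel data.frame (columns `case_id`, `reader_id`,
#'   `size_mm`, `shape`, `internal_enhancement`, `margin`).
#' @return data.frame with one row per case: `case_id`, `size_mm`, `shape`,
#'   `internal_enhancement`, `margin`.
#' @export
reader_consensus <- function(panel) {
  majority <- function(x, case) {
    tab <- sort(table(x), decreasing = TRUE)
    if (tab[1] < 2) stop("three-way reader split with no majority for case ", case)
    names(tab)[1]
  }
  by_case <- split(panel, panel$case_id)
  rows <- lapply(by_case, function(b) {
    if (nrow(b) != 3) stop("consensus requires exactly 3 readers per case; case ",
                           b$case_id[1], " has ", nrow(b))
    data.frame(
      case_id = b$case_id[1],
      size_mm = stats::median(b$size_mm),
      shape = majority(b$shape, b$case_id[1]),
      internal_enhancement = majority(b$internal_enhancement, b$case_id[1]),
      margin = majority(b$margin, b$case_id[1]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$case_id), , drop = FALSE]
}

#' Full inter-observer agreement report
#'
#' The four-descriptor agreement summary of a reader panel: the 20%-coverage
#' probability for size and Krippendorff's alpha for the three categorical
#' descriptors (nominal metric for the binary shape and internal enhancement,
#' ordinal for the graded margin), each with a case-resampling percentile
#' bootstrap CI.
#'
#' @param panel reader-panel data.frame.
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param rng_seed integer seed.
#' @return data.frame with columns `descriptor`, `statistic`, `estimate`,
#'   `ci_lo`, `ci_hi`, `n_cases`, `B`.
#' @export
agreement_report <- function(panel, B = 2000L, level = 0.95, rng_seed = 1L) {
  voc <- heip_vocabulary()
  stat_fns <- list(
    size = function(p) coverage_probability(p),
    shape = function(p) krippendorff_alpha(p$shape, p$case_id, "nominal"),
    internal_enhancement = function(p) {
      krippendorff_alpha(p$internal_enhancement, p$case_id, "nominal")
    },
    margin = function(p) {
      krippendorff_alpha(p$margin, p$case_id, "ordinal", level_order = voc$margin)
    }
  )
  n_cases <- length(unique(panel$case_id))
  rows <- lapply(seq_along(stat_fns), function(k) {
    fn <- stat_fns[[k]]
    est <- fn(panel)
    ci <- suppressWarnings(
      bootstrap_ci(fn, panel, B = B, level = level,
                   rng_seed = substream_seed(rng_seed, "bootstrap", k))
    )
    data.frame(
      descriptor = names(stat_fns)[k],
      statistic = if (names(stat_fns)[k] == "size") "pi" else "alpha",
      estimate = est, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      n_cases = n_cases, B = B, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
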