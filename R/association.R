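#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau: `(C - D) / sqrt((n0 - Tx)(n0 - Ty))` with concordant and
#' discordant pair counts `C`, `D`, `n0 = n(n-1)/2`, and tie corrections `Tx`,
#' `Ty`. Suitable for heavily tied ordinal data such as a 3-level margin
#' scale. Computed by direct pair enumeration (vectorised sign products).
#'
#' @param x,y numeric (or ordered-encodable) vectors of equal length `>= 3`.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 3) stop("x and y must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("no variation: a vector with all values tied has undefined tau")
  }
  ut <- upper.tri(matrix(0, n, n))
  sx <- sign(outer(x, x, "-"))[ut]
  sy <- sign(outer(y, y, "-"))[ut]
  num <- sum(sx * sy)
  n0 <- n * (n - 1) / 2
  tx <- sum(sx == 0)
  ty <- sum(sy == 0)
  num / sqrt((n0 - tx) * (n0 - ty))
}

#' Permutation p-value for a bivariate statistic
#'
#' Permutes `y` and recomputes the statistic `n_perm` times; the p-value uses
#' the add-one rule `p = (1 + #extreme) / (n_perm + 1)`, so it is never zero.
#' Two-sided extremeness compares `|T|`; one-sided alternatives compare the
#' signed statistic.
#'
#' @param x,y data vectors.
#' @param statistic_fn function of `(x, y)` returning a scalar (default
#'   [kendall_tau()]).
#' @param n_perm number of permutations (>= 100).
#' @param rng_seed integer seed (deterministic result).
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return p-value in `(0, 1]`; attribute `"observed"` holds the observed
#'   statistic.
#' @export
permutation_p <- function(x, y, statistic_fn = kendall_tau, n_perm = 10000L,
                          rng_seed = 1L,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  t_obs <- statistic_fn(x, y)
  extreme <- 0L
  with_local_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      t_b <- statistic_fn(x, sample(y))
      hit <- switch(alternative,
        two_sided = abs(t_b) >= abs(t_obs),
        greater = t_b >= t_obs,
        less = t_b <= t_obs
      )
      extreme <- extreme + hit
    }
  })
  p <- (1 + extreme) / (n_perm + 1)
  attr(p, "observed") <- t_obs
  p
}

#' Mann-Whitney U test of a feature against a binary descriptor
#'
#' Two-sided rank-sum test: exact enumeration for small tie-free samples
#' (both groups `<= 20`), normal approximation with tie correction otherwise
#' (the standard [stats::wilcox.test()] behaviour).
#'
#' @param values numeric feature values.
#' @param group binary grouping vector (two levels, both nonempty).
#' @return list with `U` (the rank-sum statistic of the first group level) and
#'   `p` (two-sided).
#' @export
mann_whitney <- function(values, group) {
  g <- factor(group, levels = unique(group)) # first-appearing level is group 1
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 20 && length(b) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p * m / rank`, with the running minimum taken from
#' the largest rank down and capped at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# HEIP -> candidate CEIP map (category-matched, as in the association table).
heip_ceip_map <- function() {
  inv <- ceip_inventory()
  list(
    size = inv$name[inv$category == "size"],
    shape = inv$name[inv$category == "shape"],
    internal_enhancement = inv$name[inv$category == "texture"],
    margin = inv$name[inv$category == "morphology"]
  )
}

#' Test all HEIP-CEIP associations
#'
#' Builds the 24-row association table: consensus size against each size CEIP
#' and consensus margin (ordinal, circumscribed < irregular < spiculated)
#' against each morphology CEIP via Kendall tau-b with permutation p-values;
#' consensus shape and internal enhancement against their category's CEIP via
#' the two-sided Mann-Whitney U test. Benjamini-Hochberg adjustment is applied
#' across the whole table (configurable to within-descriptor families).
#'
#' @param consensus consensus data.frame from [reader_consensus()].
#' @param features feature data.frame from [cohort_features()] (must share
#'   `case_id`s with `consensus`).
#' @param n_perm permutations for the tau tests.
#' @param rng_seed integer seed.
#' @param q significance level for the `significant` flag (default 0.05).
#' @param bh_family `"table"` (adjust across all 24 rows) or `"descriptor"`.
#' @return data.frame with columns `heip_descriptor`, `ceip_name`,
#'   `statistic_name`, `statistic`, `p_raw`, `p_bh`, `significant`.
#' @export
associate_features <- function(consensus, features, n_perm = 10000L,
                               rng_seed = 1L, q = 0.05,
                               bh_family = c("table", "descriptor")) {
  bh_family <- match.arg(bh_family)
  stopifnot(q > 0, q < 1)
  missing_ids <- setdiff(consensus$case_id, features$case_id)
  extra_ids <- setdiff(features$case_id, consensus$case_id)
  if (length(missing_ids) || length(extra_ids)) {
    stop("case_id mismatch between consensus and features; missing from features: ",
         paste(missing_ids, collapse = ", "), "; missing from consensus: ",
         paste(extra_ids, collapse = ", "))
  }
  features <- features[match(consensus$case_id, features$case_id), , drop = FALSE]
  voc <- heip_vocabulary()
  margin_rank <- match(consensus$margin, voc$margin)
  map <- heip_ceip_map()
  heip_values <- list(
    size = consensus$size_mm,
    shape = consensus$shape,
    internal_enhancement = consensus$internal_enhancement,
    margin = margin_rank
  )
  rows <- list()
  k <- 0L
  for (desc in names(map)) {
    for (feat in map[[desc]]) {
      k <- k + 1L
      xv <- features[[feat]]
      if (desc %in% c("size", "margin")) {
        p <- permutation_p(
          heip_values[[desc]], xv, statistic_fn = kendall_tau,
          n_perm = n_perm, rng_seed = substream_seed(rng_seed, "assoc_perm", k)
        )
        rows[[k]] <- data.frame(
          heip_descriptor = desc, ceip_name = feat, statistic_name = "tau_b",
          statistic = attr(p, "observed"), p_raw = as.numeric(p),
          stringsAsFactors = FALSE
        )
      } else {
        mw <- mann_whitney(xv, heip_values[[desc]])
        rows[[k]] <- data.frame(
          heip_descriptor = desc, ceip_name = feat, statistic_name = "U",
          statistic = mw$U, p_raw = mw$p, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- if (bh_family == "table") {
    benjamini_hochberg(out$p_raw)
  } else {
    stats::ave(out$p_raw, out$heip_descriptor, FUN = benjamini_hochberg)
  }
  out$significant <- out$p_bh < q
  rownames(out) <- NULL
  out
}
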