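#' Model specification for HEIP replication
#'
#' Settings of the penalised-regression replication analysis: model family,
#' elastic-net mixing grid, penalty path length, fold counts of the nested
#' cross-validation, and the hyperparameter selection rule.
#'
#' @param family `"linear"` (size), `"logistic"` (shape, internal
#'   enhancement) or `"ordinal"` (margin).
#' @param l1_ratio_grid elastic-net mixing values searched (`1` = lasso).
#' @param n_lambda length of the log-spaced penalty path.
#' @param outer_folds,inner_folds nested cross-validation fold counts.
#' @param standardise standardise features inside the solver (coefficients are
#'   always reported on the original scale).
#' @param selection `"min"` (penalty minimising inner-CV loss) or `"1se"`
#'   (largest penalty within one standard error of the minimum; sparser).
#' @param rng_seed integer seed governing all fold assignment.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear", "logistic", "ordinal"),
                       l1_ratio_grid = c(0.2, 0.5, 0.8, 1),
                       n_lambda = 30L,
                       outer_folds = 10L, inner_folds = 10L,
                       standardise = TRUE,
                       selection = c("1se", "min"),
                       rng_seed = 1L) {
  family <- match.arg(family)
  selection <- match.arg(selection)
  stopifnot(length(l1_ratio_grid) >= 1, all(l1_ratio_grid > 0 & l1_ratio_grid <= 1))
  stopifnot(outer_folds >= 2, inner_folds >= 2, n_lambda >= 5)
  structure(
    list(
      family = family, l1_ratio_grid = l1_ratio_grid, n_lambda = as.integer(n_lambda),
      outer_folds = as.integer(outer_folds), inner_folds = as.integer(inner_folds),
      standardise = isTRUE(standardise), selection = selection,
      rng_seed = as.integer(rng_seed)
    ),
    class = "model_spec"
  )
}

glmnet_family <- function(family) switch(family, linear = "gaussian", logistic = "binomial")

#' Elastic-net fit at a fixed penalty
#'
#' Minimises `(1/2n) sum loss + strength * (l1_ratio * |beta|_1 +
#' (1 - l1_ratio)/2 * |beta|_2^2)` with squared-error (linear) or logistic
#' negative log-likelihood loss, via glmnet. Constant features are dropped
#' with a warning when standardising. Coefficients are reported on the
#' original feature scale.
#'
#' @param X numeric case-by-feature matrix (no missing values).
#' @param y response (numeric, or binary 0/1 / two-level factor for logistic).
#' @param family `"linear"` or `"logistic"`.
#' @param l1_ratio elastic-net mixing in `(0, 1]`.
#' @param strength penalty strength `lambda > 0`.
#' @param standardise standardise features inside the solver.
#' @return list with `intercept`, `coefficients` (named), `family`,
#'   `l1_ratio`, `strength`.
#' @export
elastic_net_fit <- function(X, y, family = c("linear", "logistic"),
                            l1_ratio = 1, strength = 0.1, standardise = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (nrow(X) < 3) stop("need at least 3 cases")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const) && standardise) {
    warning("dropping constant feature(s): ", paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  # a short descending path ending at the requested strength keeps the
  # coordinate-descent warm starts well conditioned
  path <- sort(unique(strength * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(
    X, y, family = glmnet_family(family), alpha = l1_ratio, lambda = path,
    standardize = standardise, thresh = 1e-10
  )
  cf <- as.numeric(stats::coef(fit, s = strength, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(X))
  list(
    intercept = cf[1], coefficients = cf[-1], family = family,
    l1_ratio = l1_ratio, strength = strength
  )
}

# ---- penalised proportional-odds ordinal regression -------------------------

ordinal_nll <- function(theta, beta, Z, y_idx, K) {
  eta <- drop(Z %*% beta)
  th <- c(-Inf, theta, Inf)
  A <- stats::plogis(th[y_idx + 1L] - eta)
  B <- stats::plogis(th[y_idx] - eta)
  P <- pmax(A - B, 1e-12)
  -mean(log(P))
}

ordinal_grad <- function(theta, beta, Z, y_idx, K) {
  n <- nrow(Z)
  eta <- drop(Z %*% beta)
  th <- c(-Inf, theta, Inf)
  zA <- th[y_idx + 1L] - eta
  zB <- th[y_idx] - eta
  A <- stats::plogis(zA)
  B <- stats::plogis(zB)
  P <- pmax(A - B, 1e-12)
  fA <- A * (1 - A)
  fB <- B * (1 - B)
  g_eta <- (fA - fB) / P / n
  g_beta <- drop(crossprod(Z, g_eta))
  g_theta <- numeric(K - 1)
  for (m in seq_len(K - 1)) {
    g_theta[m] <- -sum(fA[y_idx == m] / P[y_idx == m]) / n +
      sum(fB[y_idx == m + 1L] / P[y_idx == m + 1L]) / n
  }
  list(theta = g_theta, beta = g_beta)
}

# pool-adjacent-violators projection onto non-decreasing sequences
pava_increasing <- function(v) {
  n <- length(v)
  w <- rep(1, n)
  vals <- v
  i <- 1L
  while (i < length(vals)) {
    if (vals[i] > vals[i + 1L] + 1e-12) {
      merged <- (w[i] * vals[i] + w[i + 1L] * vals[i + 1L]) / (w[i] + w[i + 1L])
      vals <- c(vals[seq_len(i - 1L)], merged, vals[-seq_len(i + 1L)])
      w <- c(w[seq_len(i - 1L)], w[i] + w[i + 1L], w[-seq_len(i + 1L)])
      i <- max(i - 1L, 1L)
    } else {
      i <- i + 1L
    }
  }
  rep(vals, times = w)
}

#' Proportional-odds ordinal regression with elastic-net penalty
#'
#' Penalised maximum likelihood for the cumulative-logit model
#' `P(y <= j | x) = logistic(theta_j - x beta)` with the elastic-net penalty
#' `strength * (l1_ratio |beta|_1 + (1 - l1_ratio)/2 |beta|_2^2)` on the
#' slopes only (thresholds are unpenalised and kept monotone by isotonic
#' projection). Solved by proximal gradient descent with backtracking line
#' search; the soft-threshold step produces exact zeros, so the fitted support
#' is well defined.
#'
#' @param X numeric case-by-feature matrix.
#' @param y ordinal response: integer codes `1..K` or an ordered factor. Every
#'   level of the declared scale must be present in the training data.
#' @param l1_ratio,strength elastic-net penalty (as in [elastic_net_fit()]).
#' @param levels_expected the full ordinal scale (integer codes); defaults to
#'   `1:max(y)`.
#' @param standardise standardise features internally.
#' @param max_iter,tol solver controls.
#' @param init optional warm start `list(theta, beta)` on the standardised
#'   scale.
#' @return list with `thresholds` (original scale), `coefficients` (original
#'   scale, named), `objective_trace`, `n_iterations`, plus the standardised-
#'   scale solution (`theta_std`, `beta_std`, `centre`, `scale`) used for warm
#'   starts.
#' @export
ordinal_elastic_net_fit <- function(X, y, l1_ratio = 1, strength = 0.1,
                                    levels_expected = NULL, standardise = TRUE,
                                    max_iter = 400L, tol = 1e-8, init = NULL) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  K <- if (is.null(levels_expected)) max(y) else max(levels_expected)
  if (K < 2) stop("need at least 2 ordinal levels")
  missing_lv <- setdiff(seq_len(K), unique(y))
  if (length(missing_lv)) {
    stop("ordinal level(s) absent from training data: ", paste(missing_lv, collapse = ", "))
  }
  n <- nrow(X)
  centre <- if (standardise) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardise) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, centre, "-"), 2, scl, "/")

  if (is.null(init)) {
    cum <- cumsum(tabulate(y, K) / n)[seq_len(K - 1)]
    theta <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
    theta <- pava_increasing(theta)
    beta <- rep(0, ncol(X))
  } else {
    theta <- init$theta
    beta <- init$beta
  }
  pen <- function(b) strength * (l1_ratio * sum(abs(b)) + (1 - l1_ratio) / 2 * sum(b^2))
  prox_point <- function(th, b, g, t) {
    th_new <- pava_increasing(th - t * g$theta)
    v <- b - t * g$beta
    b_new <- sign(v) * pmax(abs(v) - t * strength * l1_ratio, 0)
    b_new <- b_new / (1 + t * strength * (1 - l1_ratio))
    list(theta = th_new, beta = b_new)
  }
  # FISTA (accelerated proximal gradient) with backtracking and restart on
  # objective increase; stops on a small gradient-mapping norm.
  obj <- ordinal_nll(theta, beta, Z, y, K) + pen(beta)
  trace <- obj
  t_step <- 4
  mth <- theta
  mb <- beta
  momentum <- 1
  for (it in seq_len(max_iter)) {
    g <- ordinal_grad(mth, mb, Z, y, K)
    f0 <- ordinal_nll(mth, mb, Z, y, K)
    repeat {
      cand <- prox_point(mth, mb, g, t_step)
      f_new <- ordinal_nll(cand$theta, cand$beta, Z, y, K)
      dth <- cand$theta - mth
      db <- cand$beta - mb
      quad <- f0 + sum(g$theta * dth) + sum(g$beta * db) +
        (sum(dth^2) + sum(db^2)) / (2 * t_step)
      if (f_new <= quad + 1e-12 || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    obj_new <- f_new + pen(cand$beta)
    if (obj_new > obj) { # restart the momentum sequence at the last iterate
      momentum <- 1
      mth <- theta
      mb <- beta
      next
    }
    momentum_new <- (1 + sqrt(1 + 4 * momentum^2)) / 2
    gamma <- (momentum - 1) / momentum_new
    mth <- cand$theta + gamma * (cand$theta - theta)
    mb <- cand$beta + gamma * (cand$beta - beta)
    step_norm <- sqrt(sum((cand$theta - theta)^2) + sum((cand$beta - beta)^2))
    theta <- cand$theta
    beta <- cand$beta
    momentum <- momentum_new
    trace <- c(trace, obj_new)
    converged <- step_norm / t_step <= max(tol * 1e4, 1e-5) ||
      abs(obj - obj_new) <= tol * max(1, abs(obj)) && step_norm <= 1e-6
    obj <- obj_new
    if (converged) break
  }
  beta_orig <- beta / scl
  theta_orig <- theta + sum(centre * beta_orig)
  names(beta_orig) <- colnames(X)
  list(
    thresholds = theta_orig, coefficients = beta_orig,
    objective_trace = trace, n_iterations = length(trace) - 1L,
    theta_std = theta, beta_std = beta, centre = centre, scale = scl,
    l1_ratio = l1_ratio, strength = strength, K = K
  )
}

#' Linear classifier score of an ordinal fit
#' @param fit result of [ordinal_elastic_net_fit()].
#' @param X new feature matrix.
#' @return numeric score `X beta` (higher score, higher ordinal level).
#' @export
ordinal_score <- function(fit, X) {
  drop(as.matrix(X) %*% fit$coefficients)
}

# lambda at which all ordinal slopes are zero: the slope gradient of the
# thresholds-only model must be dominated by the l1 subgradient.
ordinal_lambda_max <- function(Z, y, K, l1_ratio) {
  cum <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1)]
  theta <- pava_increasing(stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3)))
  g <- ordinal_grad(theta, rep(0, ncol(Z)), Z, y, K)
  max(abs(g$beta)) / max(l1_ratio, 0.01)
}

# ---- folds ------------------------------------------------------------------

# Deterministic, case-order-invariant fold assignment: cases are put into a
# canonical order (lexicographic in y then the feature columns) before the
# seeded shuffle, so permuting the input rows permutes the fold labels with
# them.
make_folds <- function(X, y, k, stratified, seed) {
  n <- length(y)
  if (n < k) stop("fewer cases than folds; use fewer folds")
  canon <- do.call(order, c(list(as.numeric(factor(y))), as.data.frame(X)))
  fold <- integer(n)
  if (stratified) {
    y_f <- factor(y)
    counts <- table(y_f)
    if (any(counts < 2)) {
      stop("stratum too small to stratify (level ",
           paste(names(counts)[counts < 2], collapse = ", "),
           " has < 2 cases); use fewer folds or merge levels")
    }
    with_local_seed(seed, {
      for (lv in levels(y_f)) {
        idx <- canon[y_f[canon] == lv]
        fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    })
  } else {
    with_local_seed(seed, {
      fold[canon] <- sample(rep(seq_len(k), length.out = n))
    })
  }
  fold
}

# ---- inner-CV hyperparameter selection --------------------------------------

select_glmnet <- function(X, y, family, spec, foldid) {
  best <- NULL
  for (a in spec$l1_ratio_grid) {
    # cv.glmnet warns (grouped=FALSE) whenever inner folds hold < 3 cases,
    # expected for small cohorts at ten-fold settings
    cvfit <- suppressWarnings(glmnet::cv.glmnet(
      X, y, family = glmnet_family(family), alpha = a, foldid = foldid,
      nlambda = spec$n_lambda, standardize = spec$standardise
    ))
    lam <- if (spec$selection == "min") cvfit$lambda.min else cvfit$lambda.1se
    loss <- cvfit$cvm[match(lam, cvfit$lambda)]
    if (is.null(best) || loss < best$loss) {
      best <- list(alpha = a, lambda = lam, loss = loss, fit = cvfit)
    }
  }
  best
}

select_ordinal <- function(X, y, spec, foldid, K) {
  centre <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, centre, "-"), 2, scl, "/")
  best <- NULL
  folds <- sort(unique(foldid))
  for (a in spec$l1_ratio_grid) {
    lam_max <- ordinal_lambda_max(Z, y, K, a)
    path <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = spec$n_lambda))
    val_nll <- matrix(NA_real_, length(folds), length(path))
    for (fi in seq_along(folds)) {
      tr <- foldid != folds[fi]
      if (length(setdiff(seq_len(K), unique(y[tr])))) next # unusable inner split
      warm <- NULL
      for (li in seq_along(path)) {
        fit <- ordinal_elastic_net_fit(
          X[tr, , drop = FALSE], y[tr], l1_ratio = a, strength = path[li],
          levels_expected = seq_len(K), standardise = spec$standardise,
          init = warm, max_iter = 200L, tol = 1e-7
        )
        warm <- list(theta = fit$theta_std, beta = fit$beta_std)
        # validation NLL on the held-out inner fold
        Zv <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$centre, "-"), 2, fit$scale, "/")
        val_nll[fi, li] <- ordinal_nll(fit$theta_std, fit$beta_std, Zv, y[!tr], K)
      }
    }
    mean_nll <- colMeans(val_nll, na.rm = TRUE)
    if (all(!is.finite(mean_nll))) next
    li <- if (spec$selection == "min") {
      which.min(mean_nll)
    } else {
      se <- apply(val_nll, 2, function(v) stats::sd(v, na.rm = TRUE)) /
        sqrt(colSums(!is.na(val_nll)))
      thresh <- min(mean_nll, na.rm = TRUE) + se[which.min(mean_nll)]
      min(which(mean_nll <= thresh))
    }
    if (is.null(best) || mean_nll[li] < best$loss) {
      best <- list(alpha = a, lambda = path[li], loss = mean_nll[li])
    }
  }
  if (is.null(best)) stop("ordinal inner cross-validation failed on every split")
  best
}

# ---- nested cross-validation ------------------------------------------------

#' Nested cross-validated out-of-fold predictions
#'
#' For each outer fold, an inner cross-validation on the outer-training cases
#' selects the elastic-net mixing and penalty strength (minimum inner-CV loss
#' by default), the model is refit on the outer-training cases, and the
#' held-out fold is predicted. Every case is predicted exactly once. Folds are
#' stratified for categorical responses and are a deterministic function of
#' `(data, spec$rng_seed)` regardless of case order.
#'
#' @param X numeric case-by-feature matrix.
#' @param y response (numeric for `"linear"`, binary 0/1 for `"logistic"`,
#'   integer `1..K` for `"ordinal"`).
#' @param spec a [model_spec()].
#' @return list with `predictions` (linear: fitted value; logistic:
#'   probability; ordinal: classifier score), `fold` (outer fold id per case),
#'   and `chosen` (data.frame of per-fold selected hyperparameters).
#' @export
nested_cv <- function(X, y, spec) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < spec$outer_folds) stop("fewer cases than outer folds")
  stratified <- spec$family != "linear"
  K <- if (spec$family == "ordinal") max(y) else NA_integer_
  outer_fold <- make_folds(X, y, spec$outer_folds, stratified,
                           substream_seed(spec$rng_seed, "outer_folds"))
  preds <- rep(NA_real_, n)
  chosen <- vector("list", spec$outer_folds)
  for (f in sort(unique(outer_fold))) {
    tr <- outer_fold != f
    te <- !tr
    if (stratified) {
      lv <- unique(y)
      miss <- setdiff(lv, unique(y[tr]))
      if (length(miss)) {
        stop("response level ", paste(miss, collapse = ", "),
             " absent from an outer training split; use fewer folds")
      }
    }
    inner_foldid <- make_folds(
      X[tr, , drop = FALSE], y[tr], spec$inner_folds, stratified,
      substream_seed(spec$rng_seed, "inner_folds", f)
    )
    if (spec$family == "ordinal") {
      sel <- select_ordinal(X[tr, , drop = FALSE], y[tr], spec, inner_foldid, K)
      fit <- ordinal_elastic_net_fit(
        X[tr, , drop = FALSE], y[tr], l1_ratio = sel$alpha, strength = sel$lambda,
        levels_expected = seq_len(K), standardise = spec$standardise
      )
      preds[te] <- ordinal_score(fit, X[te, , drop = FALSE])
    } else {
      sel <- select_glmnet(X[tr, , drop = FALSE], y[tr], spec$family, spec, inner_foldid)
      preds[te] <- as.numeric(stats::predict(
        sel$fit$glmnet.fit, newx = X[te, , drop = FALSE], s = sel$lambda,
        type = "response"
      ))
    }
    chosen[[f]] <- data.frame(fold = f, l1_ratio = sel$alpha, lambda = sel$lambda)
  }
  list(predictions = preds, fold = outer_fold, chosen = do.call(rbind, chosen))
}

# ---- performance metrics ----------------------------------------------------

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney formulation via midranks; tied scores earn half credit.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Replication performance metric
#'
#' The per-descriptor accuracy measure: mean squared deviation for size, AUC
#' for the binary shape and internal-enhancement classifiers, and Kendall
#' tau-b between classifier score and observed level for the ordinal margin.
#'
#' @param predictions out-of-fold predictions/scores from [nested_cv()].
#' @param y observed response.
#' @param heip_kind one of `"size"`, `"shape"`, `"internal_enhancement"`,
#'   `"margin"`.
#' @return named scalar metric.
#' @export
replication_performance <- function(predictions, y,
                                    heip_kind = c("size", "shape",
                                                  "internal_enhancement", "margin")) {
  heip_kind <- match.arg(heip_kind)
  if (length(predictions) != length(y)) stop("prediction/response length mismatch")
  switch(heip_kind,
    size = c(msd = mean((predictions - y)^2)),
    shape = c(auc = auc_score(predictions, y)),
    internal_enhancement = c(auc = auc_score(predictions, y)),
    # a constant classifier score carries no ordering information: tau = 0
    # (the analogue of AUC = 0.5 under the half-credit tie rule)
    margin = c(tau_b = if (length(unique(predictions)) < 2) 0 else
      kendall_tau(predictions, y))
  )
}

#' Permutation test of predictive signal
#'
#' Permutes the response and re-runs the *entire* nested cross-validation
#' (fresh fold assignment per permutation), comparing the permuted metrics to
#' the observed one in the better-performance direction (smaller for MSD,
#' larger for AUC and tau). The add-one rule keeps `p > 0`.
#'
#' @param X feature matrix.
#' @param y response.
#' @param spec a [model_spec()].
#' @param heip_kind metric selector, see [replication_performance()].
#' @param n_perm number of permutations (>= 50).
#' @param rng_seed integer seed.
#' @return p-value in `(0, 1]`; attributes `"observed"` (metric) and
#'   `"permuted"` (vector of permuted metrics).
#' @export
permutation_signal_test <- function(X, y, spec, heip_kind, n_perm = 200L,
                                    rng_seed = 1L) {
  stopifnot(n_perm >= 50)
  spec_obs <- spec
  spec_obs$rng_seed <- substream_seed(rng_seed, "signal_obs")
  obs <- replication_performance(nested_cv(X, y, spec_obs)$predictions, y, heip_kind)
  smaller_better <- heip_kind == "size"
  perm_stats <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    y_b <- with_local_seed(substream_seed(rng_seed, "signal_perm_draw", b), sample(y))
    spec_b <- spec
    spec_b$rng_seed <- substream_seed(rng_seed, "signal_perm_cv", b)
    perm_stats[b] <- replication_performance(
      nested_cv(X, y_b, spec_b)$predictions, y_b, heip_kind
    )
  }
  extreme <- if (smaller_better) sum(perm_stats <= obs) else sum(perm_stats >= obs)
  p <- (1 + extreme) / (n_perm + 1)
  attr(p, "observed") <- unname(obs)
  attr(p, "permuted") <- perm_stats
  p
}

# Full-data model tuned by (single-level) k-fold CV and refit on all cases;
# returns the names of features with nonzero slopes.
selected_ceip <- function(X, y, spec) {
  stratified <- spec$family != "linear"
  foldid <- make_folds(X, y, spec$inner_folds, stratified,
                       substream_seed(spec$rng_seed, "full_fit_folds"))
  if (spec$family == "ordinal") {
    K <- max(y)
    sel <- select_ordinal(X, y, spec, foldid, K)
    fit <- ordinal_elastic_net_fit(X, y, l1_ratio = sel$alpha, strength = sel$lambda,
                                   levels_expected = seq_len(K),
                                   standardise = spec$standardise)
    cf <- fit$coefficients
  } else {
    sel <- select_glmnet(X, y, spec$family, spec, foldid)
    cf_full <- as.numeric(stats::coef(sel$fit$glmnet.fit, s = sel$lambda))
    cf <- cf_full[-1]
    names(cf) <- colnames(X)
  }
  names(cf)[abs(cf) > 1e-10]
}

#' Replicate all four HEIP from the category-matched CEIP
#'
#' The four-descriptor replication analysis: an elastic-net linear model predicts consensus
#' size from the 4 size CEIP (metric: MSD), elastic-net logistic classifiers
#' predict shape from the 3 shape CEIP and internal enhancement from the 14
#' texture CEIP (metric: AUC), and a penalised proportional-odds model
#' predicts the ordinal margin from the 3 morphology CEIP (metric: tau-b
#' between score and level). Performance comes from nested cross-validation,
#' signal p-values from whole-pipeline permutation tests, with
#' Benjamini-Hochberg adjustment across the four descriptors. The reported
#' selected CEIP come from the model tuned by single-level CV on all cases and
#' refit on all cases (selection and assessment kept separate).
#'
#' @param consensus consensus data.frame from [reader_consensus()].
#' @param features feature data.frame from [cohort_features()].
#' @param n_perm permutations per descriptor.
#' @param rng_seed integer seed.
#' @param l1_ratio_grid,n_lambda,outer_folds,inner_folds,selection model
#'   settings applied to every descriptor (see [model_spec()]).
#' @return data.frame with one row per descriptor: `heip_descriptor`,
#'   `model_family`, `metric_name`, `metric`, `p_perm`, `p_bh`,
#'   `selected_ceip` (comma-separated names).
#' @export
replicate_heip <- function(consensus, features, n_perm = 200L, rng_seed = 1L,
                           l1_ratio_grid = c(0.2, 0.5, 0.8, 1), n_lambda = 30L,
                           outer_folds = 10L, inner_folds = 10L,
                           selection = "1se") {
  features <- features[match(consensus$case_id, features$case_id), , drop = FALSE]
  if (anyNA(features$case_id)) stop("consensus/features case_id mismatch")
  voc <- heip_vocabulary()
  map <- heip_ceip_map()
  tasks <- list(
    size = list(family = "linear", y = consensus$size_mm),
    shape = list(family = "logistic",
                 y = as.integer(consensus$shape == "irregular")),
    internal_enhancement = list(family = "logistic",
                                y = as.integer(consensus$internal_enhancement == "heterogeneous")),
    margin = list(family = "ordinal", y = match(consensus$margin, voc$margin))
  )
  metric_names <- c(size = "MSD", shape = "AUC", internal_enhancement = "AUC",
                    margin = "tau_b")
  rows <- vector("list", length(tasks))
  for (k in seq_along(tasks)) {
    desc <- names(tasks)[k]
    task <- tasks[[k]]
    X <- as.matrix(features[, map[[desc]], drop = FALSE])
    spec <- model_spec(
      family = task$family, l1_ratio_grid = l1_ratio_grid, n_lambda = n_lambda,
      outer_folds = outer_folds, inner_folds = inner_folds,
      selection = selection, rng_seed = substream_seed(rng_seed, "replicate_cv", k)
    )
    p <- permutation_signal_test(
      X, task$y, spec, heip_kind = desc, n_perm = n_perm,
      rng_seed = substream_seed(rng_seed, "replicate_perm", k)
    )
    sel <- selected_ceip(X, task$y, spec)
    rows[[k]] <- data.frame(
      heip_descriptor = desc, model_family = task$family,
      metric_name = metric_names[[desc]], metric = attr(p, "observed"),
      p_perm = as.numeric(p),
      selected_ceip = paste(sel, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_bh <- benjamini_hochberg(out$p_perm)
  rownames(out) <- NULL
  out[, c("heip_descriptor", "model_family", "metric_name", "metric",
          "p_perm", "p_bh", "selected_ceip")]
}
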