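sim_linear <- function(n = 200, p = 6, sigma = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = 2 * X[, 1] - X[, 3] + rnorm(n, 0, sigma))
}

test_that("the unpenalised limit of the elastic net is least squares", {
  d <- sim_linear(seed = 2)
  f <- elastic_net_fit(d$X, d$y, "linear", l1_ratio = 1, strength = 1e-8)
  ols <- stats::coef(stats::lm(d$y ~ d$X))
  expect_equal(unname(c(f$intercept, f$coefficients)), unname(ols), tolerance = 1e-6)
})

test_that("above the path-start penalty every slope is exactly zero", {
  d <- sim_linear(seed = 3)
  Z <- scale(d$X) * sqrt(nrow(d$X) / (nrow(d$X) - 1)) # population-sd scaling
  lam_max <- max(abs(crossprod(Z, d$y - mean(d$y)))) / nrow(d$X)
  f <- elastic_net_fit(d$X, d$y, "linear", l1_ratio = 1, strength = lam_max * 1.01)
  expect_true(all(f$coefficients == 0))
  f2 <- elastic_net_fit(d$X, d$y, "linear", l1_ratio = 1, strength = lam_max * 0.5)
  expect_gt(sum(f2$coefficients != 0), 0)
})

test_that("constant features are dropped with a warning", {
  d <- sim_linear(n = 50, seed = 4)
  Xc <- cbind(d$X, const = 1)
  expect_warning(f <- elastic_net_fit(Xc, d$y, "linear", strength = 0.05), "constant")
  expect_false("const" %in% names(f$coefficients))
})

test_that("lasso support is non-increasing along the penalty path", {
  d <- sim_linear(seed = 5)
  lams <- exp(seq(log(2), log(1e-4), length.out = 12))
  nnz <- vapply(lams, function(l) {
    sum(elastic_net_fit(d$X, d$y, "linear", l1_ratio = 1, strength = l)$coefficients != 0)
  }, 0)
  expect_true(all(diff(nnz) >= 0)) # lams descend, support grows monotonically
})

test_that("cv-selected support recovers the true sparse model", {
  d <- sim_linear(seed = 6)
  spec <- model_spec("linear", l1_ratio_grid = 1, rng_seed = 11)
  supp <- ceipr:::selected_ceip(d$X, d$y, spec)
  expect_setequal(supp, c("x1", "x3"))
})

test_that("the ordinal fit honours its contracts", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- paste0("m", seq_len(3))
  eta <- 2 * X[, 1]
  u <- runif(n)
  y <- 1L + (u > stats::plogis(-1 - eta)) + (u > stats::plogis(1 - eta))
  fit <- ordinal_elastic_net_fit(X, y, l1_ratio = 1, strength = 0.01)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_true(fit$thresholds[1] < fit$thresholds[2])
  expect_gt(kendall_tau(ordinal_score(fit, X), y), 0.45)
  # huge penalty: slopes vanish, score constant
  fit0 <- ordinal_elastic_net_fit(X, y, l1_ratio = 1, strength = 10)
  expect_true(all(fit0$coefficients == 0))
  expect_equal(stats::sd(ordinal_score(fit0, X)), 0)
  # missing level is an error naming the level
  expect_error(
    ordinal_elastic_net_fit(X[y < 3, ], y[y < 3], levels_expected = 1:3),
    "level.*3"
  )
})

test_that("the near-unpenalised ordinal fit matches the proportional-odds MLE", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2)
  colnames(X) <- c("a", "b")
  u <- runif(n)
  eta <- 1.2 * X[, 1] - 0.5 * X[, 2]
  y <- 1L + (u > stats::plogis(-0.8 - eta)) + (u > stats::plogis(0.9 - eta))
  ours <- ordinal_elastic_net_fit(X, y, l1_ratio = 1, strength = 1e-6)
  ref <- MASS::polr(factor(y, ordered = TRUE) ~ X, method = "logistic")
  expect_equal(unname(ours$coefficients), unname(stats::coef(ref)), tolerance = 1e-3)
  expect_equal(unname(ours$thresholds), unname(ref$zeta), tolerance = 1e-3)
})

test_that("a single perfectly ordering predictor yields a perfectly monotone score", {
  x <- seq(-3, 3, length.out = 30)
  X <- cbind(sig = x, noise = 0 * x + rnorm(30, sd = 1e-3))
  y <- cut(x, c(-Inf, -1, 1, Inf), labels = FALSE)
  fit <- ordinal_elastic_net_fit(X, y, l1_ratio = 1, strength = 0.005)
  score <- ordinal_score(fit, X)
  # every cross-level pair is ordered correctly
  expect_true(all(tapply(score, y, max)[1:2] < tapply(score, y, min)[2:3]))
  # tau-b then sits exactly at its tie-correction ceiling sqrt((n0-Ty)/n0):
  # ties in the 3-level response make tau-b = 1 unattainable by construction
  n0 <- choose(30, 2)
  ty <- sum(choose(table(y), 2))
  expect_equal(kendall_tau(score, y), sqrt((n0 - ty) / n0), tolerance = 1e-10)
})

test_that("nested CV predicts each case exactly once, deterministically", {
  d <- sim_linear(n = 60, seed = 9)
  spec <- model_spec("linear", l1_ratio_grid = 1, n_lambda = 15, rng_seed = 21)
  cv1 <- nested_cv(d$X, d$y, spec)
  cv2 <- nested_cv(d$X, d$y, spec)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_true(all(!is.na(cv1$predictions)))
  expect_equal(sort(unique(cv1$fold)), 1:10)
  expect_equal(tabulate(cv1$fold), rep(6L, 10))
  # case order invariance: shuffle rows, predictions follow the cases
  set.seed(10)
  perm <- sample(60)
  cv3 <- nested_cv(d$X[perm, ], d$y[perm], spec)
  expect_equal(cv3$predictions[order(perm)], cv1$predictions, tolerance = 1e-10)
})

test_that("nested CV on pure noise estimates MSD near Var(y)", {
  msd_ratio <- vapply(1:10, function(r) {
    set.seed(30 + r)
    X <- matrix(rnorm(60 * 5), 60, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- rnorm(60)
    spec <- model_spec("linear", l1_ratio_grid = 1, n_lambda = 15,
                       rng_seed = 40 + r)
    msd <- replication_performance(nested_cv(X, y, spec)$predictions, y, "size")
    msd / stats::var(y)
  }, 0)
  expect_lt(abs(stats::median(msd_ratio) - 1), 0.15)
})

test_that("nested CV separates a deterministic binary rule almost perfectly", {
  set.seed(12)
  X <- matrix(rnorm(80 * 4), 80, 4)
  colnames(X) <- paste0("x", 1:4)
  y <- as.integer(X[, 1] > 0)
  spec <- model_spec("logistic", l1_ratio_grid = 1, n_lambda = 15, rng_seed = 5)
  auc <- replication_performance(nested_cv(X, y, spec)$predictions, y, "shape")
  expect_gte(auc, 0.95)
})

test_that("stratification failures raise instructive errors", {
  set.seed(13)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- c(rep(0L, 29), 1L)
  spec <- model_spec("logistic", rng_seed = 1)
  expect_error(nested_cv(X, y, spec), "stratum|stratify")
  expect_error(nested_cv(X[1:5, ], rnorm(5), model_spec("linear")), "fewer cases")
})

test_that("AUC matches the exhaustive pairwise oracle and the reference library", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(1, 2, 3), c(0, 0, 1)), 1)
  expect_equal(auc_score(c(1, 1, 1), c(0, 1, 0)), 0.5) # all tied: half credit
  set.seed(14)
  for (r in 1:5) {
    s <- round(rnorm(40), 1) # coarse scores force ties
    l <- as.integer(runif(40) < 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_score(s, l), auc_oracle(s, l), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  s <- rnorm(50)
  l <- as.integer(runif(50) < 0.4)
  expect_equal(
    auc_score(s, l),
    as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<"))),
    tolerance = 1e-12
  )
  expect_error(auc_score(1:4, rep(1, 4)), "one class")
  expect_equal(unname(replication_performance(c(1, 2, 3), c(1, 2, 3), "size")), 0)
})

test_that("permutation signal tests are deterministic with p > 0", {
  set.seed(15)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- paste0("x", 1:3)
  y <- rnorm(40)
  spec <- model_spec("linear", l1_ratio_grid = 1, n_lambda = 10,
                     inner_folds = 5, outer_folds = 5, rng_seed = 2)
  p1 <- permutation_signal_test(X, y, spec, "size", n_perm = 50, rng_seed = 3)
  p2 <- permutation_signal_test(X, y, spec, "size", n_perm = 50, rng_seed = 3)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gt(as.numeric(p1), 0)
  expect_length(attr(p1, "permuted"), 50)
})
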