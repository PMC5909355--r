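panel_of <- function(sizes_by_case) {
  do.call(rbind, lapply(names(sizes_by_case), function(id) {
    s <- sizes_by_case[[id]]
    data.frame(case_id = id, reader_id = sprintf("R%d", seq_along(s)), size_mm = s)
  }))
}

test_that("coverage probability follows its log-ratio definition", {
  expect_equal(coverage_probability(panel_of(list(a = c(10, 10, 10)))), 1)
  # 10 vs 12.5: ratio 1.25 > 1.20 -> miss
  expect_equal(coverage_probability(panel_of(list(a = c(10, 12.5)))), 0)
  # 10 vs 11.9: ratio 1.19 < 1.20 -> hit; pooled with one missing pair
  p <- panel_of(list(a = c(10, 11.9), b = c(30, 40)))
  expect_equal(coverage_probability(p), 0.5)
  # scale invariance
  p2 <- p; p2$size_mm <- p2$size_mm * 3.7
  expect_equal(coverage_probability(p2), coverage_probability(p))
  expect_error(coverage_probability(panel_of(list(a = 5))), "two or more")
  expect_error(coverage_probability(panel_of(list(a = c(-1, 3)))), "positive")
})

test_that("krippendorff alpha is 1 under perfect agreement and matches the hand oracle", {
  # perfect panel with two categories present across cases
  vals <- c("x", "x", "x", "y", "y", "y")
  ids <- c(1, 1, 1, 2, 2, 2)
  expect_equal(krippendorff_alpha(vals, ids, "nominal"), 1)

  # 4-case binary worked example, one dissenting rating: hand computation.
  # units: (a,a,a) (a,a,b) (b,b,b) (b,b,b)
  vals2 <- c("a", "a", "a", "a", "a", "b", "b", "b", "b", "b", "b", "b")
  ids2 <- rep(1:4, each = 3)
  # coincidence: unit2 contributes o_ab = o_ba = 1 each (2 pairs / (m-1)=2);
  # n_a = 5, n_b = 7, n = 12; D_o = 2/12; D_e = 2*5*7/(12*11)
  alpha_hand <- 1 - (2 / 12) / (2 * 5 * 7 / (12 * 11))
  expect_equal(krippendorff_alpha(vals2, ids2, "nominal"), alpha_hand)
})

test_that("alpha decreases as dissent is added and degenerate panels warn", {
  vals <- rep(c("a", "b"), each = 6)
  ids <- rep(1:4, each = 3)
  a0 <- krippendorff_alpha(vals, ids, "nominal")
  vals_d <- vals; vals_d[1] <- "b"
  a1 <- krippendorff_alpha(vals_d, ids, "nominal")
  vals_d2 <- vals_d; vals_d2[4] <- "b"
  a2 <- krippendorff_alpha(vals_d2, ids, "nominal")
  expect_equal(a0, 1)
  expect_gt(a0, a1)
  expect_gt(a1, a2)
  expect_warning(alpha_const <- krippendorff_alpha(rep("a", 6), rep(1:3, each = 2)),
                 "identical")
  expect_equal(alpha_const, 1)
})

test_that("ordinal alpha penalises far disagreements more than near ones", {
  voc <- c("circumscribed", "irregular", "spiculated")
  ids <- rep(1:6, each = 3)
  base <- rep(rep(voc, 2), each = 3)
  near <- base; near[1] <- "irregular"   # circumscribed -> irregular
  far <- base; far[1] <- "spiculated"    # circumscribed -> spiculated
  a_near <- krippendorff_alpha(near, ids, "ordinal", level_order = voc)
  a_far <- krippendorff_alpha(far, ids, "ordinal", level_order = voc)
  expect_gt(a_near, a_far)
})

test_that("bootstrap CI is reproducible, contains the estimate, and degenerates sanely", {
  truth <- sample_truth_table(60, rng_seed = 2)
  panel <- simulate_readers(truth, reader_model(rng_seed = 3))
  ci1 <- bootstrap_ci(coverage_probability, panel, B = 200, rng_seed = 7)
  ci2 <- bootstrap_ci(coverage_probability, panel, B = 200, rng_seed = 7)
  expect_identical(ci1, ci2)
  est <- coverage_probability(panel)
  expect_lte(ci1[["lo"]], est)
  expect_gte(ci1[["hi"]], est)
  degenerate <- panel_of(list(a = c(10, 10, 10), b = c(5, 5, 5), c = c(7, 7, 7)))
  ci_d <- bootstrap_ci(coverage_probability, degenerate, B = 100, rng_seed = 1)
  expect_equal(unname(ci_d[1:2]), c(1, 1))
})

test_that("bootstrap CI coverage is near nominal on calibrated panels", {
  # true pi from the closed form for sigma = 0.13
  pi_true <- 2 * stats::pnorm(log(1.2) / (0.13 * sqrt(2))) - 1
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    truth <- sample_truth_table(60, rng_seed = 1000 + r)
    panel <- simulate_readers(truth, reader_model(rng_seed = 2000 + r))
    ci <- bootstrap_ci(coverage_probability, panel, B = 200, rng_seed = 3000 + r)
    hits <- hits + (ci[["lo"]] <= pi_true && pi_true <= ci[["hi"]])
  }
  expect_gte(hits / reps, 0.85)
})

test_that("consensus takes the majority for categories and the median for size", {
  panel <- data.frame(
    case_id = rep("c1", 3), reader_id = c("R1", "R2", "R3"),
    size_mm = c(18, 20, 29),
    shape = c("irregular", "irregular", "round_oval"),
    internal_enhancement = c("homogeneous", "homogeneous", "homogeneous"),
    margin = c("circumscribed", "circumscribed", "spiculated")
  )
  cons <- reader_consensus(panel)
  expect_equal(cons$size_mm, 20)
  expect_equal(cons$shape, "irregular")
  expect_equal(cons$internal_enhancement, "homogeneous")
  expect_equal(cons$margin, "circumscribed")
  split_panel <- panel
  split_panel$margin <- c("circumscribed", "irregular", "spiculated")
  expect_error(reader_consensus(split_panel), "three-way.*c1")
  expect_error(reader_consensus(panel[1:2, ]), "exactly 3 readers")
})

test_that("the agreement report covers all four descriptors with CIs", {
  truth <- sample_truth_table(50, rng_seed = 5)
  panel <- simulate_readers(truth, reader_model(rng_seed = 6))
  rep_tab <- agreement_report(panel, B = 150, rng_seed = 8)
  expect_equal(rep_tab$descriptor,
               c("size", "shape", "internal_enhancement", "margin"))
  expect_equal(rep_tab$statistic, c("pi", "alpha", "alpha", "alpha"))
  expect_true(all(rep_tab$ci_lo <= rep_tab$estimate + 1e-12))
  expect_true(all(rep_tab$ci_hi >= rep_tab$estimate - 1e-12))
  expect_true(all(rep_tab$estimate >= -1 & rep_tab$estimate <= 1))
})
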