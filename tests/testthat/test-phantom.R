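test_that("an unperturbed, unblurred, noiseless spec rasterises a digital sphere", {
  spec <- phantom_spec(
    grid_shape = c(29, 29, 29), spacing_mm = c(1, 1, 1),
    base_radius_mm = 10, lobulation_amp = 0, margin_blur_mm = 0,
    texture_sd = 0, noise_sd = 0, rng_seed = 1
  )
  ph <- generate_phantom(spec)
  vol_true <- 4 / 3 * pi * 10^3
  expect_lt(abs(sum(ph$truth_mask) - vol_true) / vol_true, 0.05)
  # the mask is exactly the centre-inside ball
  expect_identical(ph$truth_mask, digital_ball(10, c(1, 1, 1), pad_vox = 4))
  # binary enhancement: post - pre is contrast_level on the lesion, 0 outside
  enh <- ph$post$values - ph$pre$values
  expect_equal(unique(enh[ph$truth_mask]), spec$contrast_level)
  expect_equal(unique(enh[!ph$truth_mask]), 0)
  expect_equal(ph$truth$latent_shape, "round_oval")
  expect_equal(ph$truth$latent_margin, "circumscribed")
})

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(base_radius_mm = 8, lobulation_amp = 0.25,
                       lobulation_order = 6, rng_seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pre$values, b$pre$values)
  expect_identical(a$post$values, b$post$values)
  expect_identical(a$truth_mask, b$truth_mask)
  spec2 <- phantom_spec(base_radius_mm = 8, lobulation_amp = 0.25,
                        lobulation_order = 6, rng_seed = 43)
  c <- generate_phantom(spec2)
  expect_false(identical(a$post$values, c$post$values))
})

test_that("lobulation increases surface area over the sphere (quadrature oracle)", {
  base <- list(grid_shape = c(41, 41, 41), spacing_mm = c(1, 1, 1),
               base_radius_mm = 12, margin_blur_mm = 0, texture_sd = 0,
               noise_sd = 0, rng_seed = 1)
  specs <- lapply(c(0, 0.1, 0.2, 0.3), function(a) {
    do.call(phantom_spec, c(base, list(lobulation_amp = a, lobulation_order = 6)))
  })
  # analytic: perturbed surface strictly larger than the sphere of same base radius
  areas_q <- vapply(specs, sh_area_quadrature, 0)
  expect_equal(areas_q[1], 4 * pi * 12^2, tolerance = 1e-4)
  expect_true(all(diff(areas_q) > 0))
  # rasterised: mesh area of the truth mask is non-decreasing in amplitude
  areas_mesh <- vapply(specs, function(s) {
    mask_surface_area(generate_phantom(s)$truth_mask, s$spacing_mm)
  }, 0)
  expect_true(all(diff(areas_mesh) > -1e-6))
  # mesh tracks the analytic area for the strongly lobulated case
  expect_lt(abs(areas_mesh[4] - areas_q[4]) / areas_q[4], 0.10)
})

test_that("a lesion that violates the grid margin is rejected with the axis named", {
  expect_error(
    phantom_spec(grid_shape = c(20, 64, 28), spacing_mm = c(0.7, 0.7, 2.5),
                 base_radius_mm = 10),
    "margin on axis 1"
  )
  expect_error(phantom_spec(lobulation_amp = 0.7), "lobulation_amp")
  expect_error(phantom_spec(base_radius_mm = -1), "base_radius_mm")
})

test_that("latent categories follow the documented generator thresholds", {
  cat_of <- function(amp, tsd = 0) {
    spec <- phantom_spec(base_radius_mm = 8, lobulation_amp = amp,
                         lobulation_order = 6, texture_sd = tsd)
    generate_phantom(spec)$truth[c("latent_shape", "latent_margin", "latent_enhancement")]
  }
  expect_equal(cat_of(0.05)$latent_shape, "round_oval")
  expect_equal(cat_of(0.05)$latent_margin, "circumscribed")
  expect_equal(cat_of(0.15)$latent_shape, "irregular")
  expect_equal(cat_of(0.15)$latent_margin, "irregular")
  expect_equal(cat_of(0.30)$latent_margin, "spiculated")
  expect_equal(cat_of(0.05, tsd = 0.05)$latent_enhancement, "homogeneous")
  expect_equal(cat_of(0.05, tsd = 0.20)$latent_enhancement, "heterogeneous")
})

test_that("noiseless readers with identity confusions reproduce the latent truth", {
  truth <- sample_truth_table(40, rng_seed = 3)
  model <- reader_model(
    size_log_sd = 0, shape_confusion = diag(2),
    enhancement_confusion = diag(2), margin_confusion = diag(3), rng_seed = 5
  )
  panel <- simulate_readers(truth, model)
  expect_equal(nrow(panel), 120)
  m <- merge(panel, truth, by = "case_id")
  expect_equal(m$size_mm, m$latent_size_mm)
  expect_equal(m$shape, m$latent_shape)
  expect_equal(m$internal_enhancement, m$latent_enhancement)
  expect_equal(m$margin, m$latent_margin)
})

test_that("reader models validate their confusion matrices", {
  bad <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2, byrow = TRUE)
  expect_error(reader_model(shape_confusion = bad), "sum to 1")
  expect_error(reader_model(margin_confusion = diag(2)), "3 x 3")
  expect_error(reader_model(size_log_sd = -0.1), "size_log_sd")
})

test_that("simulated panels are deterministic and reflect the confusion model", {
  truth <- sample_truth_table(200, rng_seed = 7)
  model <- reader_model(rng_seed = 9)
  p1 <- simulate_readers(truth, model)
  p2 <- simulate_readers(truth, model)
  expect_identical(p1, p2)
  # three-reader generated panels never contain an unresolvable margin split
  by_case <- split(p1$margin, p1$case_id)
  expect_true(all(vapply(by_case, function(m) length(unique(m)) < 3, TRUE)))
})

test_that("generate_cohort honours counts, ranges, and determinism", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(5, rng_seed = 21, out_dir = tmp)
  expect_length(co$phantoms, 5)
  expect_equal(nrow(co$panel), 15)
  expect_true(all(file.exists(file.path(
    tmp, paste0(co$truth$case_id, "_post.nii.gz")
  ))))
  rng <- cohort_ranges()$diameter_mm
  expect_true(all(co$truth$latent_size_mm >= rng[1] * 0.99))
  # latent size is the max caliper diameter, slightly above the sampled
  # equivalent diameter for lobulated cases; allow the lobulation headroom
  expect_true(all(co$truth$latent_size_mm <= rng[2] * (1 + 0.4) * 1.01))
  co2 <- generate_cohort(5, rng_seed = 21)
  expect_identical(co$panel, co2$panel)
  expect_identical(co$truth, co2$truth)
})

test_that("a cohort written to disk loads back intact", {
  tmp <- withr::local_tempdir()
  co <- generate_cohort(3, rng_seed = 33, out_dir = tmp)
  back <- load_cohort(tmp)
  expect_equal(back$truth$case_id, co$truth$case_id)
  expect_equal(back$panel$size_mm, co$panel$size_mm, tolerance = 1e-6)
  expect_identical(back$phantoms[[2]]$truth_mask, co$phantoms[[2]]$truth_mask)
  expect_equal(back$phantoms[[1]]$post$values, co$phantoms[[1]]$post$values,
               tolerance = 1e-4) # float storage
  file.remove(file.path(tmp, "case_0002_post.nii.gz"))
  expect_error(load_cohort(tmp), "case_0002.*missing volume")
})
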