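test_that("degenerate target proportions give single-class maps", {
  sp <- scene_spec(seed = 1, gsd_m = 0.5, target_props = c(1, 0, 0))
  tr <- generate_truth_map(sp, c(0, 0, 50, 50))
  expect_true(all(tr == COVER_CLASSES[["barren"]]))
  sp2 <- scene_spec(seed = 1, gsd_m = 0.5, target_props = c(0, 0, 1))
  expect_true(all(generate_truth_map(sp2, c(0, 0, 50, 50)) ==
                    COVER_CLASSES[["shrub"]]))
})

test_that("realized proportions track the targets within 0.02 on a 1000x1000 scene", {
  sp <- scene_spec(seed = 1, gsd_m = 0.1, target_props = c(0.755, 0.035, 0.210))
  tr <- generate_truth_map(sp, c(0, 0, 100, 100))
  expect_equal(dim(tr), c(1000L, 1000L))
  p <- class_proportions(tr)
  expect_true(all(abs(p - c(0.755, 0.035, 0.210)) <= 0.02))
})

test_that("proportion fidelity holds across seeds (property)", {
  targets <- c(0.755, 0.035, 0.210)
  for (s in 1:20) {
    sp <- scene_spec(seed = s, gsd_m = 0.1)
    tr <- generate_truth_map(sp, c(0, 0, 100, 100))
    expect_true(all(abs(class_proportions(tr) - targets) <= 0.02),
                label = sprintf("seed %d within tolerance", s))
  }
})

test_that("scene generation is bit-identical under the same spec and seed", {
  sp <- scene_spec(seed = 99, gsd_m = 0.25)
  t1 <- generate_truth_map(sp, c(0, 0, 80, 60))
  t2 <- generate_truth_map(sp, c(0, 0, 80, 60))
  expect_identical(t1, t2)
  r1 <- render_rgb(t1, sp); r2 <- render_rgb(t2, sp)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("noiseless rendering returns exact class means; confusability 1 merges spectra", {
  sp <- separable_spec(seed = 5, gsd_m = 0.5)
  tr <- generate_truth_map(sp, c(0, 0, 60, 60))
  rgb <- render_rgb(tr, sp)
  mu <- default_spectra()$means
  for (cl in COVER_CLASSES) {
    sel <- which(unclass(tr) == cl)
    if (!length(sel)) next
    np <- prod(dim(tr))
    for (band in 1:3) {
      vals <- unclass(rgb)[sel + (band - 1) * np]
      expect_true(all(vals == mu[cl, band]))
    }
  }
  spc <- scene_spec(seed = 5, gsd_m = 0.5, confusability = 1,
                    noise_sd = 0, shadow_fraction = 0)
  rgbc <- render_rgb(tr, spc)
  ns <- which(unclass(tr) == COVER_CLASSES[["nonshrub"]])
  if (length(ns)) {
    np <- prod(dim(tr))
    got <- sapply(1:3, function(b) unclass(rgbc)[ns[1] + (b - 1) * np])
    expect_equal(got, default_spectra()$dark_soil)
  }
})

test_that("shadow mask covers about the requested fraction of shrub-adjacent pixels", {
  sp <- scene_spec(seed = 7, gsd_m = 0.1, shadow_fraction = 0.1)
  tr <- generate_truth_map(sp, c(0, 0, 60, 60))
  rgb <- render_rgb(tr, sp)
  cand <- attr(rgb, "shadow_candidates")
  mask <- attr(rgb, "shadow_mask")
  expect_gt(sum(cand), 1000)
  ratio <- sum(mask) / sum(cand)
  expect_lt(abs(ratio - 0.1), 0.01)   # within 10% of 0.1
  expect_true(all(cand | !mask))       # shadows only on candidate pixels
})

test_that("simulate_study resamples one landscape across altitudes", {
  des <- survey_design(list(c(1, 1)))
  sp <- separable_spec(seed = 11, gsd_m = 0.25)
  scenes <- simulate_study(sp, des, altitudes_m = c(75, 100, 120),
                           gsd_mod = gsd_model(0.25 / 75))
  expect_equal(names(scenes), c("alt_75", "alt_100", "alt_120"))
  # native altitude: identity resample
  expect_equal(scenes$alt_75$gsd_m, 0.25)
  expect_identical(unclass(scenes$alt_75$truth),
                   unclass(generate_truth_map(sp, des)))
  # coarser gsd shrinks the pixel count roughly by the gsd ratio squared
  ratio <- prod(dim(scenes$alt_120$truth)) / prod(dim(scenes$alt_75$truth))
  expect_equal(ratio, (75 / 120)^2, tolerance = 0.02)
  expect_error(simulate_study(sp, des, altitudes_m = c(-5)), "positive")
})

test_that("scene specs round-trip through the flat config file", {
  sp <- scene_spec(seed = 13, gsd_m = 0.07, target_props = c(0.6, 0.1, 0.3),
                   spatial_corr_length_m = 2.5, shadow_fraction = 0.12,
                   confusability = 0.33, noise_sd = 7)
  f <- tempfile(fileext = ".cfg")
  write_scene_spec(sp, f)
  sp2 <- read_scene_spec(f)
  expect_equal(sp2[names(sp2) != "class_spectra"],
               sp[names(sp) != "class_spectra"])
  expect_equal(sp2$class_spectra$means, sp$class_spectra$means,
               ignore_attr = TRUE)
})
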