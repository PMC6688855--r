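test_that("two-colour image with K = 2 separates exactly with zero objective", {
  a <- array(0, c(10, 10, 3))
  a[6:10, , ] <- 200
  rgb <- rgb_raster(a, 1)
  mod <- fit_clusters(rgb, K = 2, seed = 1)
  expect_equal(sort(mod$centers[, 1]), c(0, 200))
  expect_equal(tail(mod$objective, 1), 0)
})

test_that("Lloyd objective is monotone non-increasing", {
  set.seed(4)
  a <- array(runif(40 * 40 * 3) * 255, c(40, 40, 3))
  rgb <- rgb_raster(a, 1)
  mod <- fit_clusters(rgb, K = 8, seed = 2)
  expect_true(all(diff(mod$objective) <= 1e-9))
})

test_that("fit matches an independently recomputed Lloyd trajectory", {
  set.seed(9)
  a <- array(sample(0:255, 100 * 3, replace = TRUE), c(10, 10, 3))
  rgb <- rgb_raster(a, 1)
  mod <- fit_clusters(rgb, K = 3, seed = 7, tol = 0)
  # oracle: plain R Lloyd from the same k-means++ start, step by step
  X <- matrix(as.numeric(a), ncol = 3)
  set.seed(7)
  C <- dronecover:::kmeanspp_init(X, 3)
  obj <- numeric(0)
  for (it in seq_len(mod$iterations)) {
    d <- as.matrix(dist(rbind(C, X)))[seq_len(3), -seq_len(3), drop = FALSE]
    lab <- apply(d, 2, which.min)
    obj <- c(obj, sum((X - C[lab, ])^2))
    for (k in 1:3) if (any(lab == k)) C[k, ] <- colMeans(X[lab == k, , drop = FALSE])
  }
  expect_equal(mod$objective, obj)
})

test_that("stats::kmeans started from the same centres agrees on the optimum", {
  set.seed(12)
  a <- array(runif(30 * 30 * 3) * 255, c(30, 30, 3))
  rgb <- rgb_raster(a, 1)
  mod <- fit_clusters(rgb, K = 5, seed = 3, tol = 0, max_iter = 200)
  X <- matrix(as.numeric(a), ncol = 3)
  set.seed(3)
  C0 <- dronecover:::kmeanspp_init(X, 5)
  km <- suppressWarnings(kmeans(X, centers = C0, iter.max = 200,
                                algorithm = "Lloyd"))
  expect_equal(tail(mod$objective, 1), km$tot.withinss, tolerance = 1e-8)
})

test_that("cluster reclassification follows the plurality of the reference", {
  # 3 colours <-> 3 clusters; reference swaps one cluster 60/40
  a <- array(0, c(10, 12, 3))
  a[, 5:8, ] <- 120
  a[, 9:12, ] <- 250
  rgb <- rgb_raster(a, 1)
  ref <- matrix(COVER_CLASSES[["barren"]], 10, 12)
  ref[, 5:8] <- COVER_CLASSES[["shrub"]]
  # make the third colour 60% barren / 40% shrub in the reference -> barren
  ref[1:6, 9:12] <- COVER_CLASSES[["barren"]]
  ref[7:10, 9:12] <- COVER_CLASSES[["shrub"]]
  mod <- fit_clusters(rgb, K = 3, seed = 1)
  cls <- reclassify_clusters(mod, rgb, cr(ref))
  expect_equal(unique(as.vector(unclass(cls)[, 9:12])),
               COVER_CLASSES[["barren"]])
  expect_equal(unique(as.vector(unclass(cls)[, 5:8])),
               COVER_CLASSES[["shrub"]])
  # manual mode applies the map verbatim
  cls2 <- reclassify_clusters(mod, rgb, reclass_map = rep(2L, 3))
  expect_true(all(cls2 == 2L))
})

test_that("perfectly aligned clusters reproduce the truth raster", {
  sp <- separable_spec(seed = 14, gsd_m = 0.5)
  tr <- generate_truth_map(sp, c(0, 0, 60, 60))
  rgb <- render_rgb(tr, sp)
  mod <- suppressWarnings(fit_clusters(rgb, K = 3, seed = 2))
  cls <- reclassify_clusters(mod, rgb, tr)
  expect_equal(unclass(cls), unclass(tr), ignore_attr = TRUE)
})

test_that("noiseless separable scenes classify at >= 0.99 accuracy with K = 30", {
  des <- small_design()
  sp <- separable_spec(seed = 17, gsd_m = 0.5)
  tr <- generate_truth_map(sp, des)
  rgb <- render_rgb(tr, sp)
  cls <- suppressWarnings(classify_raster(rgb, tr, K = 30, seed = 5, design = des))
  ok <- !is.na(unclass(cls))
  acc <- mean(unclass(cls)[ok] == unclass(tr)[ok])
  expect_gte(acc, 0.99)
})

test_that("mean accuracy is non-increasing in confusability (10 seeds)", {
  des <- survey_design(list(c(1, 1)))
  oa <- sapply(c(0, 0.5, 1), function(cf) {
    mean(sapply(1:10, function(s) {
      sp <- scene_spec(seed = 100 + s, gsd_m = 0.5, confusability = cf,
                       shadow_fraction = 0, noise_sd = 10)
      tr <- generate_truth_map(sp, des)
      cls <- classify_raster(render_rgb(tr, sp), tr, K = 30, seed = s)
      mean(unclass(cls) == unclass(tr))
    }))
  })
  # non-increasing up to Monte-Carlo jitter on the separable plateau,
  # with a strict overall decrease once the spectra truly overlap
  expect_true(all(diff(oa) <= 0.005))
  expect_lt(oa[3], oa[1] - 0.01)
})

test_that("higher confusability worsens non-shrub omission (direction check)", {
  des <- survey_design(list(c(2, 2)))
  om <- sapply(c(0, 1), function(cf) {
    sp <- scene_spec(seed = 23, gsd_m = 0.5, confusability = cf,
                     shadow_fraction = 0, noise_sd = 10)
    tr <- generate_truth_map(sp, des)
    rgb <- render_rgb(tr, sp)
    cls <- classify_raster(rgb, tr, K = 30, seed = 5)
    cm <- table(factor(as.vector(cls), levels = 1:3),
                factor(as.vector(tr), levels = 1:3))
    1 - cm[2, 2] / sum(cm[, 2])   # non-shrub omission error
  })
  expect_gt(om[2], om[1])
})
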