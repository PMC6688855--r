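test_that("largest-remainder apportionment matches hand arithmetic", {
  expect_equal(largest_remainder(c(0.755, 0.035, 0.210), 100), c(75L, 4L, 21L))
  expect_equal(largest_remainder(c(1, 0, 0), 100), c(100L, 0L, 0L))
  set.seed(15)
  for (rep in 1:20) {
    sh <- runif(3); n <- sample(10:500, 1)
    a <- largest_remainder(sh, n)
    expect_equal(sum(a), n)
    expect_true(all(abs(a - sh / sum(sh) * n) < 1))  # within one seat
  }
})

test_that("stratified points allocate by class area and avoid duplicates", {
  sp <- separable_spec(seed = 19, gsd_m = 0.5)
  des <- survey_design(list(c(2, 2)))
  tr <- generate_truth_map(sp, des)
  pts <- stratified_points(tr, des$plots[1, ], n_points = 100, seed = 2)
  expect_equal(nrow(pts), 100L)
  expect_equal(anyDuplicated(pts[, c("row", "col")]), 0L)
  area <- tabulate(unclass(tr)[, 1:200], 3)
  expect_equal(as.vector(table(factor(pts$mapped, levels = 1:3))),
               largest_remainder(area, 100))
  # single-class plot: everything lands in that class
  uni <- class_raster(matrix(3L, 120, 120), 1)
  p2 <- stratified_points(uni, list(xmin = 0, ymin = 0, xmax = 120, ymax = 120),
                          100, seed = 1)
  expect_true(all(p2$mapped == 3L))
})

test_that("confusion matrix counts mapped x reference pairs correctly", {
  mp <- cr(matrix(1L, 10, 10))
  rf <- cr(matrix(1L, 10, 10))
  # plant 2 known disagreements among 10 assessed points
  rf[3, 3] <- 2L; rf[7, 7] <- 3L
  pts <- tibble::tibble(row = c(1:8, 3, 7), col = c(1:8, 3, 7))
  pts$row <- c(1, 2, 4, 5, 6, 8, 9, 10, 3, 7)
  pts$col <- pts$row
  cm <- confusion_matrix(pts, mp, rf)
  expect_equal(sum(cm), 10L)
  expect_equal(sum(cm) - sum(diag(cm)), 2L)
  expect_equal(cm["barren", "nonshrub"], 1L)
  expect_equal(cm["barren", "shrub"], 1L)
  # column sums = reference counts at the points
  expect_equal(unname(colSums(cm)), c(8L, 1L, 1L))
  # identical rasters give a diagonal matrix
  cm2 <- confusion_matrix(pts, mp, mp)
  expect_equal(sum(cm2) - sum(diag(cm2)), 0L)
})

test_that("accuracy metrics reproduce the closed-form 2x2 example", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2)  # rows mapped, cols reference
  met <- accuracy_metrics(cm)
  expect_equal(met$overall_accuracy, 0.85)
  expect_equal(met$kappa, 0.70)
  perfect <- diag(c(30, 30, 40))
  mp <- accuracy_metrics(perfect)
  expect_equal(mp$overall_accuracy, 1)
  expect_equal(mp$kappa, 1)
  expect_true(all(mp$omission == 0) && all(mp$commission == 0))
  expect_warning(accuracy_metrics(matrix(c(9, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("OA and kappa agree with a brute-force oracle on random 3x3 matrices", {
  set.seed(33)
  for (rep in 1:1000) {
    cm <- matrix(sample(0:50, 9, replace = TRUE), 3, 3)
    if (sum(cm) == 0) next
    met <- suppressWarnings(accuracy_metrics(cm))
    n <- sum(cm)
    po <- (cm[1, 1] + cm[2, 2] + cm[3, 3]) / n
    pe <- 0
    for (c_ in 1:3) pe <- pe + sum(cm[c_, ]) * sum(cm[, c_]) / n^2
    expect_equal(met$overall_accuracy, po)
    if (abs(1 - pe) > 1e-12) expect_equal(met$kappa, (po - pe) / (1 - pe))
  }
})

test_that("kappa of independent random labels is near zero", {
  set.seed(44)
  n <- 1e5
  a <- sample(1:3, n, replace = TRUE, prob = c(.5, .2, .3))
  b <- sample(1:3, n, replace = TRUE, prob = c(.6, .1, .3))
  cm <- table(factor(a, levels = 1:3), factor(b, levels = 1:3))
  expect_lt(abs(accuracy_metrics(cm)$kappa), 0.05)
})

test_that("across-plot summary gives mean, sample SD and range", {
  mets <- list(list(overall_accuracy = 0.90, kappa = 0.8),
               list(overall_accuracy = 0.95, kappa = 0.9))
  s <- summarize_accuracy(mets)
  expect_equal(s$mean, c(0.925, 0.85))
  expect_equal(s$sd[1], sd(c(0.90, 0.95)))
  expect_equal(s$min, c(0.90, 0.80))
  expect_equal(s$max, c(0.95, 0.90))
  s1 <- summarize_accuracy(mets[1])
  expect_equal(s1$sd, c(0, 0))
  expect_true(all(s1$sd_undefined))
})

test_that("assessment of a perfect classification is flawless across plots", {
  sp <- separable_spec(seed = 27, gsd_m = 0.5)
  des <- small_design()
  tr <- generate_truth_map(sp, des)
  acc <- assess_accuracy(tr, tr, des, n_points = 100, seed = 9)
  expect_equal(acc$points_total, 200L)   # 100 per plot x 2 plots
  expect_equal(acc$summary$mean, c(1, 1))
})
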