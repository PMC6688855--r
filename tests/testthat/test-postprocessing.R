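test_that("majority filter: fixpoints, isolated pixels, brute-force oracle", {
  u <- cr(matrix(2L, 6, 6))
  expect_equal(unclass(majority_filter(u)), unclass(u), ignore_attr = TRUE)
  m <- matrix(1L, 3, 3); m[2, 2] <- 3L
  expect_equal(unclass(majority_filter(cr(m)))[2, 2], 1L)
  set.seed(5)
  for (rep in 1:5) {
    r <- matrix(sample(1:3, 50 * 50, replace = TRUE), 50, 50)
    for (kern in c("8-neighbour", "4-neighbour")) {
      got <- unclass(majority_filter(cr(r), kern))
      expect_equal(got, brute_majority(r, kern == "8-neighbour"),
                   ignore_attr = TRUE)
    }
  }
})

test_that("majority filter ignores no-data in the vote and preserves it", {
  m <- matrix(1L, 3, 3); m[1, 1] <- NA; m[2, 2] <- 3L
  got <- unclass(majority_filter(cr(m)))
  expect_true(is.na(got[1, 1]))
  expect_equal(got[2, 2], 1L)
})

test_that("boundary clean removes one-pixel spurs under priority and conserves pixels", {
  u <- cr(matrix(3L, 5, 5))
  expect_equal(unclass(boundary_clean(u)), unclass(u), ignore_attr = TRUE)
  # 7x7 barren sea with a 1-px shrub spur poking into it from a shrub block
  m <- matrix(1L, 7, 7)
  m[, 1:2] <- 3L
  m[4, 3] <- 3L           # the spur
  got <- boundary_clean(cr(m), priority = c(1L, 3L, 2L), iterations = 1)
  expect_equal(unclass(got)[4, 3], 1L)     # spur absorbed by barren
  expect_equal(sum(!is.na(got)), 49)       # pixel count conserved
  # no new labels ever appear
  set.seed(6)
  r <- cr(matrix(sample(c(1L, 3L), 40 * 40, replace = TRUE), 40, 40))
  out <- boundary_clean(r)
  expect_true(all(unique(as.vector(out)) %in% unique(as.vector(r))))
})

test_that("MMU sieve applies the pixel-area threshold exactly", {
  # at gsd 2.4 cm a patch needs >= 434.03 px (0.25 m^2): 434 dies, 435 lives
  g <- 0.024
  m <- matrix(1L, 80, 80)
  m[2:30, 2:16] <- 3L          # 29 x 15 = 435 px shrub patch
  m[40:70, 40:53] <- 2L        # 31 x 14 = 434 px non-shrub patch
  out <- mmu_sieve(cr2 <- class_raster(m, g), min_area_m2 = 0.25)
  expect_true(any(out == 3L))                      # 435-px patch survives
  expect_false(any(out == 2L))                     # 434-px patch removed
  expect_true(attr(out, "converged"))
})

test_that("MMU sieve relabels islands to the nearest donor and converges", {
  m <- matrix(1L, 20, 20)
  m[10, 10:12] <- 3L           # 3-px shrub island in a barren sea
  out <- mmu_sieve(class_raster(m, 0.1), min_area_m2 = 0.25)
  expect_true(all(out == 1L))
  # no small patches: unchanged
  m2 <- matrix(1L, 30, 30); m2[, 16:30] <- 3L
  out2 <- mmu_sieve(class_raster(m2, 0.1), min_area_m2 = 0.25)
  expect_equal(unclass(out2), m2, ignore_attr = TRUE)
  # all patches sub-MMU: no donor -> error
  expect_error(mmu_sieve(class_raster(matrix(1:2, 1, 2), 0.1)), "donor")
})

test_that("converged sieve leaves no patch below the MMU (property over seeds)", {
  set.seed(77)
  for (rep in 1:5) {
    r <- class_raster(matrix(sample(1:3, 60 * 60, replace = TRUE,
                                    prob = c(.6, .15, .25)), 60, 60), 0.1)
    out <- mmu_sieve(majority_filter(r), min_area_m2 = 0.25)
    if (!attr(out, "converged")) next
    pt <- patch_table(out)
    expect_true(all(pt$area_m2 >= 0.25 - 1e-9))
  }
})

test_that("the full cleaning chain never increases the patch count", {
  set.seed(101)
  for (rep in 1:20) {
    r <- class_raster(matrix(sample(1:3, 50 * 50, replace = TRUE,
                                    prob = c(.5, .2, .3)), 50, 50), 0.12)
    before <- nrow(patch_table(r))
    out <- suppressWarnings(postprocess_chain(r))
    after <- nrow(patch_table(out))
    expect_lte(after, before)
  }
})
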