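test_that("chest exclusion recovers the phantom breast", {
  ph <- phantom_fixture()
  breast <- exclude_chest(ph$image, ph$chest_mask)
  expect_gte(dice(breast, ph$breast_mask), 0.98)
  # empty chest mask: the whole foreground component (breast + chest slab)
  full <- exclude_chest(ph$image, NULL)
  expect_gt(sum(full), sum(breast))
  expect_gte(dice(full & ph$breast_mask, ph$breast_mask), 0.98)
  zero <- image_volume(array(0, c(8, 8, 8)))
  expect_error(exclude_chest(zero), "foreground")
  expect_error(exclude_chest(ph$image, array(TRUE, dim(ph$image$data))),
               "covers")
})

test_that("a 2D mid-slice chest mask propagates through the stack", {
  ph <- phantom_fixture()
  mid2d <- ph$chest_mask[, , (dim(ph$chest_mask)[3] + 1L) %/% 2L]
  breast <- exclude_chest(ph$image, mid2d)
  expect_gte(dice(breast, ph$breast_mask), 0.95)
})

test_that("bias correction is inert without bias and recovers a known field", {
  sp0 <- phantom_spec(bias_amplitude = 0, noise_sd = 0)
  ph0 <- generate_phantom(sp0)
  m0 <- ph0$breast_mask
  bc0 <- bias_correct(ph0$image, m0)
  rel_rms <- sqrt(mean((bc0$data[m0] - ph0$image$data[m0])^2)) /
    mean(ph0$image$data[m0])
  expect_lt(rel_rms, 0.005)
  expect_true(all(bc0$data[m0] > 0))
  # known smooth bias: estimated field tracks the true one inside the mask
  sp1 <- phantom_spec(bias_amplitude = 0.15, noise_sd = 0)
  ph1 <- generate_phantom(sp1)
  true_field <- ph1$image$data / ph0$image$data
  bc1 <- bias_correct(ph1$image, m0)
  est <- attr(bc1, "bias_field")
  expect_gt(cor(est[m0], true_field[m0]), 0.99)
  expect_error(bias_correct(ph0$image, array(FALSE, dim(ph0$image$data))),
               "empty")
})

test_that("one FCM sweep from fixed centers matches the hand-computed update", {
  # independent oracle (membership and center formulas evaluated separately)
  expect_warning(
    f <- fuzzy_c_means(c(1, 2, 9), centers = 2, m = 2, max_iter = 1,
                       init = c(0, 10)),
    "converge")
  expect_equal(f$centers, c(1.47644262, 8.97405343), tolerance = 1e-7)
  expect_equal(f$membership[, 1], c(0.98780488, 0.94117647, 0.01219512),
               tolerance = 1e-7)
})

test_that("FCM separates well-separated clusters and validates inputs", {
  x <- c(rep(50, 100), rep(200, 100))
  f <- fuzzy_c_means(x, centers = 2)
  expect_lt(max(abs(f$centers - c(50, 200))), 1)
  expect_gte(min(apply(f$membership, 1, max)), 0.99)
  expect_error(fuzzy_c_means(rep(3, 10), centers = 2), "distinct")
  expect_error(fuzzy_c_means(1:10, centers = 2, m = 1), "m must be")
})

test_that("FCM memberships sum to one and the objective is non-increasing", {
  set.seed(2)
  x <- c(rnorm(300, 80, 10), rnorm(700, 200, 15))
  f <- fuzzy_c_means(x, centers = 2)
  expect_lt(max(abs(rowSums(f$membership) - 1)), 1e-9)
  expect_true(all(diff(f$objective) <= 1e-8 * f$objective[1]))
})

test_that("segmentation recovers phantom tissue and intensity-scale invariance", {
  ph <- phantom_fixture()
  seg <- segmentation_fixture()
  expect_gte(dice(seg$breast_mask, ph$breast_mask), 0.98)
  expect_gte(dice(seg$fgt_mask, ph$fgt_mask), 0.90)
  expect_lt(abs(seg$percent_density - ph$percent_density), 1.5)
  expect_true(all(seg$fgt_mask[seg$fgt_mask] & seg$breast_mask[seg$fgt_mask]))
  scaled <- image_volume(ph$image$data * 2.5, ph$image$spacing,
                         ph$image$origin)
  seg2 <- segment_breast(scaled, chest_mask = ph$chest_mask)
  expect_identical(seg2$breast_mask, seg$breast_mask)
  expect_identical(seg2$fgt_mask, seg$fgt_mask)
})

test_that("compute_density implements the percent-density definition", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, , ] <- TRUE
  expect_equal(compute_density(m, m, c(10, 10, 10))$percent_density, 100)
  none <- array(FALSE, c(4, 4, 4))
  d <- compute_density(m, none, c(10, 10, 10))
  expect_equal(d$percent_density, 0)
  expect_equal(d$breast_volume, 32 * 1000 / 1000)  # 32 voxels of 1 cm^3
  expect_error(compute_density(none, none, c(1, 1, 1)), "empty")
})
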