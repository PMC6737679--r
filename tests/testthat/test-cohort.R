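test_that("nearest_psd clips eigenvalues and preserves PSD inputs", {
  expect_identical(nearest_psd(diag(3)), diag(3))
  m2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_identical(nearest_psd(m2), m2)
  m3 <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  p <- nearest_psd(m3)
  ev <- eigen(p, symmetric = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(diag(p), rep(1, 3))
  # eigen-decomposition oracle: clipping the negative eigenvalue and
  # rescaling reproduces the projection
  e <- eigen(m3, symmetric = TRUE)
  rec <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
  d <- 1 / sqrt(diag(rec))
  expect_equal(p, rec * tcrossprod(d), tolerance = 1e-10)
  expect_error(nearest_psd(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})

test_that("default correlations encode the printed and derived structure", {
  R <- default_cohort_correlations()
  expect_equal(R["age", "whole_density"], -0.56)
  expect_equal(R["age", "stiffness"], 0.29)
  expect_equal(R["volume", "stiffness"], -0.14)
  expect_equal(R["whole_density", "stiffness"], -0.09)
  expect_equal(R["local_density", "stiffness"], -0.12)
  # implied by the printed means: cov(d, v) = 100 E[fgt] - E[d] E[v]
  expect_equal(R["volume", "whole_density"],
               (100 * 72.7 - 13.1 * 584.4) / (170.4 * 5.8))
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0)
})

test_that("cohort schema, determinism and degenerate sizes", {
  cfg <- cohort_config(seed = 3)
  empty <- sample_cohort(cfg, n = 0)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "age", "breast_volume", "fgt_volume",
                    "whole_percent_density", "local_percent_density",
                    "stiffness", "roi_depth", "stiffness_repeats")
                  %in% names(empty)))
  expect_error(sample_cohort(cfg, n = -1), ">= 0")
  a <- sample_cohort(cfg, n = 50)
  b <- sample_cohort(cfg, n = 50)
  expect_identical(a, b)
  d <- sample_cohort(cohort_config(seed = 4), n = 50)
  expect_false(identical(a$stiffness, d$stiffness))
})

test_that("cohort rows satisfy the record invariants", {
  co <- sample_cohort(cohort_config(seed = 11), n = 400)
  expect_true(all(co$fgt_volume <= co$breast_volume))
  expect_equal(co$whole_percent_density,
               100 * co$fgt_volume / co$breast_volume)
  expect_true(all(co$stiffness > 0))
  expect_true(all(unlist(co$stiffness_repeats) > 0))
  expect_true(all(co$n_repeats >= 3 & co$n_repeats <= 5))
  expect_true(all(lengths(co$stiffness_repeats) == co$n_repeats))
  # the reported stiffness is one of the repeats
  picked <- mapply(function(s, r) any(abs(r - s) < 1e-12),
                   co$stiffness, co$stiffness_repeats)
  expect_true(all(picked))
})

test_that("large-n moments recover the configured values", {
  cfg <- cohort_config(seed = 5)
  co <- sample_cohort(cfg, n = 5000)
  se <- function(sd) 3 * sd / sqrt(5000)
  expect_lt(abs(mean(co$age) - cfg$age_mean), se(cfg$age_sd))
  expect_lt(abs(mean(co$breast_volume) - cfg$volume_mean), se(cfg$volume_sd))
  expect_lt(abs(mean(co$fgt_volume) - cfg$fgt_mean), 3 * se(cfg$fgt_sd))
  expect_lt(abs(mean(co$whole_percent_density) - cfg$whole_density_mean),
            se(cfg$whole_density_sd) + 0.05)
  expect_lt(abs(mean(co$stiffness) - cfg$stiffness_mean), 0.05)
  expect_lt(abs(sd(co$stiffness) - cfg$stiffness_sd), 0.05)
  expect_lt(abs(mean(co$roi_depth) - cfg$roi_depth_mean), se(cfg$roi_depth_sd))
  # observed pairwise correlations track the configured (observable) matrix
  obs <- cor(cbind(co$age, co$breast_volume, co$whole_percent_density,
                   co$local_percent_density, co$stiffness))
  expect_lt(max(abs(obs - cfg$correlations)), 0.04)
})

test_that("identity correlation matrix yields near-zero sample correlations", {
  cfg <- cohort_config(correlations = diag(5), seed = 6)
  co <- sample_cohort(cfg, n = 5000)
  vars <- cbind(co$age, co$breast_volume, co$whole_percent_density,
                co$local_percent_density, co$stiffness)
  obs <- cor(vars)
  # fgt = density * volume / 100 is deliberately correlated with both parents;
  # all *latent* pairs must decorrelate
  expect_lt(max(abs(obs - diag(5))), 0.05)
})
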