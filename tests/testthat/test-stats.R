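test_that("pearson matches the product-moment formula", {
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  # frozen value from an independent formula evaluation
  expect_equal(pearson(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  # direct formula oracle on arbitrary data
  set.seed(9)
  x <- rnorm(40)
  y <- 0.3 * x + rnorm(40)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), manual, tolerance = 1e-12)
  expect_error(pearson(1:4, 1:5), "mismatch")
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson is affine-invariant and sign-flips under negation", {
  set.seed(10)
  x <- rnorm(30)
  y <- rnorm(30)
  r <- pearson(x, y)
  expect_equal(pearson(2.5 * x + 7, y), r)
  expect_equal(pearson(x, 0.1 * y - 3), r)
  expect_equal(pearson(-x, y), -r)
})

test_that("correlation bands follow the study's rule on |r|", {
  expect_equal(as.character(classify_correlation(0.29)), "none")
  expect_equal(as.character(classify_correlation(-0.56)), "moderate")
  expect_equal(as.character(classify_correlation(0.7)), "strong")
  expect_equal(as.character(classify_correlation(c(0, 0.3, 0.5, -0.69, 1))),
               c("none", "weak", "moderate", "moderate", "strong"))
  expect_error(classify_correlation(1.2), "> 1")
})

test_that("coefficient of variation uses the n-1 sample SD", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(2, 3, 4)), 100 / 3, tolerance = 1e-9)
  expect_error(coefficient_of_variation(4), "at least 2")
  expect_error(coefficient_of_variation(c(-2, 0, 2)), "positive")
})

test_that("per-subject CV bins partition the cohort", {
  co <- sample_cohort(cohort_config(seed = 12), n = 300)
  rep <- cohort_report(co)
  expect_equal(sum(rep$cv$bins), 300)
  cvs <- rep$cv$per_subject
  expect_equal(unname(rep$cv$bins["<10%"]), sum(cvs < 10))
  expect_equal(unname(rep$cv$bins[">20%"]), sum(cvs > 20))
})

test_that("cohort report is complete, deterministic and order-invariant", {
  co <- sample_cohort(cohort_config(seed = 13), n = 40)
  rep <- cohort_report(co)
  expect_equal(rep$n, 40)
  expect_equal(nrow(rep$correlations), 5)
  expect_true(all(!is.na(rep$correlations$r)))
  shuffled <- co[sample(nrow(co)), ]
  rep2 <- cohort_report(shuffled)
  expect_equal(rep2$summaries, rep$summaries)
  expect_equal(rep2$correlations$r, rep$correlations$r)
  expect_equal(rep2$cv$mean_cv, rep$cv$mean_cv)
  # single-subject cohort: means defined, SDs flagged undefined
  r1 <- cohort_report(co[1, ])
  expect_equal(unname(r1$summaries["stiffness", "mean"]), co$stiffness[1])
  expect_true(is.na(r1$summaries["stiffness", "sd"]))
  expect_true(length(r1$flags) > 0)
  expect_error(cohort_report(co[, c("age", "stiffness")]), "missing columns")
})

test_that("reports serialize to JSON", {
  co <- sample_cohort(cohort_config(seed = 14), n = 25)
  rep <- cohort_report(co)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n, 25)
  expect_equal(back$cv$mean_cv, rep$cv$mean_cv, tolerance = 1e-9)
})
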