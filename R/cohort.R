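COHORT_VARS <- c("age", "volume", "whole_density", "local_density", "stiffness")

#' Default observable correlation matrix for the synthetic cohort
#'
#' Five printed pairwise correlations are taken from the study cohort:
#' r(age, whole density) = -0.56, r(age, stiffness) = 0.29,
#' r(volume, stiffness) = -0.14, r(whole density, stiffness) = -0.09,
#' r(local density, stiffness) = -0.12. The volume-density correlation is not
#' printed but is over-determined by the printed means, because FGT volume is
#' the product density x volume / 100: cov(d, v) = 100 E\[fgt\] - E\[d\]E\[v\].
#' With the printed means this gives r = -0.390 (larger breasts are fattier).
#' Local density is assumed to track whole density (r = 0.5) and to inherit
#' half of its age trend (r = -0.28); volume-age and volume-local default to 0.
#'
#' @param volume_mean,volume_sd,whole_density_mean,whole_density_sd,fgt_mean
#'   Moments used to derive the volume-density correlation.
#' @return A 5x5 symmetric unit-diagonal matrix over
#'   (age, volume, whole_density, local_density, stiffness).
#' @export
default_cohort_correlations <- function(volume_mean = 584.4,
                                        volume_sd = 170.4,
                                        whole_density_mean = 13.1,
                                        whole_density_sd = 5.8,
                                        fgt_mean = 72.7) {
  r_vd <- (100 * fgt_mean - whole_density_mean * volume_mean) /
    (volume_sd * whole_density_sd)
  R <- diag(5)
  dimnames(R) <- list(COHORT_VARS, COHORT_VARS)
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set("age", "whole_density", -0.56)
  set("age", "local_density", -0.28)
  set("age", "stiffness", 0.29)
  set("volume", "whole_density", r_vd)
  set("volume", "stiffness", -0.14)
  set("whole_density", "local_density", 0.5)
  set("whole_density", "stiffness", -0.09)
  set("local_density", "stiffness", -0.12)
  R
}

#' Configure a synthetic elastography cohort
#'
#' Defaults reproduce the printed summary statistics of the study cohort
#' (n = 20 women, age 24-78): stiffness 2.3 +/- 0.8 m/s, breast volume
#' 584.4 +/- 170.4 cm^3, FGT volume 72.7 +/- 31.3 cm^3, whole-breast percent
#' density 13.1 +/- 5.8 %, ROI depth from skin 1.41 +/- 0.38 cm, mean
#' coefficient of variation of the 3-5 repeated stiffness measurements 12.7%.
#' Local density and the age SD are not printed; defaults (25 +/- 11 %, 13 y)
#' are chosen from the case examples and the age range.
#'
#' @param n_subjects Default cohort size (the study had 20).
#' @param age_mean,age_sd,volume_mean,volume_sd,fgt_mean,fgt_sd Marginal
#'   moments (years, cm^3).
#' @param whole_density_mean,whole_density_sd,local_density_mean,local_density_sd
#'   Percent-density moments.
#' @param stiffness_mean,stiffness_sd Shear-wave speed moments (m/s) of the
#'   reported (selected-ROI) stiffness.
#' @param roi_depth_mean,roi_depth_sd ROI depth from the skin (cm).
#' @param roi_window_cm ROI window width x height (cm).
#' @param mean_cv Target cohort-mean per-subject CV of stiffness repeats (%).
#' @param cv_shape Gamma shape of the subject-CV distribution (mean
#'   `mean_cv`); shape 2 spans the printed 0.7-41.5% range.
#' @param n_repeats_range Inclusive range of repeats per subject.
#' @param repeat_probs Sampling weights over `n_repeats_range` ("in most of
#'   the patients, three locations were measured").
#' @param correlations Observable 5x5 correlation matrix; see
#'   [default_cohort_correlations()].
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L,
                          age_mean = 51.7, age_sd = 13,
                          volume_mean = 584.4, volume_sd = 170.4,
                          fgt_mean = 72.7, fgt_sd = 31.3,
                          whole_density_mean = 13.1, whole_density_sd = 5.8,
                          local_density_mean = 25, local_density_sd = 11,
                          stiffness_mean = 2.3, stiffness_sd = 0.8,
                          roi_depth_mean = 1.41, roi_depth_sd = 0.38,
                          roi_window_cm = c(1.0, 0.5),
                          mean_cv = 12.7, cv_shape = 2,
                          n_repeats_range = c(3L, 5L),
                          repeat_probs = c(0.6, 0.3, 0.1),
                          correlations = NULL,
                          seed = 1L) {
  sds <- c(age_sd, volume_sd, fgt_sd, whole_density_sd, local_density_sd,
           stiffness_sd, roi_depth_sd)
  if (any(sds < 0)) stopf("SDs must be >= 0")
  if (mean_cv < 0) stopf("mean_cv must be >= 0")
  if (n_subjects < 0) stopf("n_subjects must be >= 0")
  kr <- as.integer(n_repeats_range)
  if (length(kr) != 2L || kr[1] < 2L || kr[2] < kr[1])
    stopf("n_repeats_range must be an increasing integer pair with min >= 2")
  if (length(repeat_probs) != kr[2] - kr[1] + 1L)
    stopf("repeat_probs must have one weight per repeat count")
  if (is.null(correlations))
    correlations <- default_cohort_correlations(volume_mean, volume_sd,
                                                whole_density_mean,
                                                whole_density_sd, fgt_mean)
  if (!is.matrix(correlations) || any(dim(correlations) != 5L))
    stopf("correlations must be a 5x5 matrix over (%s)",
          paste(COHORT_VARS, collapse = ", "))
  if (is.null(dimnames(correlations)))
    dimnames(correlations) <- list(COHORT_VARS, COHORT_VARS)
  if (!isTRUE(all.equal(correlations, t(correlations))) ||
      any(abs(diag(correlations) - 1) > 1e-12))
    stopf("correlation matrix must be symmetric with unit diagonal")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_mean = age_mean, age_sd = age_sd,
                 volume_mean = volume_mean, volume_sd = volume_sd,
                 fgt_mean = fgt_mean, fgt_sd = fgt_sd,
                 whole_density_mean = whole_density_mean,
                 whole_density_sd = whole_density_sd,
                 local_density_mean = local_density_mean,
                 local_density_sd = local_density_sd,
                 stiffness_mean = stiffness_mean, stiffness_sd = stiffness_sd,
                 roi_depth_mean = roi_depth_mean, roi_depth_sd = roi_depth_sd,
                 roi_window_cm = roi_window_cm,
                 mean_cv = mean_cv, cv_shape = cv_shape,
                 n_repeats_range = kr, repeat_probs = repeat_probs,
                 correlations = correlations, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Project a correlation matrix to the nearest positive semi-definite one
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to `floor`, the
#' matrix is reconstructed and rescaled to unit diagonal. Already-PSD input is
#' returned unchanged.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param floor Small positive eigenvalue floor.
#' @return A positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(m, floor = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stopf("`m` must be a symmetric square matrix")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

# Mean-square effective repeat-noise CV implied by the CV model:
# subject CV ~ Gamma(shape, mean mean_cv), repeat noise SD inflated by the
# small-sample factor (1 + 1/(4k)).
effective_cv_msq <- function(config) {
  theta <- (config$mean_cv / 100) / config$cv_shape
  Ec2 <- config$cv_shape * (config$cv_shape + 1) * theta^2
  ks <- seq(config$n_repeats_range[1], config$n_repeats_range[2])
  pk <- config$repeat_probs / sum(config$repeat_probs)
  Ec2 * sum(pk * (1 + 1 / (4 * ks))^2)
}

#' Sample a synthetic elastography cohort
#'
#' Latent (age, breast volume, whole density, local density, stiffness) are
#' drawn from a multivariate normal. FGT volume is derived as
#' density x volume / 100, which together with the configured volume-density
#' correlation reproduces the printed FGT mean. Each subject receives 3-5
#' stiffness repeats `latent * (1 + eps)` with subject-specific noise drawn
#' from the gamma CV model; the reported stiffness is the repeat whose
#' "dense-appearance" score (tied to local density) is maximal, emulating the
#' selection of the most-dense-looking ROI. Because the reported stiffness
#' carries repeat noise, the latent stiffness SD and the stiffness row of the
#' correlation matrix are internally disattenuated so that the *observed*
#' stiffness matches the configured (printed) mean, SD and correlations; see
#' the methods vignette for the closed form.
#'
#' Stiffness values are clipped below at 0.1 m/s and percent densities at
#' 0.1% (required by the nonnegativity invariants; < ~1% of draws).
#'
#' @param config A [cohort_config].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @return A `data.frame` with one row per subject: `subject_id`, `age`,
#'   `breast_volume`, `fgt_volume`, `whole_percent_density`,
#'   `local_percent_density`, `stiffness`, `roi_depth`, `roi_width`,
#'   `roi_height`, `n_repeats`, and a list column `stiffness_repeats`.
#' @export
sample_cohort <- function(config = cohort_config(), n = config$n_subjects) {
  stopifnot(inherits(config, "cohort_config"))
  if (n < 0) stopf("n must be >= 0")
  schema <- data.frame(subject_id = character(), age = numeric(),
                       breast_volume = numeric(), fgt_volume = numeric(),
                       whole_percent_density = numeric(),
                       local_percent_density = numeric(),
                       stiffness = numeric(), roi_depth = numeric(),
                       roi_width = numeric(), roi_height = numeric(),
                       n_repeats = integer(), stringsAsFactors = FALSE)
  schema$stiffness_repeats <- list()
  if (n == 0) return(schema)

  m2 <- effective_cv_msq(config)
  lat_var <- config$stiffness_sd^2 - config$stiffness_mean^2 * m2
  if (lat_var <= 0)
    stopf("repeat CV model implies more variance than the stiffness SD allows")
  lat_sd <- sqrt(lat_var)
  infl <- config$stiffness_sd / lat_sd
  R <- config$correlations
  R["stiffness", -5] <- R["stiffness", -5] * infl
  R[-5, "stiffness"] <- R[-5, "stiffness"] * infl
  if (any(abs(R) > 1))
    stopf("disattenuated stiffness correlations exceed 1; reduce mean_cv")
  R <- nearest_psd(R)
  L <- chol(R)

  set.seed(config$seed)
  Z <- matrix(rnorm(n * 5), n, 5) %*% L
  age <- config$age_mean + config$age_sd * Z[, 1]
  volume <- config$volume_mean + config$volume_sd * Z[, 2]
  whole <- clip_low(config$whole_density_mean + config$whole_density_sd * Z[, 3],
                    0.1)
  whole <- pmin(whole, 99.9)
  local <- clip_low(config$local_density_mean + config$local_density_sd * Z[, 4],
                    0.1)
  local <- pmin(local, 100)
  s_lat <- clip_low(config$stiffness_mean + lat_sd * Z[, 5], 0.1)
  fgt <- whole * volume / 100

  ks <- seq(config$n_repeats_range[1], config$n_repeats_range[2])
  k <- sample(ks, n, replace = TRUE,
              prob = config$repeat_probs / sum(config$repeat_probs))
  cv_subj <- rgamma(n, shape = config$cv_shape,
                    scale = (config$mean_cv / 100) / config$cv_shape)
  sigma <- cv_subj * (1 + 1 / (4 * k))
  repeats <- vector("list", n)
  selected <- numeric(n)
  for (i in seq_len(n)) {
    reps <- clip_low(s_lat[i] * (1 + rnorm(k[i], 0, sigma[i])), 0.1)
    score <- local[i] + rnorm(k[i], 0, 5)  # dense-appearance score per ROI
    repeats[[i]] <- reps
    selected[i] <- reps[which.max(score)]
  }
  depth <- clip_low(rnorm(n, config$roi_depth_mean, config$roi_depth_sd), 0.1)

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age = age, breast_volume = volume, fgt_volume = fgt,
                    whole_percent_density = whole,
                    local_percent_density = local,
                    stiffness = selected, roi_depth = depth,
                    roi_width = config$roi_window_cm[1],
                    roi_height = config$roi_window_cm[2],
                    n_repeats = k, stringsAsFactors = FALSE)
  out$stiffness_repeats <- repeats
  out
}

#' Write / read a cohort table as CSV
#'
#' The `stiffness_repeats` list column is packed as a semicolon-separated
#' string for CSV round-tripping.
#'
#' @param cohort A cohort `data.frame` from [sample_cohort()].
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  flat <- cohort
  flat$stiffness_repeats <-
    vapply(cohort$stiffness_repeats,
           function(r) paste(format(r, digits = 12, trim = TRUE),
                             collapse = ";"), "")
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  flat$stiffness_repeats <- lapply(strsplit(as.character(flat$stiffness_repeats),
                                            ";", fixed = TRUE), as.numeric)
  flat
}
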