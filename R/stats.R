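#' Pearson product-moment correlation
#'
#' Thin validated wrapper used throughout the cohort analysis.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, non-constant.
#' @return r in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input has no defined correlation")
  cor(x, y)
}

#' Classify a correlation coefficient into the study's bands
#'
#' Bands on |r|: \[0, 0.3) none, \[0.3, 0.5) weak, \[0.5, 0.7) moderate,
#' \[0.7, 1\] strong. The absolute value is used: the study's rule is written
#' for unsigned r, yet its negative coefficients (e.g. r = -0.56 for age vs
#' density, described as a clear trend) only fit the bands under |r|.
#'
#' @param r Numeric vector of correlation coefficients, |r| <= 1.
#' @return Factor with levels none, weak, moderate, strong.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stopf("|r| > 1")
  cut(pmin(abs(r), 1), breaks = c(0, 0.3, 0.5, 0.7, 1 + 1e-9),
      labels = c("none", "weak", "moderate", "strong"), right = FALSE,
      include.lowest = TRUE)
}

#' Coefficient of variation of repeated measurements
#'
#' `100 x sample SD (n-1 denominator) / mean`, the reproducibility metric
#' for the 3-5 repeated stiffness measurements per subject.
#'
#' @param repeats Numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(repeats) {
  if (length(repeats) < 2) stopf("need at least 2 repeats")
  m <- mean(repeats)
  if (m <= 0) stopf("mean must be positive for a CV")
  100 * sd(repeats) / m
}

REQUIRED_COHORT_COLS <- c("age", "breast_volume", "fgt_volume",
                          "whole_percent_density", "local_percent_density",
                          "stiffness", "roi_depth")

#' Cohort summary report
#'
#' Reproduces the study's statistical analysis on a cohort table: mean, SD
#' and range of stiffness, breast volume, FGT volume, whole and local percent
#' density, and ROI depth; the five Pearson correlations (stiffness vs age /
#' volume / whole density / local density, and whole density vs age) with
#' their band classification; and, when `stiffness_repeats` is present, the
#' per-subject CVs, their cohort mean, and the <10% / 10-20% / >20% bin
#' counts.
#'
#' @param cohort A cohort `data.frame` (see [sample_cohort()]); the
#'   `stiffness_repeats` list column is optional.
#' @return List of class `cohort_report` with elements `n`, `summaries`,
#'   `correlations` (data.frame pair/r/n/band), `cv` (or `NULL`), and
#'   `flags`.
#' @export
cohort_report <- function(cohort) {
  missing_cols <- setdiff(REQUIRED_COHORT_COLS, names(cohort))
  if (length(missing_cols))
    stopf("cohort is missing columns: %s", paste(missing_cols, collapse = ", "))
  n <- nrow(cohort)
  flags <- character(0)
  summarize <- function(v) {
    if (n == 0) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(v), sd = if (n >= 2) sd(v) else NA_real_,
      min = min(v), max = max(v))
  }
  vars <- c("stiffness", "breast_volume", "fgt_volume",
            "whole_percent_density", "local_percent_density", "roi_depth")
  summaries <- t(vapply(vars, function(v) summarize(cohort[[v]]), numeric(4)))
  if (n == 1) flags <- c(flags, "single subject: SDs and correlations undefined")
  pairs <- list(c("stiffness", "age"), c("stiffness", "breast_volume"),
                c("stiffness", "whole_percent_density"),
                c("stiffness", "local_percent_density"),
                c("whole_percent_density", "age"))
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    r <- tryCatch(pearson(cohort[[p[1]]], cohort[[p[2]]]),
                  error = function(e) NA_real_)
    data.frame(pair = paste(p, collapse = " vs "), r = r, n = n,
               band = if (is.na(r)) NA_character_
                      else as.character(classify_correlation(r)),
               stringsAsFactors = FALSE)
  }))
  cv <- NULL
  if ("stiffness_repeats" %in% names(cohort) && n > 0) {
    per_subject <- vapply(cohort$stiffness_repeats, coefficient_of_variation,
                          numeric(1))
    cv <- list(per_subject = per_subject, mean_cv = mean(per_subject),
               bins = c(`<10%` = sum(per_subject < 10),
                        `10-20%` = sum(per_subject >= 10 & per_subject <= 20),
                        `>20%` = sum(per_subject > 20)))
  }
  structure(list(n = n, summaries = summaries, correlations = correlations,
                 cv = cv, flags = flags),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d\n", x$n))
  s <- x$summaries
  for (v in rownames(s))
    cat(sprintf("  %-22s %8.2f +/- %-7.2f range %.2f-%.2f\n", v,
                s[v, "mean"], s[v, "sd"], s[v, "min"], s[v, "max"]))
  cat("  correlations:\n")
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("    %-45s r = %6.3f (%s)\n", x$correlations$pair[i],
                x$correlations$r[i], x$correlations$band[i]))
  if (!is.null(x$cv))
    cat(sprintf("  mean CV %.1f%% | bins <10%%: %d, 10-20%%: %d, >20%%: %d\n",
                x$cv$mean_cv, x$cv$bins[1], x$cv$bins[2], x$cv$bins[3]))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Write a cohort report as JSON (and optionally the summaries as CSV)
#' @param report A `cohort_report`.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the summary table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  out <- list(n = report$n,
              summaries = as.data.frame(report$summaries),
              correlations = report$correlations,
              cv = report$cv, flags = report$flags)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  if (!is.null(csv_path))
    write.csv(cbind(variable = rownames(report$summaries),
                    as.data.frame(report$summaries)),
              csv_path, row.names = FALSE)
  invisible(json_path)
}
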