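#' Segment the breast by excluding the chest
#'
#' Foreground voxels (intensity above an automatic Otsu threshold, largest
#' 6-connected component) minus the chest region. The chest can be supplied
#' as a full 3D mask (phantom ground truth or a user file) or as a single
#' mid-slice 2D mask, which is then propagated slice by slice superiorly and
#' inferiorly, each slice initialized from its neighbor and trimmed to that
#' slice's foreground.
#'
#' @param image An [image_volume].
#' @param chest_mask `NULL` (no exclusion), a logical 3D array aligned with
#'   the image, or a logical 2D matrix (x-by-y) for the middle slice.
#' @param threshold Foreground threshold; default Otsu.
#' @param slice_axis Axis along which 2D masks are propagated (default 3,
#'   superior-inferior).
#' @return Logical breast mask (largest foreground component minus chest).
#' @export
exclude_chest <- function(image, chest_mask = NULL, threshold = NULL,
                          slice_axis = 3L) {
  stopifnot(inherits(image, "image_volume"))
  I <- image$data
  if (all(I == 0) || diff(range(I)) == 0) stopf("empty foreground: image is constant")
  thr <- threshold %||% background_threshold(as.vector(I))
  fg <- I > thr
  if (!any(fg)) stopf("empty foreground: no voxel above threshold %.4g", thr)
  fg <- array(largest_component_cpp(fg, dim(I)), dim(I))
  if (is.null(chest_mask)) {
    chest <- array(FALSE, dim(I))
  } else if (length(dim(chest_mask)) == 3L) {
    chest <- chest_mask
  } else if (length(dim(chest_mask)) == 2L) {
    if (slice_axis != 3L) stopf("2D chest propagation implemented for axis 3 only")
    nz <- dim(I)[3]
    mid <- (nz + 1L) %/% 2L
    chest <- array(FALSE, dim(I))
    # each slice initialized from its neighbor, then trimmed to the slice's
    # own foreground; an emptied estimate falls back to the template
    sweep_dir <- function(ks) {
      prev <- chest_mask
      for (k in ks) {
        cur <- prev & fg[, , k]
        if (!any(cur)) cur <- chest_mask & fg[, , k]
        chest[, , k] <<- cur
        prev <- if (any(cur)) cur else chest_mask
      }
    }
    sweep_dir(mid:nz)
    if (mid > 1L) sweep_dir((mid - 1L):1L)
  } else {
    stopf("chest_mask must be NULL, a 2D matrix or a 3D array")
  }
  breast <- fg & !chest
  if (!any(breast)) stopf("chest mask covers the entire foreground")
  array(largest_component_cpp(breast, dim(I)), dim(I))
}

#' Correct a smooth multiplicative intensity bias field
#'
#' Fits a degree-2 polynomial in normalized coordinates to the log intensity
#' inside the mask, divides the fitted (exponentiated) field out everywhere,
#' and restores the original mask-mean intensity. Nonpositive intensities
#' inside the mask are shifted before taking logs (with a warning).
#'
#' @param image An [image_volume].
#' @param mask Logical array: region used to fit the field (e.g. the breast).
#' @return The corrected [image_volume]; the estimated multiplicative field
#'   (mean 1 inside the mask) is attached as attribute `"bias_field"`.
#' @export
bias_correct <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"))
  if (!any(mask)) stopf("bias correction mask is empty")
  I <- image$data
  gs <- dim(I)
  shift <- 0
  inside <- I[mask]
  if (any(inside <= 0)) {
    shift <- abs(min(inside)) + 1e-6 * diff(range(inside))
    warnf("nonpositive intensities inside mask; shifted by %.4g before log", shift)
  }
  u <- seq(-1, 1, length.out = gs[1])
  v <- seq(-1, 1, length.out = gs[2])
  w <- seq(-1, 1, length.out = gs[3])
  idx <- which(mask, arr.ind = TRUE)
  design <- function(uu, vv, ww)
    cbind(1, uu, vv, ww, uu * vv, uu * ww, vv * ww, uu^2, vv^2, ww^2)
  Xm <- design(u[idx[, 1]], v[idx[, 2]], w[idx[, 3]])
  # trimmed least squares: the smooth field must follow the dominant (fat)
  # intensity, not the dark fibroglandular class, so voxels with strongly
  # negative residuals are dropped and the fit repeated
  ly <- log(inside + shift)
  keep <- rep(TRUE, length(ly))
  fit <- NULL
  for (pass in 1:3) {
    fit <- lm.fit(Xm[keep, , drop = FALSE], ly[keep])
    r <- ly - Xm %*% fit$coefficients
    cut <- -2.5 * max(stats::mad(r[keep]), 1e-8)
    keep_new <- r > cut
    if (identical(keep_new, keep)) break
    keep <- keep_new
  }
  # evaluate fitted log-field on the full grid
  allidx <- arrayInd(seq_along(I), gs)
  logf <- design(u[allidx[, 1]], v[allidx[, 2]], w[allidx[, 3]]) %*% fit$coefficients
  field <- array(exp(logf), gs)
  field <- field / mean(field[mask])     # multiplicative field, mean 1 in mask
  corrected <- (I + shift) / field
  corrected <- corrected * mean(inside + shift) / mean(corrected[mask]) - shift
  out <- image_volume(corrected, spacing = image$spacing, origin = image$origin)
  attr(out, "bias_field") <- field
  out
}

#' Fuzzy C-means clustering of voxel intensities
#'
#' Standard FCM with alternating membership / center updates:
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`,
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated until the largest center
#' shift falls below `tol` times the intensity range. Centers are initialized
#' deterministically at the `(2k-1)/(2c)` intensity quantiles, so results do
#' not depend on `seed` (the argument is accepted for interface stability).
#'
#' @param x Numeric vector of intensities.
#' @param centers Number of classes `c` (default 2: fat vs fibroglandular).
#' @param m Fuzzifier, > 1.
#' @param tol Convergence tolerance as a fraction of the intensity range.
#' @param max_iter Iteration cap; non-convergence returns with a warning flag.
#' @param seed Unused (deterministic quantile initialization).
#' @param init Optional explicit initial centers (overrides quantiles).
#' @return List: sorted `centers`, `membership` (n x c, columns matching the
#'   sorted centers, rows summing to 1), `iterations`, `converged`, and the
#'   non-increasing `objective` history.
#' @export
fuzzy_c_means <- function(x, centers = 2L, m = 2, tol = 1e-4, max_iter = 200L,
                          seed = NULL, init = NULL) {
  if (m <= 1) stopf("fuzzifier m must be > 1")
  c <- as.integer(centers)
  if (length(unique(x)) < c)
    stopf("need at least %d distinct intensity values, got %d",
          c, length(unique(x)))
  rng <- diff(range(x))
  ctr <- init %||% as.numeric(quantile(x, probs = (2 * seq_len(c) - 1) / (2 * c)))
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  U <- NULL
  for (iter in seq_len(max_iter)) {
    d <- abs(outer(x, ctr, "-"))
    d[d < 1e-12 * rng] <- 1e-12 * rng
    W <- d^(-expo)
    U <- W / rowSums(W)
    Um <- U^m
    new_ctr <- colSums(Um * x) / colSums(Um)
    obj <- c(obj, sum(Um * d^2))
    shift <- max(abs(new_ctr - ctr))
    ctr <- new_ctr
    if (shift < tol * rng) { converged = TRUE; break }
  }
  if (!converged) warnf("FCM did not converge in %d iterations", max_iter)
  ord <- order(ctr)
  list(centers = ctr[ord], membership = U[, ord, drop = FALSE],
       iterations = iter, converged = converged, objective = obj)
}

#' Breast volume, fibroglandular volume and percent density from masks
#'
#' @param breast_mask,fgt_mask Aligned logical arrays; FGT voxels outside the
#'   breast are ignored.
#' @param spacing Voxel size in mm (length 3 or scalar).
#' @return List with `breast_volume` and `fgt_volume` (cm^3),
#'   `percent_density` (= 100 fgt / breast), and the voxel counts.
#' @export
compute_density <- function(breast_mask, fgt_mask, spacing) {
  if (!any(breast_mask)) stopf("breast mask is empty")
  fgt_mask <- fgt_mask & breast_mask
  vox_cm3 <- voxel_volume_mm3(spacing) / 1000
  nb <- sum(breast_mask)
  nf <- sum(fgt_mask)
  list(breast_volume = nb * vox_cm3,
       fgt_volume = nf * vox_cm3,
       percent_density = 100 * nf / nb,
       n_breast_voxels = nb, n_fgt_voxels = nf)
}

#' Full breast density segmentation of one volume
#'
#' Chains [exclude_chest()], [bias_correct()] and [fuzzy_c_means()] (two
#' classes) and assigns fibroglandular tissue by winning membership. On
#' T1-weighted images fat is bright, so FGT is the darker class by default
#' (`polarity = "dark"`); set `polarity = "bright"` for inverted contrasts.
#'
#' @param image An [image_volume].
#' @param chest_mask Passed to [exclude_chest()].
#' @param polarity `"dark"` or `"bright"`: which intensity class is FGT.
#' @param threshold Optional foreground threshold override.
#' @param ... Further arguments to [fuzzy_c_means()].
#' @return List of class `segmentation_result`: `breast_mask`, `fgt_mask`,
#'   volumes and `percent_density` (see [compute_density()]), `fcm_centers`,
#'   and `mean_winning_membership`.
#' @export
segment_breast <- function(image, chest_mask = NULL,
                           polarity = c("dark", "bright"),
                           threshold = NULL, ...) {
  polarity <- match.arg(polarity)
  breast <- exclude_chest(image, chest_mask, threshold = threshold)
  corrected <- bias_correct(image, breast)
  xv <- corrected$data[breast]
  fcm <- fuzzy_c_means(xv, centers = 2L, ...)
  cls <- max.col(fcm$membership)
  fgt_class <- if (polarity == "dark") 1L else 2L
  fgt <- array(FALSE, dim(image$data))
  fgt[breast] <- cls == fgt_class
  dens <- compute_density(breast, fgt, image$spacing)
  structure(c(list(breast_mask = breast, fgt_mask = fgt,
                   fcm_centers = fcm$centers,
                   mean_winning_membership =
                     mean(fcm$membership[cbind(seq_along(cls), cls)]),
                   corrected = corrected),
              dens),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> breast %.1f cm3 | FGT %.1f cm3 | density %.2f%%\n",
    x$breast_volume, x$fgt_volume, x$percent_density))
  cat(sprintf("  FCM centers: %s | mean winning membership %.3f\n",
              paste(signif(x$fcm_centers, 5), collapse = ", "),
              x$mean_winning_membership))
  invisible(x)
}

#' Dice overlap coefficient between two masks
#' @param a,b Logical arrays of identical shape.
#' @return `2|a&b| / (|a|+|b|)`.
#' @export
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
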