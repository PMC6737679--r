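#' Specify a synthetic prone breast MR phantom
#'
#' The phantom emulates a pre-contrast T1-weighted prone acquisition: a
#' hemiellipsoidal breast attached to a posterior chest slab, a central
#' retroareolar fibroglandular (FGT) core sized to hit a target percent
#' density, a smooth multiplicative degree-2 polynomial bias field, and
#' additive Gaussian noise. Fat is bright and FGT dark, as on T1W images.
#'
#' Axis convention: +x right (lateral), +y anterior (away from the chest),
#' +z superior. The chest/breast interface is the plane y = 0; the chest slab
#' occupies y < 0.
#'
#' @param grid_shape Voxels per axis (x, y, z).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param breast_semiaxes_mm Semiaxes (a, b, c) of the hemiellipsoid in mm;
#'   `b` is the anterior (prone-hanging) extent.
#' @param chest_slab_mm Thickness of the posterior chest slab in mm.
#' @param target_percent_density Whole-breast percent density to build in,
#'   in \[0, 100\].
#' @param fat_intensity,fgt_intensity,chest_intensity Mean tissue intensities
#'   (arbitrary MR units).
#' @param bias_amplitude Peak fractional deviation of the multiplicative bias
#'   field (0 disables it).
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param seed Integer seed; phantoms are bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 48L, 64L),
                         voxel_size_mm = 2,
                         breast_semiaxes_mm = c(50, 40, 50),
                         chest_slab_mm = 14,
                         target_percent_density = 13.1,
                         fat_intensity = 200,
                         fgt_intensity = 80,
                         chest_intensity = 120,
                         bias_amplitude = 0.2,
                         noise_sd = 12,
                         seed = 1L) {
  if (any(breast_semiaxes_mm <= 0)) stopf("breast semiaxes must be positive")
  if (target_percent_density < 0 || target_percent_density > 100)
    stopf("target percent density %.1f is unreachable; achievable range is 0-100",
          target_percent_density)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (voxel_size_mm <= 0) stopf("voxel size must be positive")
  if (any(grid_shape < 8L)) stopf("grid too small")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 breast_semiaxes_mm = breast_semiaxes_mm,
                 chest_slab_mm = chest_slab_mm,
                 target_percent_density = target_percent_density,
                 fat_intensity = fat_intensity,
                 fgt_intensity = fgt_intensity,
                 chest_intensity = chest_intensity,
                 bias_amplitude = bias_amplitude,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# fixed low-order polynomial used as the bias-field shape (normalized coords)
bias_poly <- function(u, v, w) {
  0.35 * u + 0.20 * v - 0.25 * w + 0.30 * u * v - 0.20 * u * w +
    0.15 * v * w + 0.25 * u^2 - 0.30 * v^2 + 0.20 * w^2
}

#' Generate a prone breast MR phantom with ground truth
#'
#' @param spec A [phantom_spec].
#' @return A list of class `breast_phantom`: `image` ([image_volume]),
#'   logical arrays `breast_mask`, `fgt_mask`, `chest_mask`, the ground-truth
#'   `nipple_index` / `nipple_mm` (anterior-most breast surface point on the
#'   mid-sagittal slice), the `chest_plane` (point + outward anterior normal),
#'   the achieved `percent_density`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$voxel_size_mm
  ab <- spec$breast_semiaxes_mm
  # voxel-center world coords; chest interface on plane y = 0
  x <- (seq_len(gs[1]) - (gs[1] + 1) / 2) * sp
  y <- -spec$chest_slab_mm + (seq_len(gs[2]) - 0.5) * sp
  z <- (seq_len(gs[3]) - (gs[3] + 1) / 2) * sp
  origin <- c(x[1], y[1], z[1])
  ell <- outer(outer((x / ab[1])^2, (y / ab[2])^2, "+"), (z / ab[3])^2, "+")
  ypos <- aperm(array(y > 0, dim = gs[c(2, 1, 3)]), c(2, 1, 3))
  breast <- (ell <= 1) & ypos
  chest <- !ypos
  if (!any(breast)) stopf("breast geometry empty: enlarge grid or semiaxes")

  # FGT core: ellipsoidal distance from a retroareolar center, thresholded at
  # the quantile that yields the target voxel fraction (exact to one voxel)
  fgt <- array(FALSE, gs)
  tpd <- spec$target_percent_density
  if (tpd > 0) {
    r2 <- outer(outer((x / (0.6 * ab[1]))^2,
                      ((y - 0.35 * ab[2]) / (0.55 * ab[2]))^2, "+"),
                (z / (0.6 * ab[3]))^2, "+")
    rb <- r2[breast]
    thr <- as.numeric(quantile(rb, probs = tpd / 100, type = 1))
    fgt <- breast & (r2 <= thr)
  }
  achieved <- 100 * sum(fgt) / sum(breast)
  if (abs(achieved - tpd) > 1)
    warnf("achieved density %.2f%% misses target %.2f%% by more than 1 pp",
          achieved, tpd)

  img <- array(0, gs)
  img[chest] <- spec$chest_intensity
  img[breast] <- spec$fat_intensity
  img[fgt] <- spec$fgt_intensity
  if (spec$bias_amplitude != 0) {
    u <- x / max(abs(x)); v <- y / max(abs(y)); w <- z / max(abs(z))
    U <- array(rep(u, times = gs[2] * gs[3]), gs)
    V <- aperm(array(rep(v, times = gs[1] * gs[3]), gs[c(2, 1, 3)]), c(2, 1, 3))
    W <- aperm(array(rep(w, times = gs[1] * gs[2]), gs[c(3, 2, 1)]), c(3, 2, 1))
    q <- bias_poly(U, V, W)
    field <- 1 + spec$bias_amplitude * q / max(abs(q))
    img <- img * field
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + array(rnorm(prod(gs), 0, spec$noise_sd), gs)
  }

  # nipple: anterior-most breast surface voxel on the mid-sagittal slice
  imid <- which.min(abs(x))
  sl <- breast[imid, , ]
  if (!any(sl)) stopf("mid-sagittal slice contains no breast")
  jn <- max(which(apply(sl, 1, any)))
  kn <- which(sl[jn, ])
  kn <- kn[which.min(abs(z[kn]))]
  nipple_index <- c(imid, jn, kn)
  nipple_mm <- c(x[imid], y[jn], z[kn])

  structure(list(image = image_volume(img, spacing = rep(sp, 3), origin = origin),
                 breast_mask = breast, fgt_mask = fgt, chest_mask = chest,
                 nipple_index = nipple_index, nipple_mm = nipple_mm,
                 chest_plane = list(point = c(0, 0, 0), normal = c(0, 1, 0)),
                 percent_density = achieved, spec = spec),
            class = "breast_phantom")
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf(
    "<breast_phantom> %s voxels @ %.3g mm | breast %.1f cm3 | density %.2f%%\n",
    paste(dim(x$image$data), collapse = "x"), x$spec$voxel_size_mm,
    sum(x$breast_mask) * voxel_volume_mm3(x$image$spacing) / 1000,
    x$percent_density))
  invisible(x)
}
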