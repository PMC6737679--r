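#' Create an image volume
#'
#' A minimal 3D scalar image container: a numeric array plus voxel spacing
#' (mm per axis) and the world coordinate (mm) of the center of voxel
#' `[1, 1, 1]`. The voxel-to-world map is axis-aligned:
#' `world = origin + (index - 1) * spacing`.
#'
#' @param data 3D numeric or logical array.
#' @param spacing Voxel size in mm, length 3 (or a scalar, recycled).
#' @param origin World coordinate (mm) of the first voxel center, length 3.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin` and a derived 4x4 `affine`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(spacing <= 0)) stopf("voxel spacing must be positive")
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(spacing)
  affine[1:3, 4] <- origin
  structure(list(data = data, spacing = spacing, origin = origin,
                 affine = affine),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

# world-mm coordinates of voxel centers along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1L) * vol$spacing[axis]
}

voxel_volume_mm3 <- function(spacing) prod(rep_len(as.numeric(spacing), 3L))

# world mm -> nearest voxel index (1-based), no clamping
world_to_index <- function(p, spacing, origin) {
  round((p - origin) / spacing) + 1
}
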