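#' Place the ultrasound-equivalent ROI on a supine label volume
#'
#' Reproduces the elastography measurement window: on the sagittal slice
#' containing the nipple, a `width_cm` x `height_cm` box is placed with its
#' top (anterior) edge `depth_cm` below the skin surface along the anterior
#' axis, centered laterally (within the slice) on the nipple line. The skin
#' surface is the anterior-most non-background voxel on the nipple line.
#'
#' @param labels Integer label array (0 background, 1 fat, 2 FGT) in the
#'   supine configuration.
#' @param spacing,origin Grid geometry (mm).
#' @param nipple_mm World-mm nipple location.
#' @param depth_cm ROI depth from the skin surface (cm).
#' @param width_cm,height_cm ROI window size (cm); height runs along the
#'   depth (anterior) axis. Defaults 1.0 x 0.5.
#' @param thickness_cm `NULL` (default) measures on the single nipple slice,
#'   matching the study's area-based definition; a value extends the box
#'   laterally across slices for a volumetric variant.
#' @return Integer matrix of in-grid voxel indices (n x 3) with attributes
#'   `slice`, `skin_index`, `depth_index_range`, `inplane_index_range`.
#' @export
place_roi <- function(labels, spacing, origin = c(0, 0, 0), nipple_mm,
                      depth_cm, width_cm = 1.0, height_cm = 0.5,
                      thickness_cm = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  gs <- dim(labels)
  if (depth_cm < 0) stopf("ROI depth must be >= 0")
  if (width_cm <= 0 || height_cm <= 0) stopf("ROI box area must be positive")
  nip <- world_to_index(nipple_mm, spacing, origin)
  if (any(nip < 1) || any(nip > gs)) stopf("nipple outside the volume")
  i <- nip[1]                                   # sagittal slice
  kz <- nip[3]
  col <- labels[i, , kz]                        # nipple line, anterior axis
  if (!any(col > 0)) stopf("no tissue on the nipple line of slice %d", i)
  skin_j <- max(which(col > 0))
  dj <- depth_cm * 10 / spacing[2]
  hj <- height_cm * 10 / spacing[2]
  j_top <- floor(skin_j - dj)
  j_bot <- ceiling(j_top - hj) + 1L
  post_j <- min(which(col > 0))
  if (j_top < post_j)
    stopf("ROI depth %.2f cm lies beyond the posterior breast boundary", depth_cm)
  wk <- width_cm * 10 / spacing[3] / 2
  k_lo <- ceiling(kz - wk)
  k_hi <- floor(kz + wk)
  if (j_bot < 1 || j_top > gs[2] || k_lo < 1 || k_hi > gs[3])
    stopf("ROI box exceeds the grid; clipped extent would be j %d..%d, k %d..%d",
          max(1L, j_bot), min(gs[2], j_top), max(1L, k_lo), min(gs[3], k_hi))
  i_range <- i
  if (!is.null(thickness_cm)) {
    wi <- thickness_cm * 10 / spacing[1] / 2
    i_lo <- ceiling(i - wi)
    i_hi <- floor(i + wi)
    if (i_lo < 1 || i_hi > gs[1])
      stopf("ROI box exceeds the grid laterally (slices %d..%d)", i_lo, i_hi)
    i_range <- i_lo:i_hi
  }
  vox <- as.matrix(expand.grid(i = i_range, j = j_bot:j_top, k = k_lo:k_hi))
  colnames(vox) <- NULL
  structure(vox, slice = i, skin_index = skin_j,
            depth_index_range = c(j_bot, j_top),
            inplane_index_range = c(k_lo, k_hi))
}

#' Local percent density inside an ROI
#'
#' `100 x (# fibroglandular voxels in the box) / (# voxels in the box)` —
#' the denominator is the whole box, including any non-breast voxels.
#'
#' @param labels Integer label array (2 = fibroglandular).
#' @param roi_voxels n x 3 voxel index matrix from [place_roi()].
#' @return Percent in \[0, 100\].
#' @export
local_percent_density <- function(labels, roi_voxels) {
  if (is.null(dim(roi_voxels)) || nrow(roi_voxels) == 0) stopf("empty ROI")
  gs <- dim(labels)
  lin <- roi_voxels[, 1] + gs[1] * (roi_voxels[, 2] - 1) +
    gs[1] * gs[2] * (roi_voxels[, 3] - 1)
  100 * sum(labels[lin] == 2L) / nrow(roi_voxels)
}
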