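# Minimal NIfTI-1 I/O. No NIfTI reader ships with the supported R stack, so a
# small single-file (.nii / .nii.gz) codec is implemented here with readBin /
# writeBin. Only what the pipeline needs: 3D volumes, axis-aligned sform,
# datatypes uint8 / int16 / int32 / float32 / float64, little or big endian in,
# little endian out.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE))

nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume] whose spacing and origin come from the sform row
#'   vectors when present (falling back to `pixdim` / qoffset). Off-diagonal
#'   sform terms are not supported and raise an error.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    close(con)
    con <- nii_connection(path, "rb")
    on.exit(close(con), add = FALSE)
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (!identical(sizeof_hdr, 348L))
      stopf("not a NIfTI-1 file (bad header size): %s", path)
  }
  readBin(con, "raw", 36L)                              # unused fields
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                              # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                             # through aux_file
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "double", 3L, size = 4L, endian = endian)   # quatern
  qoffset <- readBin(con, "double", 3L, size = 4L, endian = endian)
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                              # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!grepl("^n\\+1", magic) && !grepl("^ni1", magic))
    stopf("corrupt NIfTI header (magic '%s'): %s", magic, path)
  if (dims[1] < 3L) stopf("expected a 3D volume, got %dD", dims[1])
  nxyz <- dims[2:4]
  if (dims[1] > 3L && any(dims[5:(dims[1] + 1)] > 1L))
    stopf("only single-frame 3D volumes are supported")
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(nxyz)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stopf("truncated NIfTI data: %s", path)
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  vals <- as.numeric(vals) * scl_slope + scl_inter
  if (sform_code > 0L) {
    offdiag <- srow[1:3, 1:3]
    diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(abs(srow[1:3, 1:3]))))
      stopf("non-axis-aligned sform is not supported")
    spacing <- abs(diag(srow[1:3, 1:3]))
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    origin <- qoffset
  }
  image_volume(array(vals, dim = nxyz), spacing = spacing, origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii` / `.nii.gz` with an axis-aligned
#' sform. Numeric data are stored as float64 (bit-exact round trip); logical
#' or 0-255 integer data as uint8.
#'
#' @param vol An [image_volume], or a 3D array (then `spacing` and `origin`
#'   apply).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing,origin Used only when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("unknown extension (expected .nii or .nii.gz): %s", path)
  if (!inherits(vol, "image_volume"))
    vol <- image_volume(vol * 1, spacing = spacing, origin = origin)
  d <- vol$data
  vals <- as.vector(d)
  uint8 <- is.logical(d) ||
    (all(vals == round(vals)) && all(vals >= 0) && all(vals <= 255))
  datatype <- if (uint8) 2L else 64L
  bitpix <- if (uint8) 8L else 64L
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4L)
  writeBin(raw(36L), con)
  wi(c(3L, dim(d), 1L, 1L, 1L, 1L), 2L)                 # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                            # intent
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)
  wf(c(1, vol$spacing, 1, 1, 1, 1))                     # pixdim
  wf(352); wf(1); wf(0)                                 # vox_offset, scl
  wi(0L, 2L); writeBin(raw(2L), con)                    # slice_end/code/units
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)                  # cal/glmax
  writeBin(raw(104L), con)                              # descrip + aux_file
  wi(0L, 2L); wi(1L, 2L)                                # qform=0, sform=1
  wf(c(0, 0, 0)); wf(vol$origin)                        # quatern, qoffset
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))
  writeBin(raw(16L), con)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                # extension flag
  if (uint8) {
    writeBin(as.integer(vals), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  }
  invisible(path)
}
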