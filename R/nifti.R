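# Minimal NIfTI-1 reader/writer.
#
# The pre-installed R stack ships no NIfTI package, so the single-file
# (.nii / .nii.gz) flavour of NIfTI-1 is handled here directly. Only what
# the pipeline needs is supported: 3D payloads (trailing singleton dims are
# tolerated), datatypes uint8 / int16 / uint16 / int32 / float32 / float64,
# scl_slope / scl_inter rescaling, and both endiannesses.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_read_header <- function(con, endian) {
  h <- list()
  h$sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", 36)                      # data_type..dim_info, unused
  h$dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                      # intent_p1..intent_code
  h$datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  h$bitpix <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "raw", 2)                       # slice_start
  h$pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  h$vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  h$scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  h$scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)                     # slice_end..aux_file
  h$qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  h$sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "raw", 24)                      # quaternion fields
  h$srow <- rbind(readBin(con, "double", 4, size = 4, endian = endian),
                  readBin(con, "double", 4, size = 4, endian = endian),
                  readBin(con, "double", 4, size = 4, endian = endian))
  readBin(con, "raw", 16)                      # intent_name
  h$magic <- rawToChar(readBin(con, "raw", 4), multiple = FALSE)
  h
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an
#' [image_volume()]. The payload must be 3D (axes beyond the third may only
#' be singletons). `scl_slope`/`scl_inter` rescaling is applied. The
#' intensity state of the result is `"raw_hu"`; the sform affine, when
#' present, is kept and reused on write.
#'
#' @param path file path.
#' @param mask if `TRUE`, return a [binary_mask()] (voxels thresholded at 0.5).
#' @return an `image_volume` (or `binary_mask`).
#' @export
read_nifti <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  open_con <- function() gzfile(path, "rb")    # gzfile reads plain files too
  con <- open_con()
  on.exit(close(con), add = TRUE)
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!identical(sz, 348L)) {
    close(con); on.exit()
    endian <- "big"
    con <- open_con()
    on.exit(close(con), add = TRUE)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!identical(sz, 348L)) stop("not a NIfTI-1 file: ", path)
  }
  close(con); on.exit()
  con <- open_con()
  on.exit(close(con), add = TRUE)
  h <- nifti_read_header(con, endian)
  if (!startsWith(h$magic, "n+1")) stop("only single-file NIfTI-1 is supported")
  nd <- h$dim[1]
  if (nd < 3L) stop("NIfTI payload is not 3D (dim[0] = ", nd, ")")
  extra <- if (nd > 3L) h$dim[5:(1 + nd)] else integer(0)
  if (length(extra) && any(extra > 1L))
    stop("NIfTI payload is not 3D (non-singleton higher dimensions)")
  shape <- h$dim[2:4]
  if (any(shape < 1L)) stop("invalid NIfTI dimensions")
  spacing <- h$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in NIfTI header")
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype)
  # skip to vox_offset (header bytes read so far: 348)
  skip <- round(h$vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vox <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                 endian = endian)
  if (length(vox) != n) stop("truncated NIfTI payload")
  vox <- as.numeric(vox)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vox <- vox * h$scl_slope + h$scl_inter
  arr <- array(vox, dim = shape)
  affine <- if (h$sform_code > 0) h$srow else NULL
  if (mask) {
    out <- binary_mask(arr > 0.5, spacing = spacing)
  } else {
    out <- image_volume(arr, spacing = spacing, intensity_state = "raw_hu")
  }
  out$affine <- affine
  out
}

pad_char <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

#' Write a NIfTI-1 volume
#'
#' Writes an [image_volume()] as float32 or a [binary_mask()] as uint8 in
#' single-file NIfTI-1 format (gzip-compressed when `path` ends in `.gz`).
#' The sform records either the affine carried over from [read_nifti()] or,
#' absent that, a diagonal affine built from the voxel spacing.
#'
#' @param x an `image_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("`x` must be an image_volume or binary_mask")
  shape <- dim(x$voxels)
  spacing <- x$spacing
  datatype <- if (is_mask) 2L else 16L
  bitpix <- if (is_mask) 8L else 32L
  affine <- x$affine
  if (is.null(affine))
    affine <- cbind(diag(spacing), c(0, 0, 0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w_i32(348L)                                  # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))          # dim
  writeBin(raw(14), con)                       # intent fields
  w_i16(datatype); w_i16(bitpix); w_i16(0L)    # datatype, bitpix, slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0))             # pixdim
  w_f32(352); w_f32(1); w_f32(0)               # vox_offset, scl_slope, scl_inter
  w_i16(0L); writeBin(raw(1), con)             # slice_end, slice_code
  writeBin(as.raw(2L), con)                    # xyzt_units: mm
  w_f32(c(0, 0, 0, 0)); w_i32(c(0L, 0L))       # cal/slice_duration/toffset/gl*
  writeBin(pad_char("lacycle", 80), con)       # descrip
  writeBin(raw(24), con)                       # aux_file
  w_i16(0L); w_i16(1L)                         # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                   # quatern b,c,d + qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  if (is_mask) {
    writeBin(as.integer(x$voxels), con, size = 1)
  } else {
    w_f32(x$voxels)
  }
  invisible(path)
}
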