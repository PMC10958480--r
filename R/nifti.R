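# Minimal NIfTI-1 single-file I/O.
#
# Covers the subset of the format this pipeline emits and consumes:
# 3-D volumes, datatypes uint8/int16/int32/float32/float64, single-file
# ("n+1") layout, optional gzip compression by filename extension.
# Orientation matrices are carried opaquely in `meta` and written back
# verbatim; the pipeline never resamples.

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "numeric", "numeric"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). Only 3-D images
#' with datatypes uint8, int16, int32, float32 or float64 are supported,
#' which covers standard SPECT volumes and integer label atlases. The
#' `scl_slope`/`scl_inter` scaling is applied when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image()] whose `meta` holds the raw header fields.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348) stopf("%s: truncated NIfTI header", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stopf("%s: not a NIfTI-1 file", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1") stopf("%s: unsupported NIfTI magic '%s'", path, magic)
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "numeric", n, 4, endian = endian)
  dims <- rd_i16(40, 8)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1))
    stopf("%s: only 3-D images are supported", path)
  shape <- dims[2:4]
  datatype <- rd_i16(70, 1)
  dt <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  if (nrow(dt) == 0) stopf("%s: unsupported NIfTI datatype %d", path, datatype)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stopf("%s: truncated NIfTI data", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_image(array(as.double(vals), shape),
               voxel_size = abs(pixdim[2:4]),
               meta = list(nifti_header = hdr_raw, datatype = datatype))
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_image()] or [label_atlas()] as a single-file NIfTI-1
#' image; gzip compression is chosen by the `.gz` extension. Volumes are
#' written as float64, atlases as int32.
#'
#' @param x A `volume_image` or `label_atlas`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "label_atlas")) {
    data <- x$labels; datatype <- 8L; voxel_size <- x$voxel_size
  } else if (inherits(x, "volume_image")) {
    data <- x$data; datatype <- 64L; voxel_size <- x$voxel_size
  } else stopf("`x` must be a volume_image or label_atlas")
  dt <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  shape <- dim(data)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                                  # sizeof_hdr
  w_raw(36)                                   # data_type, db_name, extents...
  w_i16(c(3, shape, 1, 1, 1, 1))              # dim[8]
  w_f32(c(0, 0, 0))                           # intent_p1..p3
  w_i16(0)                                    # intent_code
  w_i16(datatype)                             # datatype
  w_i16(dt$size * 8L)                         # bitpix
  w_i16(0)                                    # slice_start
  w_f32(c(1, voxel_size, 1, 1, 1, 1))         # pixdim[8] (qfac = 1)
  w_f32(352)                                  # vox_offset
  w_f32(c(1, 0))                              # scl_slope, scl_inter
  w_i16(0)                                    # slice_end
  writeBin(as.raw(c(0L, 10L)), con)           # slice_code; xyzt = mm | sec
  w_f32(c(0, 0, 0))                           # cal_max, cal_min, slice_dur
  w_f32(0)                                    # toffset
  w_i32(c(0, 0))                              # glmax, glmin
  w_raw(80 + 24)                              # descrip, aux_file
  w_i16(c(0, 1))                              # qform_code, sform_code = 1
  w_f32(c(0, 0, 0, 0, 0, 0))                  # quaternion b,c,d; qoffset
  w_f32(c(voxel_size[1], 0, 0, 0))            # srow_x
  w_f32(c(0, voxel_size[2], 0, 0))            # srow_y
  w_f32(c(0, 0, voxel_size[3], 0))            # srow_z
  w_raw(16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                                    # extender
  writeBin(if (dt$what == "integer") as.integer(data) else as.numeric(data),
           con, dt$size, endian = "little")
  invisible(path)
}

#' Read a label atlas from NIfTI plus a region table
#'
#' @param nifti_path Integer-labeled NIfTI image.
#' @param regions_path TSV file with the [region_table()] columns.
#' @return A [label_atlas()].
#' @export
read_atlas <- function(nifti_path, regions_path) {
  vol <- read_nifti(nifti_path)
  regions <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
  for (col in c("is_reference", "is_striatal"))
    if (col %in% names(regions)) regions[[col]] <- as.logical(regions[[col]])
  label_atlas(array(as.integer(round(vol$data)), dim(vol$data)),
              regions, voxel_size = vol$voxel_size)
}
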