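# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the dependency budget, so the format is
# handled directly: 348-byte header, 4-byte extension flag, raw data at
# vox_offset 352.  Only the features this package produces/consumes are
# supported: datatypes uint8, int16, int32, float32, float64; sform affine;
# no scl slope/intercept other than identity; both endiannesses on read.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64")
)

read_bin_strict <- function(con, what, n, size, endian, signed = TRUE, field = "data") {
  x <- readBin(con, what = what, n = n, size = size, endian = endian,
               signed = signed)
  if (length(x) < n) {
    stop("truncated NIfTI stream while reading '", field, "': expected ", n,
         " elements, got ", length(x), call. = FALSE)
  }
  x
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed, decided by
#' the \code{.gz} extension or transparently by \code{gzfile}).
#'
#' @param path file path.
#' @return a list with elements \code{data} (numeric array with the header's
#'   dimensionality), \code{affine} (4x4 voxel-to-world matrix, from the sform
#'   when set, else diagonal pixdim), and \code{header} (named list of the
#'   fields needed for round-tripping).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(sizeof_hdr) < 1) stop("truncated NIfTI stream: empty file", call. = FALSE)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sw <- sizeof_hdr
    sizeof_hdr <- readBin(writeBin(sw, raw(), size = 4, endian = "little"),
                          "integer", size = 4, endian = "big")
    if (sizeof_hdr != 348L) {
      stop("malformed NIfTI header: sizeof_hdr = ", sw, " (expected 348)",
           call. = FALSE)
    }
  }
  rb <- function(what, n, size, signed = TRUE, field = "header") {
    read_bin_strict(con, what, n, size, endian, signed, field)
  }
  rb("integer", 35, 1, FALSE, "pad")            # data_type, db_name, extents...
  dim_ <- rb("integer", 8, 2, TRUE, "dim")
  rb("double", 3, 4, TRUE, "intent_p")
  rb("integer", 1, 2, TRUE, "intent_code")
  datatype <- rb("integer", 1, 2, TRUE, "datatype")
  bitpix <- rb("integer", 1, 2, TRUE, "bitpix")
  rb("integer", 1, 2, TRUE, "slice_start")
  pixdim <- rb("double", 8, 4, TRUE, "pixdim")
  vox_offset <- rb("double", 1, 4, TRUE, "vox_offset")
  scl_slope <- rb("double", 1, 4, TRUE, "scl_slope")
  scl_inter <- rb("double", 1, 4, TRUE, "scl_inter")
  rb("integer", 1, 2, TRUE, "slice_end")
  rb("integer", 2, 1, FALSE, "slice_code")
  rb("double", 4, 4, TRUE, "cal")
  rb("integer", 2, 4, TRUE, "glmax")
  rb("integer", 104, 1, FALSE, "descrip")
  qform_code <- rb("integer", 1, 2, TRUE, "qform_code")
  sform_code <- rb("integer", 1, 2, TRUE, "sform_code")
  rb("double", 6, 4, TRUE, "quatern")
  srow <- matrix(rb("double", 12, 4, TRUE, "srow"), nrow = 3, byrow = TRUE)
  rb("integer", 16, 1, FALSE, "intent_name")
  magic <- rawToChar(as.raw(rb("integer", 4, 1, FALSE, "magic")[1:3]))
  if (!magic %in% c("n+1", "ni1")) {
    stop("malformed NIfTI header: magic = '", magic, "'", call. = FALSE)
  }
  ndim <- dim_[1]
  if (ndim < 1 || ndim > 7) {
    stop("malformed NIfTI header: dim[0] = ", ndim, call. = FALSE)
  }
  dims <- dim_[2:(1 + ndim)]
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  }
  # skip from byte 348 to vox_offset (extension flag etc.)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) rb("integer", skip, 1, FALSE, "extensions")
  n <- prod(dims)
  data <- rb(dt$what, n, dt$size, dt$signed, "voxel data")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  data <- array(as.numeric(data), dim = dims)
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = data, affine = affine,
       header = list(datatype = dt$r, pixdim = pixdim[2:(1 + min(ndim, 3))],
                     qform_code = qform_code, sform_code = sform_code))
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric or logical array, 3D or 4D.
#' @param path output path; gzip-compressed when it ends in \code{.gz}.
#' @param affine 4x4 voxel-to-world matrix stored as the sform (default
#'   identity).
#' @param datatype one of \code{"float64"}, \code{"float32"}, \code{"uint8"},
#'   \code{"int16"}, \code{"int32"}; logical input defaults to \code{"uint8"},
#'   numeric to \code{"float64"}.
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = NULL) {
  stopifnot(length(dim(data)) %in% c(3L, 4L), identical(dim(affine), c(4L, 4L)))
  if (is.null(datatype)) datatype <- if (is.logical(data)) "uint8" else "float64"
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype, call. = FALSE))
  dt <- NIFTI_DATATYPES[[as.character(code)]]
  dims <- dim(data)
  ndim <- length(dims)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wb_f <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wb_i(348L, 4)                          # sizeof_hdr
  wb_i(rep(0L, 35), 1)                   # data_type, db_name, extents, ..., dim_info
  wb_i(c(ndim, dims, rep(1L, 7 - ndim)), 2)   # dim[8]
  wb_f(c(0, 0, 0))                       # intent_p1..3
  wb_i(0L, 2)                            # intent_code
  wb_i(code, 2)                          # datatype
  wb_i(dt$size * 8L, 2)                  # bitpix
  wb_i(0L, 2)                            # slice_start
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  wb_f(c(1, vox, rep(1, 7 - 3)))         # pixdim[8] (qfac 1)
  wb_f(352)                              # vox_offset
  wb_f(c(1, 0))                          # scl_slope, scl_inter
  wb_i(0L, 2)                            # slice_end
  wb_i(c(0L, 10L), 1)                    # slice_code, xyzt_units (mm)
  wb_f(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_duration, toffset
  wb_i(c(0L, 0L), 4)                     # glmax, glmin
  wb_i(rep(0L, 104), 1)                  # descrip + aux_file
  wb_i(0L, 2)                            # qform_code
  wb_i(1L, 2)                            # sform_code
  wb_f(rep(0, 6))                        # quatern_b/c/d, qoffset_x/y/z
  wb_f(t(affine[1:3, ]))                 # srow_x/y/z
  wb_i(rep(0L, 16), 1)                   # intent_name
  writeBin(charToRaw("n+1"), con); wb_i(0L, 1)   # magic
  wb_i(rep(0L, 4), 1)                    # extension flag
  vals <- as.numeric(data)
  if (dt$what == "integer") {
    wb_i(round(vals), dt$size)
  } else {
    writeBin(vals, con, size = dt$size, endian = "little")
  }
  invisible(path)
}
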