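## Minimal NIfTI-1 reader/writer.
##
## No NIfTI package is available in the target environment, so the small
## subset of the format this package needs is implemented here directly:
## single-frame 3D volumes, datatypes uint8/int16/int32/uint16/float32/float64,
## scl_slope/scl_inter scaling, sform geometry, optional gzip compression.
## Oblique sforms are reduced to their dominant axis per column; that is
## sufficient for the axis/sign semantics the physics model needs.

NIFTI_DT <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

is_gz_path <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

read_raw_file <- function(path) {
  if (is_gz_path(path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, raw(), n = 1024L * 1024L)
      if (length(b) == 0L) break
      chunks[[length(chunks) + 1L]] <- b
    }
    do.call(c, chunks)
  } else {
    readBin(path, raw(), n = file.size(path))
  }
}

## build the 3x3 direction matrix (columns = lattice axes in scanner frame,
## scaled by voxel size in mm) from signed axis labels like c("x","-y","z")
axes_matrix <- function(axes, voxel_size) {
  stopifnot(length(axes) == 3, length(voxel_size) == 3)
  R <- matrix(0, 3, 3)
  letters3 <- c(x = 1L, y = 2L, z = 3L)
  seen <- integer(0)
  for (j in 1:3) {
    ax <- axes[j]
    sgn <- if (startsWith(ax, "-")) -1 else 1
    letter <- sub("^-", "", ax)
    if (!letter %in% names(letters3)) stop("invalid axis label: ", ax)
    i <- letters3[[letter]]
    seen <- c(seen, i)
    R[i, j] <- sgn * voxel_size[j]
  }
  if (length(unique(seen)) != 3) stop("axes must be a signed permutation of x, y, z")
  R
}

axes_from_matrix <- function(R) {
  axes <- character(3)
  vox <- numeric(3)
  for (j in 1:3) {
    col <- R[, j]
    i <- which.max(abs(col))
    axes[j] <- paste0(if (col[i] < 0) "-" else "", c("x", "y", "z")[i])
    vox[j] <- sqrt(sum(col^2))
  }
  list(axes = axes, voxel_size = vox)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads an uncompressed or gzipped NIfTI-1 file into a [field_map()] object.
#' The voxel size is taken from the sform when present (column norms),
#' otherwise from `pixdim`; the lattice-to-scanner axis mapping is the
#' dominant axis of each sform column, defaulting to `c("x","y","z")`
#' (dim 1 = right-left, 2 = posterior-anterior, 3 = head-feet).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param frame 1-based frame to extract from a 4D file; reading a 4D file
#'   without specifying `frame` is an error.
#' @param axes optional override of the axis mapping for files with ambiguous
#'   or missing orientation metadata.
#' @return A [field_map()] (mask unset).
#' @export
read_volume <- function(path, frame = NULL, axes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_raw_file(path)
  if (length(raw) < 352) stop("not a NIfTI-1 file (too short): ", path, call. = FALSE)
  endian <- "little"
  szh <- readBin(raw[1:4], "integer", 1, 4, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(raw[1:4], "integer", 1, 4, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("missing NIfTI magic string: ", path, call. = FALSE)
  }
  dimv <- rd(40, "integer", 8, 2)
  ndim <- dimv[1]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4),
                rd(312, "double", 4, 4))

  if (ndim < 3 || any(dimv[2:4] < 2)) {
    stop("expected a 3D volume (all three spatial dims > 1): ", path,
         call. = FALSE)
  }
  nt <- if (ndim >= 4) max(dimv[5], 1L) else 1L
  if (nt > 1L && is.null(frame)) {
    stop("4D input: select a frame with `frame =`", call. = FALSE)
  }
  frame <- frame %||% 1L
  if (frame < 1L || frame > nt) stop("frame out of range", call. = FALSE)

  dt <- Filter(function(d) d$code == datatype, NIFTI_DT)
  if (length(dt) == 0) stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  dt <- dt[[1]]
  nxyz <- prod(dimv[2:4])
  start <- as.integer(round(vox_offset)) + (frame - 1L) * nxyz * dt$size
  vals <- readBin(raw[(start + 1):(start + nxyz * dt$size)], dt$what,
                  n = nxyz, size = dt$size, endian = endian,
                  signed = dt$signed)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(vals, dim = dimv[2:4])

  if (is.null(axes)) {
    if (sform_code > 0) {
      g <- axes_from_matrix(srow[, 1:3, drop = FALSE])
      axes <- g$axes
      voxel_size <- g$voxel_size
    } else {
      axes <- c("x", "y", "z")
      voxel_size <- abs(pixdim[2:4])
    }
  } else {
    voxel_size <- if (sform_code > 0) axes_from_matrix(srow[, 1:3])$voxel_size
                  else abs(pixdim[2:4])
  }
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("missing or invalid voxel-size metadata: ", path, call. = FALSE)
  }
  field_map(arr, voxel_size = voxel_size, axes = axes)
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes a [field_map()] (or a bare 3D array plus geometry) to a NIfTI-1 file
#' with an sform encoding the voxel size and axis mapping. `float64` output
#' (the default) round-trips values bit-exactly through [read_volume()].
#'
#' @param x a [field_map()] or a 3D numeric array.
#' @param path output path (`.nii`, or `.nii.gz` for gzip compression).
#' @param voxel_size,axes geometry, required when `x` is a bare array.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"int32"`,
#'   `"uint8"`, `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = NULL, axes = NULL,
                         datatype = "float64") {
  if (inherits(x, "field_map")) {
    arr <- x$values
    voxel_size <- voxel_size %||% x$voxel_size
    axes <- axes %||% x$axes
  } else {
    arr <- x
    if (is.null(voxel_size)) stop("voxel_size required for bare arrays")
    axes <- axes %||% c("x", "y", "z")
  }
  stopifnot(length(dim(arr)) == 3)
  dt <- NIFTI_DT[[match.arg(datatype, names(NIFTI_DT))]]
  R <- axes_matrix(axes, voxel_size)

  con <- if (is_gz_path(path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wchar <- function(s, len) {
    b <- charToRaw(s)
    writeBin(c(b, raw(len - length(b))), con)
  }
  wb(348L, 4)                                   # sizeof_hdr
  wchar("", 10); wchar("", 18)                  # data_type, db_name
  wb(0L, 4); wb(0L, 2); wchar("r", 1); wchar("", 1)  # extents..dim_info
  wb(as.integer(c(3, dim(arr), 1, 1, 1, 1)), 2) # dim
  wb(c(0, 0, 0), 4)                             # intent_p1..p3 (float)
  wb(0L, 2)                                     # intent_code
  wb(dt$code, 2); wb(dt$bitpix, 2); wb(0L, 2)   # datatype, bitpix, slice_start
  wb(c(1, voxel_size, 1, 0, 0, 0), 4)           # pixdim (qfac = 1)
  wb(352, 4)                                    # vox_offset (float)
  wb(c(1, 0), 4)                                # scl_slope, scl_inter
  wb(0L, 2); wchar("", 1); wchar("", 1)         # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4)                          # cal_max..toffset
  wb(c(0L, 0L), 4)                              # glmax, glmin
  wchar("boldsens", 80); wchar("", 24)          # descrip, aux_file
  wb(c(0L, 1L), 2)                              # qform_code, sform_code
  wb(c(0, 0, 0, 0, 0, 0), 4)                    # quatern, qoffset
  wb(c(R[1, ], 0), 4); wb(c(R[2, ], 0), 4); wb(c(R[3, ], 0), 4)  # srows
  wchar("", 16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension indicator
  v <- as.vector(arr)
  if (dt$what == "integer") {
    v <- as.integer(round(v))
    writeBin(v, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
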