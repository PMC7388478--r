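# Volume/mask containers and MetaImage + NIfTI-1 readers/writers.
# Axis convention throughout: arrays are indexed (slice, row, column), 0-based
# indices in seed tables, 1-based inside R code; spacing/origin vectors follow
# the same (slice, row, column) order in mm.  On disk both formats store the
# fastest-varying axis first (x = column), so IO permutes axes accordingly.

#' Construct a 3D volume image
#'
#' @param voxels numeric 3D array indexed (slice, row, column)
#' @param spacing numeric length-3, per-axis voxel size in mm (slice, row, col)
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm
#' @return an object of class \code{volume_image}
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array indexed (slice, row, column)")
  if (any(dim(voxels) < 1L)) stop("volume must have at least 1 voxel per axis")
  if (!all(is.finite(voxels))) stop("all voxel intensities must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct a binary lesion mask
#'
#' Any nonzero voxel is foreground.  A mask with no foreground voxels is kept
#' but flagged empty (see \code{\link{mask_is_empty}}).
#'
#' @param voxels 3D array; nonzero values become 1
#' @inheritParams volume_image
#' @return an object of class \code{lesion_mask}
#' @export
lesion_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume_image(voxels, spacing, origin)
  b <- array(as.integer(v$voxels != 0), dim = dim(v$voxels))
  structure(list(voxels = b, spacing = v$spacing, origin = v$origin,
                 empty = !any(b != 0L)),
            class = "lesion_mask")
}

#' Is a lesion mask empty (zero foreground voxels)?
#' @param mask a \code{lesion_mask}
#' @return logical
#' @export
mask_is_empty <- function(mask) isTRUE(mask$empty)

.io_format <- function(path) {
  p <- tolower(path)
  if (endsWith(p, ".mhd")) "mhd"
  else if (endsWith(p, ".nii") || endsWith(p, ".nii.gz")) "nifti"
  else stop("unrecognized image format (expected .mhd, .nii or .nii.gz): ", path)
}

#' Read a 3D volume (MetaImage or NIfTI-1)
#'
#' Voxel intensities are returned unmodified; spacing and origin come from the
#' header.  Only 3D single-channel images are accepted.
#'
#' @param path path to a \code{.mhd}, \code{.nii} or \code{.nii.gz} file
#' @return a \code{\link{volume_image}}
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(.io_format(path), mhd = .read_mhd(path), nifti = .read_nifti(path))
}

#' Write a 3D volume (MetaImage or NIfTI-1)
#'
#' The on-disk element type is float32 unless \code{element_type = "uint8"},
#' which is used for masks.  Round-trips are bit-exact for data representable
#' in the chosen type.
#'
#' @param v a \code{\link{volume_image}} or \code{\link{lesion_mask}}
#' @param path output path (\code{.mhd}, \code{.nii} or \code{.nii.gz})
#' @param element_type \code{"float"} or \code{"uint8"}
#' @return \code{path}, invisibly
#' @export
write_volume <- function(v, path, element_type = c("float", "uint8")) {
  element_type <- match.arg(element_type)
  if (!inherits(v, c("volume_image", "lesion_mask")))
    stop("`v` must be a volume_image or lesion_mask")
  if (length(dim(v$voxels)) != 3L || any(dim(v$voxels) < 1L))
    stop("cannot write a volume with an empty shape")
  switch(.io_format(path),
         mhd = .write_mhd(v, path, element_type),
         nifti = .write_nifti(v, path, element_type))
  invisible(path)
}

#' Write a lesion mask (unsigned 8-bit)
#' @param mask a \code{\link{lesion_mask}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_mask <- function(mask, path) write_volume(mask, path, "uint8")

#' Read a lesion mask and validate alignment against its volume
#'
#' Nonzero voxels map to 1.  Shape must match the reference exactly and
#' spacing/origin must agree within \code{tol} mm.
#'
#' @param path mask file path
#' @param reference the paired \code{\link{volume_image}}
#' @param tol geometry tolerance in mm (default 1e-4)
#' @return a \code{\link{lesion_mask}}
#' @export
read_mask <- function(path, reference, tol = 1e-4) {
  m <- read_volume(path)
  if (!inherits(reference, "volume_image")) stop("`reference` must be a volume_image")
  if (!identical(dim(m$voxels), dim(reference$voxels)))
    stop("mask/image alignment error: mask shape (",
         paste(dim(m$voxels), collapse = ","), ") != image shape (",
         paste(dim(reference$voxels), collapse = ","), ")")
  if (any(abs(m$spacing - reference$spacing) > tol) ||
      any(abs(m$origin - reference$origin) > tol))
    stop("mask/image alignment error: mask geometry [spacing ",
         paste(m$spacing, collapse = ","), "; origin ",
         paste(m$origin, collapse = ","), "] != image geometry [spacing ",
         paste(reference$spacing, collapse = ","), "; origin ",
         paste(reference$origin, collapse = ","), "]")
  lesion_mask(m$voxels, reference$spacing, reference$origin)
}

## ---- MetaImage (.mhd + .raw) ------------------------------------------------

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

.read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("malformed MetaImage header line in ", path, ": '", ln, "'")
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop("malformed MetaImage header: missing field '", key, "' in ", path)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (is.na(ndims) || ndims != 3L)
    stop("format error in field 'NDims': expected 3D data, header declares NDims = ",
         need("NDims"))
  dimsize <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dimsize) != 3L || any(is.na(dimsize)) || any(dimsize < 1L))
    stop("format error in field 'DimSize': '", need("DimSize"), "'")
  spacing_xyz <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  if (length(spacing_xyz) != 3L || any(is.na(spacing_xyz)) || any(spacing_xyz <= 0))
    stop("format error in field 'ElementSpacing': '", kv$ElementSpacing, "'")
  origin_xyz <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (length(origin_xyz) != 3L || any(is.na(origin_xyz)))
    stop("format error in field 'Offset': '", kv$Offset, "'")
  etype <- need("ElementType")
  tinfo <- .met_types[[etype]]
  if (is.null(tinfo))
    stop("format error in field 'ElementType': unsupported type '", etype, "'")
  msb <- identical(toupper(kv[["BinaryDataByteOrderMSB"]]), "TRUE") ||
    identical(toupper(kv[["ElementByteOrderMSB"]]), "TRUE")
  if (identical(toupper(kv[["CompressedData"]]), "TRUE"))
    stop("format error in field 'CompressedData': compressed MetaImage not supported")
  datafile <- need("ElementDataFile")
  if (identical(toupper(datafile), "LOCAL"))
    stop("format error in field 'ElementDataFile': LOCAL storage not supported")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
  n <- prod(dimsize)
  con <- file(rawpath, "rb"); on.exit(close(con))
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop("raw data file ", rawpath, " holds ", length(vals),
         " elements, header declares ", n)
  # disk order x(col)-fastest -> array (col,row,slice) -> permute to (slice,row,col)
  arr <- aperm(array(as.numeric(vals), dim = dimsize), c(3, 2, 1))
  volume_image(arr, spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

.write_mhd <- function(v, path, element_type) {
  dims <- dim(v$voxels)
  base <- sub("\\.mhd$", "", basename(path), ignore.case = TRUE)
  rawname <- paste0(base, ".raw")
  etype <- if (element_type == "uint8") "MET_UCHAR" else "MET_FLOAT"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(vapply(rev(v$origin), format, "", scientific = FALSE),
                            collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(vapply(rev(v$spacing), format, "",
                                           scientific = FALSE), collapse = " ")),
    paste("DimSize =", paste(rev(dims), collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", rawname)
  )
  ok <- tryCatch({ writeLines(hdr, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  vals <- as.vector(aperm(v$voxels, c(3, 2, 1)))  # x-fastest on disk
  con <- file(file.path(dirname(path), rawname), "wb"); on.exit(close(con))
  if (element_type == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI-1 (.nii / .nii.gz) ----------------------------------------------
# Minimal single-file NIfTI-1 support: 3D, little-endian, datatypes
# uint8/int16/int32/float32/float64, sform-based origin, no orientation codes
# beyond an axis-aligned positive-diagonal sform.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

.read_nifti <- function(path) {
  con <- if (endsWith(tolower(path), ".gz")) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("malformed NIfTI header: file truncated: ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):348], what, n = n, size = size, endian = "little",
            signed = TRUE)
  }
  sizeof_hdr <- rd(0, "integer", 1, 4)
  if (sizeof_hdr != 348L)
    stop("format error in field 'sizeof_hdr': got ", sizeof_hdr,
         " (big-endian or non-NIfTI-1 files are not supported)")
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("format error in field 'magic': '", magic, "'")
  dim_field <- rd(40, "integer", 8, 2)
  ndim <- dim_field[1]
  dims <- dim_field[2:8]
  if (ndim > 3L && all(dims[(3 + 1):7] <= 1L)) ndim <- 3L
  if (ndim != 3L)
    stop("format error in field 'dim': expected 3D data, header declares dim[0] = ",
         dim_field[1])
  dimsize <- dims[1:3]
  if (any(dimsize < 1L)) stop("format error in field 'dim': ", paste(dims, collapse = " "))
  datatype <- rd(70, "integer", 1, 2)
  tinfo <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(tinfo))
    stop("format error in field 'datatype': unsupported code ", datatype)
  pixdim <- rd(76, "numeric", 8, 4)
  spacing_xyz <- pixdim[2:4]
  if (any(!is.finite(spacing_xyz)) || any(spacing_xyz <= 0))
    stop("format error in field 'pixdim': ", paste(pixdim[2:4], collapse = " "))
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)
  origin_xyz <- if (sform_code > 0) srow[, 4] else c(0, 0, 0)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dimsize)
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = "little")
  if (length(vals) != n)
    stop("NIfTI data section holds ", length(vals), " elements, header declares ", n)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- aperm(array(vals, dim = dimsize), c(3, 2, 1))
  volume_image(arr, spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

.write_nifti <- function(v, path, element_type) {
  dims <- rev(dim(v$voxels))           # x y z
  spacing_xyz <- rev(v$spacing)
  origin_xyz <- rev(v$origin)
  datatype <- if (element_type == "uint8") 2L else 16L
  bitpix <- if (element_type == "uint8") 8L else 32L
  hdr <- raw(348)
  put <- function(hdr, off, x, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, 4)                                  # sizeof_hdr
  hdr <- put(hdr, 40, as.integer(c(3, dims, 1, 1, 1, 1)), 2)   # dim
  hdr <- put(hdr, 70, datatype, 2)
  hdr <- put(hdr, 72, bitpix, 2)
  hdr <- put(hdr, 76, c(1, spacing_xyz, 1, 1, 1, 1), 4)        # pixdim
  hdr <- put(hdr, 108, 352, 4)                                 # vox_offset
  hdr <- put(hdr, 112, 1, 4)                                   # scl_slope
  hdr <- put(hdr, 116, 0, 4)                                   # scl_inter
  hdr <- put(hdr, 252, 0L, 2)                                  # qform_code
  hdr <- put(hdr, 254, 1L, 2)                                  # sform_code
  srow <- rbind(c(spacing_xyz[1], 0, 0, origin_xyz[1]),
                c(0, spacing_xyz[2], 0, origin_xyz[2]),
                c(0, 0, spacing_xyz[3], origin_xyz[3]))
  hdr <- put(hdr, 280, as.numeric(t(srow)), 4)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  con <- tryCatch(
    if (endsWith(tolower(path), ".gz")) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                                        # extension flag
  vals <- as.vector(aperm(v$voxels, c(3, 2, 1)))
  if (element_type == "uint8") writeBin(as.integer(round(vals)), con, size = 1L)
  else writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  invisible(path)
}
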