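## Volume and mask I/O: MetaImage (.mhd/.raw) and NIfTI (.nii/.nii.gz).
##
## MetaImage raw data is stored x-fastest; in memory everything is [z, y, x],
## so arrays are permuted on the way in and out. Intensities are never
## rescaled: CT thresholds downstream are learned from the data.

metaTypeMap <- c(
  MET_CHAR = "integer", MET_UCHAR = "integer", MET_SHORT = "integer",
  MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
  MET_FLOAT = "double", MET_DOUBLE = "double")

metaTypeSize <- c(
  MET_CHAR = 1L, MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
  MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

metaTypeSigned <- c(
  MET_CHAR = TRUE, MET_UCHAR = FALSE, MET_SHORT = TRUE, MET_USHORT = FALSE,
  MET_INT = TRUE, MET_UINT = FALSE, MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

parseMhdHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(x[2]), "")
  setNames(as.list(vals), keys)
}

readMetaImage <- function(path) {
  h <- parseMhdHeader(path)
  getv <- function(key, default = NULL) {
    if (!is.null(h[[key]])) h[[key]] else default
  }
  ndims <- as.integer(getv("NDims", "0"))
  if (ndims != 3L)
    stop("MetaImage format error: expected a 3D image, got NDims=", ndims)
  dimsize <- as.integer(strsplit(getv("DimSize", ""), "\\s+")[[1]])
  if (length(dimsize) != 3L || any(is.na(dimsize)) || any(dimsize < 1))
    stop("MetaImage format error: bad DimSize")
  spc <- getv("ElementSpacing", getv("ElementSize", "1 1 1"))
  spacing <- as.numeric(strsplit(spc, "\\s+")[[1]])
  if (length(spacing) != 3L || any(is.na(spacing)) || any(spacing <= 0))
    stop("MetaImage format error: non-positive or malformed spacing")
  org <- getv("Offset", getv("Origin", getv("Position", "0 0 0")))
  origin <- as.numeric(strsplit(org, "\\s+")[[1]])
  etype <- getv("ElementType", "MET_SHORT")
  if (!etype %in% names(metaTypeMap))
    stop("MetaImage format error: unsupported ElementType ", etype)
  datafile <- getv("ElementDataFile")
  if (is.null(datafile) || toupper(datafile) == "LIST")
    stop("MetaImage format error: missing or unsupported ElementDataFile")
  rawpath <- if (datafile == "LOCAL") path
             else file.path(dirname(path), datafile)
  if (datafile != "LOCAL" && !file.exists(rawpath))
    stop("MetaImage format error: companion data file not found: ", rawpath)
  endian <- if (isTRUE(toupper(getv("ElementByteOrderMSB", "False")) == "TRUE") ||
                isTRUE(toupper(getv("BinaryDataByteOrderMSB", "False")) == "TRUE"))
    "big" else "little"
  n <- prod(dimsize)
  size <- metaTypeSize[[etype]]
  compressed <- toupper(getv("CompressedData", "False")) == "TRUE"
  if (compressed) {
    bytes <- readBin(rawpath, "raw", n = file.size(rawpath))
    bytes <- memDecompress(bytes, type = "gzip")
    vals <- readBin(bytes, metaTypeMap[[etype]], n = n, size = size,
                    signed = metaTypeSigned[[etype]], endian = endian)
  } else {
    vals <- readBin(rawpath, metaTypeMap[[etype]], n = n, size = size,
                    signed = metaTypeSigned[[etype]], endian = endian)
  }
  if (length(vals) < n)
    stop("MetaImage format error: data file shorter than DimSize implies")
  # raw order is x fastest, so fill [x, y, z] and permute to [z, y, x]
  arr <- aperm(array(vals, dim = dimsize), c(3, 2, 1))
  # header stores spacing/origin as (x, y, z); internal order is (z, y, x)
  ctVolume(arr, spacing = rev(spacing), origin = rev(origin))
}

writeMetaImage <- function(vol, path, elementType) {
  stopifnot(grepl("\\.mhd$", path, ignore.case = TRUE))
  rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  d <- dim(vol@data)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", d[3], d[2], d[1]),
    paste("ElementSpacing =",
          paste(formatC(rev(vol@spacing), format = "g", digits = 17),
                collapse = " ")),
    paste("Offset =",
          paste(formatC(rev(vol@origin), format = "g", digits = 17),
                collapse = " ")),
    paste("ElementType =", elementType),
    paste("ElementDataFile =", rawname))
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write MetaImage header: ", path)
  writeLines(header, con); close(con)
  vals <- as.vector(aperm(vol@data, c(3, 2, 1)))  # back to x fastest
  if (metaTypeMap[[elementType]] == "integer") vals <- as.integer(round(vals))
  writeBin(vals, file.path(dirname(path), rawname),
           size = metaTypeSize[[elementType]], endian = "little")
}

isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a CT volume or mask from disk
#'
#' Supports MetaImage (a `.mhd` header with a companion `.raw` file,
#' uncompressed or zlib-compressed) and NIfTI (`.nii`, `.nii.gz`). Voxel
#' values are returned unchanged; spacing is taken from the header and
#' reordered to the internal (z, y, x) convention.
#'
#' @param path path to a `.mhd`, `.nii` or `.nii.gz` file.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()], [writeMask()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (isNifti(path)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("NIfTI format error: expected a 3D image")
    spacing <- attr(img, "pixdim")[1:3]          # (x, y, z)
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("NIfTI format error: non-positive spacing")
    arr <- aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1))
    return(ctVolume(arr, spacing = rev(spacing), origin = c(0, 0, 0)))
  }
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return(readMetaImage(path))
  stop("unrecognised volume format (expected .mhd or .nii/.nii.gz): ", path)
}

#' Read a binary mask from disk
#'
#' As [readVolume()], then validated/coerced to a [VoxelMask-class]; any
#' nonzero voxel becomes 1.
#'
#' @inheritParams readVolume
#' @return A [VoxelMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  voxelMask(array(as.integer(v@data != 0), dim = dim(v@data)),
            spacing = v@spacing, origin = v@origin)
}

#' Write a CT volume to disk
#'
#' MetaImage output uses signed 16-bit elements (CT Hounsfield-like range);
#' NIfTI goes through RNifti. Values are rounded to integers for integer
#' element types.
#'
#' @param vol a [CTVolume-class].
#' @param path output path ending in `.mhd` or `.nii`/`.nii.gz`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  if (isNifti(path)) {
    arr <- aperm(vol@data, c(3, 2, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(vol@spacing)
    RNifti::writeNifti(img, path)
  } else {
    writeMetaImage(vol, path, "MET_SHORT")
  }
  invisible(path)
}

#' Write a binary mask to disk
#'
#' MetaImage output uses unsigned 8-bit elements with values exactly
#' \{0, 1\}; geometry is preserved at full float precision in the header.
#'
#' @param mask a [VoxelMask-class].
#' @param path output path ending in `.mhd` or `.nii`/`.nii.gz`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VoxelMask"))
  if (isNifti(path)) {
    writeVolume(mask, path)
  } else {
    writeMetaImage(mask, path, "MET_UCHAR")
  }
  invisible(path)
}

#' Write a label volume to disk
#'
#' Labels are stored as unsigned 8-bit MetaImage elements; the legend is
#' written alongside as `<path>.legend.json`.
#'
#' @param labels a [LabelVolume-class].
#' @param path output path ending in `.mhd`.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  writeMetaImage(labels, path, "MET_UCHAR")
  if (length(labels@legend))
    jsonlite::write_json(as.list(labels@legend),
                         paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}
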