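# MetaImage (.mhd + .raw) reader/writer for 2D planar grids.
# DimSize is (cols, rows); the raw payload is row-major with the column
# index fastest, little-endian unless ElementByteOrderMSB = True.

.met_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = FALSE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

.parse_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) if (length(x) > 1) trimws(x[[2]]) else "", "")
  stats::setNames(as.list(vals), keys)
}

#' Read a 2D MetaImage
#'
#' Reads a `.mhd` header plus its raw payload into a [planar_image()].
#' Supports 8/16/32-bit integer and 32/64-bit float element types,
#' uncompressed payloads, NDims = 2 (or 3 with a singleton third
#' dimension). `ElementSpacing` supplies the pixel size; byte order follows
#' `ElementByteOrderMSB` / `BinaryDataByteOrderMSB` (little-endian default).
#'
#' @param path path to the `.mhd` header file.
#' @param view,time_post_admin_h,duration_s metadata for the returned
#'   [planar_image()] (MetaImage does not carry them).
#' @return a `planar_image`.
#' @export
read_metaimage <- function(path, view = "anterior",
                           time_post_admin_h = 0, duration_s = 1) {
  if (!file.exists(path)) stop("read_metaimage: no such file: ", path)
  h <- .parse_mhd_header(path)
  ndims <- as.integer(h$NDims %||% "2")
  dimsize <- as.integer(strsplit(trimws(h$DimSize), "\\s+")[[1]])
  if (ndims == 3L) {
    if (length(dimsize) != 3L || dimsize[3] != 1L)
      stop("read_metaimage: only 2D grids supported (NDims=3 needs a singleton third dimension)")
    dimsize <- dimsize[1:2]
  } else if (ndims != 2L) {
    stop("read_metaimage: unsupported NDims = ", ndims)
  }
  if (!is.null(h$CompressedData) && tolower(h$CompressedData) == "true")
    stop("read_metaimage: compressed payloads are not supported (CompressedData)")
  etype <- h$ElementType %||% "MET_FLOAT"
  tspec <- .met_types[[etype]]
  if (is.null(tspec))
    stop("read_metaimage: unsupported ElementType '", etype, "'")
  spacing <- as.numeric(strsplit(trimws(h$ElementSpacing %||% "1 1"), "\\s+")[[1]])
  msb <- tolower(h$ElementByteOrderMSB %||% h$BinaryDataByteOrderMSB %||% "false") == "true"
  datafile <- h$ElementDataFile %||% stop("read_metaimage: missing ElementDataFile")
  if (datafile %in% c("LOCAL", "Local")) stop("read_metaimage: LOCAL payloads not supported")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath))
    stop("read_metaimage: raw file not found: ", rawpath)
  n <- prod(dimsize)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = tspec$what, n = n, size = tspec$size,
                  signed = tspec$signed,
                  endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop("read_metaimage: raw file holds ", length(vals),
         " elements, header promises ", n)
  # cols = dimsize[1] fastest-varying -> fill by row
  px <- matrix(as.numeric(vals), nrow = dimsize[2], ncol = dimsize[1],
               byrow = TRUE)
  planar_image(px, pixel_size_mm = c(spacing[min(2, length(spacing))], spacing[1]),
               view = view, time_post_admin_h = time_post_admin_h,
               duration_s = duration_s)
}

#' Write a 2D MetaImage
#'
#' Writes a grid as a `.mhd` header plus `.raw` payload. The round trip
#' `read_metaimage(write_metaimage(img))` is lossless for the supported
#' element types (MET_DOUBLE by default).
#'
#' @param img a `planar_image`, `organ_mask`, or bare numeric matrix.
#' @param path output `.mhd` path; the raw payload goes next to it with the
#'   same stem and extension `.raw`.
#' @param element_type one of MET_UCHAR, MET_CHAR, MET_SHORT, MET_USHORT,
#'   MET_INT, MET_UINT, MET_FLOAT, MET_DOUBLE.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(img, path, element_type = "MET_DOUBLE") {
  px <- if (inherits(img, c("planar_image", "organ_mask"))) img$pixels else as.matrix(img)
  spacing <- if (inherits(img, "planar_image")) img$pixel_size_mm else c(1, 1)
  tspec <- .met_types[[element_type]]
  if (is.null(tspec))
    stop("write_metaimage: unsupported ElementType '", element_type, "'")
  rawname <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 2",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d", ncol(px), nrow(px)),
           sprintf("ElementSpacing = %s %s",
                   format(spacing[2], digits = 15), format(spacing[1], digits = 15)),
           sprintf("ElementType = %s", element_type),
           sprintf("ElementDataFile = %s", rawname))
  writeLines(hdr, path)
  vals <- as.vector(t(px))   # column index fastest
  if (tspec$what == "integer") vals <- as.integer(round(vals))
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = tspec$size, endian = "little")
  invisible(path)
}

#' Read a binary organ mask stored as MetaImage
#'
#' @param path `.mhd` path with a 0/1 payload.
#' @param label organ label for the mask (defaults to the file stem).
#' @return an `organ_mask`.
#' @export
read_mask_metaimage <- function(path, label = sub("\\.mhd$", "", basename(path))) {
  img <- read_metaimage(path)
  organ_mask((img$pixels != 0) * 1, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
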