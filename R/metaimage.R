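.met_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Read a MetaImage (.mhd/.raw) CT volume
#'
#' Parses the text header and loads the raw voxel block referenced by
#' `ElementDataFile`. Header geometry is given in `(x, y, z)` order per the
#' MetaImage convention and is converted to the internal `(z, y, x)` order.
#' Voxel values are returned as signed doubles regardless of the on-disk
#' element type. Compressed data and `ElementDataFile = LOCAL` are not
#' supported.
#'
#' @param path Path to the `.mhd` header.
#' @return A [ct_volume].
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path))
    abort(sprintf("MetaImage header not found: %s", path), class = "lungcad_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  hdr <- setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) m[2], character(1))
  )
  need <- function(key) {
    if (is.null(hdr[[key]]))
      abort(sprintf("MetaImage header %s lacks required key %s", path, key),
            class = "lungcad_format_error")
    hdr[[key]]
  }
  if (as.integer(need("NDims")) != 3L)
    abort("only NDims = 3 MetaImage volumes are supported",
          class = "lungcad_format_error")
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    abort("compressed MetaImage data is not supported", class = "lungcad_format_error")
  dims_xyz <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing_xyz <- as.numeric(strsplit(
    hdr$ElementSpacing %||% hdr$ElementSize %||% "1 1 1", "\\s+")[[1]])
  origin_xyz <- as.numeric(strsplit(hdr$Offset %||% hdr$Origin %||% "0 0 0", "\\s+")[[1]])
  type <- need("ElementType")
  tinfo <- .met_types[[type]]
  if (is.null(tinfo))
    abort(sprintf("unsupported MetaImage element type: %s", type),
          class = "lungcad_format_error")
  datafile <- need("ElementDataFile")
  if (toupper(datafile) == "LOCAL")
    abort("ElementDataFile = LOCAL is not supported", class = "lungcad_format_error")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath))
    abort(sprintf("MetaImage data file not found: %s", rawpath),
          class = "lungcad_io_error")
  n <- prod(dims_xyz)
  endian <- if (!is.null(hdr$BinaryDataByteOrderMSB) &&
                tolower(hdr$BinaryDataByteOrderMSB) == "true") "big" else "little"
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) != n)
    abort(sprintf("MetaImage data file %s is truncated (%d of %d voxels)",
                  rawpath, length(vals), n), class = "lungcad_format_error")
  # raw block is x-fastest; build (x,y,z) then permute to (z,y,x)
  arr <- aperm(array(as.numeric(vals), dim = dims_xyz), c(3, 2, 1))
  ct_volume(arr, spacing = rev(spacing_xyz), origin = rev(origin_xyz),
            series_id = sub("\\.mhd$", "", basename(path)))
}

#' Write a CT volume as a MetaImage (.mhd/.raw) pair
#'
#' Emits a header/raw pair readable by [read_metaimage()] and by standard
#' MetaImage readers. Geometry is written in the conventional `(x, y, z)`
#' order. `MET_DOUBLE` (the default) round-trips voxel values bit for bit;
#' `MET_SHORT`/`MET_UCHAR` truncate to integers.
#'
#' @param volume A [ct_volume].
#' @param path Output `.mhd` path; the `.raw` file is written next to it.
#' @param element_type One of `"MET_DOUBLE"`, `"MET_FLOAT"`, `"MET_SHORT"`,
#'   `"MET_UCHAR"`.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(volume, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(volume, "ct_volume"))
  tinfo <- .met_types[[element_type]]
  if (is.null(tinfo) || !element_type %in% c("MET_DOUBLE", "MET_FLOAT", "MET_SHORT", "MET_UCHAR"))
    abort(sprintf("unsupported element type for writing: %s", element_type))
  dir <- dirname(path)
  if (!dir.exists(dir))
    abort(sprintf("directory does not exist: %s", dir), class = "lungcad_io_error")
  rawname <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  d <- dim(volume$voxels)  # (z,y,x)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.6f %.6f %.6f",
            volume$origin[3], volume$origin[2], volume$origin[1]),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.6f %.6f %.6f",
            volume$spacing[3], volume$spacing[2], volume$spacing[1]),
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", rawname)
  )
  ok <- tryCatch({ writeLines(hdr, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write MetaImage header: %s", path),
                 class = "lungcad_io_error")
  vals <- as.vector(aperm(volume$voxels, c(3, 2, 1)))  # x fastest on disk
  if (tinfo$what == "integer") vals <- as.integer(round(vals))
  con <- file(file.path(dir, rawname), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = tinfo$size, endian = "little")
  invisible(path)
}
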