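# Grayscale image I/O. PNG and TIFF, 8- and 16-bit integer plus 32-bit float
# TIFF. Intensities are kept on their native integer scale (a 16-bit pixel
# value of 1000 reads as 1000.0, never rescaled to [0, 1]). DICOM input is
# not supported in this build: no DICOM reader is available to link against,
# and read_image() says so explicitly - convert slices to 16-bit PNG/TIFF.
#
# Float TIFFs: the underlying TIFF writer stores samples in [0, 1], so float
# images are stored as intensity / 65536 (an exact power-of-two scaling) and
# rescaled on read. Within 32-bit float precision the round trip is exact;
# this convention is specific to files written by this package.

FLOAT_TIFF_SCALE <- 65536

img_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF (or a 32-bit float TIFF
#' written by [write_image()]) into a numeric matrix. Integer intensities
#' are preserved on their native scale (not rescaled to `[0, 1]`). Color or
#' multi-channel images are rejected.
#'
#' @param path file path; format is inferred from the extension
#'   (`png`, `tif`/`tiff`).
#' @return A numeric intensity matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- img_ext(path)
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    if (length(dim(x)) == 3L)
      stop("grayscale required: '", path, "' has ", dim(x)[3L], " channels",
           call. = FALSE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    return(round(unclass(x) * (2^depth - 1)))  # PNG samples are integers
  }
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bps <- info$bits.per.sample[1L]
    spp <- info$samples.per.pixel[1L]
    if (!is.null(spp) && spp > 1L)
      stop("grayscale required: '", path, "' has ", spp, " channels",
           call. = FALSE)
    if (bps == 32L) {
      x <- tiff::readTIFF(path)           # float samples in [0, 1]
      return(unclass(x) * FLOAT_TIFF_SCALE)
    }
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L)
      stop("grayscale required: '", path, "' is multi-channel", call. = FALSE)
    return(unclass(x) + 0)
  }
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported in this build (no DICOM reader ",
         "available); convert the slice to 16-bit PNG or TIFF", call. = FALSE)
  stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
}

#' Write a grayscale image
#'
#' Writes an intensity matrix as PNG (8/16-bit) or TIFF (8/16-bit or 32-bit
#' float). Integer depths clip to the representable range and round
#' half-to-even; the float depth (TIFF only) preserves values to 32-bit
#' float precision and requires intensities in `[0, 65536)`.
#'
#' @param img numeric intensity matrix.
#' @param path output path; format inferred from the extension.
#' @param depth `"8"`, `"16"` or `"float"` (numeric 8/16 also accepted).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, depth = c("8", "16", "float")) {
  check_image(img)
  depth <- match.arg(as.character(depth), c("8", "16", "float"))
  ext <- img_ext(path)
  if (!ext %in% c("png", "tif", "tiff"))
    stop("unsupported output format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  if (depth == "float") {
    if (ext == "png")
      stop("float depth requires a TIFF output path", call. = FALSE)
    if (any(img < 0 | img >= FLOAT_TIFF_SCALE))
      stop("float TIFF storage requires intensities in [0, 65536)",
           call. = FALSE)
    tiff::writeTIFF(img / FLOAT_TIFF_SCALE, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  if (depth == "16" && ext == "png")
    stop("16-bit output requires a TIFF path (the PNG writer is 8-bit only; ",
         "16-bit PNGs can still be read)", call. = FALSE)
  top <- if (depth == "8") 255 else 65535
  v <- round(pmin(pmax(img, 0), top))     # round() is round-half-to-even
  if (ext == "png") png::writePNG(v / top, path)
  else tiff::writeTIFF(v / top, path,
                       bits.per.sample = if (depth == "8") 8L else 16L)
  invisible(path)
}
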