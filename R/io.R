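# Grayscale image file I/O. PNG and TIFF, 8- or 16-bit; intensities are
# always exposed to the rest of the package in 8-bit gray-level units
# [0, 255], with 16-bit data mapped linearly onto that range on read.

imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported image format '", ext, "' (use PNG or TIFF): ", path,
       call. = FALSE)
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF into a numeric matrix of gray levels in
#' [0, 255] (16-bit values are mapped linearly). RGB(A) images are converted
#' to grayscale by averaging the first three channels, with a warning; an
#' alpha channel is dropped.
#'
#' @param path image file path.
#' @return numeric matrix of gray levels.
#' @export
readGrayImage <- function(path) {
  fmt <- imageFormat(path)
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      warning("RGB input converted to grayscale by channel average: ", path,
              call. = FALSE)
      arr <- (arr[, , 1L] + arr[, , 2L] + arr[, , 3L]) / 3
    } else {
      arr <- arr[, , 1L]  # gray + alpha
    }
  }
  arr * 255
}

#' Write a grayscale image
#'
#' Clips the image to [0, 255] (warning if any pixel was clipped), quantizes
#' to the requested bit depth and writes a single-channel PNG or TIFF.
#' Writing then reading an integer-valued 8-bit image reproduces it exactly.
#'
#' @param img numeric matrix in gray levels.
#' @param path output path; the extension selects PNG or TIFF.
#' @param bits bit depth, 8 or 16 (16 is honoured for TIFF; PNG output is
#'   8-bit).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path, bits = 8L) {
  assertImage(img)
  stopifnot(bits %in% c(8L, 16L))
  if (any(img < 0) || any(img > 255)) {
    warning(sprintf("%d pixel(s) clipped to [0, 255] on write: %s",
                    sum(img < 0 | img > 255), path), call. = FALSE)
    img <- pmin(pmax(img, 0), 255)
  }
  fmt <- imageFormat(path)
  levels <- 2^bits - 1
  quant <- round(img / 255 * levels) / levels
  if (fmt == "png") {
    png::writePNG(quant, path)
  } else {
    tiff::writeTIFF(quant, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}
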