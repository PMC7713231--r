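#' Slide-scan image container
#'
#' A scan is a grayscale intensity matrix (rows = image rows, columns = image
#' columns, values in \[0, 1\], dark particles on a light transmitted-light
#' background) together with its physical pixel size.
#'
#' Coordinate conventions used throughout the package: pixel indices are
#' 0-based, `x` runs along columns and `y` along rows, both measured from the
#' scan's top-left corner; bounding boxes are half-open
#' `(row_min, col_min, row_max, col_max)`.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param scale Micrometres per pixel (positive).
#' @param id Free-text scan identifier.
#' @return Object of class `scan_image`.
#' @export
scan_image <- function(pixels, scale = 1, id = "scan") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("scan must have width and height >= 1")
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("scale must be a single positive number (micrometres per pixel)")
  }
  structure(
    list(pixels = pixels, scale = as.numeric(scale), id = as.character(id)),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf(
    "<scan_image '%s': %d x %d px, %.3g um/px>\n",
    x$id, ncol(x$pixels), nrow(x$pixels), x$scale
  ))
  invisible(x)
}

#' Read a slide scan from a TIFF or PNG file
#'
#' RGB images are collapsed to luminance (Rec. 709 weights); intensities are
#' clipped to \[0, 1\].
#'
#' @param path Path to a TIFF or PNG image.
#' @param scale Micrometres per pixel of the scan.
#' @param id Scan identifier; defaults to the file name without extension.
#' @return A [scan_image()].
#' @export
read_scan <- function(path, scale = 1, id = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    if (nch >= 3) {
      dat <- 0.2126 * dat[, , 1] + 0.7152 * dat[, , 2] + 0.0722 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  # EBImage stores images x-major (first dim = columns); transpose to rows x cols
  px <- t(dat)
  px <- pmin(pmax(px, 0), 1)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  scan_image(px, scale = scale, id = id)
}

#' Write a grayscale matrix as a PNG image
#'
#' @param pixels Numeric matrix in \[0, 1\] (rows x cols).
#' @param path Output file path (.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  EBImage::writeImage(EBImage::Image(t(pixels)), path)
  invisible(path)
}
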