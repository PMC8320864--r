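#' Frame objects
#'
#' An `ivc_frame` holds one grayscale ultrasound frame: a numeric matrix of
#' intensities in \[0, 1\] (rows = image y, columns = image x) plus the
#' isotropic pixel spacing in cm per pixel.
#'
#' Coordinate convention used throughout the package: `x` is the column index
#' increasing rightward, `y` is the row index increasing downward, pixel
#' centers sit at integer coordinates starting at (1, 1).  The
#' anterior-posterior (AP) axis is the image vertical (`y`).
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param spacing pixel spacing in cm per pixel (scalar, isotropic).
#' @return An object of class `ivc_frame` with fields `pixels`, `height`,
#'   `width` and `spacing`.
#' @seealso [normalize_frame()] to build a frame from raw (un-normalized)
#'   intensity data.
#' @export
frame <- function(pixels, spacing = 1) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels)) stop("frame contains missing intensities")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("frame intensities must lie in [0, 1]; use normalize_frame()")
  if (nrow(pixels) < 32 || ncol(pixels) < 32)
    stop("frame must be at least 32x32 pixels")
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         spacing = spacing),
    class = "ivc_frame")
}

#' Normalize a raw image into a frame
#'
#' Linearly rescales a nonnegative raw intensity grid so its minimum maps to 0
#' and its maximum to 1, and attaches the pixel spacing.
#'
#' @param raw numeric matrix of nonnegative raw intensities (e.g. 8- or 16-bit
#'   values already converted to numeric).
#' @param spacing pixel spacing in cm per pixel.
#' @return An [frame()] object.
#' @export
normalize_frame <- function(raw, spacing = 1) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (anyNA(raw)) stop("raw image contains missing values")
  if (min(raw) < 0) stop("raw image must be nonnegative")
  rng <- range(raw)
  if (rng[1] == rng[2]) stop("degenerate frame: constant image")
  frame((raw - rng[1]) / (rng[2] - rng[1]), spacing = spacing)
}

#' @export
print.ivc_frame <- function(x, ...) {
  cat(sprintf("<ivc_frame %d x %d px, %.4g cm/px, intensity [%.3f, %.3f]>\n",
              x$height, x$width, x$spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Bilinear intensity sampling
#'
#' Samples the frame at continuous coordinates by bilinear interpolation of
#' the four neighbouring pixel centers.  Points outside the frame are clamped
#' to the nearest edge pixel and flagged.
#'
#' @param fr an [frame()] object.
#' @param x,y numeric vectors of continuous coordinates (columns / rows).
#' @return Numeric vector of intensities with attribute `"oob"`, a logical
#'   vector marking the points that were clamped.
#' @export
sample_intensity <- function(fr, x, y) {
  stopifnot(inherits(fr, "ivc_frame"), length(x) == length(y))
  w <- fr$width; h <- fr$height
  oob <- x < 1 | x > w | y < 1 | y > h
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), h - 1L); y1 <- y0 + 1
  wx <- x - x0; wy <- y - y0
  p <- fr$pixels
  v <- (1 - wx) * (1 - wy) * p[cbind(y0, x0)] +
       wx       * (1 - wy) * p[cbind(y0, x1)] +
       (1 - wx) * wy       * p[cbind(y1, x0)] +
       wx       * wy       * p[cbind(y1, x1)]
  attr(v, "oob") <- oob
  v
}

#' Read an image sequence from disk
#'
#' Reads either a directory of single-channel PNG/TIFF frames (sorted by file
#' name, so zero-padded indices are recommended) or a single multi-page TIFF.
#' 8/16-bit unsigned input is accepted; every frame is min-max normalized on
#' load via [normalize_frame()].
#'
#' @param path directory of frames or a multi-page TIFF file.
#' @param spacing pixel spacing in cm per pixel.
#' @return List of [frame()] objects.
#' @export
read_frames <- function(path, spacing = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    mats <- lapply(files, .read_gray)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, .to_gray)
  } else stop("no such file or directory: ", path)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have inconsistent dimensions")
  lapply(mats, normalize_frame, spacing = spacing)
}

.read_gray <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to read PNG frames")
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  .to_gray(img)
}

.to_gray <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
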