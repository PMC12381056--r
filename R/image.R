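# Image container and raster helpers.
#
# Convention used throughout: a grayscale raster is a base matrix with rows = y
# (top to bottom) and columns = x; an RGB raster is an H x W x 3 array. Pixel
# values live on the 0..255 scale (doubles). Coordinates are 1-based with
# x = column, y = row. EBImage stores images transposed (x first), so the two
# helpers below mediate every EBImage call.

as_eb <- function(m) EBImage::Image(t(m))

from_eb <- function(img) t(EBImage::imageData(img))

#' Fundus image container
#'
#' Wraps an RGB raster together with its dimensions and the rescale factor that
#' maps coordinates at the analysis resolution back to the original resolution.
#'
#' @param pixels H x W x 3 numeric array with values in \[0, 255\].
#' @param scale_factor ratio of analysis resolution to original resolution
#'   (1 when the image was not resampled).
#' @return An object of class `fundus_image` with fields `pixels`, `width`,
#'   `height`, `scale_factor`.
#' @export
fundus_image <- function(pixels, scale_factor = 1) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("fundus image must be an H x W x 3 array", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 60 || d[2] < 60)
    stop("image must be at least 60 x 60 pixels", call. = FALSE)
  structure(
    list(pixels = pixels, width = d[2], height = d[1],
         scale_factor = scale_factor),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %d x %d px, scale_factor = %.4g\n",
              x$width, x$height, x$scale_factor))
  invisible(x)
}

#' Read a fundus image from PNG/JPEG/TIFF
#'
#' @param path image file path.
#' @return A [fundus_image()] at the file's native resolution.
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  # EBImage is x-major: transpose each channel to rows = y
  px <- array(0, dim = c(dim(a)[2], dim(a)[1], 3L))
  for (ch in 1:3) px[, , ch] <- t(a[, , ch])
  fundus_image(px * 255)
}

#' Resample a fundus image to the analysis resolution
#'
#' All feature extraction runs on a fixed 600 x 600 field so that the 10 x 10
#' grid of 60 x 60 patches tiles it exactly. `scale_factor` records the mapping
#' back to the original resolution.
#'
#' @param img a [fundus_image()].
#' @param size analysis field side length in pixels (default 600).
#' @return A resampled [fundus_image()] with `scale_factor` set to
#'   `original width / size`.
#' @export
to_analysis_resolution <- function(img, size = 600L) {
  stopifnot(inherits(img, "fundus_image"))
  if (img$width == size && img$height == size && img$scale_factor == 1)
    return(img)
  px <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) {
    e <- EBImage::resize(as_eb(img$pixels[, , ch]), w = size, h = size)
    px[, , ch] <- from_eb(e)
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  fundus_image(px, scale_factor = img$width / size)
}

#' Write a grayscale or binary raster as PNG
#'
#' @param m matrix on the 0..255 scale (or 0/1 for binary masks).
#' @param path output path.
#' @param binary if `TRUE`, values are written as 0/255.
#' @export
write_raster_png <- function(m, path, binary = FALSE) {
  v <- if (binary) (m > 0) * 1 else m / 255
  EBImage::writeImage(as_eb(v), path)
  invisible(path)
}

#' Write an RGB raster as PNG
#' @param px H x W x 3 array on the 0..255 scale.
#' @param path output path.
#' @export
write_rgb_png <- function(px, path) {
  a <- array(0, dim = c(dim(px)[2], dim(px)[1], 3L))
  for (ch in 1:3) a[, , ch] <- t(px[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

# Replicate (clamp-to-edge) padding by r pixels on every side.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# RGB (0..255) -> CIE Lab (D65 sRGB), returning H x W x 3 array with channels
# L (0..100), a, b. Uses grDevices::convertColor on the flattened pixel list.
rgb_to_lab <- function(px) {
  d <- dim(px)
  m <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  lab <- grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- cbind(as.vector(lab[, , 1]), as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  array(rgb * 255, dim = d)
}
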