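# Color-dominance-adaptive enhancement. The image is classified as
# red-dominant or chromatic from the variance of its blue channel; CLAHE is
# applied in Lab space to the a* (red-green) or b* (blue-yellow) channel
# accordingly, then to the green channel, followed by edge-preserving bilateral
# smoothing and a linear contrast stretch to the full 0..255 range.

#' Classify color dominance from the blue-channel variance
#'
#' A low blue-channel variance indicates red dominance (the usual appearance of
#' fundus photographs); high variance suggests chromatic variation, e.g. from
#' exudates or hemorrhages. The decision drives which Lab channel is enhanced.
#'
#' @param img a [fundus_image()].
#' @param theta decision threshold on the variance (default 1500, squared
#'   intensity units on the 0..255 scale).
#' @return A list of class `dominance_report`: `blue_variance`, `mean_blue`,
#'   `threshold`, and `dominance` (`"red_dominant"` or `"chromatic"`).
#' @export
blue_channel_variance <- function(img, theta = 1500) {
  stopifnot(inherits(img, "fundus_image"))
  B <- img$pixels[, , 3]
  mu <- mean(B)
  v <- mean((B - mu)^2)
  structure(
    list(blue_variance = v, mean_blue = mu, threshold = theta,
         dominance = if (v <= theta) "red_dominant" else "chromatic"),
    class = "dominance_report"
  )
}

#' @export
print.dominance_report <- function(x, ...) {
  cat(sprintf("<dominance_report> sigma^2 = %.1f (theta = %g) -> %s\n",
              x$blue_variance, x$threshold, x$dominance))
  invisible(x)
}

# CLAHE on a 0..1 matrix via EBImage; pads to a multiple of the tile grid
# because EBImage::clahe requires it.
clahe01 <- function(m01, tiles = 8L, clip = 2) {
  d <- dim(m01)
  ny <- as.integer(ceiling(d[1] / tiles) * tiles)
  nx <- as.integer(ceiling(d[2] / tiles) * tiles)
  if (ny != d[1] || nx != d[2]) {
    pad <- matrix(0, ny, nx)
    pad[1:d[1], 1:d[2]] <- m01
    # replicate edges into the pad strip
    if (ny > d[1]) pad[(d[1] + 1):ny, 1:d[2]] <- matrix(m01[d[1], ], ny - d[1], d[2], byrow = TRUE)
    if (nx > d[2]) pad[, (d[2] + 1):nx] <- pad[, d[2]]
    m01 <- pad
  }
  out <- from_eb(EBImage::clahe(as_eb(m01), nx = tiles, ny = tiles, limit = clip))
  out <- out[1:d[1], 1:d[2], drop = FALSE]
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Dominance-adaptive color enhancement
#'
#' Converts to CIE Lab, applies CLAHE to the a* channel for red-dominant images
#' (b* otherwise), converts back to RGB, then applies CLAHE to the green
#' channel, which carries the best vessel/disc contrast.
#'
#' @param img a [fundus_image()] at the analysis resolution.
#' @param report the [blue_channel_variance()] report for `img`.
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid.
#' @return A [fundus_image()] with the enhanced RGB raster.
#' @export
enhance_color <- function(img, report = blue_channel_variance(img),
                          clahe_clip = 2, clahe_tiles = 8L) {
  stopifnot(inherits(img, "fundus_image"), inherits(report, "dominance_report"))
  lab <- rgb_to_lab(img$pixels)
  ch <- if (report$dominance == "red_dominant") 2L else 3L
  # a*/b* nominally span about -128..127; fixed 8-bit-style affine mapping
  m01 <- (lab[, , ch] + 128) / 255
  m01[m01 < 0] <- 0; m01[m01 > 1] <- 1
  lab[, , ch] <- clahe01(m01, clahe_tiles, clahe_clip) * 255 - 128
  rgb <- lab_to_rgb(lab)
  rgb[, , 2] <- clahe01(rgb[, , 2] / 255, clahe_tiles, clahe_clip) * 255
  fundus_image(rgb, scale_factor = img$scale_factor)
}

#' Bilateral filter (edge-preserving smoothing)
#'
#' @param m grayscale matrix on the 0..255 scale.
#' @param d window diameter in pixels (odd).
#' @param sigma_range range sigma in gray levels.
#' @param sigma_space spatial sigma in pixels.
#' @return Filtered matrix, same dimensions.
#' @export
bilateral_filter <- function(m, d = 9L, sigma_range = 75, sigma_space = 75) {
  r <- (as.integer(d) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # replicate-padded copy; shifted windows are plain submatrix reads
  P <- pad_replicate(m, r)
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (dy in -r:r) for (dx in -r:r) {
    sw <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2))
    S <- P[(r + 1 + dy):(r + H + dy), (r + 1 + dx):(r + W + dx)]
    w <- sw * exp(-(S - m)^2 / (2 * sigma_range^2))
    num <- num + w * S
    den <- den + w
  }
  num / den
}

#' Contrast normalization by linear stretch
#'
#' Applies a bilateral filter, then the linear transform
#' `I_enhanced = alpha * I_filtered + beta` with
#' `alpha = 255 / (Gray_max - Gray_min)` and `beta = -Gray_min * alpha`, so the
#' filtered image's range maps onto the full 0..255 scale. A flat image is
#' returned unchanged with a warning.
#'
#' @param green_enhanced grayscale matrix (0..255), typically the CLAHE-treated
#'   green channel.
#' @param d,sigma_range,sigma_space bilateral filter parameters.
#' @return A list of class `enhanced_gray`: `gray_enhanced`, `alpha`, `beta`.
#' @export
normalize_contrast <- function(green_enhanced, d = 9L, sigma_range = 75,
                               sigma_space = 75) {
  stopifnot(is.matrix(green_enhanced))
  f <- bilateral_filter(green_enhanced, d, sigma_range, sigma_space)
  lo <- min(f); hi <- max(f)
  if (hi - lo < .Machine$double.eps * 255) {
    warning("flat image: contrast stretch skipped")
    return(structure(list(gray_enhanced = f, alpha = 1, beta = 0),
                     class = "enhanced_gray"))
  }
  alpha <- 255 / (hi - lo)
  beta <- -lo * alpha
  g <- alpha * f + beta
  g[g < 0] <- 0; g[g > 255] <- 255
  structure(list(gray_enhanced = g, alpha = alpha, beta = beta),
            class = "enhanced_gray")
}

#' Full preprocessing stage
#'
#' Resamples to the analysis resolution and chains [blue_channel_variance()],
#' [enhance_color()] and [normalize_contrast()].
#'
#' @param img a [fundus_image()].
#' @param cfg an [od_config()].
#' @return A list of class `od_preprocessed`: `rgb_enhanced` (a
#'   [fundus_image()]), `gray_enhanced` (matrix), `alpha`, `beta`, `report`,
#'   and `input` (the analysis-resolution input image).
#' @export
preprocess_image <- function(img, cfg = od_config()) {
  img <- to_analysis_resolution(img, cfg$analysis_size)
  rep <- blue_channel_variance(img, cfg$theta)
  enh <- enhance_color(img, rep, cfg$clahe_clip, cfg$clahe_tiles)
  nc <- normalize_contrast(enh$pixels[, , 2], cfg$bilateral_d,
                           cfg$bilateral_sigma_range, cfg$bilateral_sigma_space)
  structure(
    list(rgb_enhanced = enh, gray_enhanced = nc$gray_enhanced,
         alpha = nc$alpha, beta = nc$beta, report = rep, input = img),
    class = "od_preprocessed"
  )
}
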