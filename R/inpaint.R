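# PDE-based vessel removal.
#
# Vessel pixels (a dilated binary mask D) are treated as missing and filled by
# evolving the heat equation with a data-fidelity term on the known region:
#   du/dt = lambda * Laplacian(u) + chi_{Omega \ D} (f - u),  u(0) = f,
# with homogeneous Neumann boundaries, solved by explicit finite differences
# until the sup-norm update falls below a tolerance. The inpainted red and
# blue channels are then recombined as I_w = 0.7 R + 0.3 B (the green channel
# is discarded to suppress residual vessel artifacts); I_w is the Chan-Vese
# input.

#' Inpaint one channel over a vessel mask
#'
#' @param f grayscale matrix (0..255), the known image.
#' @param mask binary matrix, 1 = vessel pixel to be filled.
#' @param lambda diffusion-rate coefficient.
#' @param dt explicit time step; must satisfy `dt <= 1/(4 * lambda + 1)` (unit
#'   grid spacing) or an error is raised.
#' @param eps_stop sup-norm convergence tolerance in gray levels.
#' @param max_steps iteration cap.
#' @return A list of class `od_inpaint`: `u` (inpainted matrix), `steps`,
#'   `converged`, `max_change`.
#' @export
inpaint_channel <- function(f, mask, lambda = 0.2, dt = 0.2,
                            eps_stop = 1e-3, max_steps = 5000L) {
  stopifnot(is.matrix(f), is.matrix(mask))
  if (!identical(dim(f), dim(mask)))
    stop("mask and image dimensions differ", call. = FALSE)
  dt_stable <- 1 / (4 * lambda + 1)
  if (dt > dt_stable + 1e-12)
    stop(sprintf("dt = %g exceeds the stability bound 1/(4*lambda + 1) = %g",
                 dt, dt_stable), call. = FALSE)
  chi <- 1 - (mask > 0) * 1
  res <- inpaint_cpp(f, chi, lambda, dt, eps_stop, as.integer(max_steps))
  structure(res, class = "od_inpaint")
}

#' Remove vessels from a fundus image by inpainting
#'
#' Dilates the vessel mask and inpaints the red and blue channels
#' independently (green is discarded downstream). Set `channels = 1:3` to also
#' inpaint green for full-RGB debug output.
#'
#' @param img a [fundus_image()] at the analysis resolution.
#' @param mask binary vessel mask from [segment_vessels()].
#' @param cfg an [od_config()].
#' @param channels channel indices to inpaint (default red and blue).
#' @return A [fundus_image()] with inpainted channels; attribute `steps`
#'   records per-channel iteration counts.
#' @export
remove_vessels <- function(img, mask, cfg = od_config(), channels = c(1L, 3L)) {
  stopifnot(inherits(img, "fundus_image"))
  dil <- dilate_mask(mask, cfg$vessel_dilate)
  px <- img$pixels
  steps <- integer(0)
  for (ch in channels) {
    r <- inpaint_channel(px[, , ch], dil, cfg$lambda, cfg$dt,
                         cfg$eps_stop, cfg$max_steps)
    px[, , ch] <- r$u
    steps[as.character(ch)] <- r$steps
  }
  px[px < 0] <- 0; px[px > 255] <- 255
  out <- fundus_image(px, scale_factor = img$scale_factor)
  attr(out, "steps") <- steps
  out
}

# Binary dilation with a disc brush of the given radius.
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return((mask > 0) * 1)
  size <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  (from_eb(EBImage::dilate(as_eb((mask > 0) * 1), brush)) > 0) * 1
}

#' Recombine inpainted channels into the segmentation input
#'
#' `I_w = 0.7 * I_R + 0.3 * I_B`; the green channel is discarded.
#'
#' @param img an inpainted [fundus_image()].
#' @return Grayscale matrix `I_w` (0..255).
#' @export
recombine_channels <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  0.7 * img$pixels[, , 1] + 0.3 * img$pixels[, , 3]
}
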