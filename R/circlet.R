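# Fast Circlet Transform (FCT).
#
# The transform decomposes an image into ring-shaped components parameterized
# by a target radius r_m and a radial-frequency scale j. A bank of N compactly
# supported raised-cosine windows H_j partitions the normalized radial
# frequency axis (Nyquist radius -> 1) so that sum_j H_j(xi)^2 = 1 — a tight
# frame, hence perfect reconstruction. Each window is lifted to 2-D by the
# phase factor exp(i 2 pi f_r r_m) (f_r in cycles/pixel), which turns a
# circular edge of radius r_m into a coefficient-magnitude peak at its center
# after FFT filtering.

#' Radial frequency window of the circlet bank
#'
#' Window `j` of an `N`-filter bank is a raised cosine centered at
#' `xi_j = (j - 1) / (N - 1)` with support `|xi - xi_j| <= 1/(N - 1)`:
#' `H_j(xi) = cos(pi (N - 1) (xi - xi_j) / 2)`. Adjacent windows overlap so
#' that `sum_j H_j^2 = 1` everywhere on the covered band \[0, 1\] (partition of
#' unity). The top window (`j = N`) stays at 1 beyond `xi = 1` so the bank
#' remains tight on discrete frequency grids whose corners exceed the Nyquist
#' radius.
#'
#' @param j scale index, 1..N.
#' @param N number of filters (>= 2).
#' @param xi numeric vector of normalized radial frequencies (>= 0).
#' @return Window samples `H_j(xi)`, same length as `xi`.
#' @export
circlet_window <- function(j, N, xi) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (j < 1 || j > N) stop("j must lie in 1..N", call. = FALSE)
  xi_j <- (j - 1) / (N - 1)
  h <- numeric(length(xi))
  inside <- abs(xi - xi_j) <= 1 / (N - 1)
  h[inside] <- cos(pi * (N - 1) * (xi[inside] - xi_j) / 2)
  if (j == N) h[xi > 1] <- 1
  h
}

#' 2-D circlet filter in the frequency domain
#'
#' `K_j(xi1, xi2) = exp(i 2 pi f_r r_m) * H_j(|xi|)` on the FFT frequency grid
#' of an `H x W` image, where `f_r` is the radial frequency in cycles/pixel and
#' `|xi| = f_r / 0.5` normalizes the Nyquist radius to 1. `|K_j| = H_j(|xi|)`
#' pointwise, so the bank inherits the partition of unity.
#'
#' @param j scale index.
#' @param r_m target circle radius in pixels (>= 0).
#' @param dims image dimensions `c(H, W)`.
#' @param N number of filters.
#' @return Complex `H x W` matrix in FFT layout (DC at `[1, 1]`).
#' @export
circlet_filter <- function(j, r_m, dims, N = 5L) {
  if (r_m < 0) stop("r_m must be >= 0", call. = FALSE)
  H <- dims[1]; W <- dims[2]
  fy <- fft_freq(H); fx <- fft_freq(W)
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  xi <- fr / 0.5
  h <- matrix(circlet_window(j, N, as.vector(xi)), H, W)
  exp(2i * pi * fr * r_m) * h
}

# FFT sample frequencies in cycles/pixel for length n (DC first).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Circlet coefficients of a grayscale image
#'
#' `c = FFT^{-1}(FFT(g) * K_j)` for one `(r_m, j)` pair; linear in `g`.
#'
#' @param gray grayscale matrix (analysis resolution).
#' @param r_m target radius in pixels.
#' @param j scale index (the pipeline uses j = 2).
#' @param N number of filters in the bank.
#' @return A list of class `coefficient_map`: `radius`, `scale`, `coeffs`
#'   (complex matrix) and `magnitude` (`|c|`, same dimensions as `gray`).
#' @export
circlet_coefficients <- function(gray, r_m, j = 2L, N = 5L) {
  stopifnot(is.matrix(gray))
  K <- circlet_filter(j, r_m, dim(gray), N)
  cc <- fft(fft(gray) * K, inverse = TRUE) / length(gray)
  structure(
    list(radius = r_m, scale = j, coeffs = cc, magnitude = Mod(cc)),
    class = "coefficient_map"
  )
}

#' Patch grid over the analysis field
#'
#' The 600 x 600 analysis field is tiled by 100 non-overlapping 60 x 60
#' patches, indexed 1..100 in row-major order (top-left patch first).
#'
#' @param size field side length in pixels.
#' @param patch_size patch side length in pixels; must divide `size`.
#' @return A tibble with one row per patch: `patch`, `row`, `col`, and 1-based
#'   inclusive pixel bounds `y0`, `y1`, `x0`, `x1`.
#' @export
patch_grid <- function(size = 600L, patch_size = 60L) {
  if (size %% patch_size != 0)
    stop("patch_size must divide the field size", call. = FALSE)
  k <- size %/% patch_size
  g <- expand.grid(col = 1:k, row = 1:k)   # col varies fastest -> row-major
  tibble::tibble(
    patch = seq_len(k * k),
    row = g$row, col = g$col,
    y0 = (g$row - 1L) * patch_size + 1L, y1 = g$row * patch_size,
    x0 = (g$col - 1L) * patch_size + 1L, x1 = g$col * patch_size
  )
}

#' Per-patch maximum circlet coefficient magnitudes
#'
#' For each patch the maximum of `|c|` is taken separately for the two target
#' radii, giving the structural feature pair
#' (`Max_Coeff^(10)`, `Max_Coeff^(20)`) per patch.
#'
#' @param map_r10,map_r20 [circlet_coefficients()] maps at radii 10 and 20.
#' @param grid a [patch_grid()] matching the map dimensions.
#' @return A tibble: `patch`, `max_coeff_r10`, `max_coeff_r20`.
#' @export
patch_max_coefficients <- function(map_r10, map_r20, grid = patch_grid()) {
  stopifnot(inherits(map_r10, "coefficient_map"),
            inherits(map_r20, "coefficient_map"))
  if (!identical(dim(map_r10$magnitude), dim(map_r20$magnitude)))
    stop("coefficient maps must share dimensions", call. = FALSE)
  if (max(grid$y1) != nrow(map_r10$magnitude) ||
      max(grid$x1) != ncol(map_r10$magnitude))
    stop("patch grid does not match map dimensions", call. = FALSE)
  patch_max <- function(m) {
    vapply(seq_len(nrow(grid)), function(i)
      max(m[grid$y0[i]:grid$y1[i], grid$x0[i]:grid$x1[i]]), numeric(1))
  }
  tibble::tibble(
    patch = grid$patch,
    max_coeff_r10 = patch_max(map_r10$magnitude),
    max_coeff_r20 = patch_max(map_r20$magnitude)
  )
}

#' Circlet features of a preprocessed image
#'
#' Convenience wrapper computing the two coefficient maps (radii from `cfg`,
#' scale `cfg$scale_j`) and their per-patch maxima.
#'
#' @param gray grayscale analysis-resolution matrix (`gray_enhanced`).
#' @param cfg an [od_config()].
#' @return A tibble as from [patch_max_coefficients()].
#' @export
circlet_features <- function(gray, cfg = od_config()) {
  m1 <- circlet_coefficients(gray, cfg$radii[1], cfg$scale_j, cfg$n_filters)
  m2 <- circlet_coefficients(gray, cfg$radii[2], cfg$scale_j, cfg$n_filters)
  patch_max_coefficients(m1, m2, patch_grid(nrow(gray), cfg$patch_size))
}
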