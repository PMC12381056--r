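# Seeded synthetic fundus phantom.
#
# The phantom emulates the anatomy the pipeline exploits: a reddish-orange
# background with a smooth illumination gradient, a bright yellowish
# elliptical disc containing a brighter inner cup whose radius matches the
# circlet target radii (10-20 px), and a dark thin vessel tree whose branches
# converge at the disc center. Exact ground truth (center, disc mask, vessel
# mask) is returned, so every stage is testable without downloading fundus
# datasets. Chromatic variants add a strong blue-yellow shading ramp so the
# blue-channel variance falls on both sides of the dominance threshold across
# a suite.

#' Phantom specification
#'
#' @param seed RNG seed (the phantom is bit-identical for a fixed spec).
#' @param size output side length in pixels.
#' @param disc_center `c(x, y)` in pixels.
#' @param disc_radius mean disc radius in pixels.
#' @param cup_radius inner cup radius in pixels (must be < `disc_radius`).
#' @param n_vessel_branches number of vessel branches.
#' @param vessel_width vessel thickness in pixels.
#' @param noise_sigma additive Gaussian noise sd, gray levels.
#' @param illumination_gradient maximum relative shading of the background.
#' @param chromatic add a strong blue-yellow ramp (pushes the blue-channel
#'   variance above the red-dominance threshold).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size = 600L, disc_center = c(300, 300),
                         disc_radius = 55, cup_radius = 18,
                         n_vessel_branches = 6L, vessel_width = 3L,
                         noise_sigma = 8, illumination_gradient = 0.15,
                         chromatic = FALSE) {
  if (cup_radius >= disc_radius)
    stop("cup_radius must be smaller than disc_radius", call. = FALSE)
  margin <- disc_radius * 1.15 + 2
  if (disc_center[1] - margin < 1 || disc_center[1] + margin > size ||
      disc_center[2] - margin < 1 || disc_center[2] + margin > size)
    stop("disc must lie fully inside the image", call. = FALSE)
  structure(
    list(seed = as.integer(seed), size = as.integer(size),
         disc_center = disc_center, disc_radius = disc_radius,
         cup_radius = cup_radius,
         n_vessel_branches = as.integer(n_vessel_branches),
         vessel_width = as.integer(vessel_width), noise_sigma = noise_sigma,
         illumination_gradient = illumination_gradient,
         chromatic = isTRUE(chromatic)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_truth`: `image` (a [fundus_image()]),
#'   `disc_mask`, `vessel_mask` (binary matrices), `center` (`c(x, y)`),
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  cx <- spec$disc_center[1]; cy <- spec$disc_center[2]
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)

  # background with a smooth directional illumination gradient
  base <- c(190, 90, 45)
  ang <- stats::runif(1, 0, 2 * pi)
  ramp <- ((X - n / 2) * cos(ang) + (Y - n / 2) * sin(ang)) / n  # in [-0.7, 0.7]
  shade <- 1 + spec$illumination_gradient * 2 * ramp
  px <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) px[, , ch] <- base[ch] * shade
  if (spec$chromatic) {
    ang2 <- stats::runif(1, 0, 2 * pi)
    ramp2 <- ((X - n / 2) * cos(ang2) + (Y - n / 2) * sin(ang2)) / n
    px[, , 3] <- px[, , 3] + 160 * ramp2   # blue-yellow shading
  }

  # elliptical disc with a brighter circular cup
  a <- spec$disc_radius * stats::runif(1, 0.95, 1.12)
  b <- spec$disc_radius^2 / a
  th <- stats::runif(1, 0, pi)
  dx <- X - cx; dy <- Y - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  disc_mask <- ((u / a)^2 + (v / b)^2 <= 1) * 1
  cup_mask <- (dx^2 + dy^2 <= spec$cup_radius^2) * 1
  disc_col <- c(245, 215, 130); cup_col <- c(255, 240, 170)
  for (ch in 1:3) {
    m <- px[, , ch]
    m[disc_mask > 0] <- disc_col[ch] * shade[disc_mask > 0]
    m[cup_mask > 0] <- cup_col[ch] * shade[cup_mask > 0]
    px[, , ch] <- m
  }

  # vessel tree: wobbly branches radiating from the disc center
  vessel <- matrix(0, n, n)
  angles <- stats::runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = spec$n_vessel_branches + 1)[-1] +
    stats::rnorm(spec$n_vessel_branches, 0, 0.2)
  for (aa in angles) {
    x <- cx; y <- cy; dir <- aa
    for (s in seq_len(2 * n)) {
      xi <- round(x); yi <- round(y)
      if (xi < 1 || xi > n || yi < 1 || yi > n) break
      vessel[yi, xi] <- 1
      dir <- dir + stats::rnorm(1, 0, 0.08)
      x <- x + 2 * cos(dir); y <- y + 2 * sin(dir)
    }
  }
  vessel <- dilate_mask(vessel, (spec$vessel_width - 1) / 2)
  vcol <- c(110, 35, 30)
  for (ch in 1:3) {
    m <- px[, , ch]
    m[vessel > 0] <- vcol[ch] * shade[vessel > 0]
    px[, , ch] <- m
  }

  px <- px + array(stats::rnorm(3 * n * n, 0, spec$noise_sigma), dim = dim(px))
  px[px < 0] <- 0; px[px > 255] <- 255

  structure(
    list(image = fundus_image(px), disc_mask = disc_mask,
         vessel_mask = vessel, center = c(x = cx, y = cy), spec = spec),
    class = "phantom_truth"
  )
}

#' Generate a seeded suite of phantoms
#'
#' Centers are drawn uniformly over the central two-thirds of the field
#' (clipped so the disc stays inside), radii, branch counts and eccentricities
#' are randomized, and every other phantom is chromatic so both preprocessing
#' branches are exercised. Deterministic for a fixed `base_seed`.
#'
#' @param n number of phantoms.
#' @param base_seed suite seed.
#' @param size field side length in pixels.
#' @return A list of `phantom_truth` objects.
#' @export
phantom_suite <- function(n = 20L, base_seed = 7L, size = 600L) {
  stopifnot(n >= 1)
  set.seed(base_seed)
  specs <- lapply(seq_len(n), function(i) {
    r <- stats::runif(1, 45, 65)
    margin <- r * 1.15 + 6
    lo <- max(size / 6, margin); hi <- min(5 * size / 6, size - margin)
    phantom_spec(
      seed = (base_seed + 7919L * i) %% .Machine$integer.max,
      size = size,
      disc_center = c(stats::runif(1, lo, hi), stats::runif(1, lo, hi)),
      disc_radius = r,
      cup_radius = stats::runif(1, 12, 20),
      n_vessel_branches = sample(5:8, 1),
      chromatic = i %% 2 == 0
    )
  })
  lapply(specs, generate_phantom)
}

#' Write a phantom suite to disk
#'
#' Writes `phantom_###.png`, `phantom_###_disc.png`, `phantom_###_vessels.png`
#' and a `truth.csv` (image_id, x, y, W, H) in the formats the evaluator
#' reads.
#'
#' @param phantoms list from [phantom_suite()].
#' @param dir output directory (created if needed).
#' @return The truth tibble, invisibly.
#' @export
write_phantom_suite <- function(phantoms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(phantoms, function(ph, i) {
    id <- sprintf("phantom_%03d", i)
    write_rgb_png(ph$image$pixels, file.path(dir, paste0(id, ".png")))
    write_raster_png(ph$disc_mask, file.path(dir, paste0(id, "_disc.png")),
                     binary = TRUE)
    write_raster_png(ph$vessel_mask, file.path(dir, paste0(id, "_vessels.png")),
                     binary = TRUE)
    tibble::tibble(image_id = id, x = ph$center[1], y = ph$center[2],
                   W = ph$image$width, H = ph$image$height)
  })
  truth <- dplyr::bind_rows(rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
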