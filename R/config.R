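#' Pipeline configuration
#'
#' Collects every tunable parameter of the localization/segmentation pipeline
#' with its default. Defaults reproduce the method's stated constants
#' (blue-variance threshold 1500, K = 3 clusters, circlet radii 10 and 20 px at
#' scale j = 2, 60 x 60 patches on a 600 x 600 field, 0.7/0.3 red/blue
#' recombination); the remaining values are the package's documented choices.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `od_config`.
#' @examples
#' cfg <- od_config(adaptive = FALSE)
#' cfg$theta
#' @export
od_config <- function(...) {
  cfg <- list(
    # preprocessing
    theta = 1500,            # blue-variance threshold for color dominance
    analysis_size = 600L,    # analysis field side (10 x 10 grid of 60 px tiles)
    clahe_clip = 2,          # CLAHE clip limit
    clahe_tiles = 8L,        # CLAHE tile grid (8 x 8)
    bilateral_d = 9L,        # bilateral filter window diameter (px)
    bilateral_sigma_range = 75,   # range sigma, gray levels
    bilateral_sigma_space = 75,   # spatial sigma, px
    # circlet transform
    n_filters = 5L,          # number of radial frequency windows N
    scale_j = 2L,            # scale consumed by the patch features
    radii = c(10, 20),       # target circle radii, px (optic-cup scale)
    patch_size = 60L,        # patch side, px
    # vessel segmentation
    vessel_denoise_sigma = 1.5, # Gaussian denoise before CLAHE (px)
    vessel_avg_window = 9L,  # background-subtraction average filter (px)
    vessel_min_area = 100L,  # minimum connected component, px at 600 x 600
    vessel_dilate = 2L,      # mask dilation radius for inpainting, px
    # feature fusion
    K = 3L,                  # MWK-means cluster count
    gamma_candidates = c(1.5, 2, 2.5, 3),
    mwk_max_iter = 100L,
    mwk_tol = 1e-6,
    adaptive = TRUE,         # MWK-learned weights vs uniform 1/3
    # PDE inpainting
    lambda = 0.2,            # diffusion rate
    dt = 0.5,                # explicit time step (must be <= 1/(4*lambda + 1))
    eps_stop = 1e-3,         # sup-norm convergence tolerance, gray levels
    max_steps = 5000L,
    # Chan-Vese
    cv_mu = 0.2 * 255^2,     # contour length weight
    cv_lambda1 = 1, cv_lambda2 = 1,
    cv_eps = 1,              # Heaviside regularization width
    cv_dt = 2,               # gradient-descent step
    cv_r0 = 60,              # initial contour radius, px at 600 x 600
    cv_max_iter = 2000L,
    cv_tol_pixels = 2L,      # zero-set change tolerance (pixels)
    cv_patience = 2L,        # consecutive stable cycles required
    cv_reinit_every = 100L,  # signed-distance reinitialization period
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("od_config", "list"))
}

#' Read/write a pipeline configuration as YAML
#' @param cfg an [od_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(od_config, yaml::read_yaml(path))
}
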