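# Shared fixtures built in code.

# Solid RGB image of one color.
flat_rgb <- function(h = 64, w = 64, rgb = c(128, 128, 128)) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  fundus_image(px)
}

# Grayscale raster with a drawn annulus (circle outline).
annulus_raster <- function(n, center, radius, thickness = 1.2, fg = 255, bg = 0) {
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  d <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  m <- matrix(bg, n, n)
  m[abs(d - radius) < thickness] <- fg
  m
}

# Binary filled disc raster.
disc_raster <- function(n, center, radius) {
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  ((X - center[1])^2 + (Y - center[2])^2 <= radius^2) * 1
}

# Three well-separated Gaussian blobs in M dimensions; returns list(Y, labels).
blob_data <- function(n_per = 10, M = 3, centers = rbind(rep(0, M), rep(5, M), rep(10, M)),
                      sd = 0.3, seed = 42) {
  set.seed(seed)
  Y <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(stats::rnorm(n_per * M, mean = rep(centers[k, ], each = n_per), sd = sd),
           n_per, M)))
  list(Y = Y, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Three separated clusters whose within-cluster dispersion is identical in
# every feature by construction (permutation-symmetric offsets).
symmetric_clusters <- function(d = 0.5) {
  offs <- rbind(c(d, 0, 0), c(0, d, 0), c(0, 0, d),
                c(-d, 0, 0), c(0, -d, 0), c(0, 0, -d))
  centers <- rbind(rep(0, 3), rep(5, 3), rep(10, 3))
  do.call(rbind, lapply(1:3, function(k)
    sweep(offs, 2, centers[k, ], "+")))
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
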