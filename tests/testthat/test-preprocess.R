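test_that("blue-channel variance matches the two-pass oracle and hand values", {
  # uniform blue channel: zero variance, red-dominant
  rep0 <- blue_channel_variance(flat_rgb(64, 64, c(10, 20, 128)))
  expect_equal(rep0$blue_variance, 0)
  expect_identical(rep0$dominance, "red_dominant")

  # hand-evaluated 2x1 case: B = {0, 255}
  px <- array(0, dim = c(60, 60, 3))  # min size 60; embed the 2-value pattern
  px[, , 3] <- matrix(c(0, 255), 60, 60)
  img <- fundus_image(px)
  expect_equal(blue_channel_variance(img)$blue_variance, 16256.25)
  expect_identical(blue_channel_variance(img)$dominance, "chromatic")

  # brute-force two-pass oracle on random rasters
  set.seed(11)
  for (i in 1:5) {
    px <- array(stats::runif(60 * 60 * 3, 0, 255), dim = c(60, 60, 3))
    img <- fundus_image(px)
    B <- px[, , 3]
    mu <- sum(B) / length(B)
    oracle <- sum((B - mu)^2) / length(B)
    expect_equal(blue_channel_variance(img)$blue_variance, oracle, tolerance = 1e-9)
  }
})

test_that("dominance threshold and R/G-permutation invariance", {
  set.seed(3)
  px <- array(stats::runif(60 * 60 * 3, 0, 255), dim = c(60, 60, 3))
  img <- fundus_image(px)
  rep1 <- blue_channel_variance(img)
  # permuting R and G must not change the decision (depends only on B)
  px2 <- px[, , c(2, 1, 3)]
  rep2 <- blue_channel_variance(fundus_image(px2))
  expect_equal(rep1$blue_variance, rep2$blue_variance)
  expect_identical(rep1$dominance, rep2$dominance)
  # decision rule: sigma^2 <= theta -> red_dominant
  expect_identical(blue_channel_variance(img, theta = rep1$blue_variance)$dominance,
                   "red_dominant")
  expect_identical(blue_channel_variance(img, theta = rep1$blue_variance - 1)$dominance,
                   "chromatic")
})

test_that("enhance_color selects the a* channel for red-dominant images", {
  set.seed(5)
  px <- array(stats::runif(64 * 64 * 3, 60, 200), dim = c(64, 64, 3))
  img <- fundus_image(px)
  rep_red <- structure(list(blue_variance = 0, mean_blue = 0, threshold = 1500,
                            dominance = "red_dominant"), class = "dominance_report")
  rep_chr <- structure(list(blue_variance = 9000, mean_blue = 0, threshold = 1500,
                            dominance = "chromatic"), class = "dominance_report")
  out_red <- enhance_color(img, rep_red)
  out_chr <- enhance_color(img, rep_chr)
  expect_s3_class(out_red, "fundus_image")
  # the two branches modify different Lab channels, so outputs differ
  expect_gt(max(abs(out_red$pixels - out_chr$pixels)), 1)
  # flat input stays (near-)flat: CLAHE cannot invent contrast on flat tiles
  flat <- flat_rgb(64, 64, c(120, 110, 100))
  out_flat <- enhance_color(flat, blue_channel_variance(flat))
  expect_lt(stats::sd(out_flat$pixels[, , 2]), 2)
})

test_that("contrast stretch maps the filtered range onto [0, 255] monotonically", {
  # d = 1 makes the bilateral filter the identity, exposing the bare stretch
  m <- matrix(seq(50, 100, length.out = 100), 10, 10)
  out <- normalize_contrast(m, d = 1L)
  expect_equal(out$alpha, 255 / 50)  # = 5.1
  expect_equal(out$beta, -50 * 255 / 50)  # = -255
  expect_equal(min(out$gray_enhanced), 0)
  expect_equal(max(out$gray_enhanced), 255)
  expect_equal(out$gray_enhanced[m == 100][1], 255)
  # monotone: pixel ordering preserved
  o <- order(as.vector(m))
  expect_true(all(diff(as.vector(out$gray_enhanced)[o]) >= 0))
  # flat input: warn and pass through
  expect_warning(res <- normalize_contrast(matrix(7, 8, 8), d = 1L), "flat")
  expect_equal(res$gray_enhanced, matrix(7, 8, 8))
})

test_that("full-range inputs give identity stretch; output spans [0, 255]", {
  set.seed(9)
  m <- matrix(stats::runif(400, 0, 255), 20, 20)
  m[1] <- 0; m[400] <- 255
  out <- normalize_contrast(m, d = 1L)
  expect_equal(out$alpha, 1)
  expect_equal(out$beta, 0)
  # any non-flat input spans the full range after the stretch
  out2 <- normalize_contrast(matrix(stats::runif(400, 80, 90), 20, 20), d = 5L)
  expect_equal(range(out2$gray_enhanced), c(0, 255))
})
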