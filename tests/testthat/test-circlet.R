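test_that("window bank: centers, partition of unity, adjacent complementarity", {
  expect_equal(circlet_window(1, 5, 0), 1)  # center frequency xi_1 = 0
  for (N in c(2, 5, 8)) {
    xi <- seq(0, 1, length.out = 10001)
    s <- Reduce(`+`, lapply(1:N, function(j) circlet_window(j, N, xi)^2))
    expect_lt(max(abs(s - 1)), 1e-9)
  }
  # midpoint between adjacent centers: each window contributes 1/2
  N <- 5
  mid <- (0 + 1 / (N - 1)) / 2
  expect_equal(circlet_window(1, N, mid)^2, 0.5, tolerance = 1e-12)
  expect_equal(circlet_window(2, N, mid)^2, 0.5, tolerance = 1e-12)
  expect_error(circlet_window(1, 1, 0.5), "N must be")
})

test_that("2-D filters: modulus equals the window, tight frame, r = 0 real", {
  dims <- c(64, 64)
  K0 <- circlet_filter(2, 0, dims, 5)
  expect_equal(max(abs(Im(K0))), 0)  # zero phase at r_m = 0
  K <- circlet_filter(2, 20, dims, 5)
  fy <- circletOD:::fft_freq(64); fx <- circletOD:::fft_freq(64)
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  expect_equal(Mod(K), matrix(circlet_window(2, 5, as.vector(fr / 0.5)), 64, 64),
               tolerance = 1e-12)
  s2 <- Reduce(`+`, lapply(1:5, function(j) Mod(circlet_filter(j, 20, dims, 5))^2))
  expect_lt(max(abs(s2 - 1)), 1e-9)
})

test_that("coefficients are linear and conserve energy (tight frame)", {
  expect_equal(circlet_coefficients(matrix(0, 32, 32), 10, 2, 5)$magnitude,
               matrix(0, 32, 32))
  set.seed(21)
  g1 <- matrix(stats::rnorm(64^2), 64)
  g2 <- matrix(stats::rnorm(64^2), 64)
  c1 <- circlet_coefficients(g1, 10, 2, 5)$coeffs
  c2 <- circlet_coefficients(g2, 10, 2, 5)$coeffs
  c12 <- circlet_coefficients(g1 + g2, 10, 2, 5)$coeffs
  expect_lt(max(Mod(c12 - c1 - c2)), 1e-8)
  # Parseval across the bank
  en <- sum(vapply(1:5, function(j)
    sum(Mod(circlet_coefficients(g1, 7, j, 5)$coeffs)^2), numeric(1)))
  expect_equal(en, sum(g1^2), tolerance = 1e-6)
})

test_that("a drawn annulus produces a coefficient peak at its center", {
  set.seed(33)
  for (i in 1:20) {
    r <- sample(c(10, 20), 1)
    ctr <- round(stats::runif(2, 150, 450))
    g <- annulus_raster(600, ctr, r)
    cm <- circlet_coefficients(g, r, 2, 5)
    ij <- which(cm$magnitude == max(cm$magnitude), arr.ind = TRUE)[1, ]
    expect_lt(sqrt((ij[2] - ctr[1])^2 + (ij[1] - ctr[2])^2), 3)
  }
})

test_that("patch grid tiles the field exactly with 100 disjoint 60x60 tiles", {
  g <- patch_grid(600, 60)
  expect_equal(nrow(g), 100)
  expect_true(all(g$x1 - g$x0 == 59) && all(g$y1 - g$y0 == 59))
  cover <- matrix(0, 600, 600)
  for (i in seq_len(nrow(g))) {
    cover[g$y0[i]:g$y1[i], g$x0[i]:g$x1[i]] <-
      cover[g$y0[i]:g$y1[i], g$x0[i]:g$x1[i]] + 1
  }
  expect_true(all(cover == 1))  # exact tiling, no overlap
  # row-major indexing: patch 1 top-left, patch 11 starts second row
  expect_equal(unlist(g[g$patch == 1, c("x0", "y0")], use.names = FALSE), c(1, 1))
  expect_equal(unlist(g[g$patch == 11, c("x0", "y0")], use.names = FALSE), c(1, 61))
  expect_error(patch_grid(600, 70), "divide")
})

test_that("patch maxima equal a nested-loop brute-force oracle", {
  g <- patch_grid(600, 60)
  zero <- structure(list(radius = 10, scale = 2, coeffs = NULL,
                         magnitude = matrix(0, 600, 600)), class = "coefficient_map")
  f0 <- patch_max_coefficients(zero, zero, g)
  expect_true(all(f0$max_coeff_r10 == 0) && all(f0$max_coeff_r20 == 0))

  # single impulse at (5, 5) only lights patch 1 at r = 10
  imp <- zero; imp$magnitude[5, 5] <- 3
  f1 <- patch_max_coefficients(imp, zero, g)
  expect_equal(which(f1$max_coeff_r10 > 0), 1L)

  set.seed(8)
  m10 <- matrix(stats::runif(600^2), 600)
  m20 <- matrix(stats::runif(600^2), 600)
  a <- structure(list(radius = 10, scale = 2, magnitude = m10), class = "coefficient_map")
  b <- structure(list(radius = 20, scale = 2, magnitude = m20), class = "coefficient_map")
  f <- patch_max_coefficients(a, b, g)
  for (i in c(1, 37, 100)) {
    ys <- g$y0[i]:g$y1[i]; xs <- g$x0[i]:g$x1[i]
    mx <- -Inf
    for (y in ys) for (x in xs) mx <- max(mx, m10[y, x])
    expect_identical(f$max_coeff_r10[i], mx)
  }
  expect_equal(nrow(f), 100)
})
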