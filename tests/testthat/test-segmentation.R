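test_that("regularized Heaviside and Dirac closed forms", {
  expect_equal(heaviside_eps(0, 1), 0.5)
  expect_equal(heaviside_eps(0, 0.3), 0.5)
  expect_equal(dirac_eps(0, 1), 1 / pi)
  t <- seq(-5, 5, by = 0.25)
  expect_equal(heaviside_eps(t) + heaviside_eps(-t), rep(1, length(t)))
  expect_true(all(diff(heaviside_eps(t)) > 0))
  expect_error(heaviside_eps(0, 0), "eps")
  expect_error(dirac_eps(0, -1), "eps")
})

test_that("level-set initialization is a signed distance to the seed circle", {
  phi <- initialize_levelset(c(200, 200), c(100, 100), 40)
  expect_equal(phi[100, 100], 40)          # phi(center) = r0
  expect_equal(phi[100, 140], 0)           # on the circle
  expect_gt(phi[100, 100], 0)              # interior positive
  expect_lt(phi[1, 1], 0)                  # far corner negative
  expect_error(initialize_levelset(c(200, 200), c(300, 100), 40), "inside")
  expect_message(initialize_levelset(c(200, 200), c(10, 10), 40), "clipped")
})

test_that("converged region means match the two true region means within 1%", {
  n <- 200
  tr <- disc_raster(n, c(100, 100), 45)
  a <- 180; b <- 60
  I <- b + (a - b) * tr
  phi0 <- initialize_levelset(c(n, n), c(100, 100), 50)
  ls <- chan_vese_evolve(I, phi0)
  expect_true(ls$converged)
  expect_lt(abs(ls$alpha1 - a), 0.01 * abs(a - b))
  expect_lt(abs(ls$alpha2 - b), 0.01 * abs(a - b))
})

test_that("noise-free disc is segmented with Dice >= 0.98", {
  n <- 300
  tr <- disc_raster(n, c(150, 150), 55)
  I <- 100 + 100 * tr
  phi0 <- initialize_levelset(c(n, n), c(150, 150), 60)
  ls <- chan_vese_evolve(I, phi0)
  m <- extract_od_mask(ls)
  expect_gte(dice(m$mask, tr), 0.98)
})

test_that("H-weighted mean updates are exact minimizers of the fidelity energy", {
  n <- 200
  I <- 60 + 120 * disc_raster(n, c(100, 100), 45)
  phi <- initialize_levelset(c(n, n), c(100, 100), 50)
  H <- heaviside_eps(phi, 1)
  a1 <- sum(I * H) / sum(H)
  fid <- function(a) sum((I - a)^2 * H)
  expect_lt(fid(a1), fid(a1 * 1.01))
  expect_lt(fid(a1), fid(a1 * 0.99))
  a2 <- sum(I * (1 - H)) / sum(1 - H)
  fid2 <- function(a) sum((I - a)^2 * (1 - H))
  expect_lt(fid2(a2), fid2(a2 * 1.01))
  expect_lt(fid2(a2), fid2(a2 * 0.99))
})

test_that("energy is non-increasing within descent chunks", {
  n <- 200
  I <- 60 + 120 * disc_raster(n, c(100, 100), 45)
  phi0 <- initialize_levelset(c(n, n), c(100, 100), 55)
  ls <- chan_vese_evolve(I, phi0, max_iter = 400L, reinit_every = 100L)
  e <- ls$energy
  rel <- diff(e) / abs(e[-length(e)])
  # reinitialization steps reset the regularized length term; exclude them
  cuts <- seq(100, length(e) - 1, by = 100)
  rel <- rel[setdiff(seq_along(rel), cuts)]
  expect_lt(max(rel), 1e-3)
})

test_that("strong length penalty excludes a small bright speck", {
  n <- 200
  tr <- disc_raster(n, c(90, 100), 40)
  speck <- disc_raster(n, c(180, 180), 3)
  I <- 60 + 140 * pmin(tr + speck, 1)
  phi0 <- initialize_levelset(c(n, n), c(100, 100), 95)  # encloses both
  ls <- chan_vese_evolve(I, phi0, mu = 3 * 255^2)
  m <- (ls$phi > 0) * 1
  expect_gt(sum(m * tr) / sum(tr), 0.8)   # disc retained
  expect_equal(sum(m * speck), 0)          # speck dropped by the length term
})

test_that("translation equivariance of the final mask", {
  n <- 220
  mk <- function(cx, cy) 70 + 110 * disc_raster(n, c(cx, cy), 38)
  seg <- function(cx, cy) {
    phi0 <- initialize_levelset(c(n, n), c(cx, cy), 45)
    extract_od_mask(chan_vese_evolve(mk(cx, cy), phi0))$mask
  }
  m1 <- seg(100, 100)
  m2 <- seg(120, 110)
  # shift m2 back by (-20, -10) and compare on the common interior
  m2s <- matrix(0, n, n)
  m2s[1:(n - 10), 1:(n - 20)] <- m2[11:n, 21:n]
  core <- 60:160
  expect_equal(m1[core, core], m2s[core, core])
})

test_that("mask extraction keeps the largest component and fills holes", {
  phi <- matrix(-1, 100, 100)
  phi[10:40, 10:40] <- 1    # area 961
  phi[60:68, 60:68] <- 1    # area 81
  phi[20:25, 20:25] <- -1   # hole inside the big component
  m <- extract_od_mask(phi)
  expect_equal(m$area, 31 * 31)  # hole filled, small component dropped
  expect_equal(sum(m$mask[60:68, 60:68]), 0)
  lab <- EBImage::bwlabel(EBImage::Image(t(m$mask)))
  expect_equal(max(lab), 1)      # single connected component
  expect_error(extract_od_mask(matrix(-1, 10, 10)), "collapsed")
})
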