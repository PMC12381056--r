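test_that("feature assembly normalizes columns to [0, 1] and keeps raw copies", {
  cf <- tibble::tibble(patch = 1:100,
                       max_coeff_r10 = c(2, 6, 4, runif(97, 2, 6)),
                       max_coeff_r20 = runif(100, 0, 50))
  ef <- tibble::tibble(patch = 1:100, vessel_fraction = runif(100),
                       entropy = runif(100))
  f <- assemble_features(cf, ef)
  expect_equal(dim(circletOD:::od_feature_matrix(f)), c(100L, 3L))
  expect_true(all(f$max_coeff_r10 >= 0 & f$max_coeff_r10 <= 1))
  expect_equal(range(f$entropy), c(0, 1))
  expect_identical(f$raw_max_coeff_r20, cf$max_coeff_r20)
  # (x - min)/(max - min): value 4 in a [2, 6] column -> 0.5
  expect_equal(f$max_coeff_r10[3], (4 - min(cf$max_coeff_r10)) /
                 diff(range(cf$max_coeff_r10)))
  # constant column maps to 0.5, deterministic on identical input
  ef2 <- ef; ef2$entropy <- rep(0.7, 100)
  f2 <- assemble_features(cf, ef2)
  expect_true(all(f2$entropy == 0.5))
  expect_identical(assemble_features(cf, ef), f)
  expect_error(assemble_features(cf[1:50, ], ef), "same patches")
})

test_that("anomalous initialization seeds each separated blob deterministically", {
  bd <- blob_data(n_per = 10)
  C1 <- anomalous_init(bd$Y, 3)
  C2 <- anomalous_init(bd$Y, 3)
  expect_identical(C1, C2)  # no random step
  # each centroid lies inside a distinct blob (nearest true center is unique)
  truth <- rbind(rep(0, 3), rep(5, 3), rep(10, 3))
  nearest <- apply(C1, 1, function(c) which.min(colSums((t(truth) - c)^2)))
  expect_setequal(nearest, 1:3)
  # K = 1: a single centroid
  expect_equal(nrow(anomalous_init(bd$Y, 1)), 1L)
  expect_error(anomalous_init(bd$Y[1:2, ], 5), "exceed")
})

test_that("MWK-means: weight normalization, symmetry, monotone objective", {
  # exactly equal per-feature dispersions -> w = (1/3, 1/3, 1/3) at gamma = 2
  fit <- mwk_means(symmetric_clusters(), K = 3, gamma = 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_equal(fit$weights, rep(1 / 3, 3), tolerance = 1e-12)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  # weights sum to 1 for arbitrary data and exponents
  set.seed(77)
  for (g in c(1.5, 2, 3)) {
    Y <- matrix(stats::runif(60), 20, 3)
    f <- mwk_means(Y, K = 3, gamma = g)
    expect_equal(sum(f$weights), 1, tolerance = 1e-12)
  }
  expect_error(mwk_means(symmetric_clusters(), K = 3, gamma = 1), "gamma")
})

test_that("MWK-means recovers separated blobs exactly (Rand index 1)", {
  bd <- blob_data(n_per = 10, sd = 0.3, seed = 5)
  fit <- mwk_means(bd$Y, K = 3, gamma = 2)
  expect_equal(rand_index(fit$cluster, bd$labels), 1.0)
  expect_true(fit$converged)
})

test_that("weight update is permutation-equivariant under feature reordering", {
  bd <- blob_data(n_per = 10, M = 3, centers = rbind(c(0, 0, 0), c(6, 2, 1), c(1, 8, 3)),
                  sd = 0.4, seed = 9)
  f1 <- mwk_means(bd$Y, K = 3, gamma = 2)
  perm <- c(3, 1, 2)
  f2 <- mwk_means(bd$Y[, perm], K = 3, gamma = 2)
  expect_equal(f2$weights, f1$weights[perm], tolerance = 1e-8)
})

test_that("tidy/glance summarize the fit", {
  bd <- blob_data()
  fit <- mwk_means(bd$Y, K = 3, gamma = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$size), 30)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$objective, fit$objective)
  expect_equal(gl$w1 + gl$w2 + gl$w3, 1, tolerance = 1e-12)
})

test_that("silhouette-based gamma selection is deterministic and sane", {
  bd <- blob_data(n_per = 8, sd = 0.4, seed = 2)
  expect_equal(select_gamma(bd$Y, candidates = 2)$gamma, 2)
  sel1 <- select_gamma(bd$Y, candidates = c(1.5, 2, 2.5, 3))
  sel2 <- select_gamma(bd$Y, candidates = c(1.5, 2, 2.5, 3))
  expect_identical(sel1$gamma, sel2$gamma)
  # the selected gamma cannot score below the worst candidate
  sil <- sel1$silhouette$mean_silhouette
  expect_gte(max(sil, na.rm = TRUE), min(sil, na.rm = TRUE))
  expect_identical(sel1$gamma, sel1$silhouette$gamma[which.max(sil)])
  expect_error(select_gamma(bd$Y, candidates = numeric(0)), "candidates")
})

test_that("patch scoring follows the weighted linear combination and argmax", {
  set.seed(31)
  cf <- tibble::tibble(patch = 1:100, max_coeff_r10 = runif(100),
                       max_coeff_r20 = runif(100))
  ef <- tibble::tibble(patch = 1:100, vessel_fraction = runif(100),
                       entropy = runif(100))
  f <- assemble_features(cf, ef)
  Z <- circletOD:::od_feature_matrix(f)
  # uniform weights: score is the mean of the three normalized features
  s <- score_patches(f)
  expect_equal(s$score, rowMeans(Z))
  # degenerate weighting reduces to a single feature
  s1 <- score_patches(f, c(1, 0, 0))
  expect_equal(attr(s1, "patch_max"), which.max(Z[, 1]))
  # exhaustive scan oracle
  w <- c(0.2, 0.5, 0.3)
  sw <- score_patches(f, w)
  best <- 1; bv <- -Inf
  for (i in 1:100) {
    v <- sum(w * Z[i, ])
    if (v > bv) { bv <- v; best <- i }
  }
  expect_equal(attr(sw, "patch_max"), best)
  expect_error(score_patches(f, c(0, 0, 0)), "zero")
})

test_that("center localization picks the brightest pixel of the winning patch", {
  g <- patch_grid(600, 60)
  gray <- matrix(0, 600, 600)
  gray[135, 250] <- 200   # inside patch row 3, col 5 -> patch 25
  f <- tibble::tibble(patch = 1:100, max_coeff_r10 = 0, max_coeff_r20 = 0,
                      entropy = 0)
  f$max_coeff_r10[25] <- 1
  feats <- assemble_features(
    tibble::tibble(patch = 1:100, max_coeff_r10 = f$max_coeff_r10,
                   max_coeff_r20 = 0),
    tibble::tibble(patch = 1:100, vessel_fraction = 0, entropy = 0))
  s <- score_patches(feats, c(1, 0, 0))
  ctr <- locate_center(s, gray, g, scale_factor = 2)
  expect_equal(c(ctr$x, ctr$y), c(250, 135))
  expect_equal(c(ctr$x_original, ctr$y_original), c(500, 270))
  b <- g[g$patch == ctr$patch_max, ]
  expect_true(ctr$x >= b$x0 && ctr$x <= b$x1 && ctr$y >= b$y0 && ctr$y <= b$y1)
})
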