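# Adaptive feature fusion.
#
# The three per-patch features (max circlet magnitude at r = 10 and r = 20,
# vessel entropy) are min-max normalized and fused by the weighted linear
# score L_i = w1 * MaxCoeff_i^(10) + w2 * MaxCoeff_i^(20) + w3 * H_i. The
# weights are either uniform (1/3 each, the non-adaptive variant) or learned
# per image by Minkowski weighted K-means (MWK-means), an unsupervised
# feature-relevance method minimizing
#   F(S, C, w) = sum_k sum_i sum_v s_ik w_v^gamma |z_iv - c_kv|^gamma,
# with the Minkowski exponent gamma selected by silhouette analysis.

#' Assemble the patch feature matrix
#'
#' Joins the circlet and entropy feature tables and min-max normalizes each
#' feature across patches so circlet magnitudes and entropies are
#' commensurable in the fusion score. A constant column maps to 0.5
#' (uninformative). Raw values are kept in `raw_*` columns.
#'
#' @param circlet_tbl tibble from [circlet_features()].
#' @param entropy_tbl tibble from [patch_entropy()].
#' @return A tibble of class `od_features`: `patch`, normalized
#'   `max_coeff_r10`, `max_coeff_r20`, `entropy`, plus `raw_*` copies.
#' @export
assemble_features <- function(circlet_tbl, entropy_tbl) {
  if (nrow(circlet_tbl) != nrow(entropy_tbl) ||
      !identical(circlet_tbl$patch, entropy_tbl$patch))
    stop("feature tables must cover the same patches", call. = FALSE)
  out <- tibble::tibble(
    patch = circlet_tbl$patch,
    max_coeff_r10 = minmax01(circlet_tbl$max_coeff_r10),
    max_coeff_r20 = minmax01(circlet_tbl$max_coeff_r20),
    entropy = minmax01(entropy_tbl$entropy),
    raw_max_coeff_r10 = circlet_tbl$max_coeff_r10,
    raw_max_coeff_r20 = circlet_tbl$max_coeff_r20,
    raw_entropy = entropy_tbl$entropy
  )
  class(out) <- c("od_features", class(out))
  out
}

minmax01 <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

od_feature_matrix <- function(features) {
  stopifnot(inherits(features, "od_features"))
  as.matrix(features[, c("max_coeff_r10", "max_coeff_r20", "entropy")])
}

#' Anomalous-pattern centroid initialization
#'
#' Deterministic K-means seeding: repeatedly take the point farthest from the
#' grand mean, grow an "anomalous" cluster around it (points closer to the
#' anomalous center than to the grand mean, center re-estimated until stable),
#' remove it, and finally keep the centers of the K largest extracted
#' clusters. No randomness is involved.
#'
#' @param Y numeric n x M matrix.
#' @param K number of centroids.
#' @return K x M matrix of initial centroids.
#' @export
anomalous_init <- function(Y, K) {
  n <- nrow(Y)
  if (K > n) stop("K cannot exceed the number of points", call. = FALSE)
  gm <- colMeans(Y)
  remaining <- seq_len(n)
  centers <- list(); sizes <- integer(0)
  while (length(remaining) > 0) {
    sub <- Y[remaining, , drop = FALSE]
    d_gm <- rowSums(sweep(sub, 2, gm)^2)
    ctr <- sub[which.max(d_gm), ]
    assigned_prev <- integer(0)
    repeat {
      d_c <- rowSums(sweep(sub, 2, ctr)^2)
      assigned <- which(d_c < rowSums(sweep(sub, 2, gm)^2))
      if (!length(assigned)) assigned <- which.max(d_gm)
      if (identical(assigned, assigned_prev)) break
      ctr <- colMeans(sub[assigned, , drop = FALSE])
      assigned_prev <- assigned
    }
    centers[[length(centers) + 1L]] <- ctr
    sizes <- c(sizes, length(assigned))
    remaining <- remaining[-assigned]
  }
  if (length(centers) < K) {
    # fall back to greedy farthest-point seeding from the grand mean
    message("anomalous init extracted fewer than K clusters; ",
            "falling back to farthest-point seeding")
    C <- matrix(gm, 1, ncol(Y))
    while (nrow(C) < K + 1L) {
      dmin <- apply(Y, 1, function(z) min(colSums((t(C) - z)^2)))
      C <- rbind(C, Y[which.max(dmin), ])
    }
    return(C[-1, , drop = FALSE])
  }
  ord <- order(sizes, decreasing = TRUE)[seq_len(K)]
  do.call(rbind, centers[ord])
}

# Weighted Minkowski distance of every row of Y to one centroid.
mwk_dist <- function(Y, ctr, w, gamma) {
  colSums(w^gamma * abs(t(Y) - ctr)^gamma)
}

#' Minkowski weighted K-means
#'
#' Alternates (i) assignment of each point to the centroid minimizing the
#' weighted Minkowski distance `sum_v w_v^gamma |z_iv - c_kv|^gamma`,
#' (ii) centroid update as per-cluster feature means, and (iii) feature-weight
#' update from the within-cluster dispersions
#' `E_v = sum_k sum_{i in k} |z_iv - c_kv|^gamma` via
#' `w_v = 1 / sum_u (E_v / E_u)^{1/(gamma - 1)}`. Initialization is the
#' deterministic [anomalous_init()]; the whole fit is deterministic.
#'
#' @param Y numeric n x M matrix (or an `od_features` tibble).
#' @param K cluster count (default 3).
#' @param gamma Minkowski exponent (> 1).
#' @param max_iter iteration cap.
#' @param tol secondary stop on the objective decrease.
#' @return An object of class `od_mwk`: `cluster` (assignments), `centroids`,
#'   `weights`, `gamma`, `dispersion` (E_v), `objective` (final F),
#'   `objective_trace`, `iterations`, `converged`.
#' @export
mwk_means <- function(Y, K = 3L, gamma = 2, max_iter = 100L, tol = 1e-6) {
  if (inherits(Y, "od_features")) Y <- od_feature_matrix(Y)
  Y <- as.matrix(Y)
  if (gamma <= 1) stop("gamma must be > 1", call. = FALSE)
  n <- nrow(Y); M <- ncol(Y)
  C <- anomalous_init(Y, K)
  w <- rep(1 / M, M)
  cl <- integer(n)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- vapply(seq_len(K), function(k) mwk_dist(Y, C[k, ], w, gamma), numeric(n))
    cl_new <- max.col(-D, ties.method = "first")
    # re-seed empty clusters with the point farthest from its centroid
    for (k in which(tabulate(cl_new, K) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), cl_new)])
      message("re-seeding empty cluster ", k)
      cl_new[far] <- k
    }
    for (k in seq_len(K))
      C[k, ] <- colMeans(Y[cl_new == k, , drop = FALSE])
    E <- vapply(seq_len(M), function(v)
      sum(abs(Y[, v] - C[cl_new, v])^gamma), numeric(1))
    w <- mwk_weights(E, gamma)
    Fobj <- sum(vapply(seq_len(n), function(i)
      sum(w^gamma * abs(Y[i, ] - C[cl_new[i], ])^gamma), numeric(1)))
    trace <- c(trace, Fobj)
    stable <- identical(cl_new, cl)
    cl <- cl_new
    if (stable || (it > 1 && abs(trace[it - 1] - Fobj) < tol)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(cluster = cl, centroids = C, weights = w, gamma = gamma,
         dispersion = E, objective = trace[length(trace)],
         objective_trace = trace, iterations = length(trace),
         converged = converged, K = K, data = Y),
    class = "od_mwk"
  )
}

# Closed-form weight update; E_v = 0 receives the limiting maximal share.
mwk_weights <- function(E, gamma) {
  M <- length(E)
  if (any(E == 0)) {
    w <- as.numeric(E == 0)
    return(w / sum(w))
  }
  vapply(seq_len(M), function(v) 1 / sum((E[v] / E)^(1 / (gamma - 1))),
         numeric(1))
}

#' @export
print.od_mwk <- function(x, ...) {
  cat(sprintf("<od_mwk> K = %d, gamma = %g, F = %.5g (%d iterations%s)\n",
              x$K, x$gamma, x$objective, x$iterations,
              if (x$converged) ", converged" else ""))
  cat("weights:", sprintf("%.4f", x$weights), "\n")
  invisible(x)
}

#' @describeIn mwk_means one row per cluster: size, per-feature centroid,
#'   within-cluster contribution to the objective.
#' @param x,object an `od_mwk` fit.
#' @export
tidy.od_mwk <- function(x, ...) {
  K <- x$K
  withinss <- vapply(seq_len(K), function(k) {
    idx <- x$cluster == k
    sum(x$weights^x$gamma *
          abs(x$data[idx, , drop = FALSE] -
                matrix(x$centroids[k, ], sum(idx), ncol(x$data), byrow = TRUE))^x$gamma)
  }, numeric(1))
  out <- tibble::as_tibble(x$centroids, .name_repair = "minimal")
  names(out) <- colnames(x$data) %||% paste0("feature", seq_len(ncol(x$data)))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(K), size = tabulate(x$cluster, K)),
    out,
    tibble::tibble(withinss = withinss)
  )
}

#' @describeIn mwk_means one-row summary: objective, iterations, gamma and the
#'   learned feature weights.
#' @export
glance.od_mwk <- function(x, ...) {
  w <- setNames(as.list(x$weights), paste0("w", seq_along(x$weights)))
  dplyr::bind_cols(
    tibble::tibble(objective = x$objective, iterations = x$iterations,
                   converged = x$converged, gamma = x$gamma, K = x$K),
    tibble::as_tibble(w)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Silhouette-based selection of the Minkowski exponent
#'
#' Runs [mwk_means()] for each candidate exponent and returns the gamma whose
#' clustering maximizes the mean silhouette width, computed with the weighted
#' Minkowski distance of that fit. Ties go to the smallest candidate; if no
#' candidate yields a defined silhouette, gamma = 2 is returned.
#'
#' @param Y feature matrix or `od_features` tibble.
#' @param candidates candidate exponents (> 1).
#' @param K cluster count.
#' @param max_iter,tol passed to [mwk_means()].
#' @return A list: `gamma`, `silhouette` (per-candidate tibble), `fit` (the
#'   winning `od_mwk`).
#' @export
select_gamma <- function(Y, candidates = c(1.5, 2, 2.5, 3), K = 3L,
                         max_iter = 100L, tol = 1e-6) {
  if (!length(candidates) || any(candidates <= 1))
    stop("candidates must be > 1", call. = FALSE)
  if (inherits(Y, "od_features")) Y <- od_feature_matrix(Y)
  candidates <- sort(candidates)
  fits <- lapply(candidates, function(g)
    mwk_means(Y, K = K, gamma = g, max_iter = max_iter, tol = tol))
  sil <- vapply(fits, function(fit) {
    if (length(unique(fit$cluster)) < 2L) return(NA_real_)
    D <- minkowski_dist_matrix(Y, fit$weights, fit$gamma)
    mean(cluster::silhouette(fit$cluster, dmatrix = D)[, "sil_width"])
  }, numeric(1))
  tbl <- tibble::tibble(gamma = candidates, mean_silhouette = sil)
  if (all(is.na(sil))) {
    message("silhouette undefined for all candidates; defaulting to gamma = 2")
    return(list(gamma = 2, silhouette = tbl,
                fit = mwk_means(Y, K = K, gamma = 2, max_iter = max_iter, tol = tol)))
  }
  best <- which.max(sil)   # first maximum -> smallest gamma on ties
  list(gamma = candidates[best], silhouette = tbl, fit = fits[[best]])
}

# Full pairwise weighted Minkowski distance matrix.
minkowski_dist_matrix <- function(Y, w, gamma) {
  n <- nrow(Y)
  D <- matrix(0, n, n)
  for (v in seq_len(ncol(Y))) {
    D <- D + w[v]^gamma * abs(outer(Y[, v], Y[, v], "-"))^gamma
  }
  D
}

#' Score patches by the weighted feature combination
#'
#' `L_i = w1 * MaxCoeff_i^(10) + w2 * MaxCoeff_i^(20) + w3 * H_i` on the
#' normalized features; the winning patch is the argmax (ties resolved to the
#' lowest patch index).
#'
#' @param features an `od_features` tibble from [assemble_features()].
#' @param weights length-3 nonnegative weights; `NULL` means uniform 1/3
#'   (the non-adaptive variant).
#' @return A tibble of class `od_scores` with `patch` and `score`; attributes
#'   `patch_max` and `weights`.
#' @export
score_patches <- function(features, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / 3, 3)
  if (length(weights) != 3 || any(weights < 0))
    stop("weights must be 3 nonnegative numbers", call. = FALSE)
  if (sum(weights) == 0) stop("weights must not all be zero", call. = FALSE)
  Z <- od_feature_matrix(features)
  L <- as.vector(Z %*% weights)
  out <- tibble::tibble(patch = features$patch, score = L)
  attr(out, "patch_max") <- which.max(L)
  attr(out, "weights") <- weights
  class(out) <- c("od_scores", class(out))
  out
}

#' Locate the optic-disc center inside the winning patch
#'
#' The center is the maximum-intensity pixel of the enhanced grayscale image
#' restricted to the winning patch (ties: first in row-major scan).
#'
#' @param scores an `od_scores` tibble from [score_patches()].
#' @param gray the enhanced grayscale matrix.
#' @param grid the [patch_grid()] used throughout.
#' @param scale_factor ratio mapping analysis coordinates to the original
#'   resolution.
#' @return A list of class `od_center`: `x`, `y` (1-based, analysis
#'   resolution), `x_original`, `y_original`, `patch_max`, `weights`.
#' @export
locate_center <- function(scores, gray, grid = patch_grid(), scale_factor = 1) {
  i <- attr(scores, "patch_max")
  stopifnot(!is.null(i))
  b <- grid[grid$patch == i, ]
  sub <- gray[b$y0:b$y1, b$x0:b$x1]
  # first maximum in row-major (by-row) scan order
  idx <- which(t(sub) == max(sub), arr.ind = TRUE)[1, ]
  x <- b$x0 + idx[1] - 1L
  y <- b$y0 + idx[2] - 1L
  structure(
    list(x = unname(x), y = unname(y),
         x_original = unname(x * scale_factor), y_original = unname(y * scale_factor),
         patch_max = i, weights = attr(scores, "weights")),
    class = "od_center"
  )
}

#' @export
print.od_center <- function(x, ...) {
  cat(sprintf("<od_center> (x = %d, y = %d) in patch %d\n",
              round(x$x), round(x$y), x$patch_max))
  invisible(x)
}
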