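# Evaluation metrics: normalized center distance, Dice, Jaccard (IoU).

#' Normalized Euclidean distance between two center points
#'
#' `sqrt((x2 - x1)^2 + (y2 - y1)^2) / sqrt(W^2 + H^2)` — the localization
#' error as a fraction of the image diagonal.
#'
#' @param gt,pred numeric `c(x, y)` points.
#' @param W,H image width and height.
#' @return A value in \[0, 1\] for points inside the image.
#' @export
normalized_distance <- function(gt, pred, W, H) {
  stopifnot(W > 0, H > 0)
  sqrt(sum((as.numeric(pred) - as.numeric(gt))^2)) / sqrt(W^2 + H^2)
}

#' Overlap metrics between binary masks
#'
#' `dice(A, B) = 2 |A ∩ B| / (|A| + |B|)`;
#' `iou(A, B) = |A ∩ B| / |A ∪ B|` (Jaccard index). When both masks are
#' empty the overlap is defined as 1.
#'
#' @param A,B binary matrices of identical dimensions.
#' @return A scalar in \[0, 1\].
#' @export
dice <- function(A, B) {
  ab <- overlap_counts(A, B)
  if (ab$sa + ab$sb == 0) return(1)
  2 * ab$inter / (ab$sa + ab$sb)
}

#' @rdname dice
#' @export
iou <- function(A, B) {
  ab <- overlap_counts(A, B)
  uni <- ab$sa + ab$sb - ab$inter
  if (uni == 0) return(1)
  ab$inter / uni
}

overlap_counts <- function(A, B) {
  if (!identical(dim(A), dim(B)))
    stop("mask dimensions differ", call. = FALSE)
  a <- A > 0; b <- B > 0
  list(inter = sum(a & b), sa = sum(a), sb = sum(b))
}

#' Summarize per-image evaluation records
#'
#' @param records a tibble/data.frame with one row per image and numeric
#'   metric columns (e.g. `norm_distance`, `dice`, `iou`).
#' @param population_sd use the population standard deviation (divide by n,
#'   the default) rather than the sample one.
#' @return A tibble with one row per metric: `metric`, `mean`, `median`,
#'   `std_dev`, `max`, `min`.
#' @export
summarize_metrics <- function(records, population_sd = TRUE) {
  if (!nrow(records)) stop("no evaluation records", call. = FALSE)
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  num <- setdiff(num, c("image_id", "patch"))
  sdev <- function(x) {
    s <- stats::sd(x)
    if (is.na(s)) s <- 0
    if (population_sd) s * sqrt((length(x) - 1) / length(x)) else s
  }
  purrr::map_dfr(num, function(m) {
    x <- records[[m]]
    tibble::tibble(metric = m, mean = mean(x), median = stats::median(x),
                   std_dev = if (length(x) > 1) sdev(x) else 0,
                   max = max(x), min = min(x))
  })
}
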