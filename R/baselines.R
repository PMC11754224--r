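#' Statistical Outlier Removal (SOR)
#'
#' The classical filter: compute each point's mean distance to its `k`
#' nearest neighbors, then remove the points whose mean distance exceeds
#' `global mean + n_sigma * global standard deviation` of those values.
#' Deterministic; kept points preserve their input order and coordinates.
#'
#' @param cloud A [point_cloud()].
#' @param k Neighborhood size, `< n`.
#' @param n_sigma Threshold in standard deviations (default 1).
#' @return A `filter_result`: list with `kept` (a `point_cloud`) and
#'   `removed_indices` (indices into the input).
#' @export
sor_filter <- function(cloud, k = 8L, n_sigma = 1) {
  stopifnot(is_point_cloud(cloud))
  n <- nrow(cloud)
  k <- check_count(k, "k")
  if (k >= n) stopf("k = %d must be < n = %d", k, n)
  n_sigma <- check_scalar(n_sigma, "n_sigma")
  pts <- as_matrix(cloud)
  nb <- knn_brute(pts, pts, k, exclude = seq_len(n))
  d <- sqrt(matrix(rowSums((pts[as.vector(nb), , drop = FALSE] -
                              pts[rep.int(seq_len(n), k), , drop = FALSE])^2), n, k))
  mean_d <- rowMeans(d)
  thr <- mean(mean_d) + n_sigma * stats::sd(mean_d)
  removed <- which(mean_d > thr)
  new_filter_result(cloud, removed)
}

#' Radius Outlier Removal (ROR)
#'
#' Removes points that have fewer than `min_neighbors` other points within
#' `radius`. Increasing `min_neighbors` (or shrinking `radius`) can only
#' grow the removed set.
#'
#' @param cloud A [point_cloud()].
#' @param radius Search radius, `> 0` (cloud units).
#' @param min_neighbors Minimum neighbor count to survive (default 2).
#' @return A `filter_result` (see [sor_filter()]).
#' @export
ror_filter <- function(cloud, radius, min_neighbors = 2L) {
  stopifnot(is_point_cloud(cloud))
  radius <- check_scalar(radius, "radius")
  if (radius <= 0) stopf("radius must be positive")
  min_neighbors <- check_count(min_neighbors, "min_neighbors", min = 0L)
  pts <- as_matrix(cloud)
  n <- nrow(pts)
  r2 <- radius^2
  counts <- integer(n)
  for (start in seq(1L, n, by = 2048L)) {
    idx <- start:min(start + 2047L, n)
    d2 <- cross_sqdist(pts[idx, , drop = FALSE], pts)
    counts[idx] <- rowSums(d2 <= r2) - 1L  # self always within radius
  }
  removed <- which(counts < min_neighbors)
  new_filter_result(cloud, removed)
}

new_filter_result <- function(cloud, removed) {
  kept <- if (length(removed) > 0) {
    keep <- setdiff(seq_len(nrow(cloud)), removed)
    new_point_cloud(tibble::as_tibble(cloud[keep, , drop = FALSE]),
                    frame = pc_frame(cloud), norm = pc_norm(cloud))
  } else {
    cloud
  }
  structure(list(kept = kept, removed_indices = as.integer(removed)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> kept %d, removed %d\n",
              nrow(x$kept), length(x$removed_indices)))
  invisible(x)
}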