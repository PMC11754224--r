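#' Point clouds as tibbles
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` (one row per
#' point; meters in the `"raw"` frame, unitless in the `"normalized"` frame)
#' plus any number of extra per-point attribute columns (intensity, labels,
#' ...) that every operation carries through untouched. Two attributes ride
#' along: `frame` (`"raw"` or `"normalized"`) and, for normalized clouds, the
#' normalization record (`centroid`, `scale`) needed to restore raw
#' coordinates. Point order is meaningful — every operation in the package
#' preserves it — because noise injection, displacement prediction and paired
#' metrics all align clouds index-wise.
#'
#' @param points A numeric matrix or data frame with at least 3 columns
#'   (x, y, z); extra data-frame columns become per-point attributes.
#' @param frame `"raw"` (default) or `"normalized"`.
#' @param norm A normalization record `list(centroid =, scale =)`; required
#'   when `frame = "normalized"`.
#' @return A `point_cloud` tibble.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' pc_frame(pc)
#' @export
point_cloud <- function(points, frame = c("raw", "normalized"), norm = NULL) {
  frame <- match.arg(frame)
  if (is.matrix(points)) {
    if (ncol(points) < 3L) stopf("point matrix must have >= 3 columns")
    df <- tibble::tibble(x = as.double(points[, 1]),
                         y = as.double(points[, 2]),
                         z = as.double(points[, 3]))
    if (ncol(points) > 3L) {
      extra <- points[, -(1:3), drop = FALSE]
      cn <- colnames(extra) %||% paste0("attr", seq_len(ncol(extra)))
      cn[cn == ""] <- paste0("attr", which(cn == ""))
      for (j in seq_len(ncol(extra))) df[[cn[j]]] <- as.double(extra[, j])
    }
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points))) {
      stopf("point data frame must have columns x, y, z")
    }
    df <- tibble::as_tibble(points)
    df <- df[, c("x", "y", "z", setdiff(names(df), c("x", "y", "z")))]
  } else {
    stopf("`points` must be a matrix or data frame")
  }
  new_point_cloud(df, frame = frame, norm = norm)
}

new_point_cloud <- function(df, frame, norm = NULL) {
  n <- nrow(df)
  if (n < 1L) stopf("a point cloud needs at least one point", class = "pcdenoise_empty")
  xyz <- cbind(df$x, df$y, df$z)
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))[1]
    stopf("non-finite coordinate at point %d", bad)
  }
  if (frame == "normalized") {
    if (is.null(norm)) stopf("normalized clouds require a normalization record")
    norm <- validate_norm(norm)
  } else {
    norm <- NULL
  }
  structure(df,
            class = c("point_cloud", class(tibble::tibble())),
            pc_frame = frame, pc_norm = norm)
}

validate_norm <- function(norm) {
  if (!is.list(norm) || is.null(norm$centroid) || is.null(norm$scale)) {
    stopf("normalization record must be list(centroid =, scale =)")
  }
  centroid <- as.double(norm$centroid)
  scale <- as.double(norm$scale)
  if (length(centroid) != 3L || !all(is.finite(centroid))) {
    stopf("normalization centroid must be a finite 3-vector")
  }
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stopf("normalization scale must be a positive scalar")
  }
  list(centroid = centroid, scale = scale)
}

#' @rdname point_cloud
#' @param cloud A `point_cloud`.
#' @export
is_point_cloud <- function(cloud) inherits(cloud, "point_cloud")

#' @rdname point_cloud
#' @export
pc_frame <- function(cloud) attr(cloud, "pc_frame") %||% "raw"

#' @rdname point_cloud
#' @export
pc_norm <- function(cloud) attr(cloud, "pc_norm")

#' @rdname point_cloud
#' @export
as_matrix <- function(cloud) {
  stopifnot(is_point_cloud(cloud) || is.data.frame(cloud))
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

# Rebuild a cloud from new coordinates, keeping attribute columns and metadata.
pc_replace_coords <- function(cloud, xyz, frame = pc_frame(cloud),
                              norm = pc_norm(cloud)) {
  df <- tibble::as_tibble(as.data.frame(unclass(cloud), stringsAsFactors = FALSE))
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  new_point_cloud(df, frame = frame, norm = norm)
}

#' @export
print.point_cloud <- function(x, ...) {
  fr <- pc_frame(x)
  cat(sprintf("# A point cloud: %d points, frame = %s\n", nrow(x), fr))
  if (fr == "normalized") {
    nr <- pc_norm(x)
    cat(sprintf("# centroid (%.4g, %.4g, %.4g), scale %.4g\n",
                nr$centroid[1], nr$centroid[2], nr$centroid[3], nr$scale))
  }
  NextMethod()
  invisible(x)
}

#' Normalize a point cloud to the unit sphere
#'
#' Centers the cloud at its centroid and divides by the maximum distance from
#' the centroid, so the result fits exactly in the unit sphere (max radius 1).
#' The centroid and scale are stored on the returned cloud so
#' [denormalize_cloud()] can restore raw coordinates exactly. Unit-sphere
#' normalization makes noise levels interpretable as fractions of the object
#' radius and is assumed by [inject_noise()] and the network input contract.
#'
#' @param cloud A raw-frame `point_cloud` whose points are not all identical.
#' @return A normalized-frame `point_cloud`, same point order.
#' @seealso [denormalize_cloud()]
#' @export
normalize_cloud <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  if (pc_frame(cloud) != "raw") stopf("cloud is already normalized")
  xyz <- as_matrix(cloud)
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  scale <- sqrt(max(rowSums(centered^2)))
  if (scale == 0) {
    stopf("all points coincide; normalization scale would be zero",
          class = "pcdenoise_degenerate")
  }
  pc_replace_coords(cloud, centered / scale, frame = "normalized",
                    norm = list(centroid = centroid, scale = scale))
}

#' Restore raw coordinates of a normalized cloud
#'
#' Inverts [normalize_cloud()] using the stored record: `p * scale + centroid`.
#'
#' @param cloud A normalized-frame `point_cloud` carrying its record.
#' @return A raw-frame `point_cloud`, same point order.
#' @export
denormalize_cloud <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  if (pc_frame(cloud) != "normalized") stopf("cloud is not in the normalized frame")
  nr <- pc_norm(cloud)
  if (is.null(nr)) stopf("normalized cloud is missing its normalization record")
  xyz <- sweep(as_matrix(cloud) * nr$scale, 2, nr$centroid, "+")
  pc_replace_coords(cloud, xyz, frame = "raw", norm = NULL)
}

#' Subsample a cloud to a fixed number of points
#'
#' Draws exactly `n_out` points by one of three strategies:
#' * `"random"` — a uniform subset.
#' * `"fps"` — farthest-point sampling from a seed-chosen start index
#'   (greedily adds the point farthest from the selected set, spreading the
#'   subset over the object surface).
#' * `"patch"` — a spatially contiguous region: a seed-chosen point plus its
#'   `n_out - 1` nearest neighbors. Unlike the other two, a patch preserves
#'   the cloud's full local point density, which is what the denoiser's
#'   k-NN features see at inference time — training therefore uses patches.
#'
#' All strategies are deterministic given `seed` and preserve the original
#' relative point order in the output.
#'
#' @param cloud A `point_cloud`.
#' @param n_out Number of points to keep (`1 <= n_out <= n`).
#' @param strategy `"random"`, `"fps"` or `"patch"`.
#' @param seed Integer seed.
#' @return A `point_cloud` with `n_out` rows (a subset of the input rows).
#' @export
sample_fixed <- function(cloud, n_out, strategy = c("random", "fps", "patch"),
                         seed = 1L) {
  stopifnot(is_point_cloud(cloud))
  strategy <- match.arg(strategy)
  n <- nrow(cloud)
  n_out <- check_count(n_out, "n_out", min = 1L)
  if (n_out > n) stopf("n_out = %d exceeds cloud size %d", n_out, n)
  keep <- if (n_out == n) {
    seq_len(n)
  } else if (strategy == "random") {
    withr::with_seed(as.integer(seed), sample.int(n, n_out))
  } else if (strategy == "patch") {
    xyz <- as_matrix(cloud)
    center <- withr::with_seed(as.integer(seed), sample.int(n, 1L))
    as.vector(knn_brute(xyz[center, , drop = FALSE], xyz, n_out))
  } else {
    fps_indices(as_matrix(cloud), n_out, seed = as.integer(seed))
  }
  keep <- sort(keep)
  out <- cloud[keep, , drop = FALSE]
  new_point_cloud(tibble::as_tibble(out), frame = pc_frame(cloud),
                  norm = pc_norm(cloud))
}

fps_indices <- function(xyz, n_out, seed) {
  n <- nrow(xyz)
  start <- withr::with_seed(seed, sample.int(n, 1L))
  chosen <- integer(n_out)
  chosen[1] <- start
  mind2 <- rowSums(sweep(xyz, 2, xyz[start, ])^2)
  if (n_out > 1L) {
    for (i in 2:n_out) {
      nxt <- which.max(mind2)
      chosen[i] <- nxt
      d2 <- rowSums(sweep(xyz, 2, xyz[nxt, ])^2)
      mind2 <- pmin(mind2, d2)
    }
  }
  chosen
}
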