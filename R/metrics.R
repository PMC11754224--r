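#' Point correspondence between two clouds
#'
#' Metrics that compare clouds point-by-point need a mapping from estimate
#' points to reference points. `"paired"` is the identity mapping (requires
#' equal point counts and meaningful shared order — the case for denoising,
#' which preserves order). `"nearest"` maps each estimate point to its
#' nearest reference point (ties to the lower index).
#'
#' @param reference,estimate `point_cloud`s (or n x 3 matrices).
#' @param mode `"paired"` or `"nearest"`.
#' @return A `correspondence`: list with `mode` and `mapping` (index into the
#'   reference, one per estimate point).
#' @export
build_correspondence <- function(reference, estimate, mode = c("paired", "nearest")) {
  mode <- match.arg(mode)
  ref <- if (is_point_cloud(reference)) as_matrix(reference) else reference
  est <- if (is_point_cloud(estimate)) as_matrix(estimate) else estimate
  mapping <- if (mode == "paired") {
    if (nrow(ref) != nrow(est)) {
      stopf("paired correspondence needs equal point counts (%d vs %d)",
            nrow(ref), nrow(est))
    }
    seq_len(nrow(est))
  } else {
    as.vector(knn_brute(est, ref, 1L))
  }
  structure(list(mode = mode, mapping = mapping), class = "correspondence")
}

#' Point-cloud mean squared error
#'
#' Mean over corresponding point pairs of the squared Euclidean distance
#' (the full 3-D vector residual, not per coordinate).
#'
#' @inheritParams build_correspondence
#' @param corr A [build_correspondence()] result (default: paired).
#' @return Non-negative scalar.
#' @export
pc_mse <- function(reference, estimate, corr = NULL) {
  ref <- if (is_point_cloud(reference)) as_matrix(reference) else reference
  est <- if (is_point_cloud(estimate)) as_matrix(estimate) else estimate
  corr <- corr %||% build_correspondence(ref, est, "paired")
  mean(rowSums((est - ref[corr$mapping, , drop = FALSE])^2))
}

#' Point-cloud signal-to-noise ratio (dB)
#'
#' `10 * log10(Ps / Pn)` with signal power `Ps` the mean squared point norm
#' of the reference in its frame, and noise power `Pn` the [pc_mse()] of the
#' pair. Returns `Inf` when the residual is exactly zero. Because `Ps`
#' depends on the coordinate frame (raw georeferenced coordinates have huge
#' norms), the frame used should be reported alongside the value — the
#' [evaluate_denoising()] report does this.
#'
#' @inheritParams pc_mse
#' @return Scalar in decibels (possibly `Inf`).
#' @export
pc_snr <- function(reference, estimate, corr = NULL) {
  ref <- if (is_point_cloud(reference)) as_matrix(reference) else reference
  ps <- mean(rowSums(ref^2))
  pn <- pc_mse(reference, estimate, corr)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' One-way (forward) Hausdorff distance
#'
#' `max over a in A of min over b in B of ||a - b||` — the worst-case
#' distance from A into B, in the clouds' coordinate units (not squared).
#' The symmetric variant [hausdorff_distance()] is the max of both
#' directions.
#'
#' @param A,B Non-empty `point_cloud`s (or n x 3 matrices).
#' @return Non-negative scalar.
#' @export
hausdorff_oneway <- function(A, B) {
  a <- if (is_point_cloud(A)) as_matrix(A) else A
  b <- if (is_point_cloud(B)) as_matrix(B) else B
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("empty point set")
  # direct (a - b)^2 arithmetic, not the expanded-norm shortcut, so the
  # result is bit-identical to a naive double-loop scan
  tb <- t(b)
  worst <- 0
  for (i in seq_len(nrow(a))) {
    worst <- max(worst, min(colSums((tb - a[i, ])^2)))
  }
  sqrt(worst)
}

#' @rdname hausdorff_oneway
#' @export
hausdorff_distance <- function(A, B) {
  max(hausdorff_oneway(A, B), hausdorff_oneway(B, A))
}

#' Neighborhood-based 3D structural similarity
#'
#' An SSIM adapted from images to point sets without voxelization. For each
#' correspondence pair, the local "signal" of a point is the sorted vector of
#' distances from its `k_ssim` nearest neighbors (within its own cloud) to
#' their centroid — a rotation- and translation-invariant description of the
#' local point arrangement. The two matched signal vectors enter the standard
#' SSIM ratio with `C1 = (K1 * L_range)^2`, `C2 = (K2 * L_range)^2`, and the
#' mean local SSIM over all pairs is returned. `ssim3d(X, X)` is exactly 1,
#' and a rigid translation of the estimate leaves the score at 1.
#'
#' @inheritParams pc_mse
#' @param k_ssim Neighborhood size (default 16), `< n`.
#' @param K1,K2 SSIM stabilization constants (image-processing convention
#'   0.01 and 0.03).
#' @param L_range Dynamic range of the signal; default: the reference
#'   bounding-box diagonal.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim3d <- function(reference, estimate, corr = NULL, k_ssim = 16L,
                   K1 = 0.01, K2 = 0.03, L_range = NULL) {
  ref <- if (is_point_cloud(reference)) as_matrix(reference) else reference
  est <- if (is_point_cloud(estimate)) as_matrix(estimate) else estimate
  corr <- corr %||% build_correspondence(ref, est, "paired")
  k_ssim <- check_count(k_ssim, "k_ssim")
  if (k_ssim >= nrow(ref) || k_ssim >= nrow(est)) {
    stopf("k_ssim = %d must be smaller than both cloud sizes", k_ssim)
  }
  L_range <- L_range %||% sqrt(sum((apply(ref, 2, max) - apply(ref, 2, min))^2))
  if (L_range <= 0) stopf("L_range must be positive")
  sig_ref <- local_signals(ref, k_ssim)[corr$mapping, , drop = FALSE]
  sig_est <- local_signals(est, k_ssim)
  c1 <- (K1 * L_range)^2
  c2 <- (K2 * L_range)^2
  mu_x <- rowMeans(sig_ref); mu_y <- rowMeans(sig_est)
  var_x <- rowMeans(sig_ref^2) - mu_x^2
  var_y <- rowMeans(sig_est^2) - mu_y^2
  cov_xy <- rowMeans(sig_ref * sig_est) - mu_x * mu_y
  ssim <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean(ssim)
}

# Sorted centroid-relative neighbor-distance vectors, one row per point.
local_signals <- function(pts, k) {
  nb <- knn_brute(pts, pts, k, exclude = seq_len(nrow(pts)))
  n <- nrow(pts)
  out <- matrix(0, n, k)
  nbp <- pts[as.vector(nb), , drop = FALSE]
  dim(nbp) <- c(n, k, 3L)
  cen <- apply(nbp, c(1L, 3L), mean)
  for (j in seq_len(k)) {
    out[, j] <- sqrt(rowSums((nbp[, j, ] - cen)^2))
  }
  t(apply(out, 1L, sort))
}

#' Metric report for a denoising result
#'
#' Computes the four-metric quartet (MSE, SNR in dB, one-way Hausdorff from
#' the estimate into the reference, 3D SSIM) for the noisy and the denoised
#' cloud against the same reference, with identical settings, and returns
#' them as a two-row tibble (`cloud = "noisy" / "denoised"`). The settings
#' used (correspondence mode, `k_ssim`, `K1`, `K2`, `L_range`, frame) are
#' recorded in the `"settings"` attribute and embedded when serialized with
#' [report_json()].
#'
#' @param reference Clean/reference `point_cloud`.
#' @param noisy,denoised Clouds to score (same frame as the reference).
#' @param corr_mode `"paired"` or `"nearest"`.
#' @param k_ssim,K1,K2,L_range Passed to [ssim3d()].
#' @return A `metric_report` tibble.
#' @export
evaluate_denoising <- function(reference, noisy, denoised,
                               corr_mode = c("paired", "nearest"),
                               k_ssim = 16L, K1 = 0.01, K2 = 0.03,
                               L_range = NULL) {
  corr_mode <- match.arg(corr_mode)
  frames <- c(pc_frame(reference), pc_frame(noisy), pc_frame(denoised))
  if (length(unique(frames)) != 1L) {
    stopf("frame mismatch: reference %s, noisy %s, denoised %s",
          frames[1], frames[2], frames[3])
  }
  ref <- as_matrix(reference)
  L_range <- L_range %||% sqrt(sum((apply(ref, 2, max) - apply(ref, 2, min))^2))
  score <- function(est) {
    corr <- build_correspondence(reference, est, corr_mode)
    tibble::tibble(mse = pc_mse(reference, est, corr),
                   snr_db = pc_snr(reference, est, corr),
                   hausdorff = hausdorff_oneway(est, reference),
                   ssim = ssim3d(reference, est, corr, k_ssim = k_ssim,
                                 K1 = K1, K2 = K2, L_range = L_range))
  }
  rep <- dplyr::bind_rows(noisy = score(noisy), denoised = score(denoised),
                          .id = "cloud")
  structure(rep,
            class = c("metric_report", class(tibble::tibble())),
            settings = list(corr_mode = corr_mode, k_ssim = k_ssim, K1 = K1,
                            K2 = K2, L_range = L_range, frame = frames[1]))
}

#' @rdname evaluate_denoising
#' @param report A `metric_report`.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(list(metrics = as.data.frame(report),
                        settings = attr(report, "settings")),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Batch evaluation over many clouds
#'
#' Applies [evaluate_denoising()] to each (reference, noisy, denoised)
#' triple and appends mean and standard-deviation summary rows per cloud
#' type, mirroring the mean/std reporting convention of plot-level
#' evaluations.
#'
#' @param references,noisies,denoiseds Lists of clouds, same length.
#' @param ... Passed to [evaluate_denoising()].
#' @return A tibble with columns `id`, `cloud`, the four metrics; summary
#'   rows carry `id = "_mean"` / `"_std"`.
#' @export
evaluate_many <- function(references, noisies, denoiseds, ...) {
  stopifnot(length(references) == length(noisies),
            length(noisies) == length(denoiseds))
  rows <- purrr::map(seq_along(references), function(i) {
    r <- evaluate_denoising(references[[i]], noisies[[i]], denoiseds[[i]], ...)
    dplyr::mutate(tibble::as_tibble(r), id = as.character(i), .before = 1L)
  })
  body <- dplyr::bind_rows(rows)
  summ <- body |>
    dplyr::group_by(.data$cloud) |>
    dplyr::summarise(dplyr::across(c("mse", "snr_db", "hausdorff", "ssim"),
                                   list(mean = mean, std = stats::sd))) |>
    tidyr_pivot()
  dplyr::bind_rows(body, summ)
}

# Long-format mean/std footer rows without importing tidyr for one call.
tidyr_pivot <- function(s) {
  out <- list()
  for (stat in c("mean", "std")) {
    cols <- paste0(c("mse", "snr_db", "hausdorff", "ssim"), "_", stat)
    d <- s[, c("cloud", cols)]
    names(d) <- c("cloud", "mse", "snr_db", "hausdorff", "ssim")
    d$id <- paste0("_", stat)
    out[[stat]] <- d[, c("id", "cloud", "mse", "snr_db", "hausdorff", "ssim")]
  }
  dplyr::bind_rows(out)
}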